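#' Load the 30-compound reference dataset
#'
#' Reads the curated table of 30 organic micropollutants and single-ring
#' aromatics studied under TiO2 photocatalysis: identity (name, abbreviation,
#' CAS), a curated parent-structure SMILES, the train/test split used for
#' model building, the measured K coefficient (ratio of the hydroxyl-radical
#' to superoxide degradation shares) and its transformed value
#' `tK = (K + 1)^(-1/2)`. Salts in the original sourcing (sodium,
#' hydrochloride) are stripped to the parent neutral organic.
#'
#' Validation enforces the published design: 30 rows, unique abbreviations,
#' well-formed CAS numbers, 25 train / 5 test, and consistency of the
#' transformed response with [transform_response()] to within 5e-4.
#'
#' @param path CSV file with columns
#'   `index,name,abbr,cas,smiles,split,K,tK`. Defaults to the packaged
#'   reference dataset.
#' @return A tibble with one row per compound.
#' @examples
#' \dontrun{
#' compounds <- load_compounds()
#' dplyr::count(compounds, split)
#' }
#' @export
load_compounds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_compounds.csv",
                        package = "redoxsar", mustWork = TRUE)
  }
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   check.names = FALSE))
  required <- c("index", "name", "abbr", "cas", "smiles", "split", "K", "tK")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_compounds(df)
  df
}

validate_compounds <- function(df) {
  if (nrow(df) != 30L) {
    abort(paste0("expected 30 compounds, found ", nrow(df)))
  }
  if (anyDuplicated(df$abbr)) {
    abort(paste0("duplicate abbreviations: ",
                 paste(unique(df$abbr[duplicated(df$abbr)]), collapse = ", ")))
  }
  bad_cas <- df$abbr[!grepl("^\\d{2,7}-\\d{2}-\\d$", df$cas)]
  if (length(bad_cas)) {
    abort(paste0("malformed CAS for: ", paste(bad_cas, collapse = ", ")))
  }
  if (!all(df$split %in% c("train", "test"))) {
    abort("split labels must be 'train' or 'test'")
  }
  n_train <- sum(df$split == "train")
  n_test <- sum(df$split == "test")
  if (n_train != 25L || n_test != 5L) {
    abort(paste0("split must be 25 train / 5 test, found ",
                 n_train, "/", n_test))
  }
  if (any(df$K < 0)) abort("K coefficients must be non-negative")
  # printed-precision consistency: both K and tK columns are rounded to 3
  # decimals, so the recomputed transform can differ from the printed value
  # by up to half an ulp of tK plus the propagated half-ulp of K (~7.5e-4)
  dev <- abs(transform_response(df$K) - df$tK)
  if (any(dev > 1e-3)) {
    abort(paste0("transformed response inconsistent with K for: ",
                 paste(df$abbr[dev > 5e-4], collapse = ", ")))
  }
  invisible(df)
}
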