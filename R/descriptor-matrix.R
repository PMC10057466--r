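# Descriptor-matrix assembly: name parsing, batch computation over a
# compound table, the 0.99 correlation pre-filter, and train-fitted min-max
# normalization.

#' Parse descriptor names into computation specs
#'
#' Recognized name forms: `MATS<k><w>` (Moran autocorrelation, lag 1-8,
#' weighting u/m/v/e/p), `Mor<t><w>` (3D-MoRSE, signal 1-32),
#' `CATS2D_<ll>_<T1><T2>` (pharmacophore pair at lag 00-09) and
#' `B<kk>[X-Y]` (binary atom pair at topological distance 1-10). Any other
#' name is treated as a surrogate column that must be supplied externally.
#'
#' @param names Character vector of descriptor names.
#' @return A tibble with columns `name`, `family`, `lag`, `scheme`,
#'   `elem_a`, `elem_b`, `pair`, `needs_3d`.
#' @export
parse_descriptor_spec <- function(names) {
  one <- function(nm) {
    if (grepl("^MATS([1-8])([umvep])$", nm)) {
      m <- regmatches(nm, regexec("^MATS([1-8])([umvep])$", nm))[[1]]
      return(tibble(name = nm, family = "MATS", lag = as.integer(m[2]),
                    scheme = m[3], elem_a = NA, elem_b = NA, pair = NA,
                    needs_3d = FALSE))
    }
    if (grepl("^Mor([0-9]{1,2})([umvep])$", nm)) {
      m <- regmatches(nm, regexec("^Mor([0-9]{1,2})([umvep])$", nm))[[1]]
      sig <- as.integer(m[2])
      if (sig >= 1 && sig <= 32) {
        return(tibble(name = nm, family = "MoRSE", lag = sig, scheme = m[3],
                      elem_a = NA, elem_b = NA, pair = NA, needs_3d = TRUE))
      }
    }
    if (grepl("^CATS2D_([0-9]{2})_([DAPNL])([DAPNL])$", nm)) {
      m <- regmatches(nm,
                      regexec("^CATS2D_([0-9]{2})_([DAPNL])([DAPNL])$", nm))[[1]]
      return(tibble(name = nm, family = "CATS2D", lag = as.integer(m[2]),
                    scheme = NA, elem_a = NA, elem_b = NA,
                    pair = paste0(m[3], m[4]), needs_3d = FALSE))
    }
    if (grepl("^B([0-9]{2})\\[([A-Za-z]{1,2})-([A-Za-z]{1,2})\\]$", nm)) {
      m <- regmatches(
        nm, regexec("^B([0-9]{2})\\[([A-Za-z]{1,2})-([A-Za-z]{1,2})\\]$", nm))[[1]]
      return(tibble(name = nm, family = "B0k", lag = as.integer(m[2]),
                    scheme = NA, elem_a = m[3], elem_b = m[4], pair = NA,
                    needs_3d = FALSE))
    }
    tibble(name = nm, family = "surrogate", lag = NA_integer_, scheme = NA,
           elem_a = NA, elem_b = NA, pair = NA, needs_3d = FALSE)
  }
  out <- dplyr::bind_rows(lapply(names, one))
  if (anyDuplicated(out$name)) abort("descriptor names must be unique")
  out
}

#' The five descriptors of the final degradation-mechanism model
#'
#' @return Character vector: MATS4v, Mor10u, CATS2D_01_DN, B04\[C-Cl\],
#'   B08\[C-O\].
#' @export
final_model_descriptors <- function() {
  c("MATS4v", "Mor10u", "CATS2D_01_DN", "B04[C-Cl]", "B08[C-O]")
}

#' Default descriptor grid
#'
#' A configurable grid over the four computed families: MATS lags 1-8 under
#' the m/v/e/p weights, 3D-MoRSE signals 1-32 unweighted and
#' volume-weighted, all 15 CATS2D type pairs at lags 0-9, and binary atom
#' pairs over C/N/O/S/Cl/F at distances 1-10.
#'
#' @return Character vector of descriptor names (several hundred).
#' @export
default_descriptor_grid <- function() {
  mats <- paste0("MATS", rep(1:8, each = 4), c("m", "v", "e", "p"))
  mor <- paste0("Mor", rep(1:32, each = 2), c("u", "v"))
  tp <- PPP_TYPES
  pairs <- c()
  for (i in seq_along(tp)) for (j in i:length(tp)) {
    pairs <- c(pairs, paste0(tp[i], tp[j]))
  }
  cats <- paste0("CATS2D_", sprintf("%02d", rep(0:9, each = length(pairs))),
                 "_", pairs)
  el <- c("C", "N", "O", "S", "Cl", "F")
  ep <- c()
  for (i in seq_along(el)) for (j in i:length(el)) {
    ep <- c(ep, paste0("[", el[i], "-", el[j], "]"))
  }
  b0k <- paste0("B", sprintf("%02d", rep(1:10, each = length(ep))), ep)
  c(mats, mor, cats, b0k)
}

#' Build graphs and seeded conformers for a compound table
#'
#' @param compounds Tibble with `abbr` and `smiles` columns.
#' @param seed Conformer embedding seed.
#' @param need_3d Embed conformers (skip for purely topological grids).
#' @return Named list (by `abbr`) of lists with `graph` and `conformer`.
#' @export
prepare_structures <- function(compounds, seed = 7L, need_3d = TRUE) {
  out <- vector("list", nrow(compounds))
  names(out) <- compounds$abbr
  for (i in seq_len(nrow(compounds))) {
    smi <- compounds$smiles[i]
    res <- tryCatch(
      list(graph = build_graph(smi),
           conformer = if (need_3d) embed_conformer(smi, seed = seed)),
      error = function(e) {
        abort(paste0("structure processing failed for ",
                     compounds$abbr[i], ": ", conditionMessage(e)))
      })
    out[[i]] <- res
  }
  out
}

#' Compute a descriptor matrix for a set of compounds
#'
#' Evaluates each named descriptor for each compound. Topological families
#' use the H-depleted graph; 3D-MoRSE uses a seed-deterministic
#' hydrogen-complete conformer, so the same seed always reproduces the same
#' matrix. Surrogate columns (names not matching a computed family, e.g.
#' quantum-chemical stand-ins) are taken from `surrogates`.
#'
#' @param compounds Tibble with `abbr` and `smiles` columns.
#' @param descriptors Character vector of descriptor names; defaults to the
#'   five final-model descriptors.
#' @param seed Conformer seed (only used when 3D descriptors are present).
#' @param structures Optional [prepare_structures()] result to reuse.
#' @param surrogates Optional tibble with `abbr` plus surrogate columns.
#' @return A tibble: `abbr` column plus one numeric column per descriptor,
#'   dense (no missing values).
#' @export
compute_descriptors <- function(compounds,
                                descriptors = final_model_descriptors(),
                                seed = 7L, structures = NULL,
                                surrogates = NULL) {
  spec <- parse_descriptor_spec(descriptors)
  surro <- spec$name[spec$family == "surrogate"]
  if (length(surro)) {
    if (is.null(surrogates) || !all(c("abbr", surro) %in% names(surrogates))) {
      abort(paste0("surrogate column(s) not supplied: ",
                   paste(surro, collapse = ", ")))
    }
  }
  comp_spec <- spec[spec$family != "surrogate", , drop = FALSE]
  if (is.null(structures)) {
    structures <- prepare_structures(compounds, seed = seed,
                                     need_3d = any(comp_spec$needs_3d))
  }
  vals <- matrix(NA_real_, nrow(compounds), nrow(comp_spec),
                 dimnames = list(compounds$abbr, comp_spec$name))
  for (i in seq_len(nrow(compounds))) {
    st <- structures[[compounds$abbr[i]]]
    types <- assign_ppp_types(st$graph)
    for (j in seq_len(nrow(comp_spec))) {
      s <- comp_spec[j, ]
      vals[i, j] <- switch(
        s$family,
        MATS = moran_autocorrelation(st$graph, s$lag, s$scheme),
        MoRSE = morse_descriptor(st$conformer, s$lag, s$scheme),
        CATS2D = cats2d(st$graph, s$lag, s$pair, types = types),
        B0k = atom_pair_presence(st$graph, s$elem_a, s$elem_b, s$lag)
      )
    }
  }
  out <- dplyr::bind_cols(tibble(abbr = compounds$abbr),
                          tibble::as_tibble(vals))
  if (length(surro)) {
    out <- left_join(out, surrogates[, c("abbr", surro)], by = "abbr")
  }
  out <- out[, c("abbr", descriptors)]
  if (anyNA(out)) abort("descriptor matrix contains missing values")
  out
}

descriptor_columns <- function(desc) setdiff(names(desc), "abbr")

#' Remove near-duplicate descriptor columns
#'
#' Greedy left-to-right scan: constant columns are dropped first, then any
#' column whose absolute Pearson correlation with an already-kept column
#' reaches the threshold is dropped (the earlier column is kept).
#'
#' @param desc Descriptor tibble (`abbr` + numeric columns).
#' @param r_threshold Absolute correlation threshold, default 0.99.
#' @return List with `data` (reduced tibble) and `removed` (tibble of
#'   `name`, `partner`, `r`, `reason`).
#' @export
prefilter_correlated <- function(desc, r_threshold = 0.99) {
  cols <- descriptor_columns(desc)
  removed <- tibble(name = character(), partner = character(),
                    r = numeric(), reason = character())
  sds <- map_dbl(cols, ~ sd(desc[[.x]]))
  const <- cols[sds == 0 | is.na(sds)]
  if (length(const)) {
    removed <- bind_rows(removed,
                         tibble(name = const, partner = NA_character_,
                                r = NA_real_, reason = "constant"))
  }
  cols <- setdiff(cols, const)
  kept <- character()
  for (cl in cols) {
    drop_for <- NULL
    for (k in kept) {
      r <- cor(desc[[cl]], desc[[k]])
      if (abs(r) >= r_threshold) { drop_for <- c(k, r); break }
    }
    if (is.null(drop_for)) {
      kept <- c(kept, cl)
    } else {
      removed <- bind_rows(removed,
                           tibble(name = cl, partner = drop_for[1],
                                  r = as.numeric(drop_for[2]),
                                  reason = "correlated"))
    }
  }
  list(data = desc[, c("abbr", kept)], removed = removed)
}

#' Min-max normalize a descriptor matrix on the training rows
#'
#' Per-column scaling `(x - min) / (max - min)` with the minimum and
#' maximum taken over the training rows only, applied to all rows (test
#' values may land outside `[0, 1]`). Columns constant on the training rows
#' map to 0 everywhere.
#'
#' @param desc Descriptor tibble (`abbr` + numeric columns).
#' @param train_ids `abbr` values of the training rows.
#' @return List with `data` (normalized tibble) and `scaler` (tibble of
#'   `name`, `min`, `max`), reusable via [apply_scaler()] /
#'   [denormalize()].
#' @export
normalize_descriptors <- function(desc, train_ids) {
  if (!all(train_ids %in% desc$abbr)) abort("train_ids not all present in data")
  cols <- descriptor_columns(desc)
  tr <- desc[desc$abbr %in% train_ids, , drop = FALSE]
  scaler <- tibble(
    name = cols,
    min = map_dbl(cols, ~ min(tr[[.x]])),
    max = map_dbl(cols, ~ max(tr[[.x]]))
  )
  list(data = apply_scaler(desc, scaler), scaler = scaler)
}

#' @rdname normalize_descriptors
#' @param scaler A scaler tibble from [normalize_descriptors()].
#' @export
apply_scaler <- function(desc, scaler) {
  out <- desc
  for (i in seq_len(nrow(scaler))) {
    nm <- scaler$name[i]
    rng <- scaler$max[i] - scaler$min[i]
    out[[nm]] <- if (rng == 0) rep(0, nrow(desc)) else
      (desc[[nm]] - scaler$min[i]) / rng
  }
  out
}

#' @rdname normalize_descriptors
#' @export
denormalize <- function(desc, scaler) {
  out <- desc
  for (i in seq_len(nrow(scaler))) {
    nm <- scaler$name[i]
    rng <- scaler$max[i] - scaler$min[i]
    out[[nm]] <- if (rng == 0) rep(scaler$min[i], nrow(desc)) else
      desc[[nm]] * rng + scaler$min[i]
  }
  out
}
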