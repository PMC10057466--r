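# Synthetic data with known ground truth: first-order scavenger kinetics
# traces for the K-coefficient pipeline, and descriptor matrices with a
# planted sparse linear response for selection/validation recovery tests.

#' Generate synthetic scavenger kinetics traces
#'
#' Emulates the photocatalytic experiment: a dark adsorption period
#' removing a fixed fraction, then first-order bulk decay whose rate
#' constant depends on the scavenger condition — `k_HO + k_O2` without
#' scavenger, `k_O2` with DMSO (hydroxyl pathway off), `k_HO` with BQ
#' (superoxide pathway off), and 0 with both scavengers. Scavenger
#' suppression is modeled as complete pathway shutdown (the scavengers are
#' dosed in 200-fold excess); `suppression` < 1 leaves that fraction of
#' the scavenged pathway active. Measurement noise is multiplicative
#' Gaussian (relative HPLC-type error), clipped at zero.
#'
#' @param k_HO,k_O2 First-order rate constants (1/min) of the hydroxyl and
#'   superoxide pathways.
#' @param ads_fraction Fraction adsorbed during the dark period, `[0, 1)`.
#' @param noise_sd Relative noise standard deviation.
#' @param c0 Initial concentration (mM).
#' @param schedule Sampling times (min); negative = dark period.
#' @param suppression Fraction of the targeted pathway actually suppressed
#'   by a scavenger (1 = complete shutdown).
#' @param compound Compound label for the traces.
#' @param seed RNG seed.
#' @return Tibble with columns `compound`, `condition`, `time_min`,
#'   `conc_mM`; attribute `truth` lists `K` (= `k_HO / k_O2`), the
#'   noiseless extent-ratio limit `K_extent`, the rates and
#'   `ads_fraction`.
#' @export
gen_kinetics <- function(k_HO = 0.08, k_O2 = 0.02, ads_fraction = 0,
                         noise_sd = 0.02, c0 = 0.05,
                         schedule = c(-20, -10, 0, 2.5, 5, 10, 15, 20),
                         suppression = 1, compound = "synth", seed = 1L) {
  if (k_HO < 0 || k_O2 < 0) abort("rate constants must be non-negative")
  if (k_HO == 0 && k_O2 == 0) abort("both pathway rates are zero: no degradation to generate")
  if (ads_fraction < 0 || ads_fraction >= 1) abort("ads_fraction must lie in [0, 1)")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  t_end <- max(schedule)
  rates <- c(none = k_HO + k_O2,
             dmso = k_O2 + (1 - suppression) * k_HO,
             bq = k_HO + (1 - suppression) * k_O2,
             both = (1 - suppression) * (k_HO + k_O2))
  dark_start <- min(schedule)
  clean <- function(k) {
    map_dbl(schedule, function(t) {
      if (t == dark_start) c0
      else if (t <= 0) c0 * (1 - ads_fraction)
      else c0 * (1 - ads_fraction) * exp(-k * t)
    })
  }
  traces <- with_local_seed(seed, function() {
    bind_rows(lapply(names(rates), function(cond) {
      conc <- clean(rates[[cond]])
      if (noise_sd > 0) {
        conc <- pmax(conc * (1 + rnorm(length(conc), 0, noise_sd)), 0)
      }
      tibble(compound = compound, condition = cond,
             time_min = schedule, conc_mM = conc)
    }))
  })
  attr(traces, "truth") <- list(
    K = k_HO / k_O2,
    K_extent = (1 - exp(-rates[["bq"]] * t_end)) /
      (1 - exp(-rates[["dmso"]] * t_end)),
    k_HO = k_HO, k_O2 = k_O2, ads_fraction = ads_fraction,
    noise_sd = noise_sd
  )
  traces
}

#' Generate a descriptor matrix with a planted sparse linear response
#'
#' Draws equicorrelated Gaussian descriptor columns plus a block of binary
#' columns (mimicking atom-pair / pharmacophore-count descriptors), picks
#' an active subset, and builds the response as an affine function of the
#' active columns rescaled into a band inside `(0, 1]` — so every response
#' value is the valid transform of a positive K coefficient — plus
#' Gaussian noise.
#'
#' @param n Number of rows (compounds).
#' @param p Number of Gaussian descriptor columns.
#' @param p_binary Number of additional binary columns.
#' @param n_active Size of the active subset (<= 5), drawn from the
#'   Gaussian columns.
#' @param correlation Equicorrelation level of the Gaussian columns,
#'   `[0, 1)`.
#' @param noise_sd Noise standard deviation on the transformed response.
#' @param band Range the noiseless response is mapped into.
#' @param seed RNG seed; the output is byte-identical per seed.
#' @return List with `data` (tibble: `abbr`, `t_response`, descriptor
#'   columns `X01`..., `B01`...) and `truth` (`active`, `beta` including
#'   intercept as first element, `noise_sd`).
#' @export
gen_qsar <- function(n = 30L, p = 12L, p_binary = 4L, n_active = 3L,
                     correlation = 0, noise_sd = 0.02,
                     band = c(0.35, 0.85), seed = 1L) {
  if (n_active > 5L) abort("active subset size must be at most 5")
  if (n_active > p) abort("more active columns than Gaussian columns")
  if (correlation < 0 || correlation >= 1) {
    abort("correlation must lie in [0, 1) for a positive-definite structure")
  }
  with_local_seed(seed, function() {
    Z <- matrix(rnorm(n * p), n, p)
    if (correlation > 0) {
      common <- rnorm(n)
      Z <- sqrt(1 - correlation) * Z + sqrt(correlation) * common
    }
    Xb <- matrix(rbinom(n * p_binary, 1, 0.5), n, p_binary)
    colnames(Z) <- sprintf("X%02d", seq_len(p))
    if (p_binary > 0) colnames(Xb) <- sprintf("B%02d", seq_len(p_binary))
    active <- sort(sample(colnames(Z), n_active))
    beta_raw <- runif(n_active, 0.5, 1.5) * sample(c(-1, 1), n_active,
                                                   replace = TRUE)
    raw <- drop(Z[, active, drop = FALSE] %*% beta_raw)
    rng <- range(raw)
    scale <- diff(band) / max(diff(rng), .Machine$double.eps)
    y <- band[1] + (raw - rng[1]) * scale
    beta <- c(intercept = band[1] - rng[1] * scale,
              setNames(beta_raw * scale, active))
    y <- y + rnorm(n, 0, noise_sd)
    y <- pmin(pmax(y, 1e-6), 1)
    data <- dplyr::bind_cols(
      tibble(abbr = sprintf("cpd%02d", seq_len(n)), t_response = y),
      tibble::as_tibble(Z),
      if (p_binary > 0) tibble::as_tibble(Xb)
    )
    list(data = data,
         truth = list(active = active, beta = beta, noise_sd = noise_sd))
  })
}
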