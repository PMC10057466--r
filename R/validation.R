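# Internal and external validation of fitted models, and the Williams-plot
# applicability domain.

#' Leave-one-out cross-validation (Q2, PRESS)
#'
#' Computes the predictive residual sum of squares via the leverage
#' shortcut `e_i / (1 - h_ii)` (algebraically identical to n explicit
#' refits for OLS; an explicit refit is used for any exact-fit point with
#' `h_ii` numerically 1), then
#' `Q2 = 1 - PRESS / TSS`, `S_PRESS = sqrt(PRESS / (n - m - 1))` and
#' `S_DEP = sqrt(PRESS / n)`.
#'
#' @param model A `k_model` from [fit_ols()].
#' @return One-row tibble: `q2`, `press`, `s_press`, `s_dep`.
#' @export
q2_loo <- function(model) {
  fit <- model$fit
  y <- model$data[[model$response]]
  n <- model$n
  m <- model$m
  if (n <= m + 2L) abort("too few rows for leave-one-out")
  h <- lm.influence(fit, do.coef = FALSE)$hat
  e <- residuals(fit)
  loo_res <- numeric(n)
  for (i in seq_len(n)) {
    if (1 - h[i] > 1e-10) {
      loo_res[i] <- e[i] / (1 - h[i])
    } else {
      # exact-fit point: explicit refit without row i
      sub <- fit_ols(model$data[-i, , drop = FALSE], model$descriptors,
                     response = model$response)
      loo_res[i] <- y[i] - predict(sub, model$data[i, , drop = FALSE])$.fitted
    }
  }
  press <- sum(loo_res^2)
  tss <- sum((y - mean(y))^2)
  tibble(q2 = 1 - press / tss, press = press,
         s_press = sqrt(press / (n - m - 1)), s_dep = sqrt(press / n))
}

#' Leave-many-out cross-validation
#'
#' Repeatedly leaves out a fraction of the rows, refits the fixed
#' descriptor subset on the retained rows, and scores the left-out
#' predictions: `Q2_i = 1 - sum((y_out - yhat_out)^2) /
#' sum((y_out - mean(y_in))^2)`. Iterations whose refit is singular are
#' skipped and counted.
#'
#' @param model A `k_model`.
#' @param leave_fraction Fraction of rows left out per iteration.
#' @param iterations Number of random splits.
#' @param seed RNG seed; the iterate vector is reproducible from it.
#' @return List with `iterates` (tibble `iteration`, `q2`), `mean`, `sd`
#'   and `skipped`.
#' @export
q2_lmo <- function(model, leave_fraction = 0.3, iterations = 1000L,
                   seed = 1L) {
  n <- model$n
  k <- max(1L, round(leave_fraction * n))
  if (n - k <= model$m + 1L) abort("leave fraction too large for refitting")
  y <- model$data[[model$response]]
  q2s <- rep(NA_real_, iterations)
  with_local_seed(seed, function() {
    for (it in seq_len(iterations)) {
      out_idx <- sample.int(n, k)
      res <- tryCatch({
        sub <- fit_ols(model$data[-out_idx, , drop = FALSE],
                       model$descriptors, response = model$response)
        pr <- predict(sub, model$data[out_idx, , drop = FALSE])$.fitted
        y_out <- y[out_idx]
        1 - sum((y_out - pr)^2) /
          sum((y_out - mean(y[-out_idx]))^2)
      }, error = function(e) NA_real_)
      q2s[it] <<- res
    }
  })
  iterates <- tibble(iteration = seq_len(iterations), q2 = q2s) %>%
    filter(!is.na(.data$q2))
  list(iterates = iterates,
       mean = mean(iterates$q2), sd = sd(iterates$q2),
       skipped = iterations - nrow(iterates))
}

#' Y-scrambling (response permutation) test
#'
#' Permutes the response among the rows, refits the fixed descriptor
#' subset, and records the scrambled R2 and leave-one-out Q2. A real
#' structure-response relationship shows unpermuted statistics far above
#' the scrambled distributions (under the null the expected R2 is roughly
#' `m / (n - 1)`).
#'
#' @param model A `k_model`.
#' @param permutations Number of permutations (0 gives empty
#'   distributions).
#' @param seed RNG seed.
#' @return List with `scrambled` (tibble `permutation`, `r_squared`,
#'   `q2`), `mean_r2`, `max_r2`, `mean_q2`, `max_q2`.
#' @export
y_scrambling <- function(model, permutations = 300L, seed = 1L) {
  perms <- with_local_seed(seed, function() {
    lapply(seq_len(permutations), function(i) sample.int(model$n))
  })
  rows <- lapply(seq_along(perms), function(i) {
    dat <- model$data
    dat[[model$response]] <- dat[[model$response]][perms[[i]]]
    mod <- fit_ols(dat, model$descriptors, response = model$response)
    tibble(permutation = i, r_squared = mod$r_squared,
           q2 = q2_loo(mod)$q2)
  })
  scrambled <- if (length(rows)) bind_rows(rows) else
    tibble(permutation = integer(), r_squared = numeric(), q2 = numeric())
  list(scrambled = scrambled,
       mean_r2 = if (nrow(scrambled)) mean(scrambled$r_squared) else NA_real_,
       max_r2 = if (nrow(scrambled)) max(scrambled$r_squared) else NA_real_,
       mean_q2 = if (nrow(scrambled)) mean(scrambled$q2) else NA_real_,
       max_q2 = if (nrow(scrambled)) max(scrambled$q2) else NA_real_)
}

#' External validation on a held-out test set
#'
#' `R2_ext = 1 - sum_test((y - yhat)^2) / sum_test((y - ybar_train)^2)`,
#' with the training mean as the no-information reference.
#'
#' @param model A `k_model` fitted on training rows only.
#' @param test_data Test frame with `abbr`, response and descriptor
#'   columns.
#' @return One-row tibble: `n_test`, `r2_ext`, `rmse_ext`.
#' @export
external_validation <- function(model, test_data) {
  if (is.null(test_data) || !nrow(test_data)) abort("empty test set")
  y <- test_data[[model$response]]
  pr <- predict(model, test_data)$.fitted
  ybar_tr <- mean(model$data[[model$response]])
  tibble(n_test = nrow(test_data),
         r2_ext = 1 - sum((y - pr)^2) / sum((y - ybar_tr)^2),
         rmse_ext = sqrt(mean((y - pr)^2)))
}

#' Williams-plot applicability domain report
#'
#' Leverages `h_ii = x_i' (X'X)^{-1} x_i` from the training design matrix
#' (with intercept), the leverage threshold `h* = 3(m + 1) / n_train`, and
#' standardized residuals `e_i / s` with `s` the residual standard error
#' of the training fit. Rows beyond `h*` are structural (X) outliers; rows
#' beyond +/- 3 standardized residuals are response outliers.
#'
#' @param model A `k_model` (training fit).
#' @param newdata Optional additional rows (e.g. the test set) with
#'   `abbr`, descriptor columns and, if available, the response.
#' @param sigma_limit Residual limit in multiples of `s`.
#' @return A tibble of class `williams_ad`: `abbr`, `set`, `leverage`,
#'   `std_residual`, `x_outlier`, `response_outlier`; attributes
#'   `h_star`, `sigma`, `m`, `n_train`.
#' @export
williams_ad <- function(model, newdata = NULL, sigma_limit = 3.0) {
  X_tr <- model.matrix(model$fit)
  XtXi <- tryCatch(solve(crossprod(X_tr)),
                   error = function(e) abort("singular training design matrix"))
  h_star <- 3 * (model$m + 1) / model$n
  s <- model$sigma
  lev_of <- function(X) rowSums((X %*% XtXi) * X)
  mk <- function(data, set) {
    X <- cbind(1, as.matrix(data[, model$descriptors, drop = FALSE]))
    lev <- lev_of(X)
    res <- if (model$response %in% names(data)) {
      data[[model$response]] - predict(model, data)$.fitted
    } else rep(NA_real_, nrow(data))
    tibble(abbr = data$abbr, set = set, leverage = lev,
           std_residual = res / s)
  }
  out <- mk(model$data, "train")
  if (!is.null(newdata) && nrow(newdata)) {
    out <- bind_rows(out, mk(newdata, "test"))
  }
  out <- out %>%
    mutate(x_outlier = .data$leverage > h_star,
           response_outlier = !is.na(.data$std_residual) &
             abs(.data$std_residual) > sigma_limit)
  structure(out, class = c("williams_ad", class(out)),
            h_star = h_star, sigma = s, m = model$m, n_train = model$n)
}
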