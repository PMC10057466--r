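# Ordinary-least-squares models on descriptor subsets, with the filtering
# rules used during model building: the QUIK collinearity rule (no
# descriptor pair with |r| >= 0.6 inside a model) and the significance
# screen (model F-test p and every per-descriptor t-test p below 0.05).

#' Fit an OLS model of the transformed response on a descriptor subset
#'
#' @param data Modeling frame: tibble with an `abbr` identifier column, the
#'   response column and the descriptor columns (normally normalized).
#' @param descriptors Names of the descriptor columns to include (1-5).
#' @param response Name of the response column.
#' @return An object of class `k_model` wrapping the `lm` fit, with the
#'   training frame, descriptor subset, filter outcomes (`quik`,
#'   `significant`, `rejected`) and fit statistics. Use [tidy()] for
#'   coefficients, [glance()] for statistics, [predict()] for predictions.
#' @export
fit_ols <- function(data, descriptors, response = "t_response") {
  if (!length(descriptors)) abort("at least one descriptor required")
  missing_cols <- setdiff(c("abbr", response, descriptors), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  m <- length(descriptors)
  if (n <= m + 1L) abort("too few rows for the subset size")
  y <- data[[response]]
  if (var(y) == 0) abort("response is constant; nothing to fit")
  X <- as.data.frame(data[, descriptors, drop = FALSE])
  names(X) <- paste0("V", seq_len(m))    # guard non-syntactic names
  fit <- lm(y ~ ., data = cbind(y = y, X))
  if (fit$rank < m + 1L) abort("rank-deficient descriptor subset")
  names(fit$coefficients) <- c("(Intercept)", descriptors)
  sm <- summary(fit)
  quik <- quik_check(data, descriptors)
  coefs <- sm$coefficients
  p_T <- coefs[-1, 4]
  fstat <- sm$fstatistic
  p_M <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  significant <- all(p_T < 0.05) && p_M < 0.05
  structure(
    list(
      fit = fit,
      descriptors = descriptors,
      response = response,
      data = data,
      n = n, m = m,
      r_squared = sm$r.squared,
      sigma = sm$sigma,
      f_statistic = unname(fstat[1]),
      p_model = p_M,
      p_terms = setNames(unname(p_T), descriptors),
      quik = quik,
      significant = significant,
      rejected = !(quik$pass && significant)
    ),
    class = "k_model"
  )
}

#' QUIK collinearity rule
#'
#' A candidate model fails when any pair of its descriptors has absolute
#' Pearson correlation at or above the cutoff (default 0.6) on the supplied
#' rows; single-descriptor models pass vacuously.
#'
#' @param data Modeling frame containing the descriptor columns.
#' @param descriptors Descriptor subset to check.
#' @param cutoff Correlation cutoff.
#' @return List with `pass` (logical) and `max_r` (maximum absolute
#'   pairwise correlation; 0 for single columns).
#' @export
quik_check <- function(data, descriptors, cutoff = 0.6) {
  if (length(descriptors) < 2L) return(list(pass = TRUE, max_r = 0))
  cm <- cor(as.data.frame(data[, descriptors, drop = FALSE]))
  max_r <- max(abs(cm[upper.tri(cm)]))
  list(pass = max_r < cutoff, max_r = max_r)
}

#' @export
print.k_model <- function(x, ...) {
  cat("<k_model> ", x$m, " descriptor(s), n = ", x$n,
      ", R2 = ", signif(x$r_squared, 3),
      ", s = ", signif(x$sigma, 3),
      if (x$rejected) "  [rejected by filters]" else "", "\n", sep = "")
  cat("  ", paste(x$descriptors, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @method tidy k_model
#' @export
tidy.k_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = sm[, 4]
  )
}

#' @method glance k_model
#' @export
glance.k_model <- function(x, ...) {
  loo <- q2_loo(x)
  tibble(
    r.squared = x$r_squared,
    adj.r.squared = summary(x$fit)$adj.r.squared,
    sigma = x$sigma,
    statistic = x$f_statistic,
    p.value = x$p_model,
    q2_loo = loo$q2,
    press = loo$press,
    s_press = loo$s_press,
    s_dep = loo$s_dep,
    n = x$n,
    m = x$m,
    quik_max_r = x$quik$max_r,
    rejected = x$rejected
  )
}

#' Predict transformed responses and K coefficients
#'
#' Linear prediction on the transformed scale plus the back-transformed K.
#' Predictions above 1 on the transformed scale have no valid K preimage;
#' they are flagged and their K clamped to 0.
#'
#' @param object A `k_model`.
#' @param newdata Tibble with `abbr` and the model's descriptor columns;
#'   defaults to the training frame.
#' @param ... Unused.
#' @return Tibble with `abbr`, `.fitted` (transformed scale), `K_pred` and
#'   `out_of_range`.
#' @export
predict.k_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  missing_cols <- setdiff(object$descriptors, names(newdata))
  if (length(missing_cols)) {
    abort(paste0("newdata lacks descriptor(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.data.frame(newdata[, object$descriptors, drop = FALSE])
  names(X) <- paste0("V", seq_along(object$descriptors))
  co <- coef(object$fit)
  t_hat <- co[1] + as.matrix(X) %*% co[-1]
  t_hat <- drop(t_hat)
  oor <- t_hat > 1
  K_pred <- ifelse(oor, 0, ifelse(t_hat <= 0, Inf, t_hat^(-2) - 1))
  tibble(abbr = newdata$abbr, .fitted = t_hat, K_pred = K_pred,
         out_of_range = oor)
}
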