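# Shared fixtures, computed once per test run. Conformer embedding is the
# slow step (~10 s for all 30 compounds), so graphs/conformers and the
# final-model descriptor matrix are cached here and reused across files.

fx_compounds <- load_compounds()
fx_train_ids <- fx_compounds$abbr[fx_compounds$split == "train"]
fx_structures <- prepare_structures(fx_compounds, seed = 7)
fx_descriptors <- compute_descriptors(fx_compounds,
                                      final_model_descriptors(),
                                      seed = 7, structures = fx_structures)

# Normalized modeling frame: abbr, split, t_response + the five descriptors
fx_frame <- local({
  norm <- normalize_descriptors(fx_descriptors, fx_train_ids)
  dplyr::left_join(
    norm$data,
    dplyr::select(fx_compounds, abbr, split, t_response = tK),
    by = "abbr"
  )
})

# Independent Floyd-Warshall shortest-path oracle (O(n^3), test-only)
floyd_warshall <- function(graph) {
  n <- nrow(graph$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k]; b <- graph$bonds$b[k]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Independent best-subset oracle: enumerate all size-m subsets with plain
# lm(), apply the same filters arithmetic directly, return the best
# surviving subset by the requested fitness.
brute_force_best_subset <- function(data, candidates, m,
                                    response = "t_response",
                                    fitness = "q2_loo") {
  best <- NULL
  best_fit <- -Inf
  for (idx in utils::combn(length(candidates), m, simplify = FALSE)) {
    subset <- sort(candidates[idx])
    d <- as.data.frame(data[, c(response, subset)])
    names(d) <- c("y", paste0("V", seq_len(m)))
    fit <- lm(y ~ ., data = d)
    if (fit$rank < m + 1) next
    sm <- summary(fit)
    if (m >= 2) {
      cm <- abs(cor(d[, -1, drop = FALSE]))
      if (max(cm[upper.tri(cm)]) >= 0.6) next
    }
    p_T <- sm$coefficients[-1, 4]
    fs <- sm$fstatistic
    p_M <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    if (any(p_T >= 0.05) || p_M >= 0.05) next
    h <- lm.influence(fit, do.coef = FALSE)$hat
    press <- sum((residuals(fit) / (1 - h))^2)
    q2 <- 1 - press / sum((d$y - mean(d$y))^2)
    val <- if (fitness == "q2_loo") q2 else sm$r.squared
    if (val > best_fit) { best_fit <- val; best <- subset }
  }
  list(subset = best, fitness = best_fit)
}

# Explicit leave-one-out by n refits, independent of the leverage shortcut
explicit_loo_press <- function(model) {
  y <- model$data[[model$response]]
  sum(vapply(seq_len(model$n), function(i) {
    sub <- fit_ols(model$data[-i, , drop = FALSE], model$descriptors,
                   response = model$response)
    (y[i] - predict(sub, model$data[i, , drop = FALSE])$.fitted)^2
  }, numeric(1)))
}

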