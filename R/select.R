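# Subset search: a fixed-cardinality genetic algorithm over descriptor
# subsets (binary-mask chromosomes repaired to constant cardinality), plus
# exhaustive enumeration for small search spaces. Both apply the QUIK and
# significance filters after fitting; only surviving models are ranked.

#' Genetic-algorithm configuration
#'
#' Defaults follow the reference modeling setup: 200 chromosomes, 2000
#' generations, 20% per-gene mutation. The fitness is the leave-one-out Q2
#' by default (more protective against overfitting than the training R2,
#' which is also available).
#'
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param mutation_prob Per-gene mutation probability in `[0, 1]`.
#' @param fitness `"q2_loo"` or `"r2"`.
#' @param elitism Number of top chromosomes copied unchanged.
#' @param stall Stop early after this many generations without improvement
#'   of the best archived model.
#' @param seed RNG seed; the whole search is reproducible from it.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 200L, generations = 2000L,
                      mutation_prob = 0.20, fitness = c("q2_loo", "r2"),
                      elitism = 2L, stall = 200L, seed = 1L) {
  fitness <- match.arg(fitness)
  if (population < 2L) abort("population must be at least 2")
  if (mutation_prob < 0 || mutation_prob > 1) {
    abort("mutation_prob must lie in [0, 1]")
  }
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob, fitness = fitness,
                 elitism = as.integer(elitism), stall = as.integer(stall),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Evaluate one subset (indices into `candidates`); cached by sorted key.
make_evaluator <- function(data, candidates, response, fitness) {
  cache <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  counts$quik_fail <- 0L; counts$sig_fail <- 0L; counts$fit_fail <- 0L
  eval_subset <- function(idx) {
    key <- paste(sort(idx), collapse = "-")
    if (!is.null(cache[[key]])) return(cache[[key]])
    subset <- sort(candidates[idx])
    res <- tryCatch({
      mod <- fit_ols(data, subset, response = response)
      loo <- q2_loo(mod)
      feas <- !mod$rejected
      if (!feas) {
        if (!mod$quik$pass) counts$quik_fail <- counts$quik_fail + 1L
        else counts$sig_fail <- counts$sig_fail + 1L
      }
      fit_val <- if (fitness == "q2_loo") loo$q2 else mod$r_squared
      list(feasible = feas,
           fitness = if (feas) fit_val else -1e6 + mod$r_squared,
           r_squared = mod$r_squared, q2_loo = loo$q2,
           max_r = mod$quik$max_r, subset = subset)
    }, error = function(e) {
      counts$fit_fail <- counts$fit_fail + 1L
      list(feasible = FALSE, fitness = -2e6, r_squared = NA_real_,
           q2_loo = NA_real_, max_r = NA_real_, subset = subset)
    })
    cache[[key]] <- res
    res
  }
  list(eval = eval_subset, cache = cache, counts = counts)
}

rank_archive <- function(cache) {
  keys <- ls(cache)
  res <- lapply(keys, function(k) cache[[k]])
  feas <- res[map_lgl(res, "feasible")]
  if (!length(feas)) {
    return(tibble(subset = list(), fitness = numeric(),
                  r_squared = numeric(), q2_loo = numeric(),
                  max_r = numeric()))
  }
  out <- tibble(
    subset = map(feas, "subset"),
    fitness = map_dbl(feas, "fitness"),
    r_squared = map_dbl(feas, "r_squared"),
    q2_loo = map_dbl(feas, "q2_loo"),
    max_r = map_dbl(feas, "max_r")
  )
  # fitness descending; ties broken lexicographically by descriptor names
  key <- map(out$subset, paste, collapse = " ")
  out[order(-out$fitness, unlist(key)), ]
}

check_rule_of_thumb <- function(m, n) {
  if (m > 5L) abort("subset sizes above 5 are not considered")
  if (5L * m > n) {
    abort(paste0("rule of thumb violated: ", m, " descriptors need at least ",
                 5L * m, " training compounds, have ", n))
  }
}

#' Exhaustive subset search
#'
#' Fits every size-`m` subset of the candidate descriptors, applies the
#' QUIK and significance filters, and ranks the survivors; used for small
#' search spaces and as the reference the genetic search must reproduce.
#'
#' @inheritParams ga_select
#' @return Ranked tibble (see [ga_select()]); attribute `reason_counts`
#'   tallies filtered candidates.
#' @export
exhaustive_select <- function(data, candidates, m, response = "t_response",
                              fitness = c("q2_loo", "r2")) {
  fitness <- match.arg(fitness)
  check_rule_of_thumb(m, nrow(data))
  ev <- make_evaluator(data, candidates, response, fitness)
  idx <- combn(length(candidates), m, simplify = FALSE)
  for (s in idx) ev$eval(s)
  out <- rank_archive(ev$cache)
  attr(out, "reason_counts") <- as.list(ev$counts)
  out
}

#' Genetic-algorithm descriptor subset selection
#'
#' Searches size-`m` subsets of the candidate descriptors with a genetic
#' algorithm: fixed-cardinality chromosomes, tournament selection, uniform
#' crossover repaired to cardinality `m`, per-gene mutation. Every
#' evaluated subset is OLS-fitted on `data`; subsets failing the QUIK rule
#' or the significance screen are discarded from the ranking (their counts
#' are reported) but still steer the search through a penalized fitness.
#' The search is fully reproducible from `config$seed`.
#'
#' @param data Modeling frame (training rows): `abbr`, response and
#'   descriptor columns, normally normalized.
#' @param candidates Candidate descriptor column names.
#' @param m Subset size, 1-5; the 1:5 rule of thumb against
#'   overparameterization requires `5 * m <= nrow(data)`.
#' @param config A [ga_config()].
#' @param response Response column name.
#' @return A tibble of surviving models ranked by fitness (ties broken
#'   lexicographically): list-column `subset`, plus `fitness`,
#'   `r_squared`, `q2_loo`, `max_r`. Attribute `reason_counts` tallies
#'   discarded candidates by reason.
#' @export
ga_select <- function(data, candidates, m, config = ga_config(),
                      response = "t_response") {
  check_rule_of_thumb(m, nrow(data))
  p <- length(candidates)
  if (m > p) abort("subset size exceeds number of candidates")
  ev <- make_evaluator(data, candidates, response, config$fitness)
  total <- choose(p, m)

  with_local_seed(config$seed, function() {
    pop <- lapply(seq_len(config$population),
                  function(i) sort(sample.int(p, m)))
    best <- -Inf
    since <- 0L
    for (gen in seq_len(config$generations)) {
      fits <- map_dbl(pop, function(s) ev$eval(s)$fitness)
      gen_best <- max(fits)
      if (gen_best > best + 1e-12) { best <- gen_best; since <- 0L }
      else since <- since + 1L
      if (since >= config$stall) break
      if (length(ls(ev$cache)) >= total) break   # search space exhausted
      ord <- order(-fits)
      elite <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
      tournament <- function() {
        i <- sample.int(length(pop), 2L)
        pop[[i[which.max(fits[i])]]]
      }
      children <- list()
      while (length(children) < config$population - length(elite)) {
        p1 <- tournament(); p2 <- tournament()
        core <- intersect(p1, p2)
        extra <- setdiff(union(p1, p2), core)
        need <- m - length(core)
        child <- sort(c(core, if (need > 0)
          extra[sample.int(length(extra), need)] else integer()))
        # per-gene mutation: swap gene for a random non-member
        mut <- runif(m) < config$mutation_prob
        if (any(mut)) {
          avail <- setdiff(seq_len(p), child)
          for (g in which(mut)) {
            if (!length(avail)) break
            pick <- avail[sample.int(length(avail), 1L)]
            avail <- c(setdiff(avail, pick), child[g])
            child[g] <- pick
          }
          child <- sort(child)
        }
        children[[length(children) + 1L]] <- child
      }
      pop <- c(elite, children)
    }
    invisible(NULL)
  })

  out <- rank_archive(ev$cache)
  attr(out, "reason_counts") <- as.list(ev$counts)
  if (!nrow(out)) {
    warn("no model survived the QUIK/significance filters")
  }
  out
}

#' Best model per subset size
#'
#' Builds the champion model for each size 1-5 the way the stepwise
#' protocol does: exhaustive search when the space is small enough,
#' genetic search otherwise, always under the QUIK and significance
#' filters. Reports training and (optionally) test correlation
#' coefficients for the size-comparison curve.
#'
#' @inheritParams ga_select
#' @param sizes Subset sizes to build, subset of 1:5.
#' @param test_data Optional test frame (same columns) for external R.
#' @param exhaustive_limit Use exhaustive enumeration when the number of
#'   subsets is at most this.
#' @return Tibble with one row per size: `m`, list-column `subset`,
#'   `r_squared`, `q2_loo`, `r_train`, `r_test`, and list-column `model`
#'   (the fitted `k_model`). Sizes with no surviving model are dropped
#'   with a warning.
#' @export
stepwise_build <- function(data, candidates, sizes = 1:5,
                           config = ga_config(), response = "t_response",
                           test_data = NULL, exhaustive_limit = 3000) {
  rows <- list()
  for (m in sizes) {
    ranked <- if (choose(length(candidates), m) <= exhaustive_limit) {
      exhaustive_select(data, candidates, m, response = response,
                        fitness = config$fitness)
    } else {
      ga_select(data, candidates, m, config = config, response = response)
    }
    if (!nrow(ranked)) {
      warn(paste0("no surviving model of size ", m))
      next
    }
    subset <- ranked$subset[[1]]
    mod <- fit_ols(data, subset, response = response)
    pr_tr <- predict(mod)
    r_train <- cor(data[[response]], pr_tr$.fitted)
    r_test <- NA_real_
    if (!is.null(test_data) && nrow(test_data)) {
      pr_te <- predict(mod, test_data)
      r_test <- cor(test_data[[response]], pr_te$.fitted)
    }
    rows[[length(rows) + 1L]] <- tibble(
      m = m, subset = list(subset), r_squared = mod$r_squared,
      q2_loo = q2_loo(mod)$q2, r_train = r_train, r_test = r_test,
      model = list(mod)
    )
  }
  bind_rows(rows)
}
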