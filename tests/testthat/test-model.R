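planted_frame <- function(n = 30, noise = 0, seed = 11) {
  withr::with_seed(seed, {
    tibble::tibble(
      abbr = sprintf("c%02d", seq_len(n)),
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
      t_response = 2 * x1 - x2 + 0.5 + rnorm(n, 0, noise)
    )
  })
}

test_that("OLS recovers planted coefficients exactly at zero noise", {
  df <- planted_frame()
  mod <- suppressWarnings(fit_ols(df, c("x1", "x2")))  # exact fit
  expect_equal(mod$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(mod$fit))), 1e-10)
  co <- coef(mod$fit)
  expect_equal(unname(co), c(0.5, 2, -1), tolerance = 1e-10)
  expect_equal(names(co), c("(Intercept)", "x1", "x2"))

  td <- suppressWarnings(tidy(mod))
  expect_equal(td$term, c("(Intercept)", "x1", "x2"))
  gl <- suppressWarnings(glance(mod))
  expect_equal(gl$n, 30L)
  expect_equal(gl$q2_loo, 1, tolerance = 1e-10)
})

test_that("degenerate fits are rejected with clear errors", {
  df <- planted_frame()
  df$t_response <- 1
  expect_error(fit_ols(df, "x1"), "constant")

  df2 <- planted_frame()
  df2$x2 <- df2$x1
  expect_error(fit_ols(df2, c("x1", "x2")), "rank")

  expect_error(fit_ols(planted_frame(n = 3), c("x1", "x2", "x3")), "few rows")
})

test_that("QUIK rule flags collinear subsets and passes orthogonal ones", {
  df <- planted_frame()
  df$dup <- df$x1
  qk <- quik_check(df, c("x1", "dup"))
  expect_false(qk$pass)
  expect_equal(qk$max_r, 1)

  n <- 20
  orth <- tibble::tibble(abbr = sprintf("c%d", 1:n),
                         a = rep(c(-1, 1), n / 2),
                         b = rep(c(-1, -1, 1, 1), n / 4))
  qo <- quik_check(orth, c("a", "b"))
  expect_true(qo$pass)
  expect_equal(qo$max_r, 0)

  expect_true(quik_check(df, "x1")$pass)   # vacuous for single columns
})

test_that("the five model descriptors satisfy the QUIK rule on the fixture", {
  qk <- quik_check(fx_frame, final_model_descriptors())
  expect_true(qk$pass)
  expect_lt(qk$max_r, 0.6)
})

test_that("predictions behave like OLS predictions", {
  df <- planted_frame(noise = 0.05)
  mod <- fit_ols(df, c("x1", "x2"))
  pr <- predict(mod)
  expect_equal(mean(pr$.fitted), mean(df$t_response), tolerance = 1e-10)

  zero_row <- tibble::tibble(abbr = "z", x1 = 0, x2 = 0)
  expect_equal(predict(mod, zero_row)$.fitted,
               unname(coef(mod$fit)[1]), tolerance = 1e-12)

  noiseless <- planted_frame()
  m0 <- suppressWarnings(fit_ols(noiseless, c("x1", "x2")))
  expect_equal(predict(m0)$.fitted, noiseless$t_response, tolerance = 1e-10)

  expect_error(predict(mod, tibble::tibble(abbr = "q", x1 = 1)), "lacks")

  # transformed predictions above 1 are flagged and K clamped to 0
  band <- tibble::tibble(abbr = c("a", "b", "c", "d", "e"),
                         x = c(0, 0.25, 0.5, 0.75, 1),
                         t_response = c(0.2, 0.4, 0.6, 0.8, 1.0))
  mb <- suppressWarnings(fit_ols(band, "x"))
  hi <- predict(mb, tibble::tibble(abbr = "h", x = 2))
  expect_true(hi$out_of_range)
  expect_equal(hi$K_pred, 0)
})

test_that("GA selection matches the exhaustive oracle on small problems", {
  sim <- gen_qsar(n = 30, p = 12, p_binary = 0, n_active = 2,
                  noise_sd = 0.01, seed = 5)
  cfg <- ga_config(population = 40, generations = 60, seed = 9)
  ga <- ga_select(sim$data, sprintf("X%02d", 1:12), m = 2, config = cfg)
  oracle <- brute_force_best_subset(sim$data, sprintf("X%02d", 1:12), 2)
  expect_equal(ga$subset[[1]], oracle$subset)
  expect_equal(ga$fitness[1], oracle$fitness, tolerance = 1e-10)
  expect_equal(ga$subset[[1]], sim$truth$active)   # planted truth recovered
})

test_that("GA equals exhaustive search for p <= 15, m <= 3", {
  sim <- gen_qsar(n = 32, p = 15, p_binary = 0, n_active = 3,
                  noise_sd = 0.05, correlation = 0.2, seed = 21)
  cols <- sprintf("X%02d", 1:15)
  for (m in 2:3) {
    cfg <- ga_config(population = 60, generations = 80, seed = 3)
    ga <- ga_select(sim$data, cols, m = m, config = cfg)
    oracle <- brute_force_best_subset(sim$data, cols, m)
    expect_equal(ga$subset[[1]], oracle$subset, info = paste("m =", m))
  }
})

test_that("size-1 selection is the argmax over single columns", {
  sim <- gen_qsar(n = 25, p = 8, p_binary = 0, n_active = 1,
                  noise_sd = 0.02, seed = 13)
  cols <- sprintf("X%02d", 1:8)
  ga <- ga_select(sim$data, cols, m = 1,
                  config = ga_config(population = 10, generations = 30,
                                     seed = 2))
  oracle <- brute_force_best_subset(sim$data, cols, 1)
  expect_equal(ga$subset[[1]], oracle$subset)
})

test_that("GA runs are reproducible from the seed", {
  sim <- gen_qsar(n = 30, p = 10, p_binary = 2, n_active = 2,
                  noise_sd = 0.05, seed = 8)
  cols <- setdiff(names(sim$data), c("abbr", "t_response"))
  cfg <- ga_config(population = 30, generations = 40, seed = 77)
  g1 <- ga_select(sim$data, cols, m = 2, config = cfg)
  g2 <- ga_select(sim$data, cols, m = 2, config = cfg)
  expect_identical(g1$subset, g2$subset)
  expect_identical(g1$fitness, g2$fitness)
})

test_that("every ranked model satisfies QUIK and both significance filters", {
  sim <- gen_qsar(n = 30, p = 10, p_binary = 2, n_active = 2,
                  noise_sd = 0.1, correlation = 0.4, seed = 31)
  cols <- setdiff(names(sim$data), c("abbr", "t_response"))
  ranked <- ga_select(sim$data, cols, m = 2,
                      config = ga_config(population = 40, generations = 50,
                                         seed = 4))
  for (i in seq_len(nrow(ranked))) {
    mod <- fit_ols(sim$data, ranked$subset[[i]])
    expect_false(mod$rejected)
    expect_lt(mod$quik$max_r, 0.6)
    expect_true(all(mod$p_terms < 0.05))
    expect_lt(mod$p_model, 0.05)
  }
})

test_that("the rule of thumb caps subset size relative to training size", {
  sim <- gen_qsar(n = 20, p = 10, p_binary = 0, n_active = 2, seed = 1)
  cols <- sprintf("X%02d", 1:10)
  expect_error(ga_select(sim$data, cols, m = 5), "rule of thumb")
  expect_error(exhaustive_select(sim$data, cols, m = 6), "not considered")
})

test_that("stepwise champions improve monotonically on the training set", {
  sim <- gen_qsar(n = 30, p = 9, p_binary = 0, n_active = 3,
                  noise_sd = 0.03, seed = 17)
  cols <- sprintf("X%02d", 1:9)
  champs <- stepwise_build(sim$data, cols, sizes = 1:3,
                           config = ga_config(population = 40,
                                              generations = 50, seed = 6))
  expect_equal(champs$m, 1:3)
  expect_true(all(diff(champs$r_squared) >= -1e-12))
  expect_true(all(champs$r_train >= 0))
  for (mod in champs$model) expect_false(mod$rejected)
  expect_true(all(cols[as.integer(substr(sim$truth$active, 2, 3))] %in%
                    cols))  # sanity on naming
  # the size-3 champion contains the planted triple
  expect_setequal(champs$subset[[3]], sim$truth$active)
})
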