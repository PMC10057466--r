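# Hand-buildable conformer for closed-form MoRSE checks
toy_conformer <- function(xyz, elements) {
  structure(
    list(atoms = tibble::tibble(idx = seq_along(elements),
                                element = elements,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
         bonds = tibble::tibble(a = integer(), b = integer(),
                                order = integer()),
         seed = 0L, forcefield = "none"),
    class = "conformer"
  )
}

test_that("pharmacophore typing follows the class rules", {
  bz <- build_graph("OC(=O)c1ccccc1")
  ty <- assign_ppp_types(bz)
  oh <- which(bz$atoms$element == "O" & bz$atoms$n_h == 1)
  cx <- which(ty$N)
  expect_true(ty$D[oh])
  expect_equal(bz$atoms$element[cx], "C")        # carboxyl carbon is the N center
  expect_equal(bz$dist[oh, cx], 1L)              # D-N pair sits at lag 1

  phe <- build_graph("Oc1ccccc1")
  typ <- assign_ppp_types(phe)
  expect_equal(sum(typ$D), 1L)
  expect_equal(sum(typ$N), 0L)

  one_c <- build_graph("C")
  t1 <- assign_ppp_types(one_c)
  expect_true(t1$L[1])
  expect_false(any(t1$D[1], t1$A[1], t1$P[1], t1$N[1]))

  # nitro nitrogen is not an acceptor; its anionic oxygen is N-typed
  pnp <- build_graph("Oc1ccc(cc1)[N+](=O)[O-]")
  tp <- assign_ppp_types(pnp)
  nn <- which(pnp$atoms$element == "N")
  expect_false(tp$A[nn])
  expect_true(tp$P[nn])                          # formally positive
  expect_true(any(tp$N[pnp$atoms$charge < 0]))
})

test_that("CATS2D counts pairs at the requested lag", {
  bz <- build_graph("OC(=O)c1ccccc1")
  expect_equal(cats2d(bz, 1, "DN"), 1L)
  expect_equal(cats2d(bz, 1, "ND"), 1L)          # symmetric in the pair

  phe <- build_graph("Oc1ccccc1")
  expect_equal(cats2d(phe, 1, "DN"), 0L)

  # lag-0 self-pairs: DD at lag 0 counts the donor atoms
  amx <- fx_structures[["AMX"]]$graph
  ty <- assign_ppp_types(amx)
  expect_equal(cats2d(amx, 0, "DD", types = ty), sum(ty$D))
  expect_error(cats2d(phe, 12, "DN"), "lag")
})

test_that("carboxylic acids and only acids/charges carry the lag-1 DN pair", {
  dn <- vapply(fx_compounds$abbr, function(ab) {
    cats2d(fx_structures[[ab]]$graph, 1, "DN")
  }, integer(1))
  acids <- c("BenzAc", "o-aminoBenzAc", "SalAc", "IBP", "DCF",
             "AMX", "CIP", "ETD", "SA")
  expect_true(all(dn[acids] >= 1L))
  no_acid_no_charge <- setdiff(fx_compounds$abbr, c(acids, "m-NP", "p-NP"))
  expect_true(all(dn[no_acid_no_charge] == 0L))
})

test_that("binary atom pairs detect exact topological distances", {
  az <- fx_structures[["AZN"]]$graph
  expect_equal(atom_pair_presence(az, "C", "Cl", 4), 0L)

  dcp <- build_graph("Oc1ccc(Cl)cc1Cl")
  expect_equal(atom_pair_presence(dcp, "C", "Cl", 4), 1L)
  expect_equal(atom_pair_presence(dcp, "Cl", "C", 4), 1L)  # symmetric

  phe <- build_graph("Oc1ccccc1")
  expect_equal(atom_pair_presence(phe, "C", "O", 8), 0L)   # max C-O dist is 4
  expect_equal(atom_pair_presence(phe, "C", "Br", 3), 0L)  # absent element
})

test_that("Moran autocorrelation matches closed forms and conventions", {
  # two atoms with distinct weights at lag 1: exactly -1
  co <- build_graph("CO")
  expect_equal(moran_autocorrelation(co, 1, "v"), -1)
  expect_equal(moran_autocorrelation(co, 1, "m"), -1)

  # zero weight variance returns 0
  cc <- build_graph("CC")
  expect_equal(moran_autocorrelation(cc, 1, "v"), 0)
  expect_equal(moran_autocorrelation(cc, 3, "u"), 0)

  # no pair at the lag returns 0 (butane chain has diameter 3)
  but <- build_graph("CCCO")
  expect_equal(moran_autocorrelation(but, 4, "v"), 0)
})

test_that("Moran autocorrelation is affine-invariant in the weights", {
  for (ab in c("ALC", "CIP", "HCTZ", "OXY")) {
    g <- fx_structures[[ab]]$graph
    w <- atom_weights(g$atoms$element, "v")
    for (lag in c(2, 4, 6)) {
      base <- moran_autocorrelation(g, lag, weights = w)
      shifted <- moran_autocorrelation(g, lag, weights = 2.7 * w - 1.3)
      expect_equal(base, shifted, tolerance = 1e-12, info = paste(ab, lag))
    }
  }
})

test_that("2D descriptors are invariant to atom reordering of the SMILES", {
  variants <- list(
    c("Oc1ccc(Cl)cc1Cl", "Clc1cc(Cl)c(O)cc1"),   # 2,4-dichlorophenol
    c("OC(=O)c1ccccc1O", "c1ccc(O)c(c1)C(O)=O")  # salicylic acid
  )
  for (v in variants) {
    g1 <- build_graph(v[1]); g2 <- build_graph(v[2])
    for (lag in 1:4) {
      expect_equal(moran_autocorrelation(g1, lag, "v"),
                   moran_autocorrelation(g2, lag, "v"), tolerance = 1e-12)
    }
    expect_equal(cats2d(g1, 1, "DN"), cats2d(g2, 1, "DN"))
    expect_equal(atom_pair_presence(g1, "C", "Cl", 4),
                 atom_pair_presence(g2, "C", "Cl", 4))
    expect_equal(atom_pair_presence(g1, "C", "O", 3),
                 atom_pair_presence(g2, "C", "O", 3))
  }
})

test_that("3D-MoRSE matches closed forms and geometric invariances", {
  conf <- fx_structures[["Ph"]]$conformer
  A <- nrow(conf$atoms)
  expect_equal(morse_descriptor(conf, 1, "u"), A * (A - 1) / 2)

  # two atoms at r = pi/9: the signal-10 sinc term is sin(pi)/pi = 0
  two <- toy_conformer(rbind(c(0, 0, 0), c(pi / 9, 0, 0)), c("C", "C"))
  expect_equal(morse_descriptor(two, 10, "u"), 0, tolerance = 1e-12)

  # rigid rotation + translation leaves every signal unchanged
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% R, 2, c(1.5, -2, 0.3), `+`)
  conf2 <- conf
  conf2$atoms$x <- moved[, 1]; conf2$atoms$y <- moved[, 2]
  conf2$atoms$z <- moved[, 3]
  for (sig in c(5, 10, 21)) {
    expect_lt(abs(morse_descriptor(conf, sig, "u") -
                    morse_descriptor(conf2, sig, "u")), 1e-9)
  }

  clash <- toy_conformer(rbind(c(0, 0, 0), c(0, 0, 0)), c("C", "C"))
  expect_error(morse_descriptor(clash, 10, "u"), "coincident")
  expect_error(morse_descriptor(conf, 40, "u"), "signal")
})

test_that("descriptor matrix is dense, ordered and seed-deterministic", {
  expect_equal(descriptor_names <- names(fx_descriptors)[-1],
               final_model_descriptors())
  expect_false(anyNA(fx_descriptors))
  expect_equal(nrow(fx_descriptors), 30L)

  three <- fx_compounds[fx_compounds$abbr %in% c("Ph", "DCP", "BenzAc"), ]
  d1 <- compute_descriptors(three, c("Mor10u", "MATS4v"), seed = 3)
  d2 <- compute_descriptors(three, c("Mor10u", "MATS4v"), seed = 3)
  expect_identical(d1, d2)

  expect_gt(length(default_descriptor_grid()), 300)
  expect_error(compute_descriptors(three, c("MATS4v", "E_HOMO")),
               "surrogate")
  sur <- tibble::tibble(abbr = three$abbr, E_HOMO = c(-0.21, -0.25, -0.24))
  d3 <- compute_descriptors(three, c("MATS4v", "E_HOMO"), surrogates = sur)
  expect_equal(d3$E_HOMO, sur$E_HOMO)
})

test_that("a slice of the default grid computes densely on real molecules", {
  grid <- default_descriptor_grid()
  slice <- c(grid[grepl("^MATS", grid)][1:8],
             "Mor5u", "Mor10v",
             "CATS2D_03_AL", "CATS2D_00_DD", "B02[C-N]", "B05[C-O]")
  sub <- fx_compounds[fx_compounds$abbr %in% c("CIP", "HCTZ", "TB"), ]
  st <- fx_structures[sub$abbr]
  d <- compute_descriptors(sub, slice, structures = st)
  expect_false(anyNA(d))
  expect_equal(dim(d), c(3L, length(slice) + 1L))
})

test_that("correlation pre-filter removes duplicates and planted collinear pairs", {
  set.seed(42)
  base <- matrix(rnorm(20 * 12), 20, 12)
  df <- tibble::as_tibble(base, .name_repair = ~ sprintf("D%02d", 1:12))
  # plant 4 exactly collinear copies + one constant
  df$D13 <- df$D01 * 2
  df$D14 <- -df$D03
  df$D15 <- df$D05 + 10
  df$D16 <- df$D07 * 0.1
  df$D17 <- 1
  df <- dplyr::bind_cols(tibble::tibble(abbr = sprintf("c%02d", 1:20)), df)

  res <- prefilter_correlated(df, r_threshold = 0.99)
  expect_setequal(res$removed$name[res$removed$reason == "correlated"],
                  c("D13", "D14", "D15", "D16"))
  expect_equal(res$removed$name[res$removed$reason == "constant"], "D17")
  expect_true(all(c("D01", "D03", "D05", "D07") %in% names(res$data)))

  # moderately correlated columns are both kept
  x <- rnorm(50)
  df2 <- tibble::tibble(abbr = sprintf("c%02d", 1:50), A = x,
                        B = 0.5 * x + sqrt(1 - 0.25) * rnorm(50))
  stopifnot(abs(cor(df2$A, df2$B)) < 0.9)
  expect_equal(nrow(prefilter_correlated(df2)$removed), 0L)
})

test_that("min-max normalization fits on training rows only and round-trips", {
  df <- tibble::tibble(abbr = c("a", "b", "c", "d"),
                       x = c(2, 4, 3, 5), bin = c(0, 1, 1, 0),
                       const = c(7, 7, 7, 2))
  res <- normalize_descriptors(df, train_ids = c("a", "b", "c"))
  expect_equal(res$data$x, c(0, 1, 0.5, 1.5))    # test value may exceed 1
  expect_equal(res$data$bin, df$bin)             # binary 0/1 unchanged
  expect_equal(res$data$const[1:3], c(0, 0, 0))  # constant training column
  back <- denormalize(res$data[1:3, ], res$scaler)
  expect_equal(back$x, df$x[1:3], tolerance = 1e-12)
  expect_equal(back$const, df$const[1:3], tolerance = 1e-12)
})
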