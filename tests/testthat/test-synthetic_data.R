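small_spec <- function(...) {
  synthetic_spec(nrow = 5, ncol = 5, spacing_km = 50,
                 covariates = list(A = list(range_km = 100),
                                   B = list(range_km = 100)),
                 surfaces = list(Intercept = list(type = "constant", value = 3),
                                 A = list(type = "constant", value = 2)),
                 times = "t1", group_sizes = c(8, 9, 8), ...)
}

test_that("lattice skeleton: counts, queen adjacency, determinism", {
  sk <- generate_city_lattice(small_spec(seed = 1))
  expect_equal(nrow(sk$panel), 25)
  corner <- which(sk$panel$x == 25 & sk$panel$y == 25)
  expect_equal(sum(sk$weights$W[corner, ]), 3)      # corner: 3 queen neighbours
  expect_identical(sk$weights$W, t(sk$weights$W))
  expect_length(sk$weights$islands, 0)
  # queen adjacency equals the index-derived oracle
  expect_equal(unname(sk$weights$W), unname(lattice_weights(5, 5, "queen")$W))

  g1 <- generate_panel(small_spec(seed = 9))
  g2 <- generate_panel(small_spec(seed = 9))
  expect_identical(as.data.frame(g1$panel), as.data.frame(g2$panel))
  g3 <- generate_panel(small_spec(seed = 10))
  expect_false(identical(g1$panel$y_resp, g3$panel$y_resp))
})

test_that("covariate fields: white-noise and smooth-field Moran behaviour", {
  base <- synthetic_spec(nrow = 8, ncol = 8, spacing_km = 50,
                         covariates = list(A = list(range_km = 0.001)),
                         surfaces = list(Intercept = list(type = "constant",
                                                          value = 0),
                                         A = list(type = "constant", value = 1)),
                         times = "t1", group_sizes = c(21, 22, 21), seed = 3)
  sk <- generate_city_lattice(base)
  rough <- generate_covariates(sk, base, "t1")
  mr <- global_moran(rough$A, sk$weights)
  expect_lt(abs(mr$Z), 3)                    # no structure at vanishing range
  smooth_spec <- base
  smooth_spec$covariates$A$range_km <- 500
  smooth <- generate_covariates(sk, smooth_spec, "t1")
  ms <- global_moran(smooth$A, sk$weights)
  expect_gt(ms$Z, 3)
  expect_gt(ms$I, mr$I)
  # unit variance by construction
  expect_equal(sd(rough$A), 1, tolerance = 1e-12)
})

test_that("injected covariate correlation reproduces the closed-form VIF", {
  spec <- synthetic_spec(nrow = 20, ncol = 20, spacing_km = 50,
                         covariates = list(A = list(range_km = 1),
                                           B = list(range_km = 1)),
                         correlate = list(list(a = "A", b = "B", r = 0.9)),
                         surfaces = list(Intercept = list(type = "constant",
                                                          value = 0),
                                         A = list(type = "constant", value = 1)),
                         times = "t1", group_sizes = c(100, 150, 150),
                         seed = 5)
  gen <- generate_panel(spec)
  p <- panel_slice(gen$panel, "t1")
  v <- vif(p, c("A", "B"))$vif[1]
  expect_lt(abs(v - 1 / (1 - 0.9^2)), 1)     # 5.26 up to sampling noise
})

test_that("noiseless constant-coefficient response is exactly linear", {
  spec <- small_spec(seed = 2, noise_sd = 0)
  gen <- generate_panel(spec)
  p <- panel_slice(gen$panel, "t1")
  fit <- lm(y_resp ~ A + B, data = as.data.frame(p))
  expect_equal(unname(coef(fit)), c(3, 2, 0), tolerance = 1e-10)
  truth <- attr(gen$panel, "true_beta_by_time")[["t1"]]
  expect_equal(dim(truth), c(25, 3))
  expect_equal(colnames(truth), c("Intercept", "A", "B"))
  expect_true(all(truth[, "A"] == 2) && all(truth[, "B"] == 0))
})

test_that("OLS residual variance estimates the noise variance on a large lattice", {
  spec <- synthetic_spec(nrow = 18, ncol = 18, spacing_km = 50,
                         covariates = list(A = list(range_km = 100)),
                         surfaces = list(Intercept = list(type = "constant",
                                                          value = 1),
                                         A = list(type = "constant", value = 2)),
                         noise_sd = 0.7, times = "t1",
                         group_sizes = c(108, 108, 108), seed = 6)
  p <- panel_slice(generate_panel(spec)$panel, "t1")
  res <- residuals(lm(y_resp ~ A, data = as.data.frame(p)))
  expect_lt(abs(var(res) - 0.49), 0.12)
})

test_that("surface referencing a missing covariate errors", {
  expect_error(synthetic_spec(covariates = list(A = list(range_km = 10)),
                              surfaces = list(Z = list(type = "constant",
                                                       value = 1))),
               "missing covariate")
  expect_error(synthetic_spec(covariates = list(A = list(range_km = -5))),
               "non-positive")
  expect_error(synthetic_spec(nrow = 2, ncol = 2), "at least 9")
})

test_that("strata scenes hit the q limits and self-consistency", {
  s0 <- generate_strata_scene(L = 5, n = 100, between_sd = 1, within_sd = 0,
                              seed = 4)
  expect_equal(factor_q(s0$y, s0$strata, p_method = "none")$q, 1)
  s1 <- generate_strata_scene(L = 5, n = 20000, between_sd = 0,
                              within_sd = 1, seed = 4)
  expect_lt(factor_q(s1$y, s1$strata, p_method = "none")$q, 0.01)
  s2 <- generate_strata_scene(L = 6, n = 500, between_sd = 1,
                              within_sd = 0.5, seed = 8)
  expect_equal(factor_q(s2$y, s2$strata, p_method = "none")$q, s2$true_q,
               tolerance = 1e-12)
  expect_error(generate_strata_scene(L = 10, n = 5), "more strata")
})

test_that("synthetic spec serializes losslessly", {
  spec <- synthetic_spec(seed = 77)
  f <- withr::local_tempfile(fileext = ".json")
  write_synthetic_spec(spec, f)
  back <- read_synthetic_spec(f)
  expect_equal(unclass(back), unclass(spec), tolerance = 1e-12)
  # generated output from the restored spec agrees to printing precision
  expect_equal(as.data.frame(generate_panel(spec)$panel),
               as.data.frame(generate_panel(back)$panel),
               tolerance = 1e-9)
})
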