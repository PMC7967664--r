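# shared fixture: 7x7 lattice, gradient + sinusoid coefficient surfaces
vc_fixture <- function(seed = 7, noise = 0.5) {
  ext <- 6 * 50
  spec <- synthetic_spec(
    nrow = 7, ncol = 7, spacing_km = 50,
    covariates = list(X1 = list(range_km = 120), X2 = list(range_km = 120)),
    surfaces = list(Intercept = list(type = "constant", value = 3),
                    X1 = list(type = "gradient", base = 1, slope = 2 / ext),
                    X2 = list(type = "sinusoid", amplitude = 1.5,
                              wavelength_km = ext)),
    noise_sd = noise, times = "t1", seed = seed, group_sizes = c(16, 17, 16))
  panel_slice(generate_panel(spec)$panel, "t1")
}

test_that("kernel closed forms and monotonicity", {
  expect_equal(kernel_weights(0, kernel_spec("fixed", 3)), 1)
  expect_equal(kernel_weights(2, kernel_spec("fixed", 2)), exp(-1),
               tolerance = 1e-12)
  d <- seq(0, 10, by = 0.5)
  w <- kernel_weights(d, kernel_spec("fixed", 4))
  expect_true(all(diff(w) < 0))
  # adaptive: scale = distance to k-th nearest (self included)
  d2 <- c(0, 1, 2, 4, 8)
  w2 <- kernel_weights(d2, kernel_spec("adaptive", 3))
  expect_equal(w2, exp(-(d2 / 2)^2), tolerance = 1e-12)
  expect_error(kernel_spec("fixed", -1), "bandwidth")
})

test_that("GWR with near-infinite bandwidth reproduces OLS", {
  p <- vc_fixture()
  maxd <- max(dist(cbind(p$x, p$y)))
  g <- fit_gwr(p, bandwidth = 1e6 * maxd, kernel = "fixed")
  ols <- unname(coef(lm(y_resp ~ X1 + X2, data = as.data.frame(p))))
  for (i in seq_len(nrow(g$beta)))
    expect_equal(unname(g$beta[i, ]), ols, tolerance = 1e-6)
})

test_that("GWR is a linear smoother: fitted values equal S y", {
  p <- vc_fixture()
  g <- fit_gwr(p, bandwidth = 12)
  expect_equal(drop(g$S %*% p$y_resp), g$yhat, tolerance = 1e-10)
  expect_equal(sum(g$residuals^2), g$rss, tolerance = 1e-12)
  expect_equal(sum(diag(g$S)), g$enp, tolerance = 1e-12)
  expect_gte(g$enp, 3)
  expect_lte(g$enp, g$n)
})

test_that("GWR is equivariant to rigid motions of the coordinates", {
  p <- vc_fixture()
  g1 <- fit_gwr(p, bandwidth = 10)
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- cbind(p$x, p$y) %*% R
  df <- as.data.frame(p)
  df$x <- xy[, 1] + 123; df$y <- xy[, 2] - 77
  g2 <- fit_gwr(city_panel(df, panel_covariates(p)), bandwidth = 10)
  expect_equal(g2$beta, g1$beta, tolerance = 1e-10)
  expect_equal(g2$aicc, g1$aicc, tolerance = 1e-8)
})

test_that("constant-coefficient data yields flat surfaces at generous bandwidth", {
  set.seed(4)
  n <- 64
  coords <- expand.grid(x = 1:8, y = 1:8) * 10
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("A", "B")))
  y <- 2 + 1.5 * X[, 1] - 0.8 * X[, 2] + rnorm(n, 0, 0.2)
  p <- quick_panel(as.matrix(coords), y, X)
  g <- fit_gwr(p, bandwidth = 60, kernel = "adaptive")
  expect_lt(max(apply(g$beta, 2, sd)), 0.15)
  expect_lt(max(abs(colMeans(g$beta) - c(2, 1.5, -0.8))), 0.2)
})

test_that("AICc at the selected bandwidth is a local optimum and matches grid scan", {
  p <- vc_fixture(seed = 19)
  sel <- select_bandwidth(p)
  tr <- sel$trace
  near <- tr$aicc[abs(tr$bandwidth - sel$bandwidth) == 1]
  expect_true(all(sel$aicc <= near + 1e-9))
  grid <- select_bandwidth(p, method = "grid")
  expect_equal(sel$aicc, grid$aicc, tolerance = 1e-9)
  expect_equal(sel$bandwidth, grid$bandwidth)
})

test_that("finer coefficient variation selects a smaller bandwidth (seed-paired)", {
  mk <- function(wl) {
    spec <- synthetic_spec(
      nrow = 7, ncol = 7, spacing_km = 50,
      covariates = list(X1 = list(range_km = 30)),
      surfaces = list(Intercept = list(type = "constant", value = 0),
                      X1 = list(type = "sinusoid", amplitude = 2,
                                wavelength_km = wl)),
      noise_sd = 0.3, times = "t1", seed = 33, group_sizes = c(16, 17, 16))
    panel_slice(generate_panel(spec)$panel, "t1")
  }
  b_fine <- select_bandwidth(mk(300), "X1")$bandwidth
  b_coarse <- select_bandwidth(mk(1800), "X1")$bandwidth
  expect_lt(b_fine, b_coarse)
})

test_that("MGWR bookkeeping: ENP decomposition, trace behaviour, convergence flag", {
  p <- vc_fixture()
  m <- fit_mgwr(p, tol = 1e-5)
  expect_true(m$converged)
  expect_equal(sum(m$enp_terms), m$enp, tolerance = 1e-3)
  expect_equal(drop(m$S %*% ((p$y_resp - mean(p$y_resp)) / sd(p$y_resp))),
               m$yhat, tolerance = 1e-8)
  # SOC-f trace non-increasing after the second iteration
  sc <- m$trace$score
  if (length(sc) > 2) expect_true(all(diff(sc[-1]) <= 1e-8))
  # non-convergence surfaces as a warning, not an error
  expect_warning(m2 <- fit_mgwr(p, tol = 1e-12, max_iter = 2), "converge")
  expect_false(m2$converged)
})

test_that("MGWR with a common near-global bandwidth reduces to GWR", {
  p <- vc_fixture()
  b <- 100 * max(dist(cbind(p$x, p$y)))
  mf <- fit_mgwr(p, kernel = "fixed", standardize = TRUE, tol = 1e-10,
                 max_iter = 1000,
                 bandwidths = c(Intercept = b, X1 = b, X2 = b))
  gf <- fit_gwr(p, bandwidth = b, kernel = "fixed", standardize = TRUE)
  expect_lt(max(abs(mf$beta - gf$beta)), 1e-4)
})

test_that("at local bandwidths backfitting and the joint local fit differ", {
  # documents that partial-residual backfitting is a different estimator from
  # joint local WLS except in the flat-kernel limit
  p <- vc_fixture()
  mf <- fit_mgwr(p, standardize = TRUE, tol = 1e-9, max_iter = 1000,
                 bandwidths = c(Intercept = 15, X1 = 15, X2 = 15))
  gf <- fit_gwr(p, bandwidth = 15, standardize = TRUE)
  expect_gt(max(abs(mf$beta - gf$beta)), 1e-3)
})

test_that("AICc agrees with an independent closed-form reimplementation", {
  aicc_oracle <- function(n, rss, trS)
    2 * n * log(sqrt(rss / n)) + n * log(2 * pi) +
      n * (n + trS) / (n - 2 - trS)
  p <- vc_fixture()
  g <- fit_gwr(p, bandwidth = 14)
  expect_equal(g$aicc, aicc_oracle(g$n, g$rss, g$enp), tolerance = 1e-9)
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(30:200, 1); rss <- runif(1, 1, 50); trS <- runif(1, 3, 20)
    expect_equal(spatdrivers:::gwr_aicc(n, rss, trS),
                 aicc_oracle(n, rss, trS), tolerance = 1e-9)
  }
})

test_that("model comparison table and regional coefficient means", {
  p <- vc_fixture()
  g <- fit_gwr(p, bandwidth = 20, standardize = TRUE)
  m <- fit_mgwr(p)
  tab <- compare_models(g, m)
  expect_equal(tab$index[c(1, 4)], c("Residual Squares", "AICc"))
  expect_equal(tab$GWR[1], g$rss)
  expect_equal(tab$MGWR[5], m$r2)
  # self-comparison of identical models gives identical rows
  tab2 <- compare_models(g, m)
  expect_identical(tab, tab2)
  # CSV round trip at full precision
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(format(tab, digits = 15), f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(as.numeric(back$GWR), tab$GWR, tolerance = 1e-12)

  grp <- as.data.frame(p)$group
  rm1 <- regional_mean_coefficients(m, grp)
  expect_equal(nrow(rm1), 3)
  # group-by oracle
  for (g3 in unique(grp))
    expect_equal(unname(unlist(rm1[rm1$group == g3, colnames(m$beta)])),
                 unname(colMeans(m$beta[grp == g3, ])), tolerance = 1e-12)
  # single group = plain column means; flagged max-|coefficient| covariate
  rall <- regional_mean_coefficients(m, rep("Z", m$n))
  expect_equal(unname(unlist(rall[1, colnames(m$beta)])),
               unname(colMeans(m$beta)), tolerance = 1e-12)
  covs <- setdiff(colnames(m$beta), "Intercept")
  expect_equal(rall$top_covariate,
               covs[which.max(abs(colMeans(m$beta))[covs])])
  expect_error(regional_mean_coefficients(m, c(NA, grp[-1])), "missing")
})
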