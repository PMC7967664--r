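test_that("q closed forms: worked example and the two limits", {
  expect_equal(factor_q(c(1, 2, 3, 4), strata_assignment(c("A", "A", "B", "B")),
                        p_method = "none")$q, 0.8, tolerance = 1e-12)
  # single stratum: sigma_h = sigma -> q = 0
  expect_equal(factor_q(c(1, 2, 3), strata_assignment(c(1, 1, 1)),
                        p_method = "none")$q, 0)
  # zero within-stratum variance -> q = 1
  expect_equal(factor_q(c(2, 2, 7, 7), strata_assignment(c(1, 1, 2, 2)),
                        p_method = "none")$q, 1)
  expect_error(factor_q(rep(1, 4), strata_assignment(c(1, 1, 2, 2))),
               "zero total variance")
})

test_that("q matches the group-by oracle and stays in [0, 1]", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    L <- sample(2:5, 1)
    y <- rnorm(n, rep(seq_len(L), length.out = n))
    h <- sample(seq_len(L), n, TRUE)
    h[seq_len(L)] <- seq_len(L)          # ensure non-empty strata
    q <- factor_q(y, strata_assignment(h), p_method = "none")$q
    expect_equal(q, oracle_q(y, h), tolerance = 1e-12)
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("q is invariant to affine response transforms and grows under refinement", {
  set.seed(6)
  y <- rnorm(60, rep(1:3, each = 20))
  h <- rep(1:3, each = 20)
  q0 <- factor_q(y, strata_assignment(h), p_method = "none")$q
  qa <- factor_q(-2.5 * y + 7, strata_assignment(h), p_method = "none")$q
  expect_equal(qa, q0, tolerance = 1e-12)
  for (rep in 1:5) {
    h2 <- h
    split_at <- sample(which(h == sample(1:3, 1)), 5)
    h2[split_at] <- 4L                    # refine: split one stratum
    q2 <- factor_q(y, strata_assignment(h2), p_method = "none")$q
    expect_gte(q2, q0 - 1e-12)
  }
})

test_that("q significance: strong signal small p, permuted labels large p", {
  scene <- generate_strata_scene(L = 4, n = 200, between_sd = 2,
                                 within_sd = 0.5, seed = 3)
  r <- factor_q(scene$y, scene$strata)
  expect_lt(r$p, 1e-6)
  set.seed(8)
  rnull <- factor_q(sample(scene$y), scene$strata)
  expect_gt(rnull$p, 0.001)
  rperm <- factor_q(scene$y, scene$strata, p_method = "permutation",
                    n_perm = 199, seed = 2)
  expect_lte(rperm$p, 0.01)
})

test_that("natural breaks: stated example, saturation, exhaustive optimality", {
  s <- discretize_natural_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(s$h, c(1, 1, 1, 2, 2, 2))
  # k = number of distinct values -> singletons, SSW = 0
  s2 <- discretize_natural_breaks(c(4, 8, 15, 16), k = 4)
  expect_equal(sort(unique(s2$h)), 1:4)
  expect_equal(s2$ssw, 0)
  expect_error(discretize_natural_breaks(c(1, 1, 2), k = 3), "distinct")

  set.seed(9)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    x <- round(rnorm(n, sd = 5), 2)
    if (length(unique(x)) < k) next
    s3 <- discretize_natural_breaks(x, k)
    expect_equal(s3$ssw, oracle_jenks_ssw(x, k), tolerance = 1e-9)
    # classes contiguous in value
    expect_true(all(diff(s3$h[order(x)]) >= 0))
  }
})

test_that("weighted DP equals unweighted DP on replicated values", {
  x <- c(1, 2, 3, 10, 11, 12, 30)
  xr <- rep(x, times = c(5, 1, 2, 4, 1, 3, 2))
  s <- discretize_natural_breaks(xr, k = 3)
  expect_equal(s$ssw, oracle_jenks_ssw(xr, 3), tolerance = 1e-9)
})

test_that("ecological detector: self-comparison N, extreme separation Y, relabeling", {
  set.seed(11)
  y <- rnorm(200, rep(1:4, each = 50), 0.3)
  sA <- strata_assignment(rep(1:4, each = 50))       # strong
  sB <- strata_assignment(sample(rep(1:4, 50)))      # useless
  expect_equal(ecological_detector(y, sA, sA)$significant, "N")
  expect_equal(ecological_detector(y, sA, sB)$significant, "Y")
  # label permutation leaves the decision unchanged
  relab <- strata_assignment(c(4, 3, 2, 1)[sA$h])
  expect_equal(ecological_detector(y, relab, sB)$F,
               ecological_detector(y, sA, sB)$F, tolerance = 1e-12)
})

test_that("interaction detector: overlay identity, enhancement, oracle", {
  set.seed(12)
  n <- 300
  a <- rep(1:3, each = 100)
  b <- rep(rep(1:3, each = 20), 5)[1:n]
  y <- a + 2 * b + rnorm(n, 0, 0.5)      # additive two-factor field
  sA <- strata_assignment(a); sB <- strata_assignment(b)
  # constant second factor: overlay == A
  sConst <- strata_assignment(rep(1, n))
  expect_equal(interaction_detector(y, sA, sConst)$q_AB,
               factor_q(y, sA, p_method = "none")$q, tolerance = 1e-12)
  res <- interaction_detector(y, sA, sB)
  expect_true(res$enhanced)
  expect_gt(res$q_AB, max(res$q_A, res$q_B))
  # brute-force overlay grouping
  expect_equal(res$q_AB, oracle_q(y, paste(a, b)), tolerance = 1e-12)
})

test_that("grid sampling: counts, inheritance, area scaling", {
  square <- unit_polygons("sq", list(list(rbind(c(0, 0), c(20, 0), c(20, 20),
                                               c(0, 20), c(0, 0)))))
  vals <- data.frame(unit_id = "sq", y_resp = 42, X1 = 7)
  gs <- grid_sample(square, vals, spacing_km = 10)
  expect_equal(nrow(gs), 4)
  expect_true(all(gs$y_resp == 42 & gs$X1 == 7))
  gs5 <- grid_sample(square, vals, spacing_km = 5)
  expect_equal(nrow(gs5), 16)
  expect_error(grid_sample(square, vals, spacing_km = 1000), "smaller spacing")

  # multi-unit: each point inherits its own unit's value
  polys <- lattice_polygons(2, 2, size = 10)
  v2 <- data.frame(unit_id = as.character(1:4), y_resp = c(1, 2, 3, 4) * 10)
  g2 <- grid_sample(polys, v2, spacing_km = 5)
  expect_equal(nrow(g2), 16)
  expect_equal(sort(unique(g2$y_resp)), c(10, 20, 30, 40))
  expect_equal(as.vector(table(g2$unit_id)), rep(4, 4))
})

test_that("parameter recovery: q estimates the between-variance share", {
  scene <- generate_strata_scene(L = 8, n = 20000, between_sd = 1,
                                 within_sd = 0.8, seed = 21)
  q <- factor_q(scene$y, scene$strata, p_method = "none")$q
  # theoretical share from the realized stratum means
  expect_equal(q, scene$true_q, tolerance = 1e-12)
  expect_lt(abs(q - (1 - 0.8^2 / var(scene$y))), 0.02)
})
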