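#' Stratum assignment for the geodetector
#'
#' @param h integer/factor/character vector of stratum memberships; levels
#'   are re-indexed to 1..L keeping their order of appearance in sorted
#'   unique values.
#' @param breaks optional numeric breakpoints recording how a continuous
#'   variable was discretized (provenance only).
#' @return a `strata_assignment`: list with `h` (integer in 1..L), `L`,
#'   `levels`, `breaks`.
#' @export
strata_assignment <- function(h, breaks = NULL) {
  f <- factor(h)
  if (any(is.na(f))) stop2("missing stratum membership")
  if (any(table(f) == 0)) stop2("empty stratum")
  structure(list(h = as.integer(f), L = nlevels(f), levels = levels(f),
                 breaks = breaks),
            class = "strata_assignment")
}

#' Discretize a continuous variable by natural breaks (Jenks/Fisher)
#'
#' Finds the k-class partition of the sorted values that minimizes the total
#' within-class sum of squared deviations, by exact dynamic programming over
#' the unique values (weighted by their multiplicities), i.e. Fisher's
#' optimal 1-D classification. Classes are contiguous in value.
#'
#' @param values numeric vector.
#' @param k number of classes (>= 2; default 8, a common choice for
#'   detector-style analyses).
#' @return a [strata_assignment()] with `breaks` = the k-1 interior
#'   breakpoints (upper edges of classes 1..k-1, taken as the midpoint
#'   between adjacent class-boundary values).
#' @export
discretize_natural_breaks <- function(values, k = 8) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop2("non-finite values")
  if (k < 2) stop2("k must be >= 2")
  ux <- sort(unique(x))
  u <- length(ux)
  if (u < k) stop2("fewer distinct values (", u, ") than classes (", k, ")")
  wt <- as.numeric(table(factor(x, levels = ux)))
  # prefix sums over unique values, zero-padded so index a maps to sum(1..a-1)
  cw <- c(0, cumsum(wt)); cs <- c(0, cumsum(wt * ux))
  cs2 <- c(0, cumsum(wt * ux^2))
  seg_cost <- function(a, b) {
    # weighted SSW of unique values a..b (vectorized over a)
    W <- cw[b + 1L] - cw[a]
    S <- cs[b + 1L] - cs[a]
    S2 <- cs2[b + 1L] - cs2[a]
    pmax(S2 - S^2 / W, 0)
  }
  D <- matrix(Inf, u, k)    # D[i, c]: min SSW of first i uniques in c classes
  B <- matrix(0L, u, k)     # argmin last-class start
  D[, 1] <- seg_cost(rep(1L, u), seq_len(u))
  B[, 1] <- 1L
  if (k > 1) for (cc in 2:k) {
    for (i in cc:u) {
      starts <- cc:i                     # last class covers starts..i
      tot <- D[starts - 1L, cc - 1L] + seg_cost(starts, i)
      m <- which.min(tot)
      D[i, cc] <- tot[m]
      B[i, cc] <- starts[m]
    }
  }
  # backtrack class boundaries on unique values
  bounds <- integer(k + 1L)
  bounds[k + 1L] <- u
  i <- u
  for (cc in k:1) {
    s <- B[i, cc]
    bounds[cc] <- s - 1L
    i <- s - 1L
  }
  # interior breakpoints: midpoint between last value of class c and first of c+1
  brk <- vapply(1:(k - 1L), function(cc)
    (ux[bounds[cc + 1L]] + ux[bounds[cc + 1L] + 1L]) / 2, numeric(1))
  h <- findInterval(x, brk) + 1L
  out <- strata_assignment(h, breaks = brk)
  out$ssw <- D[u, k]
  out
}

#' Geodetector factor detector (q-statistic)
#'
#' \deqn{q = 1 - \frac{\sum_{h=1}^L N_h \sigma_h^2}{N \sigma^2}}
#' with population (divide-by-N) variances, measuring the share of the
#' response's spatial variance explained by the stratification; q is in
#' \eqn{[0, 1]}. Significance uses the noncentral-F approximation
#' \eqn{F = \frac{N-L}{L-1}\frac{q}{1-q} \sim F(L-1, N-L; \lambda)} with
#' \eqn{\lambda = \big(\sum_h \bar y_h^2 - (\sum_h \sqrt{N_h}\,\bar y_h)^2/N\big)/\sigma^2};
#' a seeded permutation fallback is available.
#'
#' @param y numeric response sampled over points/units.
#' @param s a [strata_assignment()] on the same samples.
#' @param p_method `"ncf"` (noncentral F, default), `"permutation"`, or
#'   `"none"`.
#' @param n_perm,seed permutation settings when `p_method = "permutation"`.
#' @return a `q_result`: list with `q`, `p`, `N`, `L`, `Nh`, `sigma2_h`,
#'   `sigma2`, `means_h`.
#' @export
factor_q <- function(y, s, p_method = c("ncf", "permutation", "none"),
                     n_perm = 999, seed = 1L) {
  p_method <- match.arg(p_method)
  y <- as.numeric(y)
  if (!inherits(s, "strata_assignment")) s <- strata_assignment(s)
  if (length(y) != length(s$h)) stop2("y and strata lengths differ")
  if (any(!is.finite(y))) stop2("non-finite response values")
  N <- length(y)
  pvar <- function(v) mean((v - mean(v))^2)
  sigma2 <- pvar(y)
  if (sigma2 == 0) stop2("zero total variance")
  Nh <- tabulate(s$h, nbins = s$L)
  if (any(Nh == 0)) stop2("empty stratum")
  means_h <- vapply(split(y, s$h), mean, numeric(1))
  s2h <- vapply(split(y, s$h), pvar, numeric(1))
  q <- 1 - sum(Nh * s2h) / (N * sigma2)
  q <- min(max(q, 0), 1)
  p <- NA_real_
  if (p_method == "ncf" && s$L > 1 && N > s$L) {
    Fv <- ((N - s$L) / (s$L - 1)) * q / max(1 - q, .Machine$double.eps)
    lambda <- (sum(means_h^2) - (sum(sqrt(Nh) * means_h))^2 / N) / sigma2
    p <- stats::pf(Fv, s$L - 1, N - s$L, ncp = max(lambda, 0),
                   lower.tail = FALSE)
  } else if (p_method == "permutation") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    qs <- vapply(seq_len(n_perm), function(b) {
      yp <- y[sample.int(N)]
      s2 <- vapply(split(yp, s$h), pvar, numeric(1))
      1 - sum(Nh * s2) / (N * sigma2)
    }, numeric(1))
    p <- (1 + sum(qs >= q - 1e-15)) / (1 + n_perm)
  }
  structure(list(q = q, p = p, N = N, L = s$L, Nh = Nh, sigma2_h = s2h,
                 sigma2 = sigma2, means_h = means_h, p_method = p_method),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("q = %.4f (L = %d strata, N = %d, p = %s)\n",
              x$q, x$L, x$N,
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Geodetector ecological detector
#'
#' Tests whether two stratifications differ significantly in explanatory
#' power, via the ratio of their within-stratum sums of squares
#' \eqn{F = SSW_A / SSW_B} referred (two-sided) to \eqn{F(N-1, N-1)}.
#' The decision is symmetric in A and B and invariant to stratum relabeling.
#'
#' @param y response values.
#' @param sA,sB two [strata_assignment()]s over the same samples.
#' @param alpha significance level (default 0.05).
#' @return list with `significant` ("Y"/"N"), `F`, `p`, `ssw_A`, `ssw_B`.
#' @export
ecological_detector <- function(y, sA, sB, alpha = 0.05) {
  qa <- factor_q(y, sA, p_method = "none")
  qb <- factor_q(y, sB, p_method = "none")
  N <- qa$N
  ssw_a <- sum(qa$Nh * qa$sigma2_h)
  ssw_b <- sum(qb$Nh * qb$sigma2_h)
  if (ssw_a == 0 && ssw_b == 0) {
    Fv <- 1; p <- 1
  } else if (ssw_b == 0 || ssw_a == 0) {
    Fv <- if (ssw_b == 0) Inf else 0; p <- 0
  } else {
    Fv <- ssw_a / ssw_b
    p <- 2 * min(stats::pf(Fv, N - 1, N - 1),
                 stats::pf(Fv, N - 1, N - 1, lower.tail = FALSE))
    p <- min(p, 1)
  }
  list(significant = if (p < alpha) "Y" else "N", F = Fv, p = p,
       ssw_A = ssw_a, ssw_B = ssw_b, alpha = alpha)
}

#' Geodetector interaction detector
#'
#' Computes q on the overlay stratification (distinct pairs of strata of A
#' and B present in the data) and classifies the interaction against the
#' single-factor q's:
#' nonlinear-weaken (q_AB < min), uni-weaken (min <= q_AB < max),
#' bi-enhance (max < q_AB < q_A + q_B), independent (q_AB = q_A + q_B,
#' tolerance 1e-9), nonlinear-enhance (q_AB > q_A + q_B).
#'
#' @inheritParams ecological_detector
#' @return list with `q_AB`, `q_A`, `q_B`, `class`, `enhanced` (logical),
#'   `overlay` (the overlay [strata_assignment()]).
#' @export
interaction_detector <- function(y, sA, sB) {
  if (!inherits(sA, "strata_assignment")) sA <- strata_assignment(sA)
  if (!inherits(sB, "strata_assignment")) sB <- strata_assignment(sB)
  overlay <- strata_assignment(paste(sA$h, sB$h, sep = ":"))
  if (overlay$L > length(y) / 2)
    warn2("overlay has more than N/2 strata; interaction q may be overfit")
  q_ab <- factor_q(y, overlay, p_method = "none")$q
  q_a <- factor_q(y, sA, p_method = "none")$q
  q_b <- factor_q(y, sB, p_method = "none")$q
  lo <- min(q_a, q_b); hi <- max(q_a, q_b); sm <- q_a + q_b
  tol <- 1e-9
  cls <- if (abs(q_ab - sm) <= tol) "independent"
  else if (q_ab > sm) "nonlinear-enhance"
  else if (q_ab > hi) "bi-enhance"
  else if (q_ab >= lo) "uni-weaken"
  else "nonlinear-weaken"
  list(q_AB = q_ab, q_A = q_a, q_B = q_b, class = cls,
       enhanced = q_ab > hi, overlay = overlay)
}

# ---- grid sampling ----------------------------------------------------------

point_in_ring <- function(px, py, ring) {
  # even-odd ray casting; boundary points count as inside
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

point_in_unit <- function(px, py, rings) {
  out <- rep(FALSE, length(px))
  for (r in rings) out <- out | point_in_ring(px, py, r)
  out
}

#' Sample unit attributes on a regular grid
#'
#' Lays a square lattice of the given spacing over the bounding box of the
#' unit polygons (offset half a spacing from the lower-left corner), keeps
#' the points falling inside a unit, and attaches that unit's attribute
#' values to each point. Each point is assigned to the first unit containing
#' it (units are assumed non-overlapping).
#'
#' @param geoms a `unit_polygons` object, planar km coordinates.
#' @param values_by_unit data.frame with a `unit_id` column and one column
#'   per attribute to inherit.
#' @param spacing_km grid spacing in km (default 10).
#' @return data.frame with `x`, `y`, `unit_id` and the inherited attribute
#'   columns; one row per retained grid point.
#' @export
grid_sample <- function(geoms, values_by_unit, spacing_km = 10) {
  stopifnot(inherits(geoms, "unit_polygons"))
  assert_scalar_number(spacing_km, "spacing_km", lower = 1e-9)
  allpts <- do.call(rbind, lapply(geoms$rings, function(rs) do.call(rbind, rs)))
  if (min(allpts[, 1]) + spacing_km / 2 > max(allpts[, 1]) ||
      min(allpts[, 2]) + spacing_km / 2 > max(allpts[, 2]))
    stop2("no grid point falls inside any unit; try a smaller spacing")
  gx <- seq(min(allpts[, 1]) + spacing_km / 2, max(allpts[, 1]), by = spacing_km)
  gy <- seq(min(allpts[, 2]) + spacing_km / 2, max(allpts[, 2]), by = spacing_km)
  pts <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  unit <- rep(NA_character_, nrow(pts))
  for (k in seq_along(geoms$ids)) {
    todo <- is.na(unit)
    if (!any(todo)) break
    hit <- point_in_unit(pts$x[todo], pts$y[todo], geoms$rings[[k]])
    unit[which(todo)[hit]] <- geoms$ids[k]
  }
  keep <- !is.na(unit)
  if (!any(keep))
    stop2("no grid point falls inside any unit; try a smaller spacing")
  out <- data.frame(x = pts$x[keep], y = pts$y[keep], unit_id = unit[keep],
                    stringsAsFactors = FALSE)
  mi <- match(out$unit_id, as.character(values_by_unit$unit_id))
  if (any(is.na(mi))) stop2("grid point in a unit absent from values_by_unit")
  for (cl in setdiff(names(values_by_unit), "unit_id"))
    out[[cl]] <- values_by_unit[[cl]][mi]
  out
}
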