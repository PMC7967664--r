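#' Gaussian kernel specification
#'
#' @param mode `"adaptive"` (bandwidth = neighbour count k; the kernel scale
#'   at each focal unit is the distance to its k-th nearest unit, the unit
#'   itself counting as the first) or `"fixed"` (bandwidth = distance b in
#'   the units of the coordinates).
#' @param bandwidth neighbour count (adaptive) or distance (fixed).
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(mode = c("adaptive", "fixed"), bandwidth) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    assert_scalar_number(bandwidth, "bandwidth", lower = 1e-12)
  } else {
    assert_scalar_number(bandwidth, "bandwidth", lower = 1)
    bandwidth <- as.integer(round(bandwidth))
  }
  structure(list(mode = mode, bandwidth = bandwidth), class = "kernel_spec")
}

#' Gaussian kernel weights from a focal unit's distances
#'
#' \eqn{w = \exp(-(d/b)^2)}; in adaptive mode b is the distance to the k-th
#' nearest unit among `dists` (self included when its zero distance is in
#' the vector).
#'
#' @param dists non-negative distances from the focal unit to every unit.
#' @param spec a [kernel_spec()].
#' @return numeric weight vector, 1 at distance zero.
#' @export
kernel_weights <- function(dists, spec) {
  d <- as.numeric(dists)
  if (any(d < 0)) stop2("distances must be non-negative")
  b <- if (spec$mode == "fixed") spec$bandwidth
  else {
    k <- min(spec$bandwidth, length(d))
    sort(d, partial = k)[k]
  }
  if (b <= 0) stop2("bandwidth must be positive (duplicate coordinates?)")
  exp(-(d / b)^2)
}

# ---- shared internals -------------------------------------------------------

gwr_design <- function(panel, covariates, standardize) {
  df <- as.data.frame(panel)
  y <- df$y_resp
  X <- as.matrix(df[, covariates, drop = FALSE])
  scl <- NULL
  if (standardize) {
    ym <- mean(y); ys <- stats::sd(y)
    xm <- colMeans(X); xs <- apply(X, 2, stats::sd)
    if (ys == 0 || any(xs == 0)) stop2("cannot standardize constant column")
    y <- (y - ym) / ys
    X <- sweep(sweep(X, 2, xm), 2, xs, "/")
    scl <- list(y_mean = ym, y_sd = ys, x_mean = xm, x_sd = xs)
  }
  coords <- cbind(df$x, df$y)
  if (anyDuplicated(coords)) {
    warn2("duplicate coordinates; applying deterministic micro-jitter")
    rng <- max(diff(range(coords[, 1])), diff(range(coords[, 2])), 1)
    dup <- duplicated(coords)
    coords[dup, 1] <- coords[dup, 1] + rng * 1e-9 * seq_len(sum(dup))
  }
  D <- as.matrix(stats::dist(coords))
  X <- cbind(Intercept = 1, X)
  rownames(X) <- NULL
  list(y = unname(y), X = X, coords = coords, scale = scl,
       D = unname(D), Dsort = t(apply(unname(D), 1, sort)))
}

row_bandwidths <- function(D, spec, Dsort = NULL) {
  if (spec$mode == "fixed") rep(spec$bandwidth, nrow(D))
  else {
    k <- min(spec$bandwidth, ncol(D))
    b <- if (!is.null(Dsort)) Dsort[, k]
    else apply(D, 1, function(d) sort(d, partial = k)[k])
    if (any(b <= 0)) stop2("adaptive bandwidth hits duplicate coordinates")
    b
  }
}

kernel_matrix <- function(D, spec, Dsort = NULL) {
  b <- row_bandwidths(D, spec, Dsort)
  exp(-(D / b)^2)            # b recycles down rows: D[i, j] / b[i]
}

# local WLS at every unit; returns coefficients, hat diagonal, optionally the
# full hat matrix and its exact per-term decomposition S = sum_j R_j with
# R_j[i, ] = x_j(i) * row j of (X'W_iX)^{-1} X'W_i
gwr_local_fits <- function(y, X, Wmat, hat = FALSE, term_hats = FALSE) {
  n <- nrow(X); p <- ncol(X)
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  sdiag <- numeric(n)
  S <- if (hat) matrix(0, n, n) else NULL
  Rlist <- if (term_hats) lapply(seq_len(p), function(j) matrix(0, n, n))
  for (i in seq_len(n)) {
    w <- Wmat[i, ]
    Xw <- X * w
    M <- crossprod(X, Xw)
    Minv <- tryCatch(solve(M), error = function(e)
      stop2("singular local design at unit ", i,
            "; increase the bandwidth"))
    bi <- Minv %*% crossprod(Xw, y)
    beta[i, ] <- bi
    if (term_hats) {
      Bi <- Minv %*% t(Xw)                 # p x n projector rows
      for (j in seq_len(p)) Rlist[[j]][i, ] <- X[i, j] * Bi[j, ]
      ei <- X[i, , drop = FALSE] %*% Bi
    } else {
      ei <- X[i, , drop = FALSE] %*% Minv %*% t(Xw) # hat row
    }
    sdiag[i] <- ei[1, i]
    if (hat) S[i, ] <- ei
  }
  list(beta = beta, sdiag = sdiag, S = S, Rlist = Rlist)
}

# small-sample corrected AIC for a linear smoother with trace trS
gwr_aicc <- function(n, rss, trS) {
  if (n - 2 - trS <= 0) return(Inf)
  2 * n * log(sqrt(rss / n)) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)
}

gwr_score <- function(y, X, D, spec, Dsort = NULL) {
  Wmat <- kernel_matrix(D, spec, Dsort)
  lf <- gwr_local_fits(y, X, Wmat, hat = FALSE)
  yhat <- rowSums(X * lf$beta)
  rss <- sum((y - yhat)^2)
  gwr_aicc(length(y), rss, sum(lf$sdiag))
}

# ---- GWR --------------------------------------------------------------------

#' Fit a geographically weighted regression
#'
#' At every unit a weighted least-squares regression of the response on the
#' covariates (plus intercept) is fitted with Gaussian kernel weights
#' centred on that unit, giving local coefficient surfaces. Diagnostics
#' come from the assembled hat matrix S: effective number of parameters
#' ENP = tr(S), sigma = sqrt(RSS / (n - tr S)), the small-sample corrected
#' AICc, global and local R^2.
#'
#' @param panel a [city_panel()] holding one time slice.
#' @param covariates covariate names (default: all panel covariates).
#' @param bandwidth neighbour count (adaptive) or kernel distance (fixed);
#'   when `NULL`, selected by [select_bandwidth()].
#' @param kernel `"adaptive"` (default) or `"fixed"` Gaussian kernel.
#' @param standardize z-score response and covariates before fitting
#'   (default `FALSE` for plain GWR).
#' @return a `gwr_fit`: `beta` (n x (p+1) local coefficients, first column
#'   `Intercept`), `yhat`, `residuals`, `rss`, `enp`, `sigma`, `aicc`,
#'   `r2`, `adj_r2`, `local_r2`, `bandwidth`, `kernel`, `S` (hat matrix),
#'   `scale` (standardization constants or `NULL`).
#' @export
fit_gwr <- function(panel, covariates = panel_covariates(panel),
                    bandwidth = NULL, kernel = c("adaptive", "fixed"),
                    standardize = FALSE) {
  kernel <- match.arg(kernel)
  des <- gwr_design(panel, covariates, standardize)
  n <- length(des$y); p <- ncol(des$X)
  if (n <= p + 2) stop2("need more than p + 2 units")
  if (is.null(bandwidth)) {
    sel <- select_bandwidth(panel, covariates, kernel = kernel,
                            standardize = standardize)
    bandwidth <- sel$bandwidth
  }
  spec <- kernel_spec(kernel, bandwidth)
  Wmat <- kernel_matrix(des$D, spec, des$Dsort)
  lf <- gwr_local_fits(des$y, des$X, Wmat, hat = TRUE)
  yhat <- unname(rowSums(des$X * lf$beta))
  resid <- des$y - yhat
  rss <- sum(resid^2)
  enp <- sum(diag(lf$S))
  tss <- sum((des$y - mean(des$y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - enp - 1)
  local_r2 <- vapply(seq_len(n), function(i) {
    w <- Wmat[i, ]
    fit_i <- drop(des$X %*% lf$beta[i, ])
    ybar_w <- sum(w * des$y) / sum(w)
    1 - sum(w * (des$y - fit_i)^2) / sum(w * (des$y - ybar_w)^2)
  }, numeric(1))
  structure(list(beta = lf$beta, yhat = yhat, residuals = resid, rss = rss,
                 enp = enp, sigma = sqrt(rss / (n - enp)),
                 aicc = gwr_aicc(n, rss, enp), r2 = r2, adj_r2 = adj_r2,
                 local_r2 = local_r2, bandwidth = spec$bandwidth,
                 kernel = kernel, S = lf$S, n = n, covariates = covariates,
                 scale = des$scale, y = des$y, X = des$X),
            class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf("<gwr_fit> n = %d, bandwidth = %s (%s), ENP = %.2f, AICc = %.2f, R2 = %.3f\n",
              x$n, format(x$bandwidth), x$kernel, x$enp, x$aicc, x$r2))
  invisible(x)
}

#' Select a GWR bandwidth by AICc
#'
#' Golden-section search minimizing the corrected AIC; adaptive candidates
#' are rounded to integer neighbour counts and, once the bracket closes,
#' all remaining integers in it are scanned with ties broken toward the
#' smaller (more local) bandwidth. If the evaluated profile is detectably
#' non-unimodal a warning is raised and a full grid scan is used instead.
#'
#' @inheritParams fit_gwr
#' @param bounds length-2 bandwidth bounds; default `[p+2, n]` neighbour
#'   counts (adaptive) or `[d_min, 2 d_max]` pairwise distances (fixed).
#' @param method `"golden"` (default) or `"grid"` (exhaustive over integers;
#'   adaptive only).
#' @return list with `bandwidth`, `aicc`, `trace` (data.frame of evaluated
#'   bandwidth/AICc pairs in evaluation order) and `method`.
#' @export
select_bandwidth <- function(panel, covariates = panel_covariates(panel),
                             kernel = c("adaptive", "fixed"),
                             bounds = NULL, method = c("golden", "grid"),
                             standardize = FALSE) {
  kernel <- match.arg(kernel)
  method <- match.arg(method)
  des <- gwr_design(panel, covariates, standardize)
  n <- length(des$y); p <- ncol(des$X)
  if (is.null(bounds)) {
    bounds <- if (kernel == "adaptive") c(p + 2, n)
    else {
      dpos <- des$D[des$D > 0]
      c(min(dpos), 2 * max(dpos))
    }
  }
  score <- function(b) gwr_score(des$y, des$X, des$D, kernel_spec(kernel, b),
                                 des$Dsort)
  res <- golden_min(score, bounds, adaptive = kernel == "adaptive",
                    grid = method == "grid", warn_multimodal = TRUE,
                    presample = 8)
  list(bandwidth = if (kernel == "adaptive") as.integer(res$best)
       else res$best,
       aicc = res$score,
       trace = data.frame(bandwidth = res$trace_b, aicc = res$trace_s),
       method = method, kernel = kernel)
}

# Golden-section minimizer over bandwidths, memoized; integer-valued in
# adaptive mode (ties broken toward the smaller bandwidth, i.e. more local
# detail). Detects a clearly non-unimodal evaluated profile and falls back
# to a full integer grid scan with a warning.
golden_min <- function(f, bounds, adaptive, grid = FALSE,
                       warn_multimodal = FALSE, presample = 0) {
  if (bounds[1] >= bounds[2]) stop2("invalid bandwidth bounds")
  memo <- new.env(parent = emptyenv())
  trace_b <- numeric(); trace_s <- numeric()
  fm <- function(b) {
    key <- format(b, digits = 12)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- f(b)
    memo[[key]] <- v
    trace_b <<- c(trace_b, b); trace_s <<- c(trace_s, v)
    v
  }
  pick <- function() {
    o <- order(trace_s, trace_b)
    list(best = trace_b[o[1]], score = trace_s[o[1]],
         trace_b = trace_b, trace_s = trace_s)
  }
  grid_scan <- function() {
    for (b in seq(ceiling(bounds[1]), floor(bounds[2]))) fm(b)
    pick()
  }
  if (adaptive && grid) return(grid_scan())
  invphi <- (sqrt(5) - 1) / 2
  a <- bounds[1]; b <- bounds[2]
  val <- function(x) if (adaptive) round(x) else x
  if (presample > 1) {
    # coarse log-spaced scan to land the golden bracket in the right basin
    cand <- unique(val(exp(seq(log(max(a, 1e-12)), log(b),
                               length.out = presample))))
    sc <- vapply(cand, fm, numeric(1))
    k <- which.min(sc)
    a <- if (k > 1) cand[k - 1] else a
    b <- if (k < length(cand)) cand[k + 1] else b
    if (a >= b) { a <- bounds[1]; b <- bounds[2] }
  }
  x1 <- b - invphi * (b - a); x2 <- a + invphi * (b - a)
  f1 <- fm(val(x1)); f2 <- fm(val(x2))
  while ((adaptive && (b - a) > 3) ||
         (!adaptive && (b - a) > 1e-3 * (bounds[2] - bounds[1]))) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - invphi * (b - a); f1 <- fm(val(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + invphi * (b - a); f2 <- fm(val(x2))
    }
  }
  if (adaptive) for (bb in seq(ceiling(a), floor(b))) fm(bb)
  else fm(val((a + b) / 2))
  out <- pick()
  # unimodality check: rise-fall-rise with non-trivial amplitude
  o <- order(trace_b)
  sc <- trace_s[o]
  fin <- is.finite(sc)
  if (sum(fin) >= 4) {
    scf <- sc[fin]
    amp <- max(scf) - min(scf)
    d <- diff(scf)
    d[abs(d) < max(1e-3 * amp, 1e-9)] <- 0
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    if (sign_changes > 1) {
      if (warn_multimodal)
        warn2("AICc profile looks non-unimodal; falling back to a grid scan")
      if (adaptive) out <- grid_scan()
    }
  }
  out
}

# ---- MGWR -------------------------------------------------------------------

# smoother matrix of a one-term local regression of u on x (no intercept)
term_smoother <- function(x, Wmat) {
  denom <- drop(Wmat %*% (x * x))
  Tm <- sweep(Wmat, 2, x, "*")          # w_ij * x_j
  S <- sweep(Tm, 1, denom, "/") * x     # x_i * w_ij * x_j / denom_i
  list(S = S, denom = denom)
}

term_aicc <- function(u, x, D, spec, Dsort = NULL) {
  Wmat <- kernel_matrix(D, spec, Dsort)
  denom <- drop(Wmat %*% (x * x))
  betai <- drop(Wmat %*% (x * u)) / denom
  fhat <- x * betai
  rss <- sum((u - fhat)^2)
  trS <- sum(x * x / denom)             # w_ii = 1 at distance 0
  gwr_aicc(length(u), rss, trS)
}

select_term_bandwidth <- function(u, x, D, kernel, bounds, Dsort = NULL) {
  res <- golden_min(function(b)
    term_aicc(u, x, D, kernel_spec(kernel, b), Dsort),
    bounds, adaptive = kernel == "adaptive", presample = 8)
  res$best
}

#' Fit a multiscale geographically weighted regression
#'
#' Additive model in which every term (the intercept included) has its own
#' coefficient surface and its own kernel bandwidth, fitted by backfitting:
#' terms are initialized from a GWR fit at its AICc-optimal single bandwidth
#' (so every term starts with locally-correct structure; an OLS start is
#' available), then cycled over; at each step the partial residual for a
#' term is smoothed by a one-term local regression whose bandwidth is
#' re-optimized by AICc, until the SOC-f score (root mean squared change of
#' the fitted values, normalized by their root mean square) falls below
#' `tol`. Per-term smoother matrices are accumulated exactly (the GWR
#' initializer's hat matrix is decomposed exactly across terms), so per-term
#' ENPs sum to the total ENP.
#'
#' Response and covariates are z-scored by default (the convention of the
#' multiscale GWR literature, which makes bandwidths and coefficients
#' comparable across terms); set `standardize = FALSE` to fit on raw scales.
#'
#' @inheritParams fit_gwr
#' @param tol SOC-f convergence tolerance (default 1e-5).
#' @param max_iter maximum backfitting cycles (default 200).
#' @param bandwidths optional named numeric vector (names = `"Intercept"`
#'   and covariate names) forcing fixed per-term bandwidths; when supplied
#'   no bandwidth search is done.
#' @param init `"gwr"` (default when bandwidths are searched) or `"ols"`
#'   (default when bandwidths are forced) starting fit for the additive
#'   terms.
#' @return an `mgwr_fit`: `beta` (n x terms local coefficients), per-term
#'   `bandwidths` and `enp_terms`, global `enp`, `rss`, `sigma`, `aicc`,
#'   `r2`, `adj_r2`, `yhat`, `residuals`, `trace` (iteration/score),
#'   `converged`, `scale`.
#' @export
fit_mgwr <- function(panel, covariates = panel_covariates(panel),
                     kernel = c("adaptive", "fixed"), standardize = TRUE,
                     tol = 1e-5, max_iter = 200, bandwidths = NULL,
                     init = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(init)) init <- if (is.null(bandwidths)) "gwr" else "ols"
  init <- match.arg(init, c("gwr", "ols"))
  des <- gwr_design(panel, covariates, standardize)
  y <- des$y; X <- des$X; D <- des$D; Dsort <- des$Dsort
  n <- length(y); terms <- colnames(X); pt <- length(terms)
  if (n <= pt + 2) stop2("need more than p + 2 units")
  if (!is.null(bandwidths)) {
    miss <- setdiff(terms, names(bandwidths))
    if (length(miss)) stop2("bandwidths missing for term(s): ",
                            paste(miss, collapse = ", "))
  }
  bounds <- if (kernel == "adaptive") c(3, n)
  else { dpos <- D[D > 0]; c(min(dpos), 2 * max(dpos)) }

  if (init == "gwr") {
    # GWR initialization at the AICc-optimal single bandwidth, with the hat
    # matrix decomposed exactly across terms
    gb <- if (kernel == "adaptive") c(pt + 2, n)
    else { dpos <- D[D > 0]; c(min(dpos), 2 * max(dpos)) }
    bw0 <- golden_min(function(b)
      gwr_score(y, X, D, kernel_spec(kernel, b), Dsort), gb,
      adaptive = kernel == "adaptive", presample = 8)$best
    lf0 <- gwr_local_fits(y, X,
                          kernel_matrix(D, kernel_spec(kernel, bw0), Dsort),
                          term_hats = TRUE)
    beta <- lf0$beta
    Fmat <- X * beta
    Rlist <- lf0$Rlist
  } else {
    # OLS initialization: flat additive terms, projection decomposition
    XtXinv <- solve(crossprod(X))
    B <- XtXinv %*% t(X)
    beta <- matrix(stats::lm.fit(X, y)$coefficients, n, pt, byrow = TRUE,
                   dimnames = list(NULL, terms))
    Fmat <- X * beta                     # additive terms f_j
    Rlist <- lapply(seq_len(pt), function(j) outer(X[, j], B[j, ]))
  }
  Rsum <- Reduce(`+`, Rlist)
  bw <- stats::setNames(rep(NA_real_, pt), terms)
  yhat <- rowSums(Fmat)
  trace <- data.frame(iteration = integer(), score = numeric())
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    yhat_old <- yhat
    for (j in seq_len(pt)) {
      u <- y - yhat + Fmat[, j]
      bj <- if (!is.null(bandwidths)) bandwidths[[terms[j]]]
      else select_term_bandwidth(u, X[, j], D, kernel, bounds, Dsort)
      bw[j] <- bj
      Wm <- kernel_matrix(D, kernel_spec(kernel, bj), Dsort)
      sm <- term_smoother(X[, j], Wm)
      beta[, j] <- drop(Wm %*% (X[, j] * u)) / sm$denom
      fj <- X[, j] * beta[, j]
      # map from y: R_j = S_j (I - sum_{l != j} R_l)
      Rother <- Rsum - Rlist[[j]]
      Rlist[[j]] <- sm$S - sm$S %*% Rother
      Rsum <- Rother + Rlist[[j]]
      yhat <- yhat - Fmat[, j] + fj
      Fmat[, j] <- fj
    }
    score <- sqrt(mean((yhat - yhat_old)^2) / max(mean(yhat^2),
                                                  .Machine$double.eps))
    trace <- rbind(trace, data.frame(iteration = it, score = score))
    if (score < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn2("MGWR backfitting did not converge in ", max_iter, " iterations")
  resid <- y - yhat
  rss <- sum(resid^2)
  enp_terms <- vapply(Rlist, function(R) sum(diag(R)), numeric(1))
  names(enp_terms) <- terms
  enp <- sum(diag(Rsum))
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  structure(list(beta = beta, bandwidths = bw, enp_terms = enp_terms,
                 enp = enp, rss = rss, sigma = sqrt(rss / (n - enp)),
                 aicc = gwr_aicc(n, rss, enp), r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - enp - 1),
                 yhat = yhat, residuals = resid, trace = trace,
                 converged = converged, n = n, kernel = kernel,
                 covariates = covariates, scale = des$scale,
                 S = Rsum),
            class = "mgwr_fit")
}

#' @export
print.mgwr_fit <- function(x, ...) {
  cat(sprintf("<mgwr_fit> n = %d, ENP = %.2f, AICc = %.2f, R2 = %.3f, converged = %s\n",
              x$n, x$enp, x$aicc, x$r2, x$converged))
  bw <- x$bandwidths
  cat("  bandwidths: ",
      paste(sprintf("%s=%s", names(bw), format(bw)), collapse = ", "), "\n")
  invisible(x)
}

#' GWR vs MGWR diagnostic comparison table
#'
#' @param gwr a [fit_gwr()] result.
#' @param mgwr a [fit_mgwr()] result on the same panel.
#' @return data.frame with rows Residual Squares, Effective Number, Sigma,
#'   AICc, R2, R2Adjusted and columns `GWR`, `MGWR`.
#' @export
compare_models <- function(gwr, mgwr) {
  stopifnot(inherits(gwr, "gwr_fit"), inherits(mgwr, "mgwr_fit"))
  if (gwr$n != mgwr$n) stop2("models were fitted on different panels")
  data.frame(
    index = c("Residual Squares", "Effective Number", "Sigma", "AICc",
              "R2", "R2Adjusted"),
    GWR = c(gwr$rss, gwr$enp, gwr$sigma, gwr$aicc, gwr$r2, gwr$adj_r2),
    MGWR = c(mgwr$rss, mgwr$enp, mgwr$sigma, mgwr$aicc, mgwr$r2,
             mgwr$adj_r2),
    stringsAsFactors = FALSE)
}

#' Regional means of local coefficients
#'
#' Arithmetic mean of each term's local coefficients within each group
#' (e.g. urban agglomeration), plus the covariate with the largest absolute
#' mean coefficient per group (the group's most important influencing
#' factor; the intercept is excluded from that ranking).
#'
#' @param fit a `gwr_fit` or `mgwr_fit`.
#' @param groups group label per unit (length n).
#' @return data.frame with one row per group: `group`, one column per term,
#'   and `top_covariate`.
#' @export
regional_mean_coefficients <- function(fit, groups) {
  beta <- fit$beta
  if (length(groups) != nrow(beta)) stop2("groups length must equal n")
  if (any(is.na(groups))) stop2("missing group label(s)")
  g <- factor(groups)
  if (any(table(g) == 0)) stop2("empty group")
  means <- apply(beta, 2, function(cl) tapply(cl, g, mean))
  means <- matrix(means, nrow = nlevels(g),
                  dimnames = list(levels(g), colnames(beta)))
  covs <- setdiff(colnames(beta), "Intercept")
  top <- covs[apply(abs(means[, covs, drop = FALSE]), 1, which.max)]
  out <- data.frame(group = levels(g), means, top_covariate = top,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  out
}
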