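# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive each statistic from its definition with plain
# loops, never calling the package's own computational path.

# global Moran's I by explicit double sum
oracle_global_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) if (i != j)
    num <- num + W[i, j] * z[i] * z[j]
  n * num / (sum(z^2) * sum(W))
}

# local Moran's I_i by explicit neighbour sum
oracle_local_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2)
  vapply(1:n, function(i) {
    s <- 0
    for (j in 1:n) if (j != i) s <- s + W[i, j] * z[j]
    n * z[i] * s / m2
  }, numeric(1))
}

# q-statistic by explicit group-by with population variances
oracle_q <- function(y, h) {
  N <- length(y)
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  ssw <- 0
  for (g in unique(h)) {
    v <- y[h == g]
    ssw <- ssw + length(v) * pv(v)
  }
  1 - ssw / (N * pv(y))
}

# VIF by the two-stage definition: regress covariate j on the others, 1/(1-R2)
oracle_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}

# exhaustive natural-breaks search over all ordered partitions (small n, k)
oracle_jenks_ssw <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssw_seg <- function(v) sum((v - mean(v))^2)
  best <- Inf
  # choose k-1 cut positions among n-1 gaps
  cuts <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    tot <- 0
    for (s in 1:k) tot <- tot + ssw_seg(xs[(b[s] + 1):b[s + 1]])
    if (tot < best) best <- tot
  }
  best
}

# rook / queen adjacency of an nr x nc lattice derived from indices
lattice_weights <- function(nr, nc, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  n <- nr * nc
  pos <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    dr <- abs(pos$row[i] - pos$row[j]); dc <- abs(pos$col[i] - pos$col[j])
    if (rule == "rook" && dr + dc == 1) W[i, j] <- 1
    if (rule == "queen" && max(dr, dc) == 1) W[i, j] <- 1
  }
  spatial_weights(W, as.character(seq_len(n)))
}

# checkerboard values on an nr x nc lattice (1 on one colour, 0 on the other)
checkerboard <- function(nr, nc) {
  pos <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  as.numeric((pos$row + pos$col) %% 2 == 0)
}

# grid-square polygons for an nr x nc lattice with given cell size
lattice_polygons <- function(nr, nc, size = 1) {
  n <- nr * nc
  pos <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  rings <- lapply(seq_len(n), function(k) {
    x0 <- (pos$col[k] - 1) * size; y0 <- (pos$row[k] - 1) * size
    list(rbind(c(x0, y0), c(x0 + size, y0), c(x0 + size, y0 + size),
               c(x0, y0 + size), c(x0, y0)))
  })
  unit_polygons(as.character(seq_len(n)), rings)
}

# two columns with an exact sample correlation r (orthogonalized construction)
make_pair_exact_r <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- as.numeric(scale(rnorm(n)))
  u0 <- stats::residuals(stats::lm(rnorm(n) ~ z1))
  u <- as.numeric(scale(u0))
  cbind(x1 = z1, x2 = r * z1 + sqrt(1 - r^2) * u)
}

# small single-slice panel from coordinates, response and covariate matrix
quick_panel <- function(coords, y, X, group = NULL) {
  df <- data.frame(unit_id = sprintf("u%03d", seq_along(y)),
                   x = coords[, 1], y = coords[, 2], y_resp = y)
  if (!is.null(group)) df$group <- group
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- X[, j]
  city_panel(df, colnames(X))
}
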