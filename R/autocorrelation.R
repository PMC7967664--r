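#' Global Moran's I
#'
#' Computes the global spatial autocorrelation statistic
#' \deqn{I = \frac{n \sum_i \sum_j W_{ij} (x_i-\bar x)(x_j-\bar x)}
#'            {\sum_i (x_i-\bar x)^2 \; S_0}}
#' with a binary contiguity matrix \eqn{W} (\eqn{S_0 = \sum_{ij} W_{ij}}),
#' its expectation \eqn{E[I] = -1/(n-1)}, the variance under the chosen null
#' assumption, the standard score \eqn{Z = (I - E[I]) / \sqrt{Var(I)}} and a
#' two-sided normal p-value. I usually lies in \eqn{[-1, 1]} but can exceed
#' those bounds for some weight matrices; values outside are warned about,
#' not rejected.
#'
#' @param values numeric vector, one observation per unit, ordered as
#'   `w$ids`.
#' @param w a [spatial_weights()] object.
#' @param variance `"randomization"` (default) or `"normality"` null
#'   assumption for Var(I).
#' @return a `moran_result` list: `I`, `EI`, `VarI`, `Z`, `p`, `n`, `S0`.
#' @export
global_moran <- function(values, w,
                         variance = c("randomization", "normality")) {
  variance <- match.arg(variance)
  x <- as.numeric(values)
  n <- w$n
  if (length(x) != n) stop2("values length must equal number of units")
  if (n < 3) stop2("need at least 3 units")
  if (any(!is.finite(x))) stop2("non-finite values")
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop2("constant field: zero sample variance")
  W <- w$W
  S0 <- w$S0
  I <- n * drop(crossprod(z, W %*% z)) / (m2 * S0)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VarI <- if (variance == "normality") {
    (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  } else {
    b2 <- n * sum(z^4) / m2^2
    (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
       b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  Z <- (I - EI) / sqrt(VarI)
  p <- 2 * stats::pnorm(-abs(Z))
  if (I < -1 - 1e-12 || I > 1 + 1e-12)
    warn2("Moran's I = ", signif(I, 4), " lies outside [-1, 1] for this W")
  structure(list(I = I, EI = EI, VarI = VarI, Z = Z, p = p, n = n, S0 = S0,
                 variance = variance),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f  (E[I] = %.4f, Z = %.3f, p = %.4g, n = %d)\n",
              x$I, x$EI, x$Z, x$p, x$n))
  invisible(x)
}

#' Global Moran's I with permutation inference
#'
#' Empirical (pseudo) p-value from `n_perm` random relabelings of the
#' observations over the units:
#' p = (1 + #\{|I_perm - E[I]| >= |I_obs - E[I]|\}) / (1 + n_perm).
#'
#' @inheritParams global_moran
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed; same seed gives identical p.
#' @return a `moran_result` with extra fields `p_perm`, `perm_I`, `n_perm`.
#' @export
global_moran_permutation <- function(values, w, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop2("n_perm must be at least 99")
  res <- global_moran(values, w)
  x <- as.numeric(values)
  n <- w$n
  z <- x - mean(x)
  m2 <- sum(z^2)
  W <- w$W
  cst <- n / (m2 * w$S0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  perm_I <- vapply(seq_len(n_perm), function(b) {
    zp <- z[sample.int(n)]
    cst * drop(crossprod(zp, W %*% zp))
  }, numeric(1))
  dev <- abs(res$I - res$EI)
  p_perm <- (1 + sum(abs(perm_I - res$EI) >= dev - 1e-15)) / (1 + n_perm)
  res$p_perm <- p_perm
  res$perm_I <- perm_I
  res$n_perm <- n_perm
  res
}

#' Local Moran's I (LISA)
#'
#' Per-unit statistic
#' \deqn{I_i = \frac{n (x_i-\bar x) \sum_{j} W_{ij} (x_j-\bar x)}
#'             {\sum_i (x_i-\bar x)^2}}
#' where the sum runs over the \eqn{m_i} neighbours of unit i. The local
#' statistics satisfy the exact identity \eqn{\sum_i I_i = S_0 I} with the
#' global statistic I. Inference is by conditional permutation: unit i's
#' value is held fixed and the remaining values are permuted across its
#' neighbour positions; `Z_i` standardizes `I_i` against that null, and
#' cluster labels (HH, LL, HL, LH, NS) are assigned by the quadrant of
#' (own deviation, spatial lag) when `|Z_i| >= 1.96`.
#'
#' Units with zero neighbours get `I_i = NA` and label `NS`, with a warning.
#'
#' @inheritParams global_moran_permutation
#' @return a `local_moran_result`: data.frame `table` with columns
#'   `unit_id`, `Ii`, `Zi`, `pi`, `lag`, `zdev`, `label`, plus fields
#'   `S0`, `I_global`.
#' @export
local_moran <- function(values, w, n_perm = 999, seed = 1L) {
  x <- as.numeric(values)
  n <- w$n
  if (length(x) != n) stop2("values length must equal number of units")
  if (n < 3) stop2("need at least 3 units")
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop2("constant field: zero sample variance")
  W <- w$W
  lag <- drop(W %*% z)
  Ii <- n * z * lag / m2
  mi <- rowSums(W)
  if (any(mi == 0))
    warn2(sum(mi == 0), " unit(s) with zero neighbours: local I undefined")
  Ii[mi == 0] <- NA_real_
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  Zi <- pi_ <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (mi[i] == 0) next
    zo <- z[-i]
    perm <- vapply(seq_len(n_perm), function(b)
      sum(zo[sample.int(n - 1L, mi[i])]), numeric(1))
    Ip <- n * z[i] * perm / m2
    mu <- mean(Ip); sdv <- stats::sd(Ip)
    Zi[i] <- if (sdv > 0) (Ii[i] - mu) / sdv else 0
    pi_[i] <- (1 + sum(abs(Ip - mu) >= abs(Ii[i] - mu) - 1e-15)) / (1 + n_perm)
  }
  lab <- rep("NS", n)
  sig <- !is.na(Zi) & abs(Zi) >= 1.96
  lab[sig & z > 0 & lag > 0] <- "HH"
  lab[sig & z < 0 & lag < 0] <- "LL"
  lab[sig & z > 0 & lag < 0] <- "HL"
  lab[sig & z < 0 & lag > 0] <- "LH"
  tab <- data.frame(unit_id = w$ids, Ii = Ii, Zi = Zi, pi = pi_,
                    lag = lag, zdev = z, label = lab,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, S0 = w$S0,
                 I_global = sum(Ii, na.rm = TRUE) / w$S0, n = n),
            class = "local_moran_result")
}

#' Classify LISA clusters at two significance tiers
#'
#' Applies the hot/cold-zone typology: HH ("hot zone") when both the unit
#' and its spatial lag sit above the mean and the unit is significant,
#' LL ("cold zone") when both sit below, HL/LH for the discordant
#' quadrants. Two tiers are reported: significant (|Z| >= 1.96) and
#' extremely significant (|Z| >= 2.58); ties at a threshold count as
#' significant.
#'
#' @param res a [local_moran()] result.
#' @param z_tiers increasing |Z| thresholds for the tiers
#'   (default `c(1.96, 2.58)`).
#' @return data.frame with `unit_id`, `Ii`, `Zi`, `pi`, `label`, `tier`
#'   (0 = not significant) and `zone` ("hot zone", "cold zone" or "").
#' @export
classify_clusters <- function(res, z_tiers = c(1.96, 2.58)) {
  stopifnot(inherits(res, "local_moran_result"))
  tab <- res$table
  tier <- integer(nrow(tab))
  for (k in seq_along(z_tiers))
    tier[!is.na(tab$Zi) & abs(tab$Zi) >= z_tiers[k]] <- k
  lab <- rep("NS", nrow(tab))
  sig <- tier >= 1L
  lab[sig & tab$zdev > 0 & tab$lag > 0] <- "HH"
  lab[sig & tab$zdev < 0 & tab$lag < 0] <- "LL"
  lab[sig & tab$zdev > 0 & tab$lag < 0] <- "HL"
  lab[sig & tab$zdev < 0 & tab$lag > 0] <- "LH"
  zone <- ifelse(lab == "HH", "hot zone",
                 ifelse(lab == "LL", "cold zone", ""))
  data.frame(unit_id = tab$unit_id, Ii = tab$Ii, Zi = tab$Zi, pi = tab$pi,
             label = lab, tier = tier, zone = zone, stringsAsFactors = FALSE)
}
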