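#' Recipe for a ground-truth-known synthetic city panel
#'
#' Defines a rectangular lattice of square "city" units, spatially
#' autocorrelated covariate fields, coefficient surfaces (constant, linear
#' gradient, or sinusoid) and a noise level, so that every downstream stage
#' can be validated against known truth. All randomness is driven by the
#' single `seed`.
#'
#' Defaults emulate the shape of a three-agglomeration study region:
#' a 5 x 15 lattice of 75 cities split into three contiguous groups of
#' 17, 31 and 27 units, 50 km cell spacing (a typical inter-city centroid
#' distance), five named covariates, and a noise SD of 0.5 on the response
#' scale.
#'
#' @param nrow,ncol lattice dimensions (product >= 9).
#' @param spacing_km cell size / centroid spacing in km.
#' @param covariates named list: for each covariate, a list with `range_km`
#'   (exponential-covariance correlation range of its Gaussian random
#'   field) and optionally `common_weight` in [0, 1): the loading on a
#'   shared latent smooth field (range `common_range_km`), emulating the
#'   mutual correlation of real driver fields (meteorology, economic
#'   activity). Default 0 (independent).
#' @param common_range_km correlation range of the shared latent field.
#' @param correlate optional list of `list(a =, b =, r =)` entries injecting
#'   pairwise correlation r between covariates a and b; `NULL` (default)
#'   injects r = 0.95 between `X1` and `X9` when both exist (the fixture's
#'   near-duplicate pair), otherwise nothing.
#' @param surfaces named list of coefficient surfaces, names =
#'   `"Intercept"` and covariate names; each is one of
#'   `list(type = "constant", value =)`,
#'   `list(type = "gradient", base =, slope =)` (slope per km along u+v),
#'   `list(type = "sinusoid", amplitude =, wavelength_km =)`.
#' @param noise_sd response noise SD (µg/m³ scale).
#' @param group_sizes integer vector partitioning the units (in column-major
#'   lattice order) into contiguous groups; default `c(17, 31, 27)` scaled
#'   to the lattice size.
#' @param times character vector of time labels; one panel slice (fresh
#'   covariate and noise draws) is generated per label.
#' @param seed integer master seed.
#' @return a `synthetic_spec` list (serializable to JSON and back with
#'   [write_synthetic_spec()] / [read_synthetic_spec()]).
#' @export
synthetic_spec <- function(nrow = 5, ncol = 15, spacing_km = 50,
                           covariates = list(
                             X1 = list(range_km = 30),
                             X2 = list(range_km = 30),
                             X3 = list(range_km = 100, common_weight = 0.75),
                             X4 = list(range_km = 30),
                             X5 = list(range_km = 100, common_weight = 0.75),
                             X7 = list(range_km = 80, common_weight = 0.75),
                             X9 = list(range_km = 30),
                             X13 = list(range_km = 120, common_weight = 0.75),
                             X15 = list(range_km = 120, common_weight = 0.75)),
                           correlate = NULL,
                           common_range_km = 150,
                           surfaces = NULL,
                           noise_sd = 0.5,
                           group_sizes = NULL,
                           times = c("2015", "2016", "2017", "2018"),
                           seed = 1L) {
  if (nrow * ncol < 9) stop2("lattice must have at least 9 units")
  for (nm in names(covariates))
    if (covariates[[nm]]$range_km <= 0)
      stop2("non-positive spatial range for covariate ", nm)
  if (is.null(correlate)) {
    correlate <- if (all(c("X1", "X9") %in% names(covariates)))
      list(list(a = "X1", b = "X9", r = 0.95)) else list()
  }
  for (cj in correlate)
    if (!all(c(cj$a, cj$b) %in% names(covariates)))
      stop2("correlate entry references unknown covariate(s)")
  if (is.null(surfaces)) {
    # signal covariates get the constant/gradient/sinusoid triad; any other
    # covariate is pure noise with respect to the response
    signal <- intersect(names(covariates), c("X3", "X5", "X7", "X13", "X15"))
    if (!length(signal)) signal <- names(covariates)
    ext <- (max(nrow, ncol) - 1) * spacing_km
    surfaces <- c(list(Intercept = list(type = "constant", value = 3)),
                  stats::setNames(lapply(seq_along(signal), function(j) {
                    switch(1L + (j - 1L) %% 3L,
                           list(type = "constant", value = 2.5),
                           list(type = "gradient", base = 1, slope = 3 / ext),
                           list(type = "sinusoid", base = 2, amplitude = 1,
                                wavelength_km = ext / 2))
                  }), signal))
  }
  miss <- setdiff(setdiff(names(surfaces), "Intercept"), names(covariates))
  if (length(miss))
    stop2("surface(s) reference missing covariate(s): ",
          paste(miss, collapse = ", "))
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (is.null(group_sizes)) {
    gs <- c(17, 31, 27) / 75
    group_sizes <- diff(round(c(0, cumsum(gs)) * nrow * ncol))
  }
  if (sum(group_sizes) != nrow * ncol)
    stop2("group_sizes must partition the lattice")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 spacing_km = spacing_km, covariates = covariates,
                 correlate = correlate, common_range_km = common_range_km,
                 surfaces = surfaces,
                 noise_sd = noise_sd, group_sizes = as.integer(group_sizes),
                 times = as.character(times), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Serialize / restore a synthetic spec
#' @param spec a [synthetic_spec()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `synthetic_spec` (read).
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  do.call(synthetic_spec, x)
}

#' Generate the lattice skeleton: units, polygons, groups, weights
#'
#' Unit polygons are the lattice's grid squares; centroids sit at cell
#' centres; queen contiguity weights are built from lattice indices (so the
#' lattice has no islands by construction); group labels (`"A"`, `"B"`,
#' `"C"`, ...) partition the units contiguously in column-major order,
#' mimicking a multi-agglomeration study region.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `panel` (a [city_panel()] skeleton: `y_resp` = NA),
#'   `weights` (a [spatial_weights()]), `polygons` (a `unit_polygons`).
#' @export
generate_city_lattice <- function(spec) {
  nr <- spec$nrow; nc <- spec$ncol; s <- spec$spacing_km
  n <- nr * nc
  ij <- expand.grid(row = seq_len(nr), col = seq_len(nc))   # column-major
  ids <- sprintf("u%03d", seq_len(n))
  cx <- (ij$col - 0.5) * s
  cy <- (ij$row - 0.5) * s
  group <- rep(LETTERS[seq_along(spec$group_sizes)], spec$group_sizes)
  panel <- city_panel(data.frame(unit_id = ids, x = cx, y = cy,
                                 y_resp = 0, group = group,
                                 stringsAsFactors = FALSE),
                      character(), validate = FALSE)
  panel$y_resp <- NA_real_
  # queen adjacency from lattice indices
  pairs <- list()
  idx <- matrix(seq_len(n), nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          idx[r, cc] < idx[r2, c2])
        pairs[[length(pairs) + 1L]] <- c(ids[idx[r, cc]], ids[idx[r2, c2]])
    }
  }
  w <- weights_from_adjacency(do.call(rbind, pairs), ids)
  rings <- lapply(seq_len(n), function(k) {
    x0 <- (ij$col[k] - 1) * s; y0 <- (ij$row[k] - 1) * s
    list(rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s),
               c(x0, y0)))
  })
  list(panel = panel, weights = w, polygons = unit_polygons(ids, rings))
}

# Gaussian random field over coordinates via Cholesky of an exponential
# covariance exp(-d/range); scaled to exactly unit sample variance.
gaussian_random_field <- function(coords, range_km) {
  D <- as.matrix(stats::dist(coords))
  C <- exp(-D / range_km) + diag(1e-10, nrow(D))
  L <- chol(C)
  z <- drop(crossprod(L, stats::rnorm(nrow(D))))
  (z - mean(z)) / stats::sd(z)
}

#' Draw spatially autocorrelated covariate fields
#'
#' Each covariate is a zero-mean, unit-variance Gaussian random field with
#' exponential spatial covariance at its stated range; optional pairwise
#' correlation is injected afterwards (`b <- r a + sqrt(1-r^2) b`,
#' re-standardized).
#'
#' @param skeleton result of [generate_city_lattice()].
#' @param spec a [synthetic_spec()].
#' @param time_label which time slice is being drawn (seeds differ by
#'   slice).
#' @return the skeleton panel with covariate columns filled in.
#' @export
generate_covariates <- function(skeleton, spec, time_label = spec$times[1]) {
  panel <- skeleton$panel
  coords <- cbind(panel$x, panel$y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(spec$seed, paste0("covariates:", time_label)))
  df <- as.data.frame(panel)
  common <- gaussian_random_field(coords, spec$common_range_km %||% 150)
  for (nm in names(spec$covariates)) {
    own <- gaussian_random_field(coords, spec$covariates[[nm]]$range_km)
    cw <- spec$covariates[[nm]]$common_weight %||% 0
    z <- sqrt(1 - cw^2) * own + cw * common
    df[[nm]] <- (z - mean(z)) / stats::sd(z)
  }
  for (cj in spec$correlate) {
    a <- df[[cj$a]]; b <- df[[cj$b]]; r <- cj$r
    b2 <- r * a + sqrt(1 - r^2) * b
    df[[cj$b]] <- (b2 - mean(b2)) / stats::sd(b2)
  }
  city_panel(df, names(spec$covariates), validate = FALSE)
}

coef_surface <- function(surf, x, y) {
  switch(surf$type,
         constant = rep(surf$value, length(x)),
         gradient = surf$base + surf$slope * (x + y),
         sinusoid = (surf$base %||% 0) + surf$amplitude *
           sin(2 * pi * (x + y) / surf$wavelength_km),
         stop2("unknown surface type: ", surf$type))
}

#' Build the response from coefficient surfaces plus noise
#'
#' \eqn{y_i = \beta_0(u_i,v_i) + \sum_j \beta_j(u_i,v_i) x_{ij} +
#' \varepsilon_i}, \eqn{\varepsilon \sim N(0, \sigma^2)}. Covariates with no
#' surface entry contribute nothing (pure noise covariates). The realized
#' true coefficient matrix is attached as attribute `"true_beta"`
#' (columns `Intercept` + covariates).
#'
#' @inheritParams generate_covariates
#' @param panel panel with covariates (from [generate_covariates()]).
#' @return the panel with `y_resp` filled and `true_beta` attached.
#' @export
generate_response <- function(panel, spec, time_label = spec$times[1]) {
  covs <- panel_covariates(panel)
  if (!length(covs)) stop2("covariates must be generated first")
  df <- as.data.frame(panel)
  n <- nrow(df)
  terms <- c("Intercept", covs)
  truth <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  for (nm in names(spec$surfaces)) {
    if (!nm %in% terms)
      stop2("surface references missing covariate: ", nm)
    truth[, nm] <- coef_surface(spec$surfaces[[nm]], df$x, df$y)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(spec$seed, paste0("response:", time_label)))
  eps <- stats::rnorm(n, 0, spec$noise_sd)
  X <- cbind(Intercept = 1, as.matrix(df[, covs, drop = FALSE]))
  df$y_resp <- rowSums(X * truth) + eps
  out <- city_panel(df, covs, validate = TRUE)
  attr(out, "true_beta") <- truth
  out
}

#' Generate a full synthetic panel across all time labels
#'
#' Convenience wrapper: lattice skeleton + per-time-label covariates and
#' response, stacked into one long panel. True coefficient matrices are
#' attached as attribute `"true_beta_by_time"` (a named list).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `panel` (long [city_panel()] with `time`), `weights`,
#'   `polygons`, `skeleton`.
#' @export
generate_panel <- function(spec) {
  sk <- generate_city_lattice(spec)
  slices <- list(); truth <- list()
  for (tl in spec$times) {
    p <- generate_covariates(sk, spec, tl)
    p <- generate_response(p, spec, tl)
    truth[[tl]] <- attr(p, "true_beta")
    d <- as.data.frame(p)
    d$time <- tl
    slices[[tl]] <- d
  }
  long <- do.call(rbind, slices)
  rownames(long) <- NULL
  panel <- city_panel(long, names(spec$covariates))
  attr(panel, "true_beta_by_time") <- truth
  list(panel = panel, weights = sk$weights, polygons = sk$polygons,
       skeleton = sk)
}

#' Generate a stratified scene for q-statistic validation
#'
#' L stratum means drawn from N(0, between_sd^2); within each stratum,
#' samples from N(mean_h, within_sd^2), allocated as evenly as possible.
#' The "true" q returned is the q-statistic of the realized sample (same
#' formula, same data), the quantity [factor_q()] should reproduce exactly.
#'
#' @param L number of strata (>= 2).
#' @param n total sample count (>= L).
#' @param between_sd SD of the stratum means.
#' @param within_sd SD within a stratum.
#' @param seed integer seed.
#' @return list with `y`, `strata` (a [strata_assignment()]), `true_q`.
#' @export
generate_strata_scene <- function(L = 8, n = 400, between_sd = 1,
                                  within_sd = 0.5, seed = 1L) {
  if (L < 2) stop2("L must be >= 2")
  if (L > n) stop2("more strata than samples")
  if (between_sd < 0 || within_sd < 0) stop2("SDs must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  mu <- stats::rnorm(L, 0, between_sd)
  h <- sort(rep_len(seq_len(L), n))
  y <- stats::rnorm(n, mu[h], within_sd)
  s <- strata_assignment(h)
  pvar <- function(v) mean((v - mean(v))^2)
  ssw <- sum(vapply(split(y, h), function(v) length(v) * pvar(v), numeric(1)))
  true_q <- 1 - ssw / (n * pvar(y))
  list(y = y, strata = s, true_q = true_q)
}
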