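#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end workflow. One `seed` drives all
#' stochastic steps (synthetic generation, permutation tests), so two runs
#' from the same config produce identical outputs.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed.
#' @param synthetic a [synthetic_spec()] used when no panel is supplied.
#' @param moran list: `variance` ("randomization"/"normality"), `n_perm`,
#'   `z_tiers`.
#' @param geodetector list: `spacing_km` (grid sampling), `k` (natural-breaks
#'   classes), `alpha`, `use_grid`.
#' @param screening list: `vif_threshold`, `cut` (correlation-cluster cut
#'   height), `distance`.
#' @param regression list: `kernel`, `standardize`, `tol`, `top_k` (drivers
#'   carried into regression).
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       synthetic = synthetic_spec(seed = seed),
                       moran = list(), geodetector = list(),
                       screening = list(), regression = list()) {
  defaults <- list(
    moran = list(variance = "randomization", n_perm = 999,
                 z_tiers = c(1.96, 2.58)),
    geodetector = list(spacing_km = 10, k = 8, alpha = 0.05,
                       use_grid = TRUE),
    screening = list(vif_threshold = 5, cut = 0.1, distance = "abs"),
    regression = list(kernel = "adaptive", standardize = TRUE, tol = 1e-5,
                      top_k = 5))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              synthetic = synthetic,
              moran = merge1(defaults$moran, moran),
              geodetector = merge1(defaults$geodetector, geodetector),
              screening = merge1(defaults$screening, screening),
              regression = merge1(defaults$regression, regression))
  stopifnot(cfg$moran$variance %in% c("randomization", "normality"),
            cfg$moran$n_perm >= 99,
            cfg$geodetector$k >= 2, cfg$geodetector$spacing_km > 0,
            cfg$screening$vif_threshold > 1,
            cfg$regression$kernel %in% c("adaptive", "fixed"),
            cfg$regression$top_k >= 1)
  class(cfg) <- "run_config"
  cfg
}

config_to_json <- function(cfg) {
  x <- unclass(cfg)
  x$synthetic <- unclass(x$synthetic)
  x
}

subset_weights <- function(w, ids, coords) {
  keep <- match(ids, w$ids)
  W <- w$W[keep, keep, drop = FALSE]
  islands <- ids[rowSums(W) == 0]
  sw <- spatial_weights(W, ids, islands, check = FALSE)
  if (length(islands) && length(ids) >= 2)
    sw <- repair_islands(sw, coords)
  sw
}

parse_times <- function(times) {
  ut <- unique(as.character(times))
  if (all(grepl("^\\d{4}-\\d{2}$", ut))) "monthly"
  else if (all(grepl("^\\d{4}$", ut))) "annual"
  else "label"
}

#' Global autocorrelation suite across time aggregations
#'
#' For every group (and for all units pooled) computes global Moran's I,
#' Z(I) and p for: the overall average field, each year, and — when the
#' panel carries year-month time labels — each season and each month of the
#' year pooled across years. Also writes a per-unit LISA table for every
#' year. Groups with fewer than 3 units are skipped with a warning.
#'
#' @param panel long [city_panel()] with `time` (and optionally `group`).
#' @param weights [spatial_weights()] over all units.
#' @param config a [run_config()].
#' @return list with `global` (data.frame: group, time, n, moran_i, z, p)
#'   and `lisa` (data.frame of yearly cluster labels); CSVs written to
#'   `config$out_dir`.
#' @export
run_autocorrelation_suite <- function(panel, weights, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config_to_json(config))
  df <- as.data.frame(panel)
  if (!"time" %in% names(df)) df$time <- "all"
  kind <- parse_times(df$time)
  groups <- if ("group" %in% names(df)) unique(df$group) else character()
  scopes <- c(list(ALL = unique(df$unit_id)),
              stats::setNames(lapply(groups, function(g)
                unique(df$unit_id[df$group == g])), groups))

  sel_time <- list()
  years <- unique(substr(df$time, 1, 4))
  sel_time[["Average"]] <- unique(df$time)
  for (yr in sort(years))
    sel_time[[yr]] <- unique(df$time[substr(df$time, 1, 4) == yr])
  if (kind == "monthly") {
    mo <- as.integer(substr(df$time, 6, 7))
    se <- season_of(as.integer(substr(df$time, 1, 4)), mo)
    for (s in c("spring", "summer", "autumn", "winter"))
      sel_time[[s]] <- unique(df$time[se$season == s])
    for (m in 1:12)
      sel_time[[month.name[m]]] <- unique(df$time[mo == m])
  }

  rows <- list()
  for (sc in names(scopes)) {
    ids <- scopes[[sc]]
    sub <- df[df$unit_id %in% ids, , drop = FALSE]
    coords <- unique(sub[, c("unit_id", "x", "y")])
    coords <- coords[match(ids, coords$unit_id), ]
    if (length(ids) < 3) {
      warn2("group ", sc, " has fewer than 3 units; skipped")
      next
    }
    sw <- subset_weights(weights, ids, as.matrix(coords[, c("x", "y")]))
    for (tn in names(sel_time)) {
      s2 <- sub[sub$time %in% sel_time[[tn]], , drop = FALSE]
      if (!nrow(s2)) next
      vals <- tapply(s2$y_resp, factor(s2$unit_id, levels = ids), mean)
      if (any(is.na(vals))) next
      mr <- tryCatch(global_moran(vals, sw, config$moran$variance),
                     error = function(e) NULL)
      if (is.null(mr)) next
      rows[[length(rows) + 1L]] <-
        data.frame(group = sc, time = tn, n = sw$n, moran_i = mr$I,
                   z = mr$Z, p = mr$p, stringsAsFactors = FALSE)
    }
  }
  global <- do.call(rbind, rows)
  write_table_csv(global, file.path(config$out_dir, "moran_global.csv"), hash)

  lisa_rows <- list()
  ids <- scopes[["ALL"]]
  coords <- unique(df[, c("unit_id", "x", "y")])
  coords <- coords[match(ids, coords$unit_id), ]
  sw <- subset_weights(weights, ids, as.matrix(coords[, c("x", "y")]))
  for (yr in sort(years)) {
    s2 <- df[substr(df$time, 1, 4) == yr, , drop = FALSE]
    vals <- tapply(s2$y_resp, factor(s2$unit_id, levels = ids), mean)
    if (any(is.na(vals))) next
    lm_res <- local_moran(vals, sw, n_perm = config$moran$n_perm,
                          seed = derive_seed(config$seed,
                                             paste0("lisa:", yr)))
    cl <- classify_clusters(lm_res, config$moran$z_tiers)
    cl$time <- yr
    lisa_rows[[yr]] <- cl
  }
  lisa <- do.call(rbind, lisa_rows)
  rownames(lisa) <- NULL
  write_table_csv(lisa, file.path(config$out_dir, "moran_lisa.csv"), hash)
  list(global = global, lisa = lisa)
}

#' Driver screening suite: cluster-drop, VIF filter, geodetector
#'
#' On the time-averaged panel: (1) single-linkage correlation clustering
#' removes near-duplicate covariates; (2) iterative VIF filtering removes
#' collinear ones; (3) the three geodetector submodels run on the
#' survivors (each discretized by natural breaks), ranking explanatory
#' power and selecting the top-k drivers.
#'
#' @param panel long [city_panel()].
#' @param config a [run_config()].
#' @param polygons optional `unit_polygons` for grid sampling; when absent
#'   (or `config$geodetector$use_grid` is FALSE) detectors run on unit
#'   values directly.
#' @return list with `vif_table`, `cluster_drop`, `factor_table` (q + p per
#'   covariate, ranked), `ecological` (Y/N matrix), `interaction` (q
#'   matrix, diagonal = single-factor q), `selected`.
#' @export
run_driver_screen <- function(panel, config, polygons = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config_to_json(config))
  covs <- panel_covariates(panel)
  if (length(covs) < 6) stop2("driver screen expects at least 6 covariates")
  df <- as.data.frame(panel)
  agg <- stats::aggregate(df[, c("y_resp", covs)],
                          by = list(unit_id = df$unit_id), FUN = mean)
  first <- df[!duplicated(df$unit_id), c("unit_id", "x", "y")]
  agg <- merge(first, agg, by = "unit_id", sort = TRUE)
  mpanel <- city_panel(agg, covs)

  corr <- correlation_matrix(mpanel)
  cl <- cluster_variables(corr, cut = config$screening$cut,
                          distance = config$screening$distance)
  surv1 <- intersect(covs, cl$keep)
  vf <- vif_filter(mpanel, surv1, config$screening$vif_threshold)
  survivors <- vf$kept
  if (!length(survivors)) stop2("all covariates eliminated during screening")
  vif_tab <- data.frame(Variable = vf$initial$variable,
                        VIFs = vf$initial$vif,
                        State = vf$initial$state, stringsAsFactors = FALSE)

  # geodetector inputs: grid points (default) or unit values
  if (!is.null(polygons) && isTRUE(config$geodetector$use_grid)) {
    gs <- grid_sample(polygons, agg[, c("unit_id", "y_resp", survivors)],
                      spacing_km = config$geodetector$spacing_km)
  } else {
    gs <- agg[, c("unit_id", "y_resp", survivors)]
  }
  k <- config$geodetector$k
  strata <- lapply(survivors, function(v)
    discretize_natural_breaks(gs[[v]], k = min(k, length(unique(gs[[v]])))))
  names(strata) <- survivors
  qres <- lapply(survivors, function(v) factor_q(gs$y_resp, strata[[v]]))
  names(qres) <- survivors
  factor_tab <- data.frame(variable = survivors,
                           q = vapply(qres, `[[`, numeric(1), "q"),
                           p = vapply(qres, `[[`, numeric(1), "p"),
                           stringsAsFactors = FALSE)
  factor_tab <- factor_tab[order(-factor_tab$q), ]
  rownames(factor_tab) <- NULL

  m <- length(survivors)
  eco <- matrix("-", m, m, dimnames = list(survivors, survivors))
  inter <- matrix(NA_real_, m, m, dimnames = list(survivors, survivors))
  diag(inter) <- vapply(qres, `[[`, numeric(1), "q")
  if (m >= 2) for (i in 2:m) for (j in 1:(i - 1)) {
    eco[i, j] <- ecological_detector(gs$y_resp, strata[[survivors[i]]],
                                     strata[[survivors[j]]],
                                     config$geodetector$alpha)$significant
    inter[i, j] <- interaction_detector(gs$y_resp, strata[[survivors[i]]],
                                        strata[[survivors[j]]])$q_AB
  }
  selected <- utils::head(factor_tab$variable, config$regression$top_k)

  write_table_csv(vif_tab, file.path(config$out_dir, "vif.csv"), hash)
  write_table_csv(factor_tab, file.path(config$out_dir, "factor_q.csv"),
                  hash)
  write_table_csv(as.data.frame(cbind(Variable = survivors, eco)),
                  file.path(config$out_dir, "ecological.csv"), hash)
  idf <- data.frame(Variable = survivors, round(inter, 6),
                    check.names = FALSE)
  write_table_csv(idf, file.path(config$out_dir, "interaction.csv"), hash)
  write_table_csv(data.frame(variable = selected),
                  file.path(config$out_dir, "selected.csv"), hash)
  list(vif_table = vif_tab, cluster_drop = cl$drop,
       factor_table = factor_tab, ecological = eco, interaction = inter,
       selected = selected, survivors = survivors)
}

#' Regression suite: GWR and MGWR per time label
#'
#' Fits both models on every time slice with the selected drivers, and
#' emits: a diagnostics comparison table (residual squares, ENP, sigma,
#' AICc, R2, adjusted R2 per model per time label), per-term bandwidth/ENP
#' statistics for MGWR, regional mean coefficients with each group's
#' largest-|coefficient| covariate flagged, and per-unit coefficient /
#' local-R2 surfaces.
#'
#' @param panel long [city_panel()] with `time` and `group`.
#' @param config a [run_config()].
#' @param selected covariates to regress (e.g. from [run_driver_screen()]).
#' @return list with `comparison`, `bandwidth_enp`, `regional`, `surfaces`
#'   data.frames (also written as CSV).
#' @export
run_regression_suite <- function(panel, config, selected) {
  if (!length(selected)) stop2("no covariates selected")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config_to_json(config))
  kern <- config$regression$kernel
  std <- config$regression$standardize
  times <- if ("time" %in% names(panel)) sort(unique(panel$time)) else "all"
  comp <- list(); bwe <- list(); reg <- list(); surf <- list()
  for (tl in times) {
    sl <- panel_slice(panel, tl)
    sl <- city_panel(as.data.frame(sl), selected)
    g <- fit_gwr(sl, selected, kernel = kern, standardize = std)
    m <- fit_mgwr(sl, selected, kernel = kern, standardize = std,
                  tol = config$regression$tol)
    cmp <- compare_models(g, m)
    cmp$time <- tl
    comp[[tl]] <- cmp
    bwe[[tl]] <- data.frame(time = tl, variable = names(m$bandwidths),
                            bandwidth = as.numeric(m$bandwidths),
                            enp = as.numeric(m$enp_terms),
                            stringsAsFactors = FALSE)
    rmc <- regional_mean_coefficients(m, sl$group)
    rmc <- cbind(time = tl, rmc)
    reg[[tl]] <- rmc
    surf[[tl]] <- data.frame(time = tl, unit_id = sl$unit_id,
                             gwr_local_r2 = g$local_r2, m$beta,
                             check.names = FALSE, stringsAsFactors = FALSE)
  }
  comparison <- do.call(rbind, comp); rownames(comparison) <- NULL
  bandwidth_enp <- do.call(rbind, bwe); rownames(bandwidth_enp) <- NULL
  regional <- do.call(rbind, reg); rownames(regional) <- NULL
  surfaces <- do.call(rbind, surf); rownames(surfaces) <- NULL
  write_table_csv(comparison, file.path(config$out_dir, "model_comparison.csv"), hash)
  write_table_csv(bandwidth_enp, file.path(config$out_dir, "bandwidth_enp.csv"), hash)
  write_table_csv(regional, file.path(config$out_dir, "regional_coefficients.csv"), hash)
  write_table_csv(surfaces, file.path(config$out_dir, "coefficient_surfaces.csv"), hash)
  list(comparison = comparison, bandwidth_enp = bandwidth_enp,
       regional = regional, surfaces = surfaces)
}

#' Run the full pipeline
#'
#' Generates (or accepts) a city panel, builds weights, and runs the
#' autocorrelation, driver-screening and regression suites, writing every
#' table as CSV plus a JSON sidecar recording the configuration, its hash
#' and the package version. Fully deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param panel,weights,polygons optionally pre-built inputs; when `panel`
#'   is `NULL` the synthetic generator in the config is used.
#' @return list with `moran`, `screen`, `regression`, `panel`, `weights`.
#' @export
run_all <- function(config, panel = NULL, weights = NULL, polygons = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(panel)) {
    spec <- config$synthetic
    spec$seed <- config$seed
    gen <- generate_panel(spec)
    panel <- gen$panel; weights <- gen$weights; polygons <- gen$polygons
  }
  if (is.null(weights)) stop2("weights required when a panel is supplied")
  moran <- run_autocorrelation_suite(panel, weights, config)
  screen <- run_driver_screen(panel, config, polygons)
  regression <- run_regression_suite(panel, config, screen$selected)
  sidecar <- list(package = "spatdrivers",
                  version = as.character(utils::packageVersion("spatdrivers")),
                  config = config_to_json(config),
                  config_hash = config_hash(config_to_json(config)))
  jsonlite::write_json(sidecar, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(moran = moran, screen = screen, regression = regression,
                 panel = panel, weights = weights))
}
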