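#' Pearson correlation matrix of response and covariates
#'
#' @param panel a [city_panel()].
#' @param covariates covariate subset (default: all panel covariates).
#' @param include_response include the response as the first row/column
#'   (named `y_resp`); default `TRUE`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(panel, covariates = panel_covariates(panel),
                               include_response = TRUE) {
  X <- as.data.frame(panel)[, covariates, drop = FALSE]
  if (include_response) X <- cbind(y_resp = panel$y_resp, X)
  if (nrow(X) < 3) stop2("need at least 3 complete rows")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop2("constant column(s): ", paste(names(X)[sds == 0], collapse = ", "))
  stats::cor(as.matrix(X), method = "pearson")
}

#' Single-linkage clustering of covariates by correlation
#'
#' Clusters variables with distance `1 - |r|` (so strongly negative
#' correlates also group) using minimum-distance (single-linkage)
#' agglomeration, and cuts the tree at `cut` to form flat groups. Within
#' each multi-member group all variables but one are flagged redundant;
#' the kept variable is the one most correlated (in absolute value) with
#' the response when a `y_resp` row is present, otherwise the first
#' alphabetically. This reproduces the usual pre-screening step where
#' near-duplicate covariates (e.g. several temperature summaries) are
#' collapsed before collinearity testing.
#'
#' @param corr correlation matrix from [correlation_matrix()]; a `y_resp`
#'   row/column, if present, guides which group member is kept but does not
#'   itself get clustered.
#' @param cut tree cut height on the `1 - |r|` scale (default 0.1, i.e.
#'   variables correlated above |r| = 0.9 are considered redundant).
#' @param distance `"abs"` for 1 - |r| (default) or `"signed"` for 1 - r.
#' @return list with `tree` (an `hclust`), `groups` (named integer vector),
#'   `drop` (character vector of redundant variables), `keep`.
#' @export
cluster_variables <- function(corr, cut = 0.1,
                              distance = c("abs", "signed")) {
  distance <- match.arg(distance)
  vars <- setdiff(rownames(corr), "y_resp")
  if (length(vars) < 2) stop2("need at least two covariates to cluster")
  R <- corr[vars, vars, drop = FALSE]
  D <- if (distance == "abs") 1 - abs(R) else 1 - R
  tree <- stats::hclust(stats::as.dist(D), method = "single")
  groups <- stats::cutree(tree, h = cut)
  keep <- character(); drop <- character()
  for (g in unique(groups)) {
    mem <- names(groups)[groups == g]
    if (length(mem) == 1L) { keep <- c(keep, mem); next }
    kp <- if ("y_resp" %in% rownames(corr)) {
      mem[which.max(abs(corr["y_resp", mem]))]
    } else sort(mem)[1L]
    keep <- c(keep, kp)
    drop <- c(drop, setdiff(mem, kp))
  }
  list(tree = tree, groups = groups, drop = drop,
       keep = intersect(vars, keep), cut = cut, distance = distance)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R_j^2)} where \eqn{R_j^2} comes from regressing
#' covariate j on the remaining covariates (with intercept). Perfectly
#' collinear covariates get `Inf` and state `"Failed"`.
#'
#' @param panel a [city_panel()].
#' @param covariates covariate subset to test (default: all).
#' @param threshold pass/fail cut-off; default 5.
#' @return data.frame (`vif_table`) with columns `variable`, `vif`, `state`
#'   and attribute `threshold`.
#' @export
vif <- function(panel, covariates = panel_covariates(panel), threshold = 5) {
  X <- as.matrix(as.data.frame(panel)[, covariates, drop = FALSE])
  k <- ncol(X)
  if (k < 2) stop2("need at least two covariates for VIF")
  if (nrow(X) < k + 2) stop2("need at least k + 2 rows for k covariates")
  out <- vapply(seq_len(k), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) stop2("constant covariate: ", covariates[j])
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  df <- data.frame(variable = covariates, vif = out,
                   state = ifelse(out <= threshold, "Pass", "Failed"),
                   stringsAsFactors = FALSE)
  attr(df, "threshold") <- threshold
  class(df) <- c("vif_table", "data.frame")
  df
}

#' Iterative VIF filtering
#'
#' Repeatedly drops the covariate with the largest VIF until all remaining
#' VIFs are at or below the threshold (or fewer than two covariates remain).
#'
#' @inheritParams vif
#' @return list with `table` (final [vif()] table), `kept`, `dropped`
#'   (in drop order), `initial` (the first-pass table).
#' @export
vif_filter <- function(panel, covariates = panel_covariates(panel),
                       threshold = 5) {
  current <- covariates
  dropped <- character()
  initial <- vif(panel, current, threshold)
  tab <- initial
  while (length(current) >= 2 && any(tab$vif > threshold)) {
    worst <- tab$variable[which.max(tab$vif)]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
    if (length(current) < 2) break
    tab <- vif(panel, current, threshold)
  }
  list(table = tab, kept = current, dropped = dropped, initial = initial,
       threshold = threshold)
}
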