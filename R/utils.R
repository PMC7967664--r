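# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop2(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

# Deterministic 32-bit sub-seed derived from a master seed and a stage label,
# so every stochastic stage of a run is independently but reproducibly seeded.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Stable hash of a configuration list (md5 of its canonical JSON serialization).
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# CSV writer that prefixes a provenance comment line (module version + config
# hash); read back with `read.csv(comment.char = "#")`.
write_table_csv <- function(df, path, hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# spatdrivers %s%s",
                     as.character(utils::packageVersion("spatdrivers")),
                     if (is.null(hash)) "" else paste0(" config=", hash)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
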