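# internal helpers shared across modules

#' Days per month used for all schedule arithmetic
#'
#' One month is defined as 365.25 / 12 = 30.4375 days throughout the package,
#' so "Month 18" corresponds to 547.875 days.
#'
#' @format A length-one numeric.
#' @export
DAYS_PER_MONTH <- 30.4375

`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_number <- function(x, name, lower = -Inf, upper = Inf,
                           allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("`%s` must be a single finite number", name)
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    .stopf("`%s` = %g is outside its valid range", name, x)
  invisible(x)
}

# package-level cache for deterministic calibration results (delay distribution,
# truncated-normal moment matches); keyed by a string digest of the targets
.namdsim_cache <- new.env(parent = emptyenv())

.cache_get_or <- function(key, compute) {
  if (!is.null(.namdsim_cache[[key]])) return(.namdsim_cache[[key]])
  val <- compute()
  assign(key, val, envir = .namdsim_cache)
  val
}

# write a numeric so that read.csv recovers the identical double
.format_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

.write_csv_exact <- function(df, path, header_lines = character()) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
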