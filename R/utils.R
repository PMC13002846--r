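# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding used for table-facing output, matching the convention of most
#' clinical publications (0.005 -> 0.01), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_probability <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

# Canonical string key for an itemset (sorted, "+"-joined).
itemset_key <- function(items) {
  paste(sort(items), collapse = "+")
}

# Deterministic CSV writer: no row names, no quoting surprises.
write_csv_strict <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
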