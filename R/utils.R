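#' Round half away from zero at a given number of decimals
#'
#' Display rounding for tables. Unlike [base::round()], halves round away
#' from zero (27.15 -> 27.2), matching the convention of printed statistical
#' tables. A small relative epsilon absorbs IEEE representation error so
#' that decimal halves such as 48.15 stored as 48.1499... still round up.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  z <- abs(x) * p
  z <- floor(z + 0.5 + 1e-8 * pmax(1, z))
  sign(x) * z / p
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a condition class so callers can distinguish error kinds
abort_landpov <- function(msg, class) {
  stop(structure(
    class = c(class, "landpov_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# seeded evaluation that does not disturb the caller's RNG stream;
# substream offsets keep stages independently reproducible from one seed
with_seed <- function(seed, expr, offset = 0L) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}
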