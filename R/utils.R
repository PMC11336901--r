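#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used for printed
#' percentages (so 49.35 -> 49.4), as opposed to [base::round()]'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Geometric mean and geometric SD
#'
#' Computed on the natural-log scale with the sample (n-1) standard
#' deviation. An offset (default 0.5) is added before taking logs so that
#' zero counts do not collapse the geometric mean to zero; set
#' `offset = 0` to evaluate the bare formula.
#'
#' @param x positive numeric vector (counts).
#' @param offset added to `x` before the log transform.
#' @return named list with elements `geomean` and `geosd`.
#' @keywords internal
geom_stats <- function(x, offset = 0.5) {
  x <- x + offset
  if (any(x <= 0)) {
    stop("geometric statistics undefined for non-positive values; ",
         "enable the count offset", call. = FALSE)
  }
  lx <- log(x)
  list(geomean = exp(mean(lx)), geosd = exp(stats::sd(lx)))
}

## stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

## deterministic RNG scope: run code under a seed without disturbing the
## caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## validate a numeric gene x sample matrix with dimnames
check_expr_matrix <- function(m, what = "matrix") {
  check_that(is.matrix(m) && is.numeric(m), "%s must be a numeric matrix", what)
  check_that(!is.null(rownames(m)), "%s must carry gene symbols as rownames", what)
  check_that(!is.null(colnames(m)), "%s must carry sample ids as colnames", what)
  check_that(!anyDuplicated(rownames(m)), "%s has duplicated gene symbols", what)
  check_that(!anyDuplicated(colnames(m)), "%s has duplicated sample ids", what)
  invisible(m)
}

## column-wise 75th percentile (linear interpolation, type 7)
col_q3 <- function(m) apply(m, 2, stats::quantile, probs = 0.75, names = FALSE)
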