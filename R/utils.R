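#' @useDynLib nanoshapes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_polarity <- function(polarity) {
  if (!is.character(polarity) || length(polarity) != 1 ||
      !polarity %in% c("dark_particles", "bright_particles")) {
    stop_input("polarity must be 'dark_particles' or 'bright_particles'")
  }
  polarity
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    stop_input("mask must be a matrix of 0/1 values")
  }
  invisible(mask)
}
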