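#' @useDynLib spikestates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom rnorm pchisq qchisq sd aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# Run code under a local RNG state seeded with `seed`; the caller's RNG
# stream is left untouched. seed = NULL runs unseeded (still isolated).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

# Derive n reproducible sub-seeds from a parent seed. Keeps every derived
# seed in [1, 2^31 - 2] so it is a valid R integer seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

# Fixed task structure: stimulus -> cued direction and taste quality.
STIMULI <- c("S", "Q", "M", "O")

#' Task maps from stimulus to cued direction and taste quality
#'
#' The four tastants map to response directions and taste qualities in a
#' fixed, deliberately crossed design: sucrose (S) and quinine (Q) cue a
#' left response, maltose (M) and octaacetate (O) cue a right response,
#' while S and M are sweet and Q and O are bitter. Quality is therefore
#' orthogonal to the rewarded direction.
#'
#' @param stimulus Character vector with elements in `c("S","Q","M","O")`.
#' @return Character vector of `"left"`/`"right"` (for
#'   `stimulus_direction`) or `"sweet"`/`"bitter"` (for
#'   `stimulus_quality`).
#' @examples
#' stimulus_direction(c("S", "M"))
#' stimulus_quality(c("Q", "M"))
#' @export
stimulus_direction <- function(stimulus) {
  stopifnot(all(stimulus %in% STIMULI))
  ifelse(stimulus %in% c("S", "Q"), "left", "right")
}

#' @rdname stimulus_direction
#' @export
stimulus_quality <- function(stimulus) {
  stopifnot(all(stimulus %in% STIMULI))
  ifelse(stimulus %in% c("S", "M"), "sweet", "bitter")
}

# Gaussian smoothing used for onset densities and similarity traces.
# `width` is the full kernel width in points; sigma = width / 6, kernel
# truncated at the window and renormalized at the edges.
gaussian_smooth <- function(x, width) {
  if (width <= 1 || length(x) < 3) return(x)
  half <- floor(width / 2)
  sigma <- width / 6
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  den <- stats::filter(wp, k, sides = 2)[(half + 1):(half + n)]
  as.numeric(num / den)
}
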