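#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median rnorm runif sd setNames
#' @importFrom utils combn head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' random streams (tree simulation, niche evolution, occupancy, each null
#' distribution) use substream seeds derived deterministically by this
#' function, so results are bit-reproducible and streams do not collide.
#'
#' @param seed master seed (integer).
#' @param i substream index (non-negative integer).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
sub_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  as.integer((abs(seed) + 7919 * (i + 1)) %% 2147483646 + 1)
}

# atomic file write: run writer against a temp file in the same directory,
# then rename over the destination
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# fixed-format number printing for output tables so identical runs are
# byte-identical regardless of locale/options
fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), "", formatC(x, format = "g", digits = digits))
}
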