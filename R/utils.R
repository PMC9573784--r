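#' @keywords internal
#' @useDynLib carpelseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All generators in the package funnel their randomness through this so that
# (params, seed) -> output is a pure function.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary_mask <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

assert_mask <- function(m, name = deparse(substitute(m))) {
  if (!is_binary_mask(m))
    stop(sprintf("`%s` must be a numeric matrix with values in {0, 1}", name),
         call. = FALSE)
  invisible(m)
}

# Centroid of a binary mask as the unweighted mean of member pixel
# coordinates, in (row, col) with origin top-left and integer pixel centres.
mask_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_))
  c(mean(idx[, 1L]), mean(idx[, 2L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
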