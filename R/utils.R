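#' Run code with a temporary RNG seed
#'
#' Sets the RNG to a known state, evaluates `code`, and restores the previous
#' state, so seeded generators do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a global one; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_binary_labels <- function(y, what = "label") {
  if (!all(y %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0 and 1", what), call. = FALSE)
  }
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Logical (or 0/1) matrices of equal dimension.
#' @return IoU in [0, 1]; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
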