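#' @useDynLib tomoshell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cor oneway.test t.test p.adjust pt
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so simulation helpers do not clobber the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

as_triple <- function(x, name) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L || !is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric scalar or length-3 vector", name))
  }
  as.numeric(x)
}

#' Label connected components of a 3D logical array
#'
#' Components use 26-connectivity (face, edge and corner neighbours).
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in scan order.
#' @keywords internal
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  cpp_label3d(mask, as.integer(dim(mask)))
}
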