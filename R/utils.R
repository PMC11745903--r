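# Internal numeric helpers shared across modules.

#' @keywords internal
.activations <- list(
  identity = list(
    f    = function(x) x,
    grad = function(x, y) array(1, dim = dim(as.matrix(x)))
  ),
  relu = list(
    f    = function(x) pmax(x, 0),
    grad = function(x, y) (x > 0) * 1
  ),
  sigmoid = list(
    f    = function(x) 1 / (1 + exp(-x)),
    grad = function(x, y) y * (1 - y)
  ),
  tanh = list(
    f    = function(x) tanh(x),
    grad = function(x, y) 1 - y^2
  )
)

#' @keywords internal
.get_activation <- function(id) {
  if (is.function(id)) {
    return(list(f = id, grad = NULL))
  }
  act <- .activations[[id]]
  if (is.null(act)) {
    stop("unknown activation: '", id, "'", call. = FALSE)
  }
  act
}

# Glorot (uniform) initialization; draws from the current RNG stream.
#' @keywords internal
.glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

#' @keywords internal
.check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

# sigmoid kept as a plain function for scalar call sites
#' @keywords internal
.sigmoid <- function(x) 1 / (1 + exp(-x))

# Deterministic 32-bit string hash (FNV-1a), used for seed-stable fold
# assignment of grouping-unit ids. Returns a non-negative double < 2^31.
#' @keywords internal
.hash_id <- function(ids, seed = 0L) {
  vapply(ids, function(id) {
    h <- 2166136261
    for (b in utf8ToInt(paste0(id, ":", seed))) {
      h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
      h <- (h * 16777619) %% 2^31
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Derive a child seed (< 2^31) from a base seed and a stream label.
#' @keywords internal
.derive_seed <- function(seed, label) {
  as.integer((.hash_id(label, seed = seed) + as.numeric(seed)) %% .Machine$integer.max)
}
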