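#' Build a Hebbian weight matrix from weighted patterns
#'
#' Implements the batch Hebbian rule W = X'X with the diagonal zeroed,
#' where the rows of X are the stored patterns. A row scaled by a
#' multiplier `m` contributes `m^2` times its outer product, which is how
#' "presenting a stimulus with weight m" enters the model: scaling the
#' pattern entries before the outer product. Multipliers may differ per
#' row; `j` identical copies of a pattern are equivalent to a single row
#' with squared-multiplier `j`.
#'
#' All arithmetic is integer-valued (for integer multipliers), so the
#' incremental update path ([add_target_copies()]) reproduces the batch
#' build bit-exactly.
#'
#' @param patterns Integer matrix, one \{-1, +1\} pattern per row.
#' @param multipliers Positive numeric vector recycled to `nrow(patterns)`;
#'   the per-row scaling applied to pattern entries before the outer
#'   product (default 1).
#' @return An `n` x `n` symmetric numeric matrix with zero diagonal.
#' @examples
#' build_weight_matrix(matrix(c(1, 1, -1), nrow = 1))
#' @export
build_weight_matrix <- function(patterns, multipliers = 1) {
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1)
  p <- nrow(patterns)
  n <- ncol(patterns)
  if (p == 0) return(matrix(0, n, n))
  if (any(multipliers <= 0)) stop("multipliers must be positive", call. = FALSE)
  multipliers <- rep_len(multipliers, p)
  X <- patterns * multipliers          # scale rows, then W = X'X
  W <- crossprod(X)
  diag(W) <- 0
  W
}

#' Add Hebbian contributions of a target pattern to existing weights
#'
#' Incremental equivalent of appending `count` unscaled copies of `target`
#' to the stored-pattern matrix and rebuilding: adds
#' `count * target %o% target` with the diagonal kept at zero. Under
#' integer inputs the result is exactly equal to the batch rebuild.
#'
#' @param W Weight matrix (symmetric, zero diagonal).
#' @param target Pattern vector of length `nrow(W)`.
#' @param count Positive integer number of copies to add.
#' @return Updated weight matrix.
#' @export
add_target_copies <- function(W, target, count = 1) {
  if (length(target) != nrow(W)) stop("dimension mismatch", call. = FALSE)
  if (count < 1) stop("`count` must be at least 1", call. = FALSE)
  W2 <- W + count * tcrossprod(target)
  diag(W2) <- 0
  W2
}
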