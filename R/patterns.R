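#' Generate a random binary pattern
#'
#' Draws a length-`n` vector of independent, equiprobable spins in
#' \{-1, +1\}. Patterns play a double role in the Amari-Hopfield model:
#' they are both the stimuli stored via the Hebbian rule and the network
#' states that evolve under the dynamics.
#'
#' Randomness comes from R's global RNG stream; call [set.seed()] (or use
#' the seeded experiment drivers) for reproducibility.
#'
#' @param n Positive integer, number of neurons.
#' @return Integer vector of length `n` with entries in \{-1L, 1L\}.
#' @examples
#' set.seed(1)
#' random_pattern(10)
#' @export
random_pattern <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  sample(c(-1L, 1L), as.integer(n), replace = TRUE)
}

#' Generate a set of random patterns as a matrix
#'
#' Returns a `p` x `n` integer matrix whose rows are independent random
#' \{-1, +1\} patterns — the layout used to build Hebbian weights, where
#' each row is one stored stimulus.
#'
#' @param p Number of patterns (rows). `p = 0` yields a 0 x `n` matrix.
#' @param n Number of neurons (columns).
#' @return Integer matrix of dimension `p` x `n`.
#' @export
random_pattern_matrix <- function(p, n) {
  if (p < 0) stop("`p` must be nonnegative", call. = FALSE)
  if (p == 0) return(matrix(integer(0), nrow = 0, ncol = n))
  matrix(sample(c(-1L, 1L), as.integer(p) * as.integer(n), replace = TRUE),
         nrow = p, ncol = n, byrow = TRUE)
}

#' Enumerate all states of an n-neuron binary network
#'
#' Produces the full state space as a `2^n` x `n` matrix of \{-1, +1\}
#' entries. Row `i` encodes the binary expansion of `i - 1` with the
#' least-significant bit in column 1 and a set bit mapped to +1, so the
#' ordering is deterministic and the row index of any state is recoverable
#' with [state_index()].
#'
#' @param n Neuron count; capped at 20 to guard against state-space
#'   explosion (`2^20` rows is already ~1e6).
#' @return Integer matrix with `2^n` rows, each a distinct state.
#' @examples
#' enumerate_states(2)
#' @export
enumerate_states <- function(n) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (n > 20) stop("state space too large: n must be <= 20", call. = FALSE)
  ids <- 0:(2^n - 1)
  bits <- vapply(seq_len(n) - 1L, function(b) bitwAnd(bitwShiftR(ids, b), 1L),
                 integer(length(ids)))
  storage.mode(bits) <- "integer"
  matrix(2L * bits - 1L, nrow = length(ids), ncol = n)
}

#' Row index of states in the canonical enumeration
#'
#' Inverse of [enumerate_states()]: maps states (rows of a matrix, entries
#' in \{-1, +1\}) to their 1-based row index in the canonical ordering.
#'
#' @param states Matrix with one state per row (a single state may be
#'   passed as a vector).
#' @return Integer vector of 1-based indices into `enumerate_states(n)`.
#' @export
state_index <- function(states) {
  if (is.vector(states)) states <- matrix(states, nrow = 1)
  n <- ncol(states)
  pow2 <- 2^(seq_len(n) - 1)
  as.integer(((states + 1L) / 2) %*% pow2) + 1L
}

#' Sample states at a fixed Hamming distance from a target
#'
#' Draws `m` states that differ from `target` in exactly `k` positions
#' (the Hamming shell at distance `k`). When the shell holds at least `m`
#' states (`choose(n, k) >= m`) the sample is drawn without replacement so
#' all returned states are distinct; otherwise flip sets are drawn with
#' replacement and duplicates can occur.
#'
#' @param target Pattern vector (entries in \{-1, +1\}).
#' @param k Hamming distance, `0 <= k <= length(target)`.
#' @param m Number of states to sample.
#' @return Integer matrix of `m` rows, each at Hamming distance `k` from
#'   `target`.
#' @export
sample_states_at_distance <- function(target, k, m) {
  n <- length(target)
  if (k < 0 || k > n) stop("`k` must lie in [0, n]", call. = FALSE)
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  shell <- choose(n, k)
  out <- matrix(rep(as.integer(target), each = m), nrow = m, ncol = n)
  if (k == 0) return(out)
  if (shell >= m && shell <= 1e6) {
    # distinct flip sets: sample combination ranks without replacement when
    # the shell is small enough to index, else rejection-sample
    seen <- new.env(hash = TRUE)
    got <- 0L
    while (got < m) {
      fl <- sort(sample.int(n, k))
      key <- paste(fl, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[got, fl] <- -out[got, fl]
      }
    }
  } else {
    for (i in seq_len(m)) {
      fl <- sample.int(n, k)
      out[i, fl] <- -out[i, fl]
    }
  }
  out
}

#' Write/read patterns as plain CSV
#'
#' Patterns serialise as rows of +1/-1 integers with no header; weight
#' matrices as square integer CSV. Both round-trip exactly.
#'
#' @param x Integer matrix (patterns as rows, or a square weight matrix).
#' @param path File path.
#' @return `write_pattern_csv()` returns `path` invisibly;
#'   `read_pattern_csv()` returns an integer matrix.
#' @export
write_pattern_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
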