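#' One synchronous update of the network state
#'
#' Applies s(t+1) = sign(W s(t)) with all neurons updated simultaneously.
#' The sign convention resolves ties upward: a local field of exactly zero
#' yields +1 (so an all-zero weight matrix maps every state to the
#' all-(+1) state).
#'
#' @param W Weight matrix.
#' @param s State vector, or a matrix of states (one per row) to update in
#'   a single batched matrix product.
#' @return Updated state in the same shape as `s`.
#' @export
synchronous_update <- function(W, s) {
  if (is.matrix(s)) {
    field <- s %*% W          # W symmetric, so (W s)' = s' W
    out <- matrix(ifelse(field >= 0, 1L, -1L), nrow = nrow(s))
    return(out)
  }
  field <- as.vector(W %*% s)
  ifelse(field >= 0, 1L, -1L)
}

# Local fields for a batch of states under a low-rank Hebbian weight
# operator: W = sum_mu w_mu x_mu x_mu' with zero diagonal. Because entries
# are +-1, diag(W_full) would be sum(w), so field = (S P') (w * P) - sum(w) S.
# Equivalent to S %*% W in O(m p n) instead of O(m n^2); used by the
# large-network experiments where p (stored patterns) is tiny.
lowrank_field <- function(S, P, w) {
  (S %*% t(P)) %*% (w * P) - sum(w) * S
}

lowrank_update <- function(S, P, w) {
  field <- lowrank_field(S, P, w)
  matrix(ifelse(field >= 0, 1L, -1L), nrow = nrow(S))
}

#' Evolve a state to a fixed point or limit cycle
#'
#' Iterates [synchronous_update()] from `s0` until the state stops
#' changing (a fixed point), revisits the state from two steps earlier (a
#' period-2 limit cycle — the only cycle length possible under symmetric
#' zero-diagonal synchronous dynamics), or `max_iters` updates elapse.
#'
#' Convention: `steps` counts updates actually applied, so a state that is
#' already a fixed point returns `steps = 1` (one update was needed to
#' observe that nothing changed) with `final` equal to `s0`.
#'
#' @param W Weight matrix.
#' @param s0 Initial state vector.
#' @param max_iters Safety cap on updates (default 200, far above observed
#'   transient lengths at the network sizes studied).
#' @return List with `outcome` (`"fixed_point"`, `"limit_cycle"` or
#'   `"max_iter_exceeded"`), `final` (the fixed point, or last state
#'   otherwise), and `steps`.
#' @export
evolve <- function(W, s0, max_iters = 200) {
  if (max_iters < 1) stop("`max_iters` must be at least 1", call. = FALSE)
  prev2 <- NULL
  prev <- s0
  for (t in seq_len(max_iters)) {
    cur <- synchronous_update(W, prev)
    if (identical(all.equal(cur, prev, check.attributes = FALSE), TRUE) ||
        all(cur == prev)) {
      return(list(outcome = "fixed_point", final = cur, steps = t))
    }
    if (!is.null(prev2) && all(cur == prev2)) {
      return(list(outcome = "limit_cycle", final = cur, steps = t))
    }
    prev2 <- prev
    prev <- cur
  }
  list(outcome = "max_iter_exceeded", final = prev, steps = max_iters)
}

# Batched terminal states for many initial states at once.
# Returns a list: outcome (character per row), final (matrix of terminal
# states: the fixed point for converged rows, last state otherwise).
# field_fun(S) must return sign-updated states for all rows of S.
evolve_batch_fun <- function(update_fun, S, max_iters = 200) {
  m <- nrow(S)
  outcome <- rep("max_iter_exceeded", m)
  final <- S
  active <- rep(TRUE, m)
  prev2 <- NULL
  prev <- S
  for (t in seq_len(max_iters)) {
    cur <- prev
    cur[active, ] <- update_fun(prev[active, , drop = FALSE])
    fixed <- active & rowSums(cur != prev) == 0
    if (any(fixed)) {
      outcome[fixed] <- "fixed_point"
      final[fixed, ] <- cur[fixed, , drop = FALSE]
      active[fixed] <- FALSE
    }
    if (!is.null(prev2)) {
      cyc <- active & rowSums(cur != prev2) == 0
      if (any(cyc)) {
        outcome[cyc] <- "limit_cycle"
        final[cyc, ] <- cur[cyc, , drop = FALSE]
        active[cyc] <- FALSE
      }
    }
    if (!any(active)) break
    prev2 <- prev
    prev <- cur
  }
  list(outcome = outcome, final = final)
}

#' Batched evolution of many initial states
#'
#' Evolves every row of `S` under the dense weight matrix `W` until each
#' reaches a fixed point or period-2 limit cycle (see [evolve()]).
#'
#' @param W Weight matrix.
#' @param S Matrix of initial states, one per row.
#' @param max_iters Update cap per state.
#' @return List with per-row `outcome` and the matrix of terminal states
#'   `final`.
#' @export
evolve_batch <- function(W, S, max_iters = 200) {
  evolve_batch_fun(function(X) synchronous_update(W, X), S, max_iters)
}
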