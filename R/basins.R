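#' Build the one-step state-transition map
#'
#' For every state in `states` (by convention the full enumeration from
#' [enumerate_states()]), computes the unique successor under one
#' synchronous update, giving the functional graph of the dynamics: every
#' node has out-degree one, fixed points are self-successors, and the only
#' other recurrent structures are period-2 cycles.
#'
#' @param W Weight matrix.
#' @param states State matrix, one state per row (rows must be indexable
#'   by [state_index()], i.e. in the canonical \{-1,+1\} encoding).
#' @return Integer vector `succ` with `succ[i]` the row index (in the
#'   canonical enumeration) of the successor of state `i`.
#' @export
build_transition_map <- function(W, states) {
  field <- states %*% W
  bits <- field >= 0
  n <- ncol(states)
  pow2 <- 2^(seq_len(n) - 1)
  as.integer(bits %*% pow2) + 1L
}

# Terminal map by pointer doubling: after k doublings g = succ^(2^k).
# 2^k >= N bounds every transient, and 2^k is even, so states draining to
# a fixed point map to it and states draining to a 2-cycle map to a fixed
# member of that cycle.
terminal_map <- function(succ) {
  g <- succ
  doublings <- max(1L, ceiling(log2(length(succ))))
  for (k in seq_len(doublings)) g <- g[g]
  g
}

# Logical basin membership of the fixed point at index t_idx; all FALSE if
# the target is not currently a fixed point.
basin_membership <- function(succ, t_idx) {
  if (succ[t_idx] != t_idx) return(rep(FALSE, length(succ)))
  terminal_map(succ) == t_idx
}

#' Exhaustive attractor basin of a target pattern
#'
#' Evolves every supplied state and returns those that converge to the
#' target as a fixed point. States ending in period-2 limit cycles (or in
#' other fixed points) belong to no basin here; the target itself is a
#' member exactly when it is a fixed point. Membership is computed on the
#' whole state space at once via the transition map and pointer doubling;
#' the per-state evolution loop gives identical results (tested) but is
#' far slower.
#'
#' @param W Weight matrix.
#' @param target Target pattern vector.
#' @param states State matrix (default: the full enumeration for
#'   `length(target)` neurons).
#' @return Integer vector of canonical state indices in the basin.
#' @examples
#' W <- build_weight_matrix(matrix(c(1, 1, -1, 1), nrow = 1))
#' target_basin(W, c(1, 1, -1, 1))
#' @export
target_basin <- function(W, target, states = enumerate_states(length(target))) {
  succ <- build_transition_map(W, states)
  which(basin_membership(succ, state_index(target)))
}

#' States newly acquired by the basin after a jump
#'
#' Set difference of basin membership after versus before a presentation
#' that increased the basin.
#'
#' @param basin_before,basin_after Integer vectors of state indices.
#' @return Integer vector of indices in `basin_after` but not
#'   `basin_before`.
#' @export
new_states_after_jump <- function(basin_before, basin_after) {
  setdiff(basin_after, basin_before)
}

#' Partition newly acquired basin states into branches
#'
#' After a basin-size jump, the new states organise into branches of the
#' transition tree. A branch head is a new state whose one-step successor
#' is not itself a new state (it already belonged to the basin), or the
#' target fixed point itself when the target first becomes an attractor
#' (its successor is itself, so it can root a branch but never hang from
#' one). Each new state is assigned to the head its forward path reaches
#' without leaving the new-state set; branch size counts the head plus all
#' states assigned to it, so branch sizes sum to the number of new states.
#'
#' @param new_states Integer vector of canonical indices of new states.
#' @param succ Transition map from [build_transition_map()].
#' @return Tibble with one row per branch: `head_index`, `branch_size`.
#' @export
partition_branches <- function(new_states, succ) {
  if (length(new_states) == 0) {
    return(tibble::tibble(head_index = integer(0), branch_size = integer(0)))
  }
  is_new <- rep(FALSE, length(succ))
  is_new[new_states] <- TRUE
  is_head <- function(s) !is_new[succ[s]] || succ[s] == s
  head_of <- integer(length(succ))  # 0 = unassigned
  for (s in new_states) {
    if (head_of[s] != 0L) next
    path <- integer(0)
    cur <- s
    repeat {
      if (head_of[cur] != 0L) {
        h <- head_of[cur]
        break
      }
      if (is_head(cur)) {
        h <- cur
        break
      }
      path <- c(path, cur)
      cur <- succ[cur]
      if (length(path) > length(succ)) {
        stop("malformed basin: forward path never reaches a branch head",
             call. = FALSE)
      }
    }
    head_of[c(path, cur)] <- h
  }
  sizes <- table(head_of[new_states])
  tibble::tibble(head_index = as.integer(names(sizes)),
                 branch_size = as.integer(sizes))
}

#' Descendant counts for every state in the transition graph
#'
#' For each state `v`, counts the states (including `v` itself) whose
#' forward orbit visits `v` — the size of the "branch" of the state
#' transition graph that drains through `v`. For a fixed point this is the
#' size of its whole basin of attraction plus itself; for a member of a
#' period-2 cycle the forward orbit of anything entering the cycle visits
#' both members, so both carry the full component count; for a transient
#' state it is the size of its in-flowing subtree.
#'
#' @param succ Transition map (integer successor vector over the full
#'   enumeration).
#' @return Integer vector of counts, one per state, each at least 1.
#' @export
descendant_counts <- function(succ) {
  N <- length(succ)
  fixed <- succ == seq_len(N)
  two_cycle <- !fixed & succ[succ] == seq_len(N)
  on_cycle <- fixed | two_cycle

  # depth-to-cycle, then accumulate subtree sizes from the leaves inward
  depth <- rep(NA_integer_, N)
  depth[on_cycle] <- 0L
  while (anyNA(depth)) {
    ready <- is.na(depth) & !is.na(depth[succ])
    if (!any(ready)) stop("transition map contains a cycle of period > 2")
    depth[ready] <- depth[succ[ready]] + 1L
  }
  cnt <- rep(1L, N)
  for (s in order(depth, decreasing = TRUE)) {
    if (on_cycle[s]) next
    cnt[succ[s]] <- cnt[succ[s]] + cnt[s]
  }

  # cycle members see the whole component that drains into their cycle
  g <- terminal_map(succ)
  if (any(fixed)) {
    comp <- tabulate(g[g %in% which(fixed)], nbins = N)
    cnt[fixed] <- comp[fixed]
  }
  for (a in which(two_cycle)) {
    b <- succ[a]
    if (a < b) {
      comp <- sum(g == a | g == b)
      cnt[a] <- comp
      cnt[b] <- comp
    }
  }
  cnt
}

#' Extract positive basin-size jumps from a trajectory
#'
#' A jump at presentation `j` is a positive change `sizes[j] -
#' sizes[j-1]`; zero and negative changes produce no record (negative
#' changes — the basin can also shed states — are retained in the
#' trajectory and can be counted separately).
#'
#' @param sizes Numeric vector of basin sizes indexed by presentation
#'   count `j = 0..J` (length `J + 1`).
#' @return Tibble with columns `j` (presentation index of the increase)
#'   and `size` (states gained).
#' @export
extract_jumps <- function(sizes) {
  if (length(sizes) < 2) stop("trajectory must have at least 2 entries",
                              call. = FALSE)
  d <- diff(sizes)
  idx <- which(d > 0)
  tibble::tibble(j = idx, size = as.integer(d[idx]))
}
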