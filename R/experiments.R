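#' Deterministic child seed for run r of an experiment
#'
#' Each run of a seeded experiment draws its own seed as
#' `(base_seed + 48271 * r) mod (2^31 - 1)` so that runs are individually
#' reproducible and distinct runs never share a stream (48271 is the
#' classic Lehmer multiplier; the modulus keeps seeds in 32-bit integer
#' range).
#'
#' @param base_seed Integer base seed of the experiment.
#' @param r Run number (1-based).
#' @return A single integer seed.
#' @export
child_seed <- function(base_seed, r) {
  as.integer((as.numeric(base_seed) + 48271 * as.numeric(r)) %% 2147483647)
}

#' Single run of the repeated-presentation protocol
#'
#' Pretrains an `n`-neuron Amari-Hopfield network with `pretrain_count`
#' random patterns each scaled by `pretrain_multiplier`, draws a fresh
#' random target, then presents the target `J` times. After each
#' presentation the weights gain one unscaled Hebbian copy of the target
#' (incrementally — exactly equal to rebuilding from the concatenated
#' pattern matrix) and the target's attractor basin is recomputed over the
#' exhaustively enumerated state space. Basin-size jumps and, optionally,
#' the branch decomposition of the newly acquired states are recorded at
#' every increase.
#'
#' @param n Neuron count (exhaustive enumeration, so `n <= 20`).
#' @param pretrain_count Number of pretraining patterns.
#' @param pretrain_multiplier Scaling applied to each pretraining pattern.
#' @param J Number of target presentations.
#' @param seed Integer seed for this run (`NULL` to use the current RNG
#'   state).
#' @param record_branches If `TRUE`, partition the new states into
#'   branches at every jump.
#' @param record_network_counts If `TRUE`, after every jump also record
#'   the network-wide descendant counts of the post-jump transition graph
#'   (the branch sizes of *all* states, not just newly acquired ones);
#'   counts of 1 (leaf states) are omitted from the table.
#' @param run_id Identifier stored in the output tables.
#' @return Object of class `presentation_run`: a list with tibbles
#'   `trajectory` (`run_id`, `j`, `basin_size`), `jumps` (`run_id`, `j`,
#'   `size`), `branches` (`run_id`, `j`, `head_index`, `branch_size`),
#'   `network_counts` (`run_id`, `j`, `count`; post-jump snapshots,
#'   counts >= 2), the count `negative_changes`, and the `target`
#'   pattern.
#' @examples
#' run <- run_presentation_experiment(n = 8, pretrain_count = 5,
#'                                    pretrain_multiplier = 10, J = 50,
#'                                    seed = 1)
#' run$trajectory
#' @export
run_presentation_experiment <- function(n = 10, pretrain_count = 50,
                                        pretrain_multiplier = 10, J = 1000,
                                        seed = NULL, record_branches = TRUE,
                                        record_network_counts = FALSE,
                                        run_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  pre <- random_pattern_matrix(pretrain_count, n)
  target <- random_pattern(n)
  states <- enumerate_states(n)
  pow2 <- 2^(seq_len(n) - 1)
  t_idx <- state_index(target)

  W <- build_weight_matrix(pre, pretrain_multiplier)
  TT <- tcrossprod(target)
  diag(TT) <- 0

  sizes <- integer(J + 1)
  member_prev <- basin_membership(build_transition_map(W, states), t_idx)
  sizes[1] <- sum(member_prev)
  jumps_j <- integer(0)
  jumps_size <- integer(0)
  branch_rows <- list()
  count_rows <- list()
  negative_changes <- 0L

  for (j in seq_len(J)) {
    W <- W + TT
    bits <- (states %*% W) >= 0
    succ <- as.integer(bits %*% pow2) + 1L
    member <- basin_membership(succ, t_idx)
    sizes[j + 1] <- sum(member)
    delta <- sizes[j + 1] - sizes[j]
    if (delta > 0) {
      jumps_j <- c(jumps_j, j)
      jumps_size <- c(jumps_size, delta)
      if (record_branches) {
        new_idx <- which(member & !member_prev)
        br <- partition_branches(new_idx, succ)
        br$j <- j
        branch_rows[[length(branch_rows) + 1L]] <- br
      }
      if (record_network_counts) {
        cnt <- descendant_counts(succ)
        cnt <- cnt[cnt >= 2]
        count_rows[[length(count_rows) + 1L]] <-
          tibble::tibble(j = j, count = cnt)
      }
    } else if (delta < 0) {
      negative_changes <- negative_changes + 1L
    }
    member_prev <- member
  }

  branches <- if (length(branch_rows)) {
    dplyr::bind_rows(branch_rows)
  } else {
    tibble::tibble(head_index = integer(0), branch_size = integer(0),
                   j = integer(0))
  }
  branches <- tibble::tibble(run_id = rep(as.integer(run_id), nrow(branches)),
                             j = branches$j,
                             head_index = branches$head_index,
                             branch_size = branches$branch_size)
  network_counts <- if (length(count_rows)) {
    dplyr::bind_rows(count_rows)
  } else {
    tibble::tibble(j = integer(0), count = integer(0))
  }
  network_counts <- tibble::tibble(
    run_id = rep(as.integer(run_id), nrow(network_counts)),
    j = network_counts$j, count = network_counts$count
  )
  out <- list(
    trajectory = tibble::tibble(run_id = as.integer(run_id), j = 0:J,
                                basin_size = sizes),
    jumps = tibble::tibble(run_id = rep(as.integer(run_id), length(jumps_j)),
                           j = jumps_j, size = jumps_size),
    branches = branches,
    network_counts = network_counts,
    negative_changes = negative_changes,
    target = target,
    config = list(n = n, pretrain_count = pretrain_count,
                  pretrain_multiplier = pretrain_multiplier, J = J,
                  seed = seed)
  )
  class(out) <- "presentation_run"
  out
}

#' Multi-run basin-growth study
#'
#' Repeats [run_presentation_experiment()] over `runs` independent runs,
#' each with a fresh pretraining set and target drawn under a
#' deterministic child seed ([child_seed()]). Default parameters are the
#' study conditions: 10 neurons, 50 pretraining patterns scaled by 10,
#' 1,000 target presentations, 100 runs.
#'
#' @param runs Number of independent runs.
#' @param base_seed Base seed; run `r` uses `child_seed(base_seed, r)`.
#' @param record_branches Record branch partitions at every jump.
#' @inheritParams run_presentation_experiment
#' @return Object of class `basin_study`: list with pooled tibbles
#'   `trajectories`, `jumps`, `branches`, `network_counts`, the total
#'   `negative_changes`, and `config`.
#' @export
run_basin_study <- function(runs = 100, n = 10, pretrain_count = 50,
                            pretrain_multiplier = 10, J = 1000,
                            base_seed = 1, record_branches = TRUE,
                            record_network_counts = FALSE) {
  res <- purrr::map(seq_len(runs), function(r) {
    run_presentation_experiment(n = n, pretrain_count = pretrain_count,
                                pretrain_multiplier = pretrain_multiplier,
                                J = J, seed = child_seed(base_seed, r),
                                record_branches = record_branches,
                                record_network_counts = record_network_counts,
                                run_id = r)
  })
  out <- list(
    trajectories = dplyr::bind_rows(purrr::map(res, "trajectory")),
    jumps = dplyr::bind_rows(purrr::map(res, "jumps")),
    branches = dplyr::bind_rows(purrr::map(res, "branches")),
    network_counts = dplyr::bind_rows(purrr::map(res, "network_counts")),
    negative_changes = sum(purrr::map_int(res, "negative_changes")),
    config = list(runs = runs, n = n, pretrain_count = pretrain_count,
                  pretrain_multiplier = pretrain_multiplier, J = J,
                  base_seed = base_seed)
  )
  class(out) <- "basin_study"
  out
}

#' Pool positive jumps across runs
#'
#' Collects all positive basin-size jumps of a study into one sample and
#' reports the proportion of presentations that produced an increase.
#'
#' @param study A `basin_study`, or a jumps tibble with a `size` column
#'   (in which case `runs` and `J` must be given).
#' @param runs,J Run count and presentations per run (taken from the
#'   study's config when a `basin_study` is passed).
#' @return List with `pool` (integer vector of jump sizes) and
#'   `proportion` (jumps per presentation).
#' @export
aggregate_jump_pool <- function(study, runs = NULL, J = NULL) {
  if (inherits(study, "basin_study")) {
    runs <- study$config$runs
    J <- study$config$J
    jumps <- study$jumps
  } else {
    jumps <- study
    if (is.null(runs) || is.null(J)) {
      stop("`runs` and `J` are required when passing a raw jumps table",
           call. = FALSE)
    }
  }
  list(pool = as.integer(jumps$size),
       proportion = nrow(jumps) / (runs * J))
}

#' Network-wide descendant counts over pretrained networks
#'
#' For each of `networks` freshly pretrained networks (no target
#' presentations), builds the full transition map and computes the
#' descendant count of every state ([descendant_counts()]). Pooling the
#' counts of two or more across networks gives the network-wide branch
#' size distribution.
#'
#' @param networks Number of independent pretrained networks.
#' @param base_seed Base seed; network `r` uses `child_seed(base_seed, r)`.
#' @inheritParams run_presentation_experiment
#' @return Tibble with columns `network_id`, `state_index`, `count`.
#' @export
descendant_count_study <- function(networks = 100, n = 10,
                                   pretrain_count = 50,
                                   pretrain_multiplier = 10,
                                   base_seed = 1) {
  states <- enumerate_states(n)
  purrr::map_dfr(seq_len(networks), function(r) {
    set.seed(child_seed(base_seed, r))
    pre <- random_pattern_matrix(pretrain_count, n)
    W <- build_weight_matrix(pre, pretrain_multiplier)
    succ <- build_transition_map(W, states)
    cnt <- descendant_counts(succ)
    tibble::tibble(network_id = r, state_index = seq_along(cnt),
                   count = cnt)
  })
}
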