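# Membership of sampled states in the target basin under a low-rank
# Hebbian weight operator (patterns P, squared-multiplier weights w): a
# sampled state is in the basin iff it evolves to the target as a fixed
# point (limit cycles are non-members).
sampled_membership <- function(S, P, w, target, max_iters = 200) {
  ev <- evolve_batch_fun(function(X) lowrank_update(X, P, w), S, max_iters)
  ev$outcome == "fixed_point" &
    rowSums(ev$final != matrix(target, nrow(S), length(target),
                               byrow = TRUE)) == 0
}

#' Sampled-state basin accuracy in large networks
#'
#' For networks too large to enumerate, basin growth is tracked on fixed
#' random samples of initial states at chosen Hamming distances from the
#' target. The network is pretrained with `pretrain_count` random
#' patterns scaled by `pretrain_multiplier`; after each of `J` target
#' presentations the proportion of the `m` sampled states at each
#' distance `k` that converge to the target is recorded. The same sampled
#' states are reused across all presentations, so the curves are free of
#' resampling noise and change only when the basin boundary actually
#' moves.
#'
#' Defaults mirror the 100-neuron condition (one pretraining stimulus
#' scaled by 30, 500 presentations, distances 1-20); for a 1,000-neuron
#' network use `pretrain_multiplier = 100` and
#' `k_list = c(1, 2, 3, 5, 10, 20, 50, 100)`.
#'
#' @param n Neuron count.
#' @param k_list Hamming distances to sample.
#' @param m Sampled states per distance.
#' @param pretrain_count,pretrain_multiplier Pretraining condition.
#' @param J Number of target presentations.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Object of class `sampled_accuracy`: tibble with columns `k`,
#'   `j` (0..J) and `proportion`, plus a `config` attribute.
#' @export
sampled_accuracy_experiment <- function(n = 100,
                                        k_list = c(1, 2, 3, 5, 10, 20),
                                        m = 100, pretrain_count = 1,
                                        pretrain_multiplier = 30, J = 500,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pre <- random_pattern_matrix(pretrain_count, n)
  target <- random_pattern(n)
  S <- do.call(rbind, lapply(k_list, function(k) {
    sample_states_at_distance(target, k, m)
  }))
  k_of_row <- rep(k_list, each = m)
  P <- rbind(pre, matrix(target, nrow = 1))
  w_pre <- rep(pretrain_multiplier^2, pretrain_count)

  rows <- vector("list", J + 1)
  for (j in 0:J) {
    w <- c(w_pre, j)
    keep <- w > 0  # j = 0: target not yet stored
    member <- sampled_membership(S, P[keep, , drop = FALSE], w[keep], target)
    rows[[j + 1]] <- tibble::tibble(
      k = k_list, j = j,
      proportion = as.numeric(tapply(member, k_of_row, mean)[as.character(k_list)])
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$k, .data$j)
  attr(out, "config") <- list(n = n, k_list = k_list, m = m,
                              pretrain_count = pretrain_count,
                              pretrain_multiplier = pretrain_multiplier,
                              J = J, seed = seed)
  class(out) <- c("sampled_accuracy", class(out))
  out
}

#' Degradation / interference sweeps of jump-size variability
#'
#' Runs the sampled-basin protocol across conditions and summarises, per
#' run, the coefficient of variation (CV = sample sd / mean) of positive
#' jumps in the count of in-basin sampled states:
#'
#' * `"degradation"`: Hamming distance `k` of the probe states sweeps
#'   5, 10, 15, 20, 25 with a single pretraining stimulus (scaled by 20);
#' * `"interference"`: `k` fixed at 20 while the number of pretraining
#'   stimuli (each scaled by 20) sweeps 1-5.
#'
#' Each run presents the target `J = 300` times and counts, after every
#' presentation, how many of the `m = 100` frozen sampled states at the
#' run's distance lie in the target basin; a jump is any increase in this
#' count between consecutive presentations. Runs with fewer than two
#' positive jumps have an undefined CV and carry `NA`.
#'
#' @param sweep `"degradation"` or `"interference"`.
#' @param runs Runs per condition.
#' @param n Neuron count.
#' @param m Sampled states per run.
#' @param J Presentations per run.
#' @param pretrain_multiplier Scaling of each pretraining stimulus.
#' @param base_seed Base seed; condition `c`, run `r` uses a distinct
#'   deterministic child seed.
#' @return Object of class `condition_sweep`: tibble with columns
#'   `sweep`, `condition`, `run_id`, `n_jumps`, `cv`.
#' @export
run_condition_sweep <- function(sweep = c("degradation", "interference"),
                                runs = 100, n = 100, m = 100, J = 300,
                                pretrain_multiplier = 20, base_seed = 1) {
  sweep <- match.arg(sweep)
  conditions <- if (sweep == "degradation") c(5, 10, 15, 20, 25) else 1:5
  rows <- vector("list", length(conditions) * runs)
  i <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    k <- if (sweep == "degradation") cond else 20
    n_pre <- if (sweep == "degradation") 1 else cond
    for (r in seq_len(runs)) {
      set.seed(child_seed(base_seed, (ci - 1L) * runs + r))
      pre <- random_pattern_matrix(n_pre, n)
      target <- random_pattern(n)
      S <- sample_states_at_distance(target, k, m)
      P <- rbind(pre, matrix(target, nrow = 1))
      w_pre <- rep(pretrain_multiplier^2, n_pre)
      counts <- integer(J + 1)
      counts[1] <- sum(sampled_membership(S, P[seq_len(n_pre), , drop = FALSE],
                                          w_pre, target))
      for (j in seq_len(J)) {
        counts[j + 1] <- sum(sampled_membership(S, P, c(w_pre, j), target))
      }
      jumps <- diff(counts)
      jumps <- jumps[jumps > 0]
      cv <- if (length(jumps) >= 2) stats::sd(jumps) / mean(jumps) else NA_real_
      i <- i + 1L
      rows[[i]] <- tibble::tibble(sweep = sweep, condition = cond,
                                  run_id = r, n_jumps = length(jumps),
                                  cv = cv)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("condition_sweep", class(out))
  out
}

#' Welch's unequal-variance one-way ANOVA
#'
#' Tests whether group means differ without assuming equal variances,
#' via the Welch (1951) statistic with Satterthwaite-style denominator
#' degrees of freedom (computed by [stats::oneway.test()]). Used here to
#' test whether stimulus degradation (distance `k`) or memory
#' interference (pretraining count) shifts the per-run CV of jump sizes.
#'
#' @param groups A list of numeric vectors (one per group), or a
#'   `condition_sweep` tibble (groups are the conditions, values the
#'   non-missing CVs).
#' @return One-row tibble with `statistic` (F), `df1`, `df2`, `p.value`.
#' @examples
#' welch_anova(list(c(1, 2, 3, 4), c(2, 3, 4, 5), c(10, 11, 12, 13)))
#' @export
welch_anova <- function(groups) {
  if (inherits(groups, "condition_sweep") ||
      (is.data.frame(groups) && all(c("condition", "cv") %in% names(groups)))) {
    groups <- split(groups$cv[!is.na(groups$cv)],
                    groups$condition[!is.na(groups$cv)])
  }
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values",
                           call. = FALSE)
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("degenerate group: zero variance", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(y ~ g, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df1 = unname(ht$parameter[1]),
                 df2 = unname(ht$parameter[2]),
                 p.value = ht$p.value)
}
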