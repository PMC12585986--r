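test_that("zero-weight networks have a single all-states basin", {
  W0 <- matrix(0, 10, 10)
  states <- enumerate_states(10)
  # every state maps to all-(+1), which is fixed: basin is the whole space
  expect_length(target_basin(W0, rep(1, 10), states), 1024)
  # any other target is not a fixed point: empty basin
  expect_length(target_basin(W0, c(-1, rep(1, 9)), states), 0)
})

test_that("vectorized basin equals the per-state evolution oracle", {
  states <- enumerate_states(10)
  # single stored pattern, no pretraining
  set.seed(13)
  x <- random_pattern(10)
  W <- build_weight_matrix(x)
  expect_identical(sort(target_basin(W, x, states)),
                   sort(oracle_basin(W, x, states)))
  # pretrained network mid-way through the presentation protocol
  net <- make_network(seed = 31)
  W2 <- add_target_copies(net$W, net$target, 600)
  expect_identical(sort(target_basin(W2, net$target, states)),
                   sort(oracle_basin(W2, net$target, states)))
})

test_that("basins of distinct fixed points are disjoint", {
  states <- enumerate_states(10)
  for (seed in 1:5) {
    net <- make_network(seed = seed)
    succ <- build_transition_map(net$W, states)
    fixed <- which(succ == seq_len(1024))
    basins <- lapply(fixed, function(f) {
      which(basinjumps:::basin_membership(succ, f))
    })
    all_members <- unlist(basins)
    expect_equal(anyDuplicated(all_members), 0)
  }
})

test_that("jump extraction follows the positive-change definition", {
  j <- extract_jumps(c(3, 3, 5, 5, 4, 9))
  expect_equal(j$j, c(2, 5))
  expect_equal(j$size, c(2L, 5L))
  expect_equal(nrow(extract_jumps(rep(7, 10))), 0)
  expect_error(extract_jumps(5), "at least 2")

  # telescoping: jumps sum to at least the net growth, with equality iff
  # the trajectory never decreases
  set.seed(8)
  for (rep in 1:20) {
    sizes <- cumsum(sample(-2:5, 30, replace = TRUE))
    sizes <- pmax(sizes, 0)
    jl <- extract_jumps(sizes)
    expect_gte(sum(jl$size), sizes[length(sizes)] - sizes[1])
    if (all(diff(sizes) >= 0)) {
      expect_equal(sum(jl$size), sizes[length(sizes)] - sizes[1])
    }
  }
})

test_that("presentation runs track basins exactly and reproducibly", {
  run <- run_presentation_experiment(n = 10, pretrain_count = 50,
                                     pretrain_multiplier = 10, J = 40,
                                     seed = 99)
  expect_equal(nrow(run$trajectory), 41)  # j = 0..J
  expect_true(all(run$trajectory$basin_size >= 0 &
                    run$trajectory$basin_size <= 1024))
  run2 <- run_presentation_experiment(n = 10, pretrain_count = 50,
                                      pretrain_multiplier = 10, J = 40,
                                      seed = 99)
  expect_identical(run$trajectory, run2$trajectory)

  # with no pretraining and one presentation the basin is the single
  # stored-pattern basin
  run0 <- run_presentation_experiment(n = 10, pretrain_count = 0,
                                      pretrain_multiplier = 10, J = 1,
                                      seed = 55)
  set.seed(55)
  invisible(random_pattern_matrix(0, 10))
  target <- random_pattern(10)
  W1 <- build_weight_matrix(target)
  expect_equal(run0$trajectory$basin_size[2],
               length(target_basin(W1, target)))
})

test_that("jump sizes reconcile with gained and lost state sets", {
  # net jump size = |new states| - |lost states|; branch partitions cover
  # exactly the new states
  states <- enumerate_states(10)
  net <- make_network(seed = 77)
  W <- net$W
  TT <- tcrossprod(net$target)
  diag(TT) <- 0
  member_prev <- basinjumps:::basin_membership(
    build_transition_map(W, states), state_index(net$target))
  checked <- 0
  for (j in 1:700) {
    W <- W + TT
    succ <- build_transition_map(W, states)
    member <- basinjumps:::basin_membership(succ, state_index(net$target))
    delta <- sum(member) - sum(member_prev)
    if (delta > 0) {
      gained <- sum(member & !member_prev)
      lost <- sum(member_prev & !member)
      expect_equal(gained - lost, delta)
      br <- partition_branches(which(member & !member_prev), succ)
      expect_equal(sum(br$branch_size), gained)
      checked <- checked + 1
    }
    member_prev <- member
  }
  expect_gt(checked, 0)
})

test_that("basins grow on average over the presentation protocol", {
  study <- run_basin_study(runs = 20, J = 1000, base_seed = 5,
                           record_branches = FALSE)
  first <- dplyr::filter(study$trajectories, j == 0)
  last <- dplyr::filter(study$trajectories, j == 1000)
  expect_gt(mean(last$basin_size), mean(first$basin_size))
})
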