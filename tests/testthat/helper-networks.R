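# Shared fixture builders: small random networks and brute-force oracles
# used across test files. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# A pretrained small network plus a random target.
make_network <- function(n = 10, pretrain = 50, mult = 10, seed = 1) {
  set.seed(seed)
  pre <- random_pattern_matrix(pretrain, n)
  target <- random_pattern(n)
  list(W = build_weight_matrix(pre, mult), pre = pre, target = target, n = n)
}

# Brute-force basin oracle: evolve every state individually with evolve()
# and keep those that end at the target fixed point.
oracle_basin <- function(W, target, states) {
  hits <- integer(0)
  for (i in seq_len(nrow(states))) {
    ev <- evolve(W, states[i, ])
    if (ev$outcome == "fixed_point" && all(ev$final == target)) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Brute-force descendant-count oracle: for every state v, walk every
# state's forward orbit (with cycle detection) and count orbits visiting v.
oracle_descendant_counts <- function(succ) {
  N <- length(succ)
  visits <- matrix(FALSE, N, N)  # visits[u, v]: orbit of u reaches v
  for (u in seq_len(N)) {
    seen <- logical(N)
    cur <- u
    while (!seen[cur]) {
      seen[cur] <- TRUE
      cur <- succ[cur]
    }
    visits[u, ] <- seen
  }
  colSums(visits)
}
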