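# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: the multinomial oracle uses stats::dmultinom,
# matrix exponentials come from Matrix::expm, and tree likelihoods are
# exhaustive sums over internal-node state assignments.

# Exhaustive upper-tail trinomial probability: sum dmultinom over every
# (i, j) split with i >= k_min.
oracle_tail <- function(k_min, n, probs) {
  if (k_min > n) return(0)
  tot <- 0
  for (i in k_min:n) for (j in 0:(n - i))
    tot <- tot + stats::dmultinom(c(i, j, n - i - j), prob = probs)
  tot
}

# Independent matrix exponential.
oracle_expm <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# Exhaustive tree likelihood: sum over all assignments of states to
# internal nodes of prior(root) * prod over edges of P_e[parent, child].
# Tip states given as indices named by tip label.
oracle_tree_lik <- function(tree, tip_idx, Q, root_pr) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  ns <- nrow(Q)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nnode)))
  states <- integer(ntip + nnode)
  states[seq_len(ntip)] <- tip_idx[tree$tip.label]
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    states[ntip + seq_len(nnode)] <- grid[g, ]
    pr <- root_pr[states[ntip + 1L]]
    if (pr == 0) next
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][states[tree$edge[e, 1]], states[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  tot
}

# Marginal posterior P(state at node v | data) by the same exhaustive sum.
oracle_node_marginal <- function(tree, tip_idx, Q, root_pr, node) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  ns <- nrow(Q)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nnode)))
  states <- integer(ntip + nnode)
  states[seq_len(ntip)] <- tip_idx[tree$tip.label]
  marg <- numeric(ns)
  for (g in seq_len(nrow(grid))) {
    states[ntip + seq_len(nnode)] <- grid[g, ]
    pr <- root_pr[states[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][states[tree$edge[e, 1]], states[tree$edge[e, 2]]]
    marg[states[node]] <- marg[states[node]] + pr
  }
  marg / sum(marg)
}

# Marginal posterior of the state at relative position u along edge `e`
# (0 = rootward end), by splitting the edge at u and summing exhaustively
# over internal nodes and the inserted point.
oracle_point_marginal <- function(tree, tip_idx, Q, root_pr, e, u) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- nrow(Q)
  t_e <- tree$edge.length[e]
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  P1 <- oracle_expm(Q, u * t_e)
  P2 <- oracle_expm(Q, (1 - u) * t_e)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nnode)))
  states <- integer(ntip + nnode)
  states[seq_len(ntip)] <- tip_idx[tree$tip.label]
  marg <- numeric(ns)
  for (g in seq_len(nrow(grid))) {
    states[ntip + seq_len(nnode)] <- grid[g, ]
    base <- root_pr[states[ntip + 1L]]
    for (ee in seq_len(nrow(tree$edge)))
      if (ee != e)
        base <- base * P[[ee]][states[tree$edge[ee, 1]], states[tree$edge[ee, 2]]]
    a <- states[tree$edge[e, 1]]; b <- states[tree$edge[e, 2]]
    marg <- marg + base * P1[a, ] * P2[, b]
  }
  marg / sum(marg)
}

# A fixed small test tree and tip data on the default 8-state space.
fixture_4tip <- function() {
  tree <- read_newick("((A:0.4,B:0.6):0.5,(C:0.7,D:0.3):0.4);", text = TRUE)
  tips <- data.frame(taxon = c("A", "B", "C", "D"),
                     diploid_number = c(12L, 10L, 8L, 10L),
                     system = c("XY", "XY", "neoXY", "XY"))
  space <- karyo_states(6L, 12L)
  list(tree = tree, tips = tips, space = space,
       Q = karyo_rate_matrix(space, karyo_rates(0.6, 0.5, 0.5, 0.8)),
       root = list(type = "fixed", i = 12L, system = "XY"))
}

# Tip indices named by taxon for the oracle functions.
tip_indices <- function(tips, space) {
  stats::setNames(match(paste0(tips$diploid_number, "_", tips$system),
                        rownames(space)), tips$taxon)
}
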