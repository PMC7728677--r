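## Stochastic character maps of the karyotype chain: forward realizations
## and draws conditional on observed tip states. A map stores, for every
## edge of the tree, the ordered (state, duration) segments from the
## rootward end to the tipward end, plus the state at every node.

new_karyo_map <- function(tree, space, edge_maps, node_states) {
  structure(list(tree = tree, space = space, edge_maps = edge_maps,
                 node_states = node_states),
            class = "karyo_map")
}

#' @export
print.karyo_map <- function(x, ...) {
  ev <- map_events(x)
  cat(sprintf("Stochastic karyotype map: %d tips, %d events (%s)\n",
              length(x$tree$tip.label), nrow(ev),
              if (nrow(ev)) paste(names(table(ev$class)), table(ev$class),
                                  sep = ":", collapse = ", ") else "none"))
  invisible(x)
}

## Forward CTMC simulation along one branch from state `a` for time `t`.
## Returns list(states, durations); last state is the state at the child.
sim_branch_forward <- function(Q, a, t) {
  states <- integer(0); durs <- numeric(0)
  s <- a; rem <- t
  repeat {
    out <- -Q[s, s]
    if (out <= 0) { states <- c(states, s); durs <- c(durs, rem); break }
    w <- stats::rexp(1, out)
    if (w >= rem) { states <- c(states, s); durs <- c(durs, rem); break }
    states <- c(states, s); durs <- c(durs, w)
    rem <- rem - w
    rates <- Q[s, ]; rates[s] <- 0
    s <- sample.int(length(rates), 1L, prob = rates)
  }
  list(states = states, durations = durs)
}

#' Simulate a karyotype history forward along a tree
#'
#' Exact realization of the continuous-time karyotype chain down a rooted
#' tree: exponential waiting times and competing transitions, starting
#' from a given root state. Deterministic under a fixed seed.
#'
#' @param tree rooted `"phylo"` tree with branch lengths.
#' @param Q generator from [karyo_rate_matrix()].
#' @param space the matching [karyo_states()] space.
#' @param root_state root state as `list(i =, system =)` or a state label.
#' @param seed integer seed (optional; when `NULL` the current RNG stream
#'   is used).
#' @return a `"karyo_map"` object.
#' @export
sim_karyo_history <- function(tree, Q, space,
                              root_state = list(i = 12L, system = "XY"),
                              seed = NULL) {
  check_tree(tree)
  if (!is.null(seed)) set.seed(substream_seed(seed, "forward"))
  ridx <- if (is.character(root_state)) match(root_state, rownames(space))
          else state_index(space, root_state$i, root_state$system)
  if (is.na(ridx)) stop("root state outside the state space")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  node_states <- integer(nn)
  node_states[ntip + 1L] <- ridx
  edge_maps <- vector("list", nrow(tree$edge))
  ord <- rev(ape::postorder(tree))            # preorder over edges
  for (e in ord) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    seg <- sim_branch_forward(Q, node_states[par], tree$edge.length[e])
    edge_maps[[e]] <- seg
    node_states[chd] <- seg$states[length(seg$states)]
  }
  new_karyo_map(tree, space, edge_maps, node_states)
}

## ---- endpoint-conditioned path sampling (uniformization) ---------------

## Sample a path of the chain on [0, t] conditional on starting in `a` and
## ending in `b`, by embedding in a Poisson process with dominating rate
## Omega = max_i |Q_ii| and transition kernel R = I + Q/Omega. When
## Omega t = 0 the path is necessarily constant. `Pab` is the transition
## probability expm(Qt)[a, b], passed in to avoid recomputation.
sample_branch_conditional <- function(Q, a, b, t, Pab) {
  ns <- nrow(Q)
  Omega <- max(-diag(Q))
  if (Omega <= 0 || t == 0) {
    if (a != b) stop("internal error: distinct endpoints with zero dominating rate")
    return(list(states = a, durations = t))
  }
  if (Pab <= 0)
    stop("internal error: endpoint pair with zero transition probability")
  R <- diag(ns) + Q / Omega
  # sample the number of uniformized jumps N | endpoints
  Rpow <- list(diag(ns))                      # Rpow[[n+1]] = R^n
  u <- stats::runif(1) * Pab
  acc <- 0; n <- 0L
  nmax <- stats::qpois(1 - 1e-13, Omega * t) + ns + 10L
  repeat {
    acc <- acc + stats::dpois(n, Omega * t) * Rpow[[n + 1L]][a, b]
    if (acc >= u || n >= nmax) break
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  }
  if (n == 0L) return(list(states = a, durations = t))
  jumps <- sort(stats::runif(n)) * t
  states <- integer(n + 1L); states[1L] <- a; states[n + 1L] <- b
  if (n > 1L) for (k in 2:n) {
    w <- R[states[k - 1L], ] * Rpow[[n - k + 2L]][, b]   # R^(n-k+1) to reach b
    states[k] <- sample.int(ns, 1L, prob = w)
  }
  # merge virtual (self) jumps into segments
  bounds <- c(0, jumps, t)
  keep <- c(TRUE, states[-1L] != states[-(n + 1L)])
  segs <- states[keep]
  starts <- bounds[-length(bounds)][keep]
  durs <- diff(c(starts, t))
  list(states = segs, durations = durs)
}

## Sample node states from the pruning conditionals, root to tips.
sample_node_states <- function(tree, pruned, root_pr) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  node_states <- integer(nn)
  root <- ntip + 1L
  w <- root_pr * pruned$partial[root, ]
  node_states[root] <- sample.int(length(w), 1L, prob = w)
  for (e in rev(ape::postorder(tree))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    w <- pruned$P[[e]][node_states[par], ] * pruned$partial[chd, ]
    node_states[chd] <- sample.int(length(w), 1L, prob = w)
  }
  node_states
}

#' Draw stochastic maps conditional on observed tip states
#'
#' Samples full karyotype histories from their distribution given the tip
#' data: node states are drawn from the pruning conditionals from the
#' root towards the tips, then each branch path is drawn conditional on
#' its endpoint states by uniformization (a branch with zero dominating
#' rate is necessarily constant). Every returned map reproduces the
#' observed tip states exactly; the draw is deterministic under a fixed
#' seed.
#'
#' @inheritParams karyo_loglik
#' @param n_maps number of maps to draw.
#' @param seed integer seed.
#' @return an object of class `"karyo_maps"`: a list of `"karyo_map"`.
#' @export
karyo_simmap <- function(tree, tip_states, Q, space,
                         root = list(type = "fixed", i = 12L, system = "XY"),
                         n_maps = 100L, seed = 1L) {
  check_tree(tree)
  tip_states <- validate_tip_states(tip_states, space)
  tipL <- tip_partials(tree, tip_states, space)
  pr <- root_prior(root, space)
  dec <- ctmc_decompose(Q)
  pruned <- prune_tree(tree, tipL, dec, pr)
  if (!is.finite(pruned$loglik))
    stop("tip states have zero likelihood under this model; cannot draw maps")
  if (!is.null(seed)) set.seed(substream_seed(seed, "maps"))
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    ns_states <- sample_node_states(tree, pruned, pr)
    edge_maps <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      a <- ns_states[tree$edge[e, 1]]; b <- ns_states[tree$edge[e, 2]]
      edge_maps[[e]] <- sample_branch_conditional(
        Q, a, b, tree$edge.length[e], pruned$P[[e]][a, b])
    }
    maps[[m]] <- new_karyo_map(tree, space, edge_maps, ns_states)
  }
  structure(maps, class = "karyo_maps")
}

#' @export
print.karyo_maps <- function(x, ...) {
  cat(sprintf("%d stochastic karyotype maps on a %d-tip tree\n",
              length(x), length(x[[1]]$tree$tip.label)))
  invisible(x)
}

#' Draw stochastic maps from a fitted karyotype model
#'
#' The `simulate` method for [karyo_fit()] objects draws `nsim` stochastic
#' maps conditional on the data the model was fitted to, at the maximum
#' likelihood rates.
#'
#' @param object a `"karyo_fit"`.
#' @param nsim number of maps.
#' @param seed integer seed.
#' @param ... unused.
#' @return a `"karyo_maps"` list.
#' @export
simulate.karyo_fit <- function(object, nsim = 100L, seed = 1L, ...) {
  Q <- karyo_rate_matrix(object$space, object$rates)
  karyo_simmap(object$tree, object$tip_states, Q, object$space,
               root = object$root, n_maps = nsim, seed = seed)
}

#' Events recorded on a stochastic map
#'
#' @param map a `"karyo_map"`.
#' @return a data frame with one row per transition: `edge` (row of
#'   `tree$edge`), `time` (from the rootward end of the edge), `from`,
#'   `to` (state labels) and `class` (one of `AA_fusion`, `SA_fusion`,
#'   `fission`, `neoXY_decay`).
#' @export
map_events <- function(map) {
  out <- list()
  labs <- rownames(map$space)
  for (e in seq_along(map$edge_maps)) {
    seg <- map$edge_maps[[e]]
    k <- length(seg$states)
    if (k < 2L) next
    tcum <- cumsum(seg$durations)
    for (j in seq_len(k - 1L)) {
      cls <- transition_class(map$space, seg$states[j], seg$states[j + 1L])
      out[[length(out) + 1L]] <- data.frame(
        edge = e, time = tcum[j], from = labs[seg$states[j]],
        to = labs[seg$states[j + 1L]], class = cls)
    }
  }
  if (!length(out))
    return(data.frame(edge = integer(), time = numeric(), from = character(),
                      to = character(), class = character()))
  do.call(rbind, out)
}

#' Validate the internal consistency of a stochastic map
#'
#' Checks that segment durations on every branch sum to the branch length,
#' that consecutive segments differ by exactly one permitted transition,
#' and that segment endpoints agree with the recorded node states.
#'
#' @param map a `"karyo_map"`.
#' @param tol absolute tolerance on branch-length sums.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_karyo_map <- function(map, tol = 1e-9) {
  tree <- map$tree
  for (e in seq_along(map$edge_maps)) {
    seg <- map$edge_maps[[e]]
    if (abs(sum(seg$durations) - tree$edge.length[e]) > tol)
      stop(sprintf("map integrity: durations on edge %d sum to %.12g, branch length %.12g",
                   e, sum(seg$durations), tree$edge.length[e]))
    if (any(seg$durations < 0))
      stop(sprintf("map integrity: negative duration on edge %d", e))
    if (seg$states[1L] != map$node_states[tree$edge[e, 1]])
      stop(sprintf("map integrity: edge %d does not start in its parent state", e))
    if (seg$states[length(seg$states)] != map$node_states[tree$edge[e, 2]])
      stop(sprintf("map integrity: edge %d does not end in its child state", e))
    if (length(seg$states) > 1L)
      for (j in seq_len(length(seg$states) - 1L))
        if (is.na(transition_class(map$space, seg$states[j], seg$states[j + 1L])))
          stop(sprintf("map integrity: forbidden transition %s -> %s on edge %d",
                       rownames(map$space)[seg$states[j]],
                       rownames(map$space)[seg$states[j + 1L]], e))
  }
  invisible(TRUE)
}

#' Time-in-state and event-count summary of a stochastic map
#'
#' Extracts the proportion of total tree length spent in each karyotype
#' state and the number of events of each class, the quantities that feed
#' the clade-level comparison of observed versus expected SA-fusion
#' proportions.
#'
#' @param map a `"karyo_map"`.
#' @return an object of class `"karyo_map_summary"`: a list with
#'   `time_in_state` (named proportions summing to 1), `counts` (named
#'   event counts), `total_length` and `n_events`.
#' @export
summarize_map <- function(map) {
  ns <- nrow(map$space)
  occ <- numeric(ns)
  counts <- stats::setNames(integer(length(event_classes)), event_classes)
  for (e in seq_along(map$edge_maps)) {
    seg <- map$edge_maps[[e]]
    occ <- occ + as.numeric(
      tapply(seg$durations, factor(seg$states, levels = seq_len(ns)), sum,
             default = 0))
    k <- length(seg$states)
    if (k > 1L) for (j in seq_len(k - 1L)) {
      cls <- transition_class(map$space, seg$states[j], seg$states[j + 1L])
      if (is.na(cls))
        stop(sprintf("map integrity: forbidden transition on edge %d", e))
      counts[cls] <- counts[cls] + 1L
    }
  }
  total <- sum(map$tree$edge.length)
  structure(list(time_in_state = stats::setNames(occ / total, rownames(map$space)),
                 counts = counts, total_length = total,
                 n_events = sum(counts)),
            class = "karyo_map_summary")
}

#' @export
print.karyo_map_summary <- function(x, ...) {
  cat("Stochastic-map summary\n  time in state (proportion of tree length):\n")
  print(round(x$time_in_state, 4))
  cat("  event counts:\n")
  print(x$counts)
  invisible(x)
}

#' Marginal ancestral state probabilities at the nodes
#'
#' Standard two-pass (inside-outside) computation of the posterior
#' probability of each karyotype state at every node, conditional on the
#' tip data, the generator and the root condition. Useful as a
#' cross-check on stochastic maps: node-state frequencies across many
#' conditional maps converge to these marginals.
#'
#' @inheritParams karyo_loglik
#' @return a matrix (nodes x states) of posterior probabilities; rows are
#'   tips first (in `tree$tip.label` order) then internal nodes in `ape`
#'   numbering.
#' @export
node_marginals <- function(tree, tip_states, Q, space,
                           root = list(type = "fixed", i = 12L, system = "XY")) {
  check_tree(tree)
  tip_states <- validate_tip_states(tip_states, space)
  tipL <- tip_partials(tree, tip_states, space)
  pr <- root_prior(root, space)
  dec <- ctmc_decompose(Q)
  pruned <- prune_tree(tree, tipL, dec, pr)
  if (!is.finite(pruned$loglik)) stop("zero-likelihood data")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  # per-edge child contribution at the parent: w_e[a] = (P_e partial_child)[a]
  w <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.numeric(pruned$P[[e]] %*% pruned$partial[tree$edge[e, 2], ]))
  outside <- matrix(0, nn, ncol(tipL))
  outside[ntip + 1L, ] <- pr
  for (e in rev(ape::postorder(tree))) {          # preorder
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    sibs <- which(tree$edge[, 1] == par & seq_len(nrow(tree$edge)) != e)
    above <- outside[par, ]
    for (s in sibs) above <- above * w[[s]]
    outside[chd, ] <- as.numeric(above %*% pruned$P[[e]])
  }
  post <- outside * pruned$partial[seq_len(nn), ]
  post <- post / rowSums(post)
  dimnames(post) <- list(c(tree$tip.label, ntip + seq_len(tree$Nnode)),
                         rownames(space))
  post
}
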