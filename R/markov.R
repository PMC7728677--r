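#' State space for the karyotype Markov model
#'
#' A lineage carries a (male) diploid chromosome number `i` and either an
#' `XY` or a `neoXY` sex chromosome system. States are ordered by
#' ascending `i` with `XY` before `neoXY` at each diploid number, and
#' labelled `"<i>_XY"` / `"<i>_neoXY"`.
#'
#' @param min_i,max_i even diploid-number bounds (inclusive); `min_i >= 4`
#'   so that every state retains at least one autosome pair beside the sex
#'   chromosomes.
#' @return an object of class `"karyo_states"`: a data frame with columns
#'   `i` and `system` and row names equal to the state labels.
#' @examples
#' karyo_states(6, 12)   # the 8-state space used for fly-style analyses
#' @export
karyo_states <- function(min_i = 6L, max_i = 12L) {
  if (min_i %% 2L != 0L || max_i %% 2L != 0L)
    stop("diploid-number bounds must be even")
  if (min_i > max_i) stop("'min_i' must not exceed 'max_i'")
  if (min_i < 4L) stop("'min_i' must be at least 4 (one autosome pair plus sex chromosomes)")
  i <- rep(seq.int(min_i, max_i, by = 2L), each = 2L)
  system <- rep(c("XY", "neoXY"), length.out = length(i))
  out <- data.frame(i = as.integer(i), system = system)
  rownames(out) <- paste0(out$i, "_", out$system)
  class(out) <- c("karyo_states", "data.frame")
  attr(out, "bounds") <- c(min_i = as.integer(min_i), max_i = as.integer(max_i))
  out
}

state_index <- function(space, i, system) {
  idx <- match(paste0(i, "_", system), rownames(space))
  if (any(is.na(idx)))
    stop(sprintf("state (%s, %s) outside the state space",
                 paste(i[is.na(idx)], collapse = ","),
                 paste(system[is.na(idx)], collapse = ",")))
  idx
}

#' Rate parameters of the karyotype model
#'
#' The model has four transitions: `delta`, fusion of two autosomes
#' (diploid number drops by 2); `gamma`, fission of an autosome (diploid
#' number rises by 2); `sigma`, fusion of a sex chromosome and an autosome
#' (diploid number drops by 2 and the system becomes neoXY); and `rho`,
#' decay of a neoXY system back to a plain XY at unchanged diploid number.
#' All rates are events per unit branch length.
#'
#' @param delta,gamma,sigma,rho non-negative rates.
#' @return a named numeric vector of class `"karyo_rates"`.
#' @export
karyo_rates <- function(delta = 0, gamma = 0, sigma = 0, rho = 0) {
  r <- c(delta = delta, gamma = gamma, sigma = sigma, rho = rho)
  if (any(!is.finite(r)) || any(r < 0))
    stop("all rates must be finite and non-negative")
  structure(r, class = "karyo_rates")
}

#' Build the transition rate matrix of the karyotype model
#'
#' From an `XY` state at diploid number `i` a lineage can move to
#' `(i - 2, XY)` at rate `delta` (AA-fusion), to `(i + 2, XY)` at rate
#' `gamma` (fission), or to `(i - 2, neoXY)` at rate `sigma` (SA-fusion).
#' From a `neoXY` state it can move to `(i - 2, neoXY)` at rate `delta`,
#' to `(i + 2, neoXY)` at rate `gamma`, or to `(i, XY)` at rate `rho`.
#' A neoXY lineage cannot undergo a further SA-fusion before reverting.
#' Transitions that would leave the diploid-number bounds are simply
#' absent (reflecting boundaries by omission). Diagonal entries make each
#' row sum to zero.
#'
#' @param space a [karyo_states()] state space.
#' @param rates a [karyo_rates()] vector (or anything coercible).
#' @return a square rate matrix with state labels as dimnames.
#' @export
karyo_rate_matrix <- function(space, rates) {
  rates <- do.call(karyo_rates, as.list(unclass(rates)))
  ns <- nrow(space)
  Q <- matrix(0, ns, ns, dimnames = list(rownames(space), rownames(space)))
  b <- attr(space, "bounds")
  for (s in seq_len(ns)) {
    i <- space$i[s]; sys <- space$system[s]
    if (i - 2L >= b["min_i"])
      Q[s, state_index(space, i - 2L, sys)] <- rates["delta"]
    if (i + 2L <= b["max_i"])
      Q[s, state_index(space, i + 2L, sys)] <- rates["gamma"]
    if (sys == "XY" && i - 2L >= b["min_i"])
      Q[s, state_index(space, i - 2L, "neoXY")] <- rates["sigma"]
    if (sys == "neoXY")
      Q[s, state_index(space, i, "XY")] <- rates["rho"]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## Classify a single permitted transition by event type; NA for forbidden
## jumps (used to validate stochastic maps).
transition_class <- function(space, from, to) {
  di <- space$i[to] - space$i[from]
  fs <- space$system[from]; ts <- space$system[to]
  if (di == -2L && fs == ts) "AA_fusion"
  else if (di == -2L && fs == "XY" && ts == "neoXY") "SA_fusion"
  else if (di == 2L && fs == ts) "fission"
  else if (di == 0L && fs == "neoXY" && ts == "XY") "neoXY_decay"
  else NA_character_
}

event_classes <- c("AA_fusion", "SA_fusion", "fission", "neoXY_decay")

## ---- matrix exponential -------------------------------------------------
## Transition probabilities are needed thousands of times per likelihood
## optimization, so Q is decomposed once (eigendecomposition when well
## conditioned) and P(t) assembled per branch length. The fallback is
## scaling-and-squaring with a Taylor series, which is unconditionally
## stable for the small generators used here.

expm_taylor <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  k <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^k
  P <- diag(n); term <- diag(n)
  for (m in 1:40) {
    term <- term %*% As / m
    P <- P + term
    if (max(abs(term)) < 1e-18) break
  }
  for (j in seq_len(k)) P <- P %*% P
  P
}

ctmc_decompose <- function(Q) {
  dec <- list(Q = Q)
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ev)) {
    Vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      # accept the eigenroute only if it reproduces P(1) accurately
      P1 <- Re(ev$vectors %*% (exp(ev$values) * Vinv))
      if (max(abs(rowSums(P1) - 1)) < 1e-9 && min(P1) > -1e-9) {
        dec$values <- ev$values; dec$vectors <- ev$vectors; dec$vinv <- Vinv
      }
    }
  }
  dec
}

ctmc_transition <- function(dec, t) {
  n <- nrow(dec$Q)
  if (t == 0) return(diag(n))
  P <- if (!is.null(dec$values)) {
    Re(dec$vectors %*% (exp(dec$values * t) * dec$vinv))
  } else {
    expm_taylor(dec$Q * t)
  }
  if (!is.null(dec$values) &&
      (max(abs(rowSums(P) - 1)) > 1e-9 || min(P) < -1e-9))
    P <- expm_taylor(dec$Q * t)   # eigenroute degraded at this t
  rs <- rowSums(P)
  if (max(abs(rs - 1)) > 1e-6)
    stop("internal inconsistency: transition matrix rows do not sum to 1")
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(dec$Q)
  P
}

#' Transition probabilities of the karyotype chain over a branch
#'
#' Computes `expm(Q t)`, the matrix of state-to-state transition
#' probabilities over elapsed time `t`, by eigendecomposition with a
#' scaling-and-squaring Taylor fallback when the generator is defective or
#' ill conditioned. Rows sum to one within `1e-10`; negative entries at
#' rounding level are clipped to zero.
#'
#' @param Q a rate matrix from [karyo_rate_matrix()] (any generator works).
#' @param t branch length (non-negative).
#' @return a stochastic matrix of the same dimension as `Q`.
#' @export
transition_probs <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length 't' must be a single non-negative number")
  ctmc_transition(ctmc_decompose(Q), t)
}

## ---- pruning likelihood -------------------------------------------------

## Root specification: either list(type = "fixed", i =, system =) /
## "fixed" with a state label, or "flat" for a uniform prior, or a
## numeric prior vector over states.
root_prior <- function(root, space) {
  ns <- nrow(space)
  if (is.character(root) && length(root) == 1L && root == "flat")
    return(rep(1 / ns, ns))
  if (is.numeric(root)) {
    if (length(root) != ns || any(root < 0) || abs(sum(root) - 1) > 1e-8)
      stop("numeric root prior must be a probability vector over the state space")
    return(as.numeric(root))
  }
  if (is.list(root) && identical(root$type, "fixed")) {
    pr <- numeric(ns)
    pr[state_index(space, root$i, root$system)] <- 1
    return(pr)
  }
  if (is.character(root) && root %in% rownames(space)) {
    pr <- numeric(ns)
    pr[match(root, rownames(space))] <- 1
    return(pr)
  }
  stop("unrecognized root condition")
}

## Tip partial likelihood matrix (tips x states) from a tip-state table.
tip_partials <- function(tree, tip_states, space) {
  if (!all(tree$tip.label %in% tip_states$taxon))
    stop(sprintf("no karyotype state for tip(s): %s",
                 paste(setdiff(tree$tip.label, tip_states$taxon), collapse = ", ")))
  rowi <- match(tree$tip.label, tip_states$taxon)
  idx <- state_index(space, tip_states$diploid_number[rowi],
                     tip_states$system[rowi])
  L <- matrix(0, length(tree$tip.label), nrow(space))
  L[cbind(seq_along(idx), idx)] <- 1
  L
}

## Post-order pruning with per-node rescaling. Returns the per-node
## partial matrix (nodes x states), the log scaling factors, and the
## total log-likelihood under the given root condition.
prune_tree <- function(tree, tipL, dec, root_pr) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- ncol(tipL)
  partial <- matrix(0, ntip + nnode, ns)
  partial[seq_len(ntip), ] <- tipL
  logscale <- numeric(ntip + nnode)
  # per-edge transition matrices
  Pe <- lapply(tree$edge.length, function(t) ctmc_transition(dec, t))
  ord <- reorder(tree, "postorder")
  # walk edges in postorder, accumulating child contributions into parents;
  # map ord edges back to original edge indices to reuse Pe
  acc <- matrix(1, ntip + nnode, ns)
  eidx <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; chd <- ord$edge[e, 2]
    if (chd > ntip) {
      partial[chd, ] <- acc[chd, ]
      mx <- max(partial[chd, ])
      if (mx <= 0) return(list(loglik = -Inf))
      partial[chd, ] <- partial[chd, ] / mx
      logscale[chd] <- logscale[chd] + log(mx)
    }
    acc[par, ] <- acc[par, ] * as.numeric(Pe[[eidx[e]]] %*% partial[chd, ])
    logscale[par] <- logscale[par] + logscale[chd]
  }
  root <- ntip + 1L
  partial[root, ] <- acc[root, ]
  mx <- max(partial[root, ])
  if (mx <= 0) return(list(loglik = -Inf))
  partial[root, ] <- partial[root, ] / mx
  logscale[root] <- logscale[root] + log(mx)
  lik <- sum(root_pr * partial[root, ])
  list(loglik = if (lik > 0) log(lik) + logscale[root] else -Inf,
       partial = partial, logscale = logscale, P = Pe)
}

#' Pruning log-likelihood of tip karyotypes under the Markov model
#'
#' Standard post-order (pruning) computation of the probability of the
#' observed tip states on a rooted tree with branch lengths, under the
#' continuous-time karyotype chain with generator `Q`. With a fixed root
#' state the root partial for that state alone is used; with a prior the
#' partials are averaged under it.
#'
#' @param tree an `ape` "phylo" tree, rooted, with branch lengths.
#' @param tip_states data frame with columns `taxon`, `diploid_number`,
#'   `system` covering every tip.
#' @param Q generator from [karyo_rate_matrix()].
#' @param space the matching [karyo_states()] space.
#' @param root root condition: `list(type = "fixed", i =, system =)`, a
#'   state label, `"flat"`, or a prior vector over states.
#' @return the log-likelihood (may be `-Inf`).
#' @export
karyo_loglik <- function(tree, tip_states, Q, space,
                         root = list(type = "fixed", i = 12L, system = "XY")) {
  check_tree(tree)
  tipL <- tip_partials(tree, tip_states, space)
  pr <- root_prior(root, space)
  prune_tree(tree, tipL, ctmc_decompose(Q), pr)$loglik
}

#' Fit the karyotype model by maximum likelihood
#'
#' Estimates the four transition rates (AA-fusion `delta`, fission
#' `gamma`, SA-fusion `sigma`, neoXY decay `rho`) by maximizing the
#' pruning likelihood with box-constrained quasi-Newton search on log
#' rates, from several random starting points.
#'
#' @inheritParams karyo_loglik
#' @param include_rho if `FALSE`, `rho` is fixed at zero (no reversion of
#'   neoXY systems), mirroring the usual sensitivity analysis.
#' @param n_starts number of random multistart initial points.
#' @param seed integer seed controlling the starting points.
#' @param lower,upper box constraints on each rate.
#' @param reltol convergence tolerance passed to the optimizer.
#' @return an object of class `"karyo_fit"` with components `rates`
#'   (named vector), `loglik`, `tree`, `tip_states`, `space`, `root`,
#'   `starts` (per-start results) and `convergence`.
#' @examples
#' \donttest{
#' sim <- synthesize(n_tips = 60, rates = karyo_rates(0.5, 0.5, 0.4, 1),
#'                   seed = 1)
#' fit <- karyo_fit(sim$tree, sim$tip_states, seed = 1)
#' coef(fit)
#' }
#' @export
karyo_fit <- function(tree, tip_states, space = karyo_states(6L, 12L),
                      root = list(type = "fixed", i = 12L, system = "XY"),
                      include_rho = TRUE, n_starts = 3L, seed = 1L,
                      lower = 1e-8, upper = 100, reltol = 1e-10) {
  check_tree(tree)
  tip_states <- validate_tip_states(tip_states, space)
  tipL <- tip_partials(tree, tip_states, space)
  pr <- root_prior(root, space)
  free <- if (include_rho) c("delta", "gamma", "sigma", "rho")
          else c("delta", "gamma", "sigma")

  nll <- function(logr) {
    r <- karyo_rates()
    r[free] <- exp(logr)
    Q <- karyo_rate_matrix(space, r)
    ll <- prune_tree(tree, tipL, ctmc_decompose(Q), pr)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }

  set.seed(substream_seed(seed, "fit-starts"))
  inits <- c(list(rep(log(0.5), length(free))),
             lapply(seq_len(max(0L, n_starts - 1L)), function(i)
               log(stats::runif(length(free), 0.05, 2))))
  starts <- lapply(inits, function(x0) {
    stats::optim(x0, nll, method = "L-BFGS-B",
                 lower = rep(log(lower), length(free)),
                 upper = rep(log(upper), length(free)),
                 control = list(factr = reltol / .Machine$double.eps,
                                maxit = 500))
  })
  vals <- vapply(starts, function(s) s$value, numeric(1))
  if (all(vals >= 1e10))
    stop("rate optimization failed from every start; best value non-finite")
  best <- starts[[which.min(vals)]]
  init_nll <- vapply(inits, nll, numeric(1))
  if (min(vals) > min(init_nll) + 1e-6)
    stop("optimizer failed to improve on its initial points")
  rates <- karyo_rates()
  rates[free] <- exp(best$par)
  structure(list(rates = rates, loglik = -best$value, tree = tree,
                 tip_states = tip_states, space = space, root = root,
                 include_rho = include_rho,
                 convergence = best$convergence,
                 starts = data.frame(loglik = -vals,
                                     convergence = vapply(starts, function(s)
                                       s$convergence, numeric(1)))),
            class = "karyo_fit")
}

#' @export
print.karyo_fit <- function(x, ...) {
  cat("Karyotype-evolution model fit (maximum likelihood)\n")
  cat(sprintf("  %d tips, %d states (diploid %d-%d), root %s\n",
              length(x$tree$tip.label), nrow(x$space),
              attr(x$space, "bounds")[1], attr(x$space, "bounds")[2],
              if (is.list(x$root)) sprintf("fixed at (%s, %s)", x$root$i, x$root$system)
              else paste(x$root, collapse = " ")))
  cat("  rates (events per unit branch length):\n")
  print(round(unclass(x$rates), 5))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.karyo_fit <- function(object, ...) unclass(object$rates)

#' @export
logLik.karyo_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$include_rho) 4L else 3L,
            class = "logLik")
}

#' @export
summary.karyo_fit <- function(object, ...) {
  Q <- karyo_rate_matrix(object$space, object$rates)
  tl <- sum(object$tree$edge.length)
  out <- list(fit = object, Q = Q, tree_length = tl,
              expected_events = unclass(object$rates) * tl)
  class(out) <- "summary.karyo_fit"
  out
}

#' @export
print.summary.karyo_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  total tree length: %.4f\n", x$tree_length))
  cat("  crude expected event counts (rate x total length):\n")
  print(round(x$expected_events, 2))
  invisible(x)
}
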