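#' Simulate a pure-birth (Yule) tree
#'
#' Ultrametric rooted trees for synthetic karyotype datasets. Only the
#' shape and amount of branch length matter to the downstream pipeline,
#' so a parameter-light pure-birth process suffices; the tree can be
#' rescaled to a fixed depth so that rates are expressed per tree depth.
#'
#' @param n_tips number of tips (at least 2).
#' @param birth_rate per-lineage speciation rate.
#' @param seed integer seed; the same seed always yields the same tree.
#' @param scale_depth if non-`NULL`, rescale all branch lengths so the
#'   root-to-tip depth equals this value.
#' @return an ultrametric `"phylo"` tree with tips `t1..tn`.
#' @examples
#' tr <- yule_tree(10, seed = 42)
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed = 1L, scale_depth = NULL) {
  if (n_tips < 2L) stop("'n_tips' must be at least 2")
  if (birth_rate <= 0) stop("'birth_rate' must be positive")
  if (!is.null(seed)) set.seed(substream_seed(seed, "tree"))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  if (!is.null(scale_depth)) {
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * scale_depth / depth
  }
  tr
}

#' Generate a synthetic karyotype dataset with known ground truth
#'
#' Composes [yule_tree()] and [sim_karyo_history()]: simulates a tree,
#' runs the karyotype chain forward along it from the root state, and
#' returns the tree, the generating rates, the full true history and the
#' resulting tip-state table. The defaults emulate a fly-style dataset:
#' 120 tips, unit depth, diploid numbers bounded in 6-12, root at
#' (12, XY).
#'
#' @param n_tips number of tips.
#' @param rates generating [karyo_rates()].
#' @param space state space bounds via [karyo_states()].
#' @param root_state root state, `list(i =, system =)`.
#' @param birth_rate,scale_depth passed to [yule_tree()].
#' @param seed top-level integer seed; tree and history use distinct
#'   substreams derived from it.
#' @return an object of class `"karyo_synth"`: a list with `tree`,
#'   `true_rates`, `true_history` (a `"karyo_map"`), `tip_states`, and
#'   `seed`.
#' @examples
#' sim <- synthesize(n_tips = 20, rates = karyo_rates(0.5, 0.5, 0.4, 1),
#'                   seed = 7)
#' table(sim$tip_states$system)
#' @export
synthesize <- function(n_tips = 120L, rates = karyo_rates(0.5, 0.5, 0.4, 1),
                       space = karyo_states(6L, 12L),
                       root_state = list(i = 12L, system = "XY"),
                       birth_rate = 1, scale_depth = 1, seed = 1L) {
  tr <- yule_tree(n_tips, birth_rate = birth_rate, seed = seed,
                  scale_depth = scale_depth)
  Q <- karyo_rate_matrix(space, rates)
  hist <- sim_karyo_history(tr, Q, space, root_state = root_state,
                            seed = substream_seed(seed, "history"))
  tips <- data.frame(
    taxon = tr$tip.label,
    diploid_number = space$i[hist$node_states[seq_len(n_tips)]],
    system = space$system[hist$node_states[seq_len(n_tips)]])
  structure(list(tree = tr, true_rates = rates, true_history = hist,
                 tip_states = tips, space = space, seed = seed),
            class = "karyo_synth")
}

#' @export
print.karyo_synth <- function(x, ...) {
  ev <- map_events(x$true_history)
  cat(sprintf("Synthetic karyotype dataset: %d tips, rates (d=%g, g=%g, s=%g, r=%g)\n",
              length(x$tree$tip.label), x$true_rates["delta"],
              x$true_rates["gamma"], x$true_rates["sigma"], x$true_rates["rho"]))
  cat(sprintf("  true history: %d events; tip systems: %s\n", nrow(ev),
              paste(names(table(x$tip_states$system)),
                    table(x$tip_states$system), sep = ":", collapse = ", ")))
  invisible(x)
}
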