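## Small shared validators and the seed-substream helper.

## Derive a deterministic 31-bit sub-seed from a top-level seed and a
## stream name, so every source of randomness (tree, history, maps,
## optimizer starts) gets its own reproducible stream.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be an ape \"phylo\" object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; the model is time-dependent and unit lengths are not assumed")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate tip label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  invisible(tree)
}

## Normalize and validate a tip-state table; `space` (optional) restricts
## states to the configured bounds.
validate_tip_states <- function(tab, space = NULL) {
  need <- c("taxon", "diploid_number", "system")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("tip-state table lacks column(s): %s", paste(miss, collapse = ", ")))
  tab <- as.data.frame(tab)
  tab$taxon <- as.character(tab$taxon)
  if (anyDuplicated(tab$taxon))
    stop("tip-state table has duplicated taxa")
  sys <- tolower(as.character(tab$system))
  bad <- !(sys %in% c("xy", "neoxy"))
  if (any(bad))
    stop(sprintf("unknown sex chromosome system in row(s) %s: %s (expected XY or neoXY)",
                 paste(which(bad), collapse = ", "),
                 paste(unique(tab$system[bad]), collapse = ", ")))
  tab$system <- ifelse(sys == "xy", "XY", "neoXY")
  dn <- tab$diploid_number
  if (any(!is.finite(dn)) || any(dn != round(dn)) || any(dn %% 2 != 0))
    stop(sprintf("diploid_number must be an even integer; offending row(s): %s",
                 paste(which(!is.finite(dn) | dn != round(dn) | dn %% 2 != 0),
                       collapse = ", ")))
  tab$diploid_number <- as.integer(dn)
  if (!is.null(space)) {
    idx <- match(paste0(tab$diploid_number, "_", tab$system), rownames(space))
    if (any(is.na(idx)))
      stop(sprintf("tip state(s) outside the state space: %s",
                   paste(tab$taxon[is.na(idx)], collapse = ", ")))
  }
  tab
}
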