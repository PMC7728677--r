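#' Read a rooted tree with branch lengths from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the requirements of
#' the karyotype pipeline: the tree must parse, be rooted, carry branch
#' lengths on every edge, and have unique tip labels. Polytomies are
#' preserved.
#'
#' @param path path to a Newick file (or a Newick string when
#'   `text = TRUE`).
#' @param text treat `path` as Newick text rather than a file name.
#' @return a `"phylo"` tree.
#' @export
read_newick <- function(path, text = FALSE) {
  tr <- tryCatch(
    if (text) ape::read.tree(text = path) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop(sprintf("malformed Newick in '%s'", if (text) "<text>" else path))
  check_tree(tr)
  tr
}

#' Write a tree to a Newick file
#' @param tree a `"phylo"` tree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tip karyotype-state table
#'
#' Reads a CSV with exactly the columns `taxon`, `diploid_number`,
#' `system` (one row per taxon). System labels are matched
#' case-insensitively against `XY` and `neoXY` and normalized; diploid
#' numbers must be even integers. Mismatches are reported by row.
#'
#' @param path CSV path.
#' @param space optional [karyo_states()] space; when given, every state
#'   must fall inside it.
#' @return a validated data frame.
#' @export
read_tip_states <- function(path, space = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tip_states(tab, space)
}

#' @rdname read_tip_states
#' @param tab a tip-state data frame.
#' @export
write_tip_states <- function(tab, path) {
  utils::write.csv(tab[, c("taxon", "diploid_number", "system")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- stochastic-map serialization ---------------------------------------

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

## Newick with per-edge segment annotations `{state,dur:state,dur}`
## (rootward to tipward), in the style long used for stochastic character
## maps. Internal nodes receive generated labels so the text form can be
## read back losslessly.
map_label_nodes <- function(tree) {
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- paste0("nd", seq_len(tree$Nnode))
  tree
}

#' Serialize a stochastic map to annotated-Newick text
#'
#' Writes a `"karyo_map"` as a Newick string whose branch lengths are
#' replaced by `{state,duration:...}` segment lists ordered from the
#' rootward end of each branch, with internal node labels added so the
#' map can be read back. [read_karyo_map()] inverts it; a lossless JSON
#' form is available via `format = "json"` in [write_karyo_map()].
#'
#' @param map a `"karyo_map"`.
#' @return a single character string.
#' @export
format_karyo_map <- function(map) {
  tree <- map_label_nodes(map$tree)
  ntip <- length(tree$tip.label)
  labs <- rownames(map$space)
  node_name <- function(v)
    if (v <= ntip) tree$tip.label[v] else tree$node.label[v - ntip]
  ann <- function(e) {
    seg <- map$edge_maps[[e]]
    paste0("{", paste(labs[seg$states], fmt_num(seg$durations),
                      sep = ",", collapse = ":"), "}")
  }
  build <- function(v) {
    kids <- which(tree$edge[, 1] == v)
    core <- if (!length(kids)) node_name(v)
    else paste0("(", paste(vapply(kids, function(e)
      paste0(build(tree$edge[e, 2]), ":", ann(e)), character(1)),
      collapse = ","), ")", node_name(v))
    core
  }
  paste0(build(ntip + 1L), ";")
}

#' Write a stochastic map to a file
#'
#' @param map a `"karyo_map"`.
#' @param path output path.
#' @param format `"simmap"` for the annotated-Newick dialect or `"json"`
#'   for a lossless JSON form; both round-trip through
#'   [read_karyo_map()].
#' @return the path, invisibly.
#' @export
write_karyo_map <- function(map, path, format = c("simmap", "json")) {
  format <- match.arg(format)
  if (format == "simmap") {
    writeLines(format_karyo_map(map), path)
  } else {
    tree <- map_label_nodes(map$tree)
    ntip <- length(tree$tip.label)
    labs <- rownames(map$space)
    node_name <- c(tree$tip.label, tree$node.label)
    edges <- stats::setNames(lapply(seq_len(nrow(tree$edge)), function(e)
      list(states = labs[map$edge_maps[[e]]$states],
           durations = map$edge_maps[[e]]$durations)),
      node_name[tree$edge[, 2]])
    obj <- list(newick = ape::write.tree(tree),
                bounds = as.list(attr(map$space, "bounds")),
                edges = edges,
                node_states = stats::setNames(as.list(labs[map$node_states]),
                                              node_name))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Read a stochastic map written by [write_karyo_map()]
#'
#' @param path input path.
#' @param format `"simmap"` or `"json"`.
#' @return a `"karyo_map"`.
#' @export
read_karyo_map <- function(path, format = c("simmap", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tree <- read_newick(obj$newick, text = TRUE)
    space <- karyo_states(obj$bounds$min_i, obj$bounds$max_i)
    return(map_from_named_edges(tree, space, obj$edges))
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_simmap_text(txt, path)
}

## One annotated-Newick map string -> karyo_map.
parse_simmap_text <- function(txt, path = "<text>") {
  m <- gregexpr("([^(),:{}]+):\\{([^{}]*)\\}", txt)[[1]]
  if (m[1] == -1) stop(sprintf("no segment annotations found in '%s'", path))
  pieces <- regmatches(txt, gregexpr("([^(),:{}]+):\\{([^{}]*)\\}", txt))[[1]]
  seg_by_label <- list()
  plain <- txt
  for (p in pieces) {
    lab <- sub(":\\{.*$", "", p)
    body <- sub("^.*:\\{", "", sub("\\}$", "", p))
    parts <- strsplit(strsplit(body, ":", fixed = TRUE)[[1]], ",", fixed = TRUE)
    seg_by_label[[lab]] <- list(
      states = vapply(parts, `[`, character(1), 1L),
      durations = as.numeric(vapply(parts, `[`, character(1), 2L)))
    plain <- sub(p, paste0(lab, ":", fmt_num(sum(seg_by_label[[lab]]$durations))),
                 plain, fixed = TRUE)
  }
  tree <- read_newick(plain, text = TRUE)
  all_i <- as.integer(sub("_.*$", "", unlist(lapply(seg_by_label, `[[`, "states"))))
  space <- karyo_states(min(all_i), max(all_i))
  map_from_named_edges(tree, space, seg_by_label)
}

#' Read a multi-map file (one annotated Newick per line)
#'
#' @param path file with one [format_karyo_map()] string per line.
#' @return a `"karyo_maps"` list.
#' @export
read_karyo_maps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  structure(lapply(lines, parse_simmap_text, path = path), class = "karyo_maps")
}

#' @rdname read_karyo_maps
#' @param maps a `"karyo_maps"` list.
#' @export
write_karyo_maps <- function(maps, path) {
  writeLines(vapply(maps, format_karyo_map, character(1)), path)
  invisible(path)
}

## Rebuild a karyo_map from per-child-label segment lists.
map_from_named_edges <- function(tree, space, edges) {
  ntip <- length(tree$tip.label)
  node_name <- c(tree$tip.label,
                 if (!is.null(tree$node.label)) tree$node.label
                 else paste0("nd", seq_len(tree$Nnode)))
  edge_maps <- vector("list", nrow(tree$edge))
  node_states <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    lab <- node_name[tree$edge[e, 2]]
    seg <- edges[[lab]]
    if (is.null(seg)) stop(sprintf("no segments for node '%s'", lab))
    idx <- match(seg$states, rownames(space))
    if (any(is.na(idx)))
      stop(sprintf("unknown state label(s) in segments of '%s'", lab))
    edge_maps[[e]] <- list(states = idx, durations = as.numeric(seg$durations))
    node_states[tree$edge[e, 2]] <- idx[length(idx)]
  }
  root_edge <- which(tree$edge[, 1] == ntip + 1L)[1]
  node_states[ntip + 1L] <- edge_maps[[root_edge]]$states[1]
  new_karyo_map(tree, space, edge_maps, node_states)
}

## ---- reports -------------------------------------------------------------

report_to_list <- function(x) {
  if (inherits(x, "fusion_probs")) {
    k <- attr(x, "karyotype")
    list(kind = "fusion_probabilities",
         p_sa = x[["p_sa"]], p_aa = x[["p_aa"]], p_ss = x[["p_ss"]],
         karyotype = list(Da = k$Da, Xs = k$Xs, Y = k$Y, system = k$system),
         mu = attr(x, "mu"))
  } else if (inherits(x, "sa_fusion_test")) {
    list(kind = "sa_fusion_test", p_value = x$p_value, tail = x$tail,
         counts = as.list(x$counts), n = x$n, k_min = x$k_min,
         null_probs = as.list(x$null_probs), mu = x$mu,
         karyotype = list(Da = x$karyotype$Da, Xs = x$karyotype$Xs,
                          Y = x$karyotype$Y, system = x$karyotype$system))
  } else if (inherits(x, "clade_report")) {
    list(kind = "clade_report", expected = x$expected, observed = x$observed,
         mean_sa_count = x$mean_sa_count, overlap = x$overlap,
         n_maps = x$n_maps, n_observed_used = x$n_observed_used,
         n_excluded = x$n_excluded, level = x$level, mu = x$mu)
  } else if (inherits(x, "sa_tail")) {
    list(kind = "sa_tail", p_value = x$p_value, n = x$n, k_min = x$k_min,
         null_probs = as.list(x$null_probs))
  } else if (is.list(x)) {
    x
  } else stop("unsupported report object")
}

#' Write an analysis report to JSON or TSV
#'
#' Serializes the package's result objects (fusion probabilities, exact
#' test results, clade reports) to a machine-readable file. Any
#' `config` attribute on the object (the effective run configuration,
#' attached by the command-line interface) is included for provenance.
#' JSON output preserves full double precision and round-trips
#' bit-for-bit through [jsonlite::read_json()].
#'
#' @param x a result object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  obj <- report_to_list(x)
  if (!is.null(attr(x, "config"))) obj$config <- attr(x, "config")
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
  } else {
    flat <- unlist(obj)
    writeLines(paste(names(flat), as.character(flat), sep = "\t"), path)
  }
  invisible(path)
}
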