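# internal helpers: conditions, label handling, tree traversal

pf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "paleofit_error", "error", "condition")))
}
pf_parse_error <- function(msg) pf_stop(msg, "paleofit_parse_error")
pf_input_error <- function(msg) pf_stop(msg, "paleofit_input_error")
pf_reconcile_error <- function(msg) pf_stop(msg, "paleofit_reconcile_error")
pf_degenerate_error <- function(msg) pf_stop(msg, "paleofit_degenerate_error")

#' Normalize a taxon label
#'
#' Trims surrounding whitespace and replaces internal whitespace with
#' underscores, so that `"A b"` and `"A_b"` refer to the same taxon (the
#' usual Newick convention).
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_label <- function(x) gsub("[ \t]+", "_", trimws(as.character(x)))

# number of nodes (tips + internals) of a phylo
.n_nodes <- function(tree) length(tree$tip.label) + tree$Nnode

.root_node <- function(tree) length(tree$tip.label) + 1L

# children of every node, in input order; list indexed by node number
.children <- function(tree) {
  nn <- .n_nodes(tree)
  out <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    out[[p]] <- c(out[[p]], tree$edge[i, 2L])
  }
  out
}

# parent of every node (0 for root)
.parents <- function(tree) {
  par <- integer(.n_nodes(tree))
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# edge matrix in postorder (children before parents)
.postorder_edges <- function(tree) ape::reorder.phylo(tree, "postorder")$edge

# display names for all nodes: tip labels, then "node<N>" for internals
.node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  c(tree$tip.label, paste0("node", (ntip + 1L):.n_nodes(tree)))
}

.assert_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) {
    pf_input_error("expected a 'phylo' tree (see parse_newick())")
  }
  invisible(tree)
}
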