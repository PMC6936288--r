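#' Minimum node ages implied by first appearances
#'
#' Every tip is dated by its first-appearance datum (FAD); every internal
#' node by the oldest FAD among its descendant tips. Ages therefore never
#' decrease from child to parent, and the root carries the oldest FAD
#' overall. Ages are in Ma (larger = older).
#'
#' @param tree a rooted `phylo` (polytomies allowed).
#' @param table an `occurrence_table` covering every tip.
#' @return a named numeric vector of ages over all nodes (tips first, then
#'   internal nodes named `node<N>`).
#' @export
node_min_ages <- function(tree, table) {
  .assert_phylo(tree)
  tips <- normalize_label(tree$tip.label)
  fad <- stats::setNames(table$fad_ma, normalize_label(table$taxon))
  miss <- setdiff(tips, names(fad))
  if (length(miss)) {
    pf_input_error(paste0("no FAD for tip(s): ", paste(miss, collapse = ", ")))
  }
  nn <- .n_nodes(tree)
  ntip <- length(tips)
  age <- c(unname(fad[tips]), rep(-Inf, nn - ntip))
  po <- .postorder_edges(tree)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    if (age[ch] > age[p]) age[p] <- age[ch]
  }
  stats::setNames(age, .node_names(tree))
}

#' Minimum implied gap (summed ghost lineages)
#'
#' The ghost lineage on the branch to a node is the difference between its
#' parent's minimum age and its own: the span during which the lineage must
#' have existed without fossil record, forced by the earlier appearance of
#' relatives. The minimum implied gap (MIG) of a topology is the sum of
#' these branch gaps. Polytomies are treated as hard: each child is dated
#' against the polytomous parent's age (see [resolve_polytomy_min_mig()] for
#' the soft option).
#'
#' @inheritParams node_min_ages
#' @return a list with `mig` (Myr) and `branch_gaps`, a named vector of
#'   per-branch ghost durations keyed by child node.
#' @export
minimum_implied_gap <- function(tree, table) {
  age <- node_min_ages(tree, table)
  par <- .parents(tree)
  nn <- .n_nodes(tree)
  non_root <- setdiff(seq_len(nn), .root_node(tree))
  gaps <- age[par[non_root]] - age[non_root]
  names(gaps) <- .node_names(tree)[non_root]
  list(mig = sum(gaps), branch_gaps = gaps)
}

#' Theoretical minimum gap for a set of first appearances
#'
#' The smallest MIG any topology can achieve for a fixed set of FADs: the
#' difference between the oldest and the youngest FAD, attained by a
#' pectinate tree with taxa ordered oldest-outermost.
#'
#' @param table an `occurrence_table` with at least 2 taxa.
#' @return the minimum gap, in Myr.
#' @export
g_min <- function(table) {
  fad <- table$fad_ma
  if (length(fad) < 2L) pf_input_error("g_min needs at least 2 taxa")
  max(fad) - min(fad)
}

#' Maximum gap for a set of first appearances
#'
#' The summed differences between the origination time of the oldest taxon
#' and that of every other taxon; taxa tied with the oldest contribute 0.
#'
#' @inheritParams g_min
#' @return the maximum gap, in Myr.
#' @export
g_max <- function(table) {
  fad <- table$fad_ma
  if (length(fad) < 2L) pf_input_error("g_max needs at least 2 taxa")
  sum(max(fad) - fad)
}

#' Gap excess ratio of a topology against first appearances
#'
#' GER = 1 - (MIG - Gmin) / (Gmax - Gmin). A GER of 1 indicates the best
#' possible fit between topology and stratigraphic occurrence; a GER of 0
#' the least congruent arrangement (the oldest taxon maximally nested).
#' The occurrence table is restricted to the tree's tips; every tip must be
#' covered (run [reconcile()] first otherwise). Degenerate stratigraphy
#' (fewer than two distinct FADs, so Gmax = Gmin) is an explicit error
#' rather than a NaN.
#'
#' @inheritParams node_min_ages
#' @return an object of class `ger_result` with fields `mig`, `g_min`,
#'   `g_max`, `ger`, `branch_gaps`, `node_ages`, `n_taxa`.
#' @examples
#' tr <- parse_newick("(A,(B,(C,D)));")
#' occ <- occurrence_table(c("A", "B", "C", "D"), c(10, 8, 5, 2))
#' gap_excess_ratio(tr, occ)$ger  # 1: perfectly congruent ladder
#' @export
gap_excess_ratio <- function(tree, table) {
  .assert_phylo(tree)
  tips <- normalize_label(tree$tip.label)
  tab <- table[normalize_label(table$taxon) %in% tips, , drop = FALSE]
  mig <- minimum_implied_gap(tree, tab)
  gmin <- g_min(tab)
  gmax <- g_max(tab)
  if (gmax - gmin <= 1e-12) {
    pf_degenerate_error("degenerate stratigraphy: Gmax equals Gmin (fewer than 2 distinct FADs)")
  }
  ger <- 1 - (mig$mig - gmin) / (gmax - gmin)
  ger <- min(max(ger, 0), 1)  # guard float dust at the closed endpoints
  structure(list(mig = mig$mig, g_min = gmin, g_max = gmax, ger = ger,
                 branch_gaps = mig$branch_gaps,
                 node_ages = node_min_ages(tree, tab),
                 n_taxa = length(tips)),
            class = "ger_result")
}

#' @export
print.ger_result <- function(x, ...) {
  cat(sprintf("Gap excess ratio over %d taxa\n", x$n_taxa))
  cat(sprintf("  MIG  = %.2f Myr\n  Gmin = %.2f Myr\n  Gmax = %.2f Myr\n  GER  = %.4f\n",
              x$mig, x$g_min, x$g_max, x$ger))
  invisible(x)
}

#' Compare the stratigraphic fit of competing topologies
#'
#' For each tree: prunes to the taxa shared with the table (and the optional
#' `scope` subset), computes MIG, Gmin, Gmax and GER on the tree's own
#' surviving taxon set, and tabulates. Because Gmin/Gmax are per-tree, rows
#' with different `n_taxa` are not directly comparable; the taxon count is
#' reported so they are not naively compared.
#'
#' @param trees a `multiPhylo` or (named) list of `phylo` objects.
#' @param table an `occurrence_table`.
#' @param scope optional character vector restricting the analysis to a
#'   taxon subset.
#' @return a `data.frame` (class `ger_comparison`), one row per tree with
#'   columns `tree`, `n_taxa`, `mig`, `g_min`, `g_max`, `ger`, `best`,
#'   sorted by GER descending; the highest-GER tree(s) are flagged.
#' @export
compare_topologies <- function(trees, table, scope = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) pf_input_error("no trees supplied")
  nms <- names(trees)
  if (is.null(nms) || any(!nzchar(nms))) nms <- paste0("tree", seq_along(trees))
  tab <- table
  if (!is.null(scope)) {
    tab <- tab[normalize_label(tab$taxon) %in% normalize_label(scope), , drop = FALSE]
    if (!nrow(tab)) pf_reconcile_error("scope shares no taxa with the occurrence table")
  }
  rows <- lapply(seq_along(trees), function(i) {
    rec <- reconcile(trees[[i]], tab, mode = "prune")
    g <- gap_excess_ratio(rec$tree, rec$table)
    data.frame(tree = nms[i], n_taxa = g$n_taxa, mig = g$mig,
               g_min = g$g_min, g_max = g$g_max, ger = g$ger,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ger, out$tree), , drop = FALSE]
  out$best <- out$ger >= max(out$ger) - 1e-12
  rownames(out) <- NULL
  class(out) <- c("ger_comparison", "data.frame")
  out
}

#' Resolve polytomies to minimize the implied gap
#'
#' Treats polytomies as soft (unresolved rather than simultaneous
#' divergence): each polytomy is replaced by the pectinate arrangement of
#' its child subtrees ordered by descending subtree age, oldest outermost,
#' which attains the minimum MIG over all binary resolutions. Ties among
#' subtree ages are broken by the lexicographically smallest tip label, for
#' determinism. The returned tree's MIG never exceeds the input tree's.
#'
#' @inheritParams node_min_ages
#' @return a binary `phylo`.
#' @export
resolve_polytomy_min_mig <- function(tree, table) {
  age <- node_min_ages(tree, table)
  kids <- .children(tree)
  ntip <- length(tree$tip.label)
  # lexicographically smallest descendant tip label, per node (tie-breaks)
  minlab <- character(.n_nodes(tree))
  minlab[seq_len(ntip)] <- tree$tip.label
  po <- .postorder_edges(tree)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    if (!nzchar(minlab[p]) || minlab[ch] < minlab[p]) minlab[p] <- minlab[ch]
  }
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    ch <- kids[[v]]
    ch <- ch[order(-age[ch], minlab[ch])]
    parts <- vapply(ch, build, "")
    while (length(parts) > 1L) {
      n <- length(parts)
      parts <- c(parts[seq_len(n - 2L)],
                 paste0("(", parts[n - 1L], ",", parts[n], ")"))
    }
    parts
  }
  parse_newick(paste0(build(.root_node(tree)), ";"))
}
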