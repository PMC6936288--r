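#' Indicator area distributions at the tips
#'
#' Each terminal taxon is restricted to a single geographic area — by
#' convention the continent yielding the oldest material confidently
#' assigned to it — so its distribution is the indicator on that area. The
#' area universe is closed over the areas observed at the tips.
#'
#' @param table a data.frame with columns `taxon` and `area` (an
#'   `occurrence_table` works).
#' @param tree a `phylo` whose tips must all carry an area.
#' @return a numeric matrix, tips x areas, rows summing to 1.
#' @export
tip_area_distributions <- function(table, tree) {
  .assert_phylo(tree)
  tips <- normalize_label(tree$tip.label)
  area <- stats::setNames(as.character(table$area), normalize_label(table$taxon))
  miss <- tips[!(tips %in% names(area)) | is.na(area[tips]) | !nzchar(area[tips])]
  if (length(miss)) {
    pf_input_error(paste0("tip(s) without area label: ", paste(miss, collapse = ", ")))
  }
  areas <- sort(unique(unname(area[tips])))
  m <- matrix(0, length(tips), length(areas), dimnames = list(tips, areas))
  m[cbind(seq_along(tips), match(area[tips], areas))] <- 1
  m
}

#' Propagate area probabilities from tips to root
#'
#' Post-order (tip-to-base) recursion on a rooted, possibly polytomous
#' tree. Under the default `"mean"` rule each internal node's distribution
#' is the arithmetic mean of its children's distributions (equal weights;
#' a k-child polytomy averages over all k children). This is the
#' equiprobable-scenario reading of combining child areas by multiplication
#' and addition, and on binary trees it yields dyadic probabilities
#' (k/2^d). The alternative `"product"` rule takes the normalized
#' elementwise product of child distributions (falling back to the mean,
#' with a warning, where child supports are disjoint and the product
#' vanishes); it is exposed for sensitivity reporting.
#'
#' @param tree a rooted `phylo`.
#' @param tip_dists tips x areas matrix from [tip_area_distributions()];
#'   derived from `table` when omitted.
#' @param table optional data.frame with `taxon` and `area` columns.
#' @param rule `"mean"` (default) or `"product"`.
#' @return a numeric matrix, all nodes x areas (tips first, internal nodes
#'   named `node<N>`), every row summing to 1; attribute `"rule"` records
#'   the propagation rule.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' occ <- occurrence_table(c("A","B","C","D"), c(5,5,5,5),
#'                         area = c("Europe","Europe","NorthAmerica","NorthAmerica"))
#' node_area_probabilities(tr, table = occ)["node5", ]  # 0.5 / 0.5 at the root
#' @export
node_area_probabilities <- function(tree, tip_dists = NULL, table = NULL,
                                    rule = c("mean", "product")) {
  rule <- match.arg(rule)
  .assert_phylo(tree)
  if (is.null(tip_dists)) {
    if (is.null(table)) pf_input_error("supply tip_dists or table")
    tip_dists <- tip_area_distributions(table, tree)
  }
  tips <- normalize_label(tree$tip.label)
  if (!all(tips %in% rownames(tip_dists))) {
    pf_input_error("tip_dists does not cover all tree tips")
  }
  ntip <- length(tips)
  nn <- .n_nodes(tree)
  k <- ncol(tip_dists)
  P <- matrix(NA_real_, nn, k, dimnames = list(.node_names(tree), colnames(tip_dists)))
  P[seq_len(ntip), ] <- tip_dists[tips, , drop = FALSE]
  po <- .postorder_edges(tree)
  for (v in unique(po[, 1L])) {
    ch <- po[po[, 1L] == v, 2L]
    rows <- P[ch, , drop = FALSE]
    if (rule == "mean") {
      P[v, ] <- colMeans(rows)
    } else {
      p <- apply(rows, 2L, prod)
      if (sum(p) <= 0) {
        warning(sprintf("product rule: disjoint child supports at node %d; falling back to mean", v))
        P[v, ] <- colMeans(rows)
      } else {
        P[v, ] <- p / sum(p)
      }
    }
  }
  structure(P, rule = rule)
}

#' Tabulate ancestral-area probabilities
#'
#' One row per node in post-order (children before parents), or one row per
#' focal clade when `focal_clades` is given. Focal clades are defined by tip
#' sets and resolved to the most recent common ancestor (MRCA); if the MRCA
#' subtends tips beyond the given set — common on consensus trees, where
#' strict monophyly checks are brittle — a warning reports the extra tips
#' and the MRCA row is returned anyway.
#'
#' @param tree a rooted `phylo`.
#' @param dists node x area matrix from [node_area_probabilities()].
#' @param focal_clades optional named list of tip-label vectors.
#' @return a `data.frame` with columns `node`, `label`, `clade` and one
#'   `p_<area>` column per area.
#' @export
area_report <- function(tree, dists, focal_clades = NULL) {
  .assert_phylo(tree)
  ntip <- length(tree$tip.label)
  nms <- .node_names(tree)
  po <- .postorder_edges(tree)
  order_nodes <- unique(c(po[, 2L], .root_node(tree)))  # postorder incl. tips
  areas <- colnames(dists)
  row_for <- function(node, clade) {
    out <- data.frame(node = node,
                      label = if (node <= ntip) tree$tip.label[node] else nms[node],
                      clade = clade, stringsAsFactors = FALSE)
    for (a in areas) out[[paste0("p_", a)]] <- unname(dists[nms[node], a])
    out
  }
  if (is.null(focal_clades)) {
    res <- do.call(rbind, lapply(order_nodes, row_for, clade = NA_character_))
  } else {
    if (is.null(names(focal_clades)) || any(!nzchar(names(focal_clades)))) {
      pf_input_error("focal_clades must be a named list of tip sets")
    }
    res <- do.call(rbind, lapply(names(focal_clades), function(cl) {
      want <- normalize_label(focal_clades[[cl]])
      miss <- setdiff(want, tree$tip.label)
      if (length(miss)) pf_input_error(paste0("focal clade ", cl, ": unknown tip(s) ", paste(miss, collapse = ", ")))
      node <- if (length(want) == 1L) match(want, tree$tip.label)
              else ape::getMRCA(tree, want)
      got <- if (node <= ntip) tree$tip.label[node] else
        tree$tip.label[.descendant_tips(tree, node)]
      extra <- setdiff(got, want)
      if (length(extra)) {
        warning(sprintf("focal clade %s: MRCA (node %d) also subtends %s",
                        cl, node, paste(extra, collapse = ", ")))
      }
      row_for(node, cl)
    }))
  }
  rownames(res) <- NULL
  res
}

# tip indices descending from a node
.descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- .children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}
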