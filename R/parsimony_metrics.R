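# Parsimony scoring of trees against discrete character matrices.
#
# The workhorse is generalized (Sankoff) dynamic programming over the rooted
# tree with a per-character cost matrix: unit costs between distinct states
# for unordered (Fitch) characters, linear costs |i - j| for ordered
# (Wagner) characters. Polymorphic tips are scored any-of (cost 0 for each
# listed state); missing and gap cells cost 0 for every state. Polytomies
# are handled natively by the DP.

# per-character scoring context
.char_ctx <- function(cm, j) {
  if (j < 1L || j > cm$n_char) pf_input_error(sprintf("character index %d out of range (1..%d)", j, cm$n_char))
  sets <- .char_state_sets(cm, j)
  universe <- .char_universe(sets)
  k <- length(universe)
  cost <- if (k) {
    if (cm$ordered[j]) abs(outer(universe, universe, "-")) else 1 - diag(k)
  } else matrix(0, 0, 0)
  list(sets = sets, universe = universe, cost = cost)
}

# tip cost matrix: 0 for allowed states, Inf otherwise; missing = all 0
.tip_costs <- function(ctx, n_tip) {
  k <- length(ctx$universe)
  tc <- matrix(Inf, n_tip, k)
  for (i in seq_len(n_tip)) {
    s <- ctx$sets[[i]]
    if (is.null(s)) tc[i, ] <- 0 else tc[i, match(s, ctx$universe)] <- 0
  }
  tc
}

# Sankoff down-pass. Returns D ((tips+internals) x k subtree cost matrix)
# and M (per-node k-vector: min over child states of D + cost, cached for
# the up-pass).
.sankoff_down <- function(tree, tipcost, cost) {
  ntip <- nrow(tipcost)
  nn <- .n_nodes(tree)
  k <- ncol(tipcost)
  D <- matrix(0, nn, k)
  D[seq_len(ntip), ] <- tipcost
  M <- vector("list", nn)
  po <- .postorder_edges(tree)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    m <- vapply(seq_len(k), function(s) min(D[ch, ] + cost[s, ]), 0)
    M[[ch]] <- m
    D[p, ] <- D[p, ] + m
  }
  list(D = D, M = M)
}

# up-pass: A[v, s] = min cost of all edges outside v's subtree (including
# the edge to v's parent) given state s at v; A[root, ] = 0.
.sankoff_up <- function(tree, down, cost) {
  nn <- .n_nodes(tree)
  k <- ncol(cost)
  A <- matrix(0, nn, k)
  po <- .postorder_edges(tree)
  for (i in rev(seq_len(nrow(po)))) {       # preorder: parents before children
    p <- po[i, 1L]; ch <- po[i, 2L]
    w <- A[p, ] + (down$D[p, ] - down$M[[ch]])   # outside-cost at p, excluding ch
    A[ch, ] <- vapply(seq_len(k), function(s) min(w + cost[, s]), 0)
  }
  A
}

#' Parsimony length of one character on a tree
#'
#' Minimum total cost over all internal-state assignments, by cost-matrix
#' dynamic programming. A tip costs 0 for any state in its state set
#' (polymorphism = any-of) and is unconstrained when missing; an
#' all-missing or constant character scores 0.
#'
#' @param tree a rooted `phylo` (polytomies allowed).
#' @param cm a `char_matrix` whose taxa cover the tree's tips.
#' @param j 1-based character index.
#' @return number of steps (numeric).
#' @export
character_length <- function(tree, cm, j) {
  cm <- .align_matrix(tree, cm)
  ctx <- .char_ctx(cm, j)
  if (length(ctx$universe) < 2L) return(0)
  down <- .sankoff_down(tree, .tip_costs(ctx, length(cm$taxa)), ctx$cost)
  min(down$D[.root_node(tree), ])
}

# reorder matrix rows to match tree tips; error on uncovered tips
.align_matrix <- function(tree, cm) {
  .assert_phylo(tree)
  tips <- normalize_label(tree$tip.label)
  idx <- match(tips, cm$taxa)
  if (anyNA(idx)) {
    pf_reconcile_error(paste0("tip(s) missing from character matrix: ",
                              paste(tips[is.na(idx)], collapse = ", ")))
  }
  cm$taxa <- cm$taxa[idx]
  cm$cells <- cm$cells[idx, , drop = FALSE]
  cm$is_gap <- cm$is_gap[idx, , drop = FALSE]
  cm
}

#' Parsimony length of a tree over a whole matrix
#'
#' @inheritParams character_length
#' @return total steps, the sum of [character_length()] over all characters.
#' @export
tree_length <- function(tree, cm) {
  cm <- .align_matrix(tree, cm)
  sum(vapply(seq_len(cm$n_char), function(j) character_length(tree, cm, j), 0))
}

#' Minimum conceivable steps of a character (m)
#'
#' The smallest number of steps the character can require on any tree.
#' Unordered: (size of the smallest state set hitting every scored cell,
#' choosing polymorphic representatives freely) - 1. Ordered: the width of
#' the narrowest state interval intersecting every scored cell. Missing
#' cells are ignored.
#'
#' @param cm a `char_matrix`.
#' @param j 1-based character index.
#' @return steps (numeric).
#' @export
char_min_steps <- function(cm, j) {
  ctx <- .char_ctx(cm, j)
  sets <- Filter(Negate(is.null), ctx$sets)
  if (length(sets) == 0L || length(ctx$universe) < 2L) return(0)
  u <- ctx$universe
  if (!cm$ordered[j]) {
    for (size in seq_along(u)) {
      combos <- utils::combn(u, size, simplify = FALSE)
      for (cs in combos) {
        if (all(vapply(sets, function(s) any(s %in% cs), TRUE))) return(size - 1)
      }
    }
    return(length(u) - 1)  # unreachable; defensive
  }
  best <- Inf
  for (a in u) for (b in u[u >= a]) {
    if (b - a >= best) next
    if (all(vapply(sets, function(s) any(s >= a & s <= b), TRUE))) best <- b - a
  }
  best
}

#' Maximum conceivable steps of a character (g)
#'
#' The character's length on the star tree (a single internal node joining
#' all scored taxa), computed exactly: the minimum over root states of the
#' summed per-taxon costs, each taxon contributing its cheapest listed
#' state. This is the `g` of the retention index.
#'
#' @inheritParams char_min_steps
#' @return steps (numeric).
#' @export
char_max_steps <- function(cm, j) {
  ctx <- .char_ctx(cm, j)
  sets <- Filter(Negate(is.null), ctx$sets)
  if (length(sets) == 0L || length(ctx$universe) < 2L) return(0)
  u <- ctx$universe
  roots <- if (cm$ordered[j]) seq(min(u), max(u)) else u
  best <- Inf
  for (r in roots) {
    tot <- sum(vapply(sets, function(s) {
      if (cm$ordered[j]) min(abs(r - s)) else as.numeric(!(r %in% s))
    }, 0))
    if (tot < best) best <- tot
  }
  best
}

#' Tree-fit statistics: length and ensemble CI/RI/HI/RC
#'
#' Scores every character on the tree and assembles the classical fit
#' indices from the per-character steps `s`, minima `m` and maxima `g`:
#' ensemble CI = sum(m)/sum(s), RI = (sum(g) - sum(s))/(sum(g) - sum(m)),
#' HI = 1 - CI, RC = CI x RI. Per-character indices use ci = m/s (1 when
#' s = 0) and ri = (g - s)/(g - m) (1 when g = m). Characters with g = m
#' (parsimony-uninformative) are excluded from the RI sums, the standard
#' convention; `exclude_uninformative = TRUE` additionally drops them from
#' the CI/HI sums (the alternative report some programs print). Tree length
#' always sums over all characters.
#'
#' @inheritParams character_length
#' @param exclude_uninformative drop parsimony-uninformative characters
#'   (g = m) from the CI/HI sums.
#' @return an object of class `tree_fit_stats`: list with `length`, `CI`,
#'   `RI`, `HI`, `RC`, `n_char`, `exclude_uninformative`, and
#'   `per_character` (a data.frame of `char`, `s`, `m`, `g`, `ci`, `ri`,
#'   `rc`, `informative`).
#' @export
tree_fit_indices <- function(tree, cm, exclude_uninformative = FALSE) {
  cm <- .align_matrix(tree, cm)
  js <- seq_len(cm$n_char)
  s <- vapply(js, function(j) character_length(tree, cm, j), 0)
  m <- vapply(js, function(j) char_min_steps(cm, j), 0)
  g <- vapply(js, function(j) char_max_steps(cm, j), 0)
  ci <- ifelse(s > 0, m / s, 1)
  ri <- ifelse(g > m, (g - s) / (g - m), 1)
  per <- data.frame(char = js, s = s, m = m, g = g, ci = ci, ri = ri,
                    rc = ci * ri, informative = g > m)
  ci_set <- if (exclude_uninformative) per$informative else rep(TRUE, length(js))
  CI <- if (sum(s[ci_set]) > 0) sum(m[ci_set]) / sum(s[ci_set]) else 1
  inf <- per$informative
  RI <- if (any(inf) && sum(g[inf]) > sum(m[inf])) {
    (sum(g[inf]) - sum(s[inf])) / (sum(g[inf]) - sum(m[inf]))
  } else 1
  structure(list(length = sum(s), CI = CI, RI = RI, HI = 1 - CI, RC = CI * RI,
                 n_char = cm$n_char, exclude_uninformative = exclude_uninformative,
                 per_character = per),
            class = "tree_fit_stats")
}

#' @export
print.tree_fit_stats <- function(x, ...) {
  cat(sprintf("Tree length %g steps over %d characters%s\n", x$length, x$n_char,
              if (x$exclude_uninformative) " (CI excludes uninformative characters)" else ""))
  cat(sprintf("  CI = %.4f  RI = %.4f  HI = %.4f  RC = %.4f\n", x$CI, x$RI, x$HI, x$RC))
  invisible(x)
}

#' Unambiguous synapomorphies of a clade
#'
#' A character change is an unambiguous synapomorphy of a clade when every
#' minimum-cost reconstruction places a change on the branch subtending the
#' clade's node. Membership is decided by re-running the dynamic program
#' with the branch's endpoints constrained equal: if the constrained optimum
#' exceeds the unconstrained tree length, no optimal reconstruction avoids a
#' change there. Note that for a child of the root of a basally dichotomous
#' tree the single change can often sit on either root-adjacent branch, so
#' basal synapomorphies become ambiguous unless an outgroup fixes the root
#' side.
#'
#' @inheritParams character_length
#' @param node the clade: an internal node number, or a character vector of
#'   tip labels whose MRCA is used. Must not be the root.
#' @return a `data.frame` with columns `char` (1-based index) and `state`
#'   (the derived state(s) at the clade node across all optimal
#'   reconstructions, `/`-joined when several are optimal).
#' @export
unambiguous_synapomorphies <- function(tree, cm, node) {
  cm <- .align_matrix(tree, cm)
  ntip <- length(tree$tip.label)
  if (is.character(node)) {
    want <- normalize_label(node)
    miss <- setdiff(want, tree$tip.label)
    if (length(miss)) pf_input_error(paste0("unknown tip(s): ", paste(miss, collapse = ", ")))
    if (length(want) < 2L) pf_input_error("clade must contain at least 2 tips")
    node <- ape::getMRCA(tree, want)
  }
  node <- as.integer(node)
  if (node <= ntip || node > .n_nodes(tree)) pf_input_error("node must be an internal node")
  if (node == .root_node(tree)) pf_input_error("the root subtends no branch; choose a non-root clade")
  par <- .parents(tree)[node]
  sym_of <- stats::setNames(names(cm$state_of), cm$state_of)
  hits <- list()
  for (j in seq_len(cm$n_char)) {
    ctx <- .char_ctx(cm, j)
    if (length(ctx$universe) < 2L) next
    down <- .sankoff_down(tree, .tip_costs(ctx, ntip), ctx$cost)
    L <- min(down$D[.root_node(tree), ])
    # cost of everything outside `node`'s subtree with parent state s and the
    # node--parent edge collapsed (endpoints equal, change forbidden)
    A <- .sankoff_up(tree, down, ctx$cost)
    other <- down$D[par, ] - down$M[[node]]
    constrained <- min(down$D[node, ] + A[par, ] + other)
    if (constrained > L + 1e-9) {
      opt <- ctx$universe[abs(down$D[node, ] + A[node, ] - L) < 1e-9]
      hits[[length(hits) + 1L]] <- data.frame(
        char = j, state = paste(sym_of[as.character(opt)], collapse = "/"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(char = integer(0), state = character(0)))
  do.call(rbind, hits)
}
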