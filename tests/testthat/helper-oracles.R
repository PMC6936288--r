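# Independent brute-force oracles. These enumerate exhaustively and never
# share code with the package's dynamic programs.

# all rooted binary topologies on a set of leaf units (characters or newick
# substrings), as nested lists; (2n-3)!! trees
all_rooted_topologies <- function(leaves) {
  insert_below <- function(t, leaf) {
    if (!is.list(t)) return(list())
    res <- list()
    for (i in 1:2) {
      sub <- t[[i]]
      t2 <- t; t2[[i]] <- list(sub, leaf)
      res <- c(res, list(t2))
      for (r in insert_below(sub, leaf)) {
        t3 <- t; t3[[i]] <- r
        res <- c(res, list(t3))
      }
    }
    res
  }
  trees <- list(leaves[[1L]])
  for (leaf in leaves[-1L]) {
    trees <- unlist(lapply(trees, function(t) {
      c(list(list(t, leaf)), insert_below(t, leaf))
    }), recursive = FALSE)
  }
  trees
}

nested_to_newick <- function(t) {
  if (!is.list(t)) return(t)
  paste0("(", nested_to_newick(t[[1L]]), ",", nested_to_newick(t[[2L]]), ")")
}

# MIG of a nested-list tree under a named FAD vector (leaf units must be
# names into fads); returns list(age, mig)
nested_mig <- function(t, fads) {
  if (!is.list(t)) return(list(age = unname(fads[[t]]), mig = 0))
  l <- nested_mig(t[[1L]], fads)
  r <- nested_mig(t[[2L]], fads)
  age <- max(l$age, r$age)
  list(age = age, mig = l$mig + r$mig + (age - l$age) + (age - r$age))
}

# brute-force minimum and maximum MIG over all rooted binary topologies
brute_mig_range <- function(fads) {
  migs <- vapply(all_rooted_topologies(as.list(names(fads))),
                 function(t) nested_mig(t, fads)$mig, 0)
  c(min = min(migs), max = max(migs))
}

# brute-force parsimony length of one character by enumerating every
# internal-state assignment; sets: list over tips (NULL = missing)
brute_char_length <- function(tree, sets, universe, ordered) {
  k <- length(universe)
  if (k < 2L) return(0)
  cost <- if (ordered) abs(outer(universe, universe, "-")) else 1 - diag(k)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  tot <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L] - ntip
    ch <- tree$edge[e, 2L]
    if (ch > ntip) {
      tot <- tot + cost[cbind(grid[, p], grid[, ch - ntip])]
    } else {
      s <- sets[[ch]]
      if (is.null(s)) next
      allowed <- match(s, universe)
      tipc <- apply(cost[, allowed, drop = FALSE], 1L, min)
      tot <- tot + tipc[grid[, p]]
    }
  }
  min(tot)
}

# every binary resolution of a (possibly polytomous) rooted tree, as newick
all_binary_resolutions <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    alts_per_child <- lapply(kids[[v]], rec)   # list of character vectors
    combos <- expand.grid(alts_per_child, stringsAsFactors = FALSE)
    out <- character(0)
    for (r in seq_len(nrow(combos))) {
      units <- as.character(unlist(combos[r, ]))
      if (length(units) == 1L) { out <- c(out, units); next }
      topos <- all_rooted_topologies(as.list(units))
      out <- c(out, vapply(topos, nested_to_newick, ""))
    }
    unique(out)
  }
  paste0(rec(ntip + 1L), ";")
}

# enumeration oracle for unambiguous changes: does every minimum-cost full
# labeling place a change on the branch above `node`?
brute_unambiguous <- function(tree, sets, universe, ordered, node) {
  k <- length(universe)
  if (k < 2L) return(FALSE)
  cost <- if (ordered) abs(outer(universe, universe, "-")) else 1 - diag(k)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  # enumerate states of ALL nodes (tips restricted to their sets)
  choices <- lapply(seq_len(nn), function(v) {
    if (v <= ntip) {
      if (is.null(sets[[v]])) seq_len(k) else match(sets[[v]], universe)
    } else seq_len(k)
  })
  grid <- as.matrix(expand.grid(choices))
  tot <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    tot <- tot + cost[cbind(grid[, tree$edge[e, 1L]], grid[, tree$edge[e, 2L]])]
  }
  opt <- which(tot == min(tot))
  par <- tree$edge[match(node, tree$edge[, 2L]), 1L]
  all(grid[opt, par] != grid[opt, node])
}

# random tree helpers -------------------------------------------------------

random_binary_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- NULL
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# collapse random internal edges to create polytomies (child counts capped
# so exhaustive resolution enumeration stays feasible)
random_polytomous_tree <- function(n, p_collapse = 0.5, max_children = 5L) {
  repeat {
    tr <- random_binary_tree(n)
    tr <- ape::di2multi(ape::compute.brlen(tr, runif), tol = p_collapse)
    tr$edge.length <- NULL
    if (max(tabulate(tr$edge[, 1L])) <= max_children) return(tr)
  }
}

random_occurrences <- function(tree, distinct = TRUE) {
  n <- length(tree$tip.label)
  f <- if (distinct) sample(seq(2, 100), n) else sample(seq(2, 12), n, replace = TRUE)
  occurrence_table(tree$tip.label, f)
}

# random character-scoring pattern for oracle comparisons
random_char_sets <- function(ntip, k, p_missing = 0.15, p_poly = 0.15) {
  universe <- seq_len(k) - 1L
  sets <- lapply(seq_len(ntip), function(i) {
    if (runif(1) < p_missing) return(NULL)
    s <- sample(universe, 1L)
    if (k > 1L && runif(1) < p_poly) {
      s <- sort(unique(c(s, sample(universe, 1L))))
    }
    s
  })
  # guarantee at least one scored taxon
  if (all(vapply(sets, is.null, TRUE))) sets[[1L]] <- sample(universe, 1L)
  sets
}

sets_to_char_matrix <- function(taxa, sets, ordered = FALSE) {
  tok <- vapply(sets, function(s) if (is.null(s)) NA_character_ else paste(s, collapse = "/"), "")
  char_matrix(taxa, matrix(tok, ncol = 1L), ordered = ordered,
              symbols = as.character(0:9))
}

expect_isomorphic <- function(a, b) {
  testthat::expect_true(isTRUE(ape::all.equal.phylo(a, b, use.edge.length = FALSE)))
}

quiet <- function(expr) suppressMessages(expr)
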