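#' Simulation configuration
#'
#' Bundles the knobs for the seeded generators. Defaults describe a modest
#' fossil clade: 16 tips, a 100 Ma root, Yule branching, 50 three-state
#' characters with about two expected changes each, and two continents with
#' a 10% per-branch switching probability. Identical configuration and seed
#' give bit-identical outputs.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed; each generator derives its stream from it.
#' @param root_age age of the root, Ma.
#' @param birth_rate pure-birth speciation rate, per Myr.
#' @param congruence in `[0, 1]`: steers the expected gap excess ratio of
#'   simulated first appearances (1 = perfectly congruent, 0 = maximally
#'   incongruent; see [simulate_fads()]).
#' @param n_characters,n_states matrix dimensions for [simulate_characters()].
#' @param change_rate expected number of state changes per character over
#'   the whole tree.
#' @param missing_prob,polymorphism_prob per-cell probabilities of injecting
#'   missing scores / one extra polymorphic state.
#' @param areas character vector of area labels.
#' @param area_switch_prob per-branch probability of an area switch.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 16L, seed = 1L, root_age = 100, birth_rate = 0.1,
                       congruence = 1, n_characters = 50L, n_states = 3L,
                       change_rate = 2, missing_prob = 0, polymorphism_prob = 0,
                       areas = c("NorthAmerica", "Europe"), area_switch_prob = 0.1) {
  cfg <- list(n_tips = as.integer(n_tips), seed = as.integer(seed),
              root_age = root_age, birth_rate = birth_rate,
              congruence = congruence, n_characters = as.integer(n_characters),
              n_states = as.integer(n_states), change_rate = change_rate,
              missing_prob = missing_prob, polymorphism_prob = polymorphism_prob,
              areas = as.character(areas), area_switch_prob = area_switch_prob)
  if (cfg$n_tips < 3L) pf_input_error("n_tips must be >= 3")
  if (cfg$congruence < 0 || cfg$congruence > 1) pf_input_error("congruence must lie in [0, 1]")
  if (cfg$area_switch_prob < 0 || cfg$area_switch_prob > 1) pf_input_error("area_switch_prob must lie in [0, 1]")
  if (cfg$birth_rate <= 0 || cfg$root_age <= 0 || cfg$change_rate < 0 ||
      cfg$missing_prob < 0 || cfg$polymorphism_prob < 0) {
    pf_input_error("rates, ages and probabilities must be non-negative (birth_rate, root_age positive)")
  }
  if (cfg$n_states < 2L) pf_input_error("n_states must be >= 2")
  structure(cfg, class = "sim_config")
}

#' Simulate a rooted binary tree (pure birth)
#'
#' A Yule tree with `n_tips` tips via [ape::rphylo()], rescaled so the root
#' sits at `root_age`. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return a binary `phylo` with branch lengths in Myr.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_tips, config$birth_rate, 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$root_age / depth
  tr
}

#' Simulate first appearances with controlled stratigraphic congruence
#'
#' Builds two deterministic-per-seed age assignments for the tree and
#' interpolates between them with the `congruence` parameter:
#'
#' * `congruence = 1`: ages decrease along a root-to-tip path, with each
#'   subtree hanging off the path dated as a unit (all its tips share the
#'   subtree's age). On a binary tree this attains MIG = Gmin exactly, so
#'   the tree's GER is exactly 1. Tied ages are essential: most non-pectinate
#'   shapes cannot reach Gmin with all-distinct first appearances.
#' * `congruence = 0`: a dominating set of tips — chosen so that every
#'   tip-bearing internal node has one at maximal age — is pinned to the
#'   root age, forcing every remaining taxon's full gap to be expressed on
#'   its terminal branch: MIG = Gmax exactly, GER exactly 0 (the oldest
#'   taxa are maximally nested).
#' * intermediate values blend the two age vectors linearly, giving a
#'   monotone (in expectation) congruence-to-GER relationship.
#'
#' The exactness guarantees hold for binary trees (which [simulate_tree()]
#' produces); on a star tree MIG equals Gmax identically, so GER = 1 is
#' unattainable for any assignment.
#'
#' @param tree a rooted `phylo`.
#' @param config a [sim_config()]; uses `seed`, `root_age`, `congruence`.
#' @return an `occurrence_table` (LAD = FAD, no areas).
#' @export
simulate_fads <- function(tree, config) {
  .assert_phylo(tree)
  set.seed(config$seed + 1L)
  a1 <- .fads_congruent(tree, config$root_age)
  a0 <- .fads_incongruent(tree, config$root_age)
  cg <- config$congruence
  f <- if (cg == 1) a1 else if (cg == 0) a0 else cg * a1 + (1 - cg) * a0
  occurrence_table(tree$tip.label, f)
}

# ages attaining MIG = Gmin on binary trees: subtree-constant ages strictly
# decreasing along a random root-to-tip path, path tip youngest
.fads_congruent <- function(tree, root_age) {
  ntip <- length(tree$tip.label)
  par <- .parents(tree)
  kids <- .children(tree)
  depth <- integer(ntip)
  for (i in seq_len(ntip)) {
    v <- i; d <- 0L
    while (par[v] != 0L) { v <- par[v]; d <- d + 1L }
    depth[i] <- d
  }
  cand <- which(depth >= 2L)
  if (!length(cand)) cand <- seq_len(ntip)      # star tree: no exact target
  tau <- cand[sample.int(length(cand), 1L)]
  path <- tau
  v <- tau
  while (par[v] != 0L) { v <- par[v]; path <- c(v, path) }  # root .. tau
  hanging <- list()
  for (i in seq_len(length(path) - 1L)) {
    off <- setdiff(kids[[path[i]]], path[i + 1L])
    for (h in off) hanging[[length(hanging) + 1L]] <- h
  }
  H <- length(hanging)
  vals <- sort(stats::runif(H + 1L, 0.1 * root_age, root_age), decreasing = TRUE)
  f <- numeric(ntip)
  for (i in seq_len(H)) {
    tips_h <- .descendant_tips(tree, hanging[[i]])
    f[tips_h] <- vals[i]
  }
  f[tau] <- vals[H + 1L]
  f
}

# ages attaining MIG = Gmax: pin a dominating set of tips to the root age so
# every tip-bearing internal node carries the oldest age
.fads_incongruent <- function(tree, root_age) {
  ntip <- length(tree$tip.label)
  kids <- .children(tree)
  nn <- .n_nodes(tree)
  has0 <- logical(nn)
  pinned <- integer(0)
  po <- .postorder_edges(tree)
  for (v in unique(po[, 1L])) {               # postorder over internal nodes
    ch <- kids[[v]]
    has0[v] <- any(has0[ch])
    tip_ch <- ch[ch <= ntip]
    if (length(tip_ch) && !has0[v]) {
      pinned <- c(pinned, tip_ch[1L])
      has0[v] <- TRUE
    }
  }
  f <- numeric(ntip)
  f[pinned] <- root_age
  rest <- setdiff(seq_len(ntip), pinned)
  f[rest] <- stats::runif(length(rest), 0.05 * root_age, 0.9 * root_age)
  f
}

#' Permute first appearances across taxa (null resamples)
#'
#' Returns `n` copies of the table with the (FAD, LAD) pairs permuted over
#' taxa; the multiset of ages — hence Gmin and Gmax — is preserved exactly.
#'
#' @param table an `occurrence_table`.
#' @param n number of permuted tables (>= 1).
#' @param seed integer seed.
#' @return a list of `occurrence_table`s.
#' @export
permute_fads_null <- function(table, n, seed = 1L) {
  if (n < 1L) pf_input_error("n must be >= 1")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- sample.int(nrow(table))
    out <- table
    out$fad_ma <- table$fad_ma[p]
    out$lad_ma <- table$lad_ma[p]
    validate_occurrence_table(out)
  })
}

#' Simulate discrete characters on a tree (Mk-style)
#'
#' Each character evolves independently by a symmetric k-state change
#' process: per branch, a Poisson number of change events proportional to
#' branch length (scaled so a character expects `change_rate` changes over
#' the tree), each event replacing the current state by a uniformly chosen
#' different state. The realized change count per character is recorded in
#' attribute `"true_changes"`; parsimony length can never exceed it.
#' Optional missing-data and polymorphism injection follow the configured
#' per-cell probabilities.
#'
#' @param tree a rooted `phylo` with branch lengths (unit lengths assumed
#'   when absent).
#' @param config a [sim_config()].
#' @return a `char_matrix` with attribute `true_changes` (integer vector).
#' @export
simulate_characters <- function(tree, config) {
  .assert_phylo(tree)
  set.seed(config$seed + 2L)
  ntip <- length(tree$tip.label)
  nn <- .n_nodes(tree)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(tree$edge))
  lam <- config$change_rate * el / sum(el)
  k <- config$n_states
  po <- .postorder_edges(tree)
  pre <- rev(seq_len(nrow(po)))
  cells <- matrix(NA_character_, ntip, config$n_characters)
  gap <- matrix(FALSE, ntip, config$n_characters)
  true_changes <- integer(config$n_characters)
  lam_po <- lam[match(paste(po[, 1L], po[, 2L]), paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (j in seq_len(config$n_characters)) {
    state <- integer(nn)
    state[.root_node(tree)] <- sample.int(k, 1L) - 1L
    nch <- stats::rpois(nrow(po), lam_po)
    for (i in pre) {
      s <- state[po[i, 1L]]
      if (nch[i] > 0L) for (e in seq_len(nch[i])) {
        alt <- (0:(k - 1L))[-(s + 1L)]
        s <- alt[sample.int(length(alt), 1L)]
      }
      state[po[i, 2L]] <- s
    }
    true_changes[j] <- sum(nch)
    tok <- as.character(state[seq_len(ntip)])
    if (config$polymorphism_prob > 0) {
      poly <- stats::runif(ntip) < config$polymorphism_prob
      for (i in which(poly)) {
        alt <- (0:(k - 1L))[-(state[i] + 1L)]
        extra <- alt[sample.int(length(alt), 1L)]
        tok[i] <- paste(sort(c(state[i], extra)), collapse = "/")
      }
    }
    if (config$missing_prob > 0) tok[stats::runif(ntip) < config$missing_prob] <- NA_character_
    cells[, j] <- tok
  }
  cm <- char_matrix(tree$tip.label, cells, symbols = as.character(0:(k - 1L)), is_gap = gap)
  attr(cm, "true_changes") <- true_changes
  cm
}

#' Simulate tip areas by a per-branch switching walk
#'
#' The root's area is drawn uniformly; along each branch the area switches
#' with probability `area_switch_prob` to a uniformly chosen different
#' area. Deterministic per seed.
#'
#' @param tree a rooted `phylo`.
#' @param config a [sim_config()]; uses `seed`, `areas`, `area_switch_prob`.
#' @return a `data.frame` with columns `taxon` and `area`.
#' @export
simulate_tip_areas <- function(tree, config) {
  .assert_phylo(tree)
  if (!length(config$areas)) pf_input_error("at least one area label required")
  set.seed(config$seed + 3L)
  nn <- .n_nodes(tree)
  ntip <- length(tree$tip.label)
  areas <- config$areas
  a <- integer(nn)
  a[.root_node(tree)] <- sample.int(length(areas), 1L)
  po <- .postorder_edges(tree)
  for (i in rev(seq_len(nrow(po)))) {
    s <- a[po[i, 1L]]
    if (length(areas) > 1L && stats::runif(1L) < config$area_switch_prob) {
      alt <- seq_along(areas)[-s]
      s <- alt[sample.int(length(alt), 1L)]
    }
    a[po[i, 2L]] <- s
  }
  data.frame(taxon = tree$tip.label, area = areas[a[seq_len(ntip)]],
             stringsAsFactors = FALSE)
}

#' Packaged marine-turtle example (illustrative)
#'
#' Four competing arrangements of the americhelydian lineages — differing in
#' where the protostegids and *Allopleuron* attach — together with an
#' occurrence table of first/last appearances (Ma) and continent-level
#' areas. Clade age constraints are realized implicitly: a clade's age is
#' the maximum FAD of its members, so constraining a clade by a taxon is
#' equivalent to including that taxon with its FAD.
#'
#' The `provenance` column separates the single record stated outright in
#' the source description (*Asmodochelys parhami*: Demopolis Chalk,
#' 79-74.5 Ma, North America) from the remaining records, which are
#' illustrative stand-ins consistent with the published fossil record; the
#' fixture demonstrates the machinery and must not be mistaken for the
#' study's supplementary occurrence data.
#'
#' @return a list with `trees` (named `multiPhylo`: `evers_benson_2019`,
#'   `evers_etal_2019`, `weighted_parsimony`, `joyce_2007`), `table` (an
#'   `occurrence_table` with `area` and `provenance`), `consensus` (the
#'   weighted-parsimony tree, used for ancestral areas) and `clades` (named
#'   tip sets: crown Chelonioidea and the youngest stem-chelonioid node).
#' @export
americhelydia_fixture <- function() {
  trees <- structure(list(
    evers_benson_2019 = parse_newick(
      "(Chelydroidea,(Toxochelys,((Asmodochelys,Ctenochelys),((Euclastes,(Argillochelys,Allopleuron)),(Desmatochelys,Eosphargis)))));"),
    evers_etal_2019 = parse_newick(
      "(Chelydroidea,(Desmatochelys,(Toxochelys,(((Asmodochelys,Ctenochelys),(Euclastes,(Argillochelys,Allopleuron))),Eosphargis))));"),
    weighted_parsimony = parse_newick(
      "(Chelydroidea,(Desmatochelys,(Toxochelys,((Asmodochelys,Ctenochelys),((Euclastes,Argillochelys),(Allopleuron,Eosphargis))))));"),
    joyce_2007 = parse_newick(
      "(Desmatochelys,(Chelydroidea,(Toxochelys,((Asmodochelys,Ctenochelys),((Euclastes,(Argillochelys,Allopleuron)),Eosphargis)))));")
  ), class = "multiPhylo")
  table <- occurrence_table(
    taxon = c("Chelydroidea", "Desmatochelys", "Toxochelys", "Ctenochelys",
              "Asmodochelys", "Euclastes", "Argillochelys", "Allopleuron", "Eosphargis"),
    fad_ma = c(56, 102, 85, 84, 79, 67, 50, 68, 56),
    lad_ma = c(0, 93, 83, 78, 74.5, 60, 48, 66, 54),
    area = c("NorthAmerica", "SouthAmerica", "NorthAmerica", "NorthAmerica",
             "NorthAmerica", "NorthAmerica", "Europe", "Europe", "Europe"),
    provenance = c("illustrative", "illustrative", "illustrative", "illustrative",
                   "paper", "illustrative", "illustrative", "illustrative", "illustrative"))
  list(trees = trees, table = table,
       consensus = trees$weighted_parsimony,
       clades = list(
         crown_chelonioidea = c("Euclastes", "Argillochelys", "Allopleuron", "Eosphargis"),
         youngest_stem_chelonioids = c("Asmodochelys", "Ctenochelys", "Euclastes",
                                       "Argillochelys", "Allopleuron", "Eosphargis")))
}
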