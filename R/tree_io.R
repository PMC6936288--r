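#' Parse a Newick string into a rooted tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Polytomies and the
#' input order of children are preserved; unary (single-child) nodes are
#' collapsed; tip labels are normalized (whitespace to underscores) and must
#' be unique and non-empty. Branch lengths, if present, are tolerated but
#' ignored by every stratigraphic computation in this package: node ages
#' always derive from occurrence data, never from the cladogram. A note is
#' emitted when branch lengths are encountered.
#'
#' @param text a single Newick string (terminating `;` optional).
#' @return an object of class `phylo`.
#' @seealso [write_newick()]
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    pf_parse_error("empty Newick input")
  }
  # locate unbalanced parentheses before handing to ape, so the error can
  # name a position
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        pf_parse_error(sprintf("unbalanced ')' at position %d in Newick input", i))
      }
    }
  }
  if (depth != 0L) {
    pf_parse_error(sprintf("unbalanced parentheses in Newick input (%d '(' left open)", depth))
  }
  txt <- trimws(text)
  if (!endsWith(txt, ";")) txt <- paste0(txt, ";")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) pf_parse_error(paste0("Newick parse failure: ", conditionMessage(e))))
  if (is.null(tree)) pf_parse_error("Newick parse failure: ape::read.tree returned no tree")
  if (!is.null(tree$edge.length)) {
    message("parse_newick: branch lengths present in input; they are ignored downstream (ages come from occurrence data)")
  }
  tree <- ape::collapse.singles(tree)
  tree$tip.label <- normalize_label(gsub("^['\"]|['\"]$", "", tree$tip.label))
  if (any(!nzchar(tree$tip.label))) pf_parse_error("empty tip label in Newick input")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    pf_parse_error(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (length(tree$tip.label) < 2L) pf_parse_error("tree must have at least 2 tips")
  tree
}

#' Write a tree as a Newick string
#'
#' Round-trips through [parse_newick()] to an isomorphic tree (identical tip
#' sets under every node, polytomies preserved).
#'
#' @param tree a `phylo` object.
#' @return a single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree) {
  .assert_phylo(tree)
  ape::write.tree(tree)
}

#' Build an occurrence table
#'
#' An occurrence table records, per taxon, the first-appearance datum (FAD)
#' and last-appearance datum (LAD) in Ma (larger = older) and an optional
#' geographic area label. LADs are carried for range reporting only; all
#' stratigraphic-congruence arithmetic uses FADs exclusively.
#'
#' @param taxon character vector of taxon labels (unique after normalization).
#' @param fad_ma numeric first appearances (Ma).
#' @param lad_ma numeric last appearances (Ma); defaults to `fad_ma`.
#' @param area optional character vector of area labels (`NA` = unknown).
#' @param provenance optional character vector recording the source of each
#'   row (e.g. `"paper"` vs `"illustrative"` in packaged fixtures).
#' @return a `data.frame` of class `occurrence_table`.
#' @export
occurrence_table <- function(taxon, fad_ma, lad_ma = fad_ma, area = NA_character_,
                             provenance = NULL) {
  tab <- data.frame(taxon = normalize_label(taxon),
                    fad_ma = as.numeric(fad_ma),
                    lad_ma = as.numeric(lad_ma),
                    area = as.character(area),
                    stringsAsFactors = FALSE)
  if (!is.null(provenance)) tab$provenance <- as.character(provenance)
  validate_occurrence_table(tab)
}

#' @rdname occurrence_table
#' @param tab a candidate occurrence table.
#' @export
validate_occurrence_table <- function(tab) {
  req <- c("taxon", "fad_ma", "lad_ma")
  miss <- setdiff(req, names(tab))
  if (length(miss)) pf_input_error(paste0("occurrence table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyNA(tab$fad_ma)) pf_input_error("occurrence table has missing fad_ma values")
  bad <- which(tab$fad_ma < tab$lad_ma)
  if (length(bad)) {
    pf_input_error(sprintf("row %d (%s): fad_ma (%g) < lad_ma (%g); ages are in Ma, larger = older",
                           bad[1L], tab$taxon[bad[1L]], tab$fad_ma[bad[1L]], tab$lad_ma[bad[1L]]))
  }
  bad <- which(tab$lad_ma < 0 | tab$fad_ma < 0)
  if (length(bad)) pf_input_error(sprintf("row %d (%s): negative age", bad[1L], tab$taxon[bad[1L]]))
  dup <- unique(tab$taxon[duplicated(tab$taxon)])
  if (length(dup)) pf_input_error(paste0("duplicate taxon in occurrence table: ", paste(dup, collapse = ", ")))
  class(tab) <- unique(c("occurrence_table", class(tab)))
  tab
}

#' Read an occurrence table from CSV/TSV
#'
#' Expects a header with columns `taxon` and `fad_ma`; `lad_ma` and `area`
#' are optional (`lad_ma` defaults to `fad_ma`). The field separator is
#' auto-detected (tab if the header contains one, comma otherwise).
#'
#' @param path path to a delimited text file.
#' @return an `occurrence_table`.
#' @export
read_occurrence_table <- function(path) {
  if (!file.exists(path)) pf_input_error(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           strip.white = TRUE, comment.char = "")
  if (!all(c("taxon", "fad_ma") %in% names(raw))) {
    pf_parse_error(paste0(path, ": occurrence table needs header columns 'taxon' and 'fad_ma'"))
  }
  if (is.null(raw$lad_ma)) raw$lad_ma <- raw$fad_ma
  raw$lad_ma[is.na(raw$lad_ma)] <- raw$fad_ma[is.na(raw$lad_ma)]
  if (is.null(raw$area)) raw$area <- NA_character_
  occurrence_table(raw$taxon, raw$fad_ma, raw$lad_ma, raw$area,
                   provenance = raw$provenance)
}

#' Write an occurrence table to CSV
#'
#' @param tab an `occurrence_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconcile a tree with an occurrence table
#'
#' Restricts the table to taxa present in the tree, and handles tips without
#' records: `strict` mode errors naming the uncovered tips; `prune` mode
#' drops them (collapsing any resulting unary nodes), logging each removal,
#' and errors if fewer than 3 tips survive.
#'
#' @param tree a `phylo`.
#' @param table an `occurrence_table` (or data.frame with a `taxon` column).
#' @param mode `"strict"` or `"prune"`.
#' @return a list with elements `tree` and `table`, mutually consistent.
#' @export
reconcile <- function(tree, table, mode = c("strict", "prune")) {
  mode <- match.arg(mode)
  .assert_phylo(tree)
  tips <- normalize_label(tree$tip.label)
  taxa <- normalize_label(table$taxon)
  common <- intersect(tips, taxa)
  if (!length(common)) pf_reconcile_error("tree and occurrence table share no taxa")
  uncovered <- setdiff(tips, taxa)
  if (length(uncovered)) {
    if (mode == "strict") {
      pf_reconcile_error(paste0("tip(s) without occurrence record: ", paste(uncovered, collapse = ", ")))
    }
    for (u in uncovered) message("reconcile: pruning tip without occurrence record: ", u)
    if (length(common) < 3L) {
      pf_reconcile_error(sprintf("fewer than 3 tips (%d) remain after pruning", length(common)))
    }
    tree$tip.label <- tips
    tree <- ape::keep.tip(tree, common)
  }
  tab <- table[taxa %in% tips, , drop = FALSE]
  rownames(tab) <- NULL
  list(tree = tree, table = validate_occurrence_table(tab))
}

# ---------------------------------------------------------------------------
# NEXUS

#' Parse a NEXUS file
#'
#' Reads whichever of a DATA/CHARACTERS block (via [read_nexus_matrix()]) and
#' a TREES block (via [read_nexus_trees()]) the file contains.
#'
#' @param path path to a NEXUS file.
#' @return a list with elements `matrix` (a `char_matrix` or `NULL`) and
#'   `trees` (a named `multiPhylo` or `NULL`).
#' @export
parse_nexus <- function(path) {
  if (!file.exists(path)) pf_input_error(paste0("file not found: ", path))
  up <- toupper(paste(readLines(path, warn = FALSE), collapse = "\n"))
  out <- list(matrix = NULL, trees = NULL)
  if (grepl("BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)) out$matrix <- read_nexus_matrix(path)
  if (grepl("BEGIN\\s+TREES\\s*;", up)) out$trees <- read_nexus_trees(path)
  if (is.null(out$matrix) && is.null(out$trees)) {
    pf_parse_error(paste0(path, ": no DATA/CHARACTERS or TREES block found"))
  }
  out
}

#' Read trees from a NEXUS TREES block
#'
#' Wrapper around [ape::read.nexus()] (TRANSLATE tables are resolved); tip
#' labels are normalized.
#'
#' @param path path to a NEXUS file.
#' @return a named `multiPhylo`.
#' @export
read_nexus_trees <- function(path) {
  trees <- tryCatch(ape::read.nexus(path),
                    error = function(e) pf_parse_error(paste0(path, ": ", conditionMessage(e))))
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
    names(trees) <- "tree1"
  }
  for (i in seq_along(trees)) trees[[i]]$tip.label <- normalize_label(trees[[i]]$tip.label)
  trees
}

#' Construct a character matrix
#'
#' A `char_matrix` holds taxa-by-characters discrete scores. Each cell is a
#' token over the state symbols: a single symbol (`"0"`), a `/`-joined set
#' for polymorphism (`"0/1"`), or `NA` for missing. The gap symbol `-` is
#' recorded (in `is_gap`) but treated as missing data in every computation,
#' the conventional reading for morphological matrices. Missing cells expand
#' to the full observed state universe of their character. Character indices
#' are 1-based in all user-facing interfaces.
#'
#' @param taxa character vector of taxon labels.
#' @param cells character matrix (`length(taxa)` rows) of tokens as above.
#' @param ordered logical vector, one flag per character (default all
#'   unordered); ordered characters use linear (Wagner) costs `|i - j|`,
#'   unordered use unit (Fitch) costs.
#' @param symbols state symbols in use; defaults to those observed. Digits
#'   map to their numeric value; letters map to their position in `symbols`.
#' @param is_gap optional logical matrix marking cells scored as gaps.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(taxa, cells, ordered = NULL, symbols = NULL, is_gap = NULL) {
  taxa <- normalize_label(taxa)
  cells <- matrix(as.character(cells), nrow = length(taxa))
  n_char <- ncol(cells)
  if (anyDuplicated(taxa)) pf_input_error("duplicate taxon labels in character matrix")
  obs <- sort(unique(unlist(strsplit(cells[!is.na(cells)], "/", fixed = TRUE))))
  if (is.null(symbols)) symbols <- obs
  unknown <- setdiff(obs, symbols)
  if (length(unknown)) {
    bad <- which(vapply(strsplit(cells, "/", fixed = TRUE),
                        function(s) any(s %in% unknown), TRUE) & !is.na(cells))[1L]
    i <- (bad - 1L) %% length(taxa) + 1L
    j <- (bad - 1L) %/% length(taxa) + 1L
    pf_parse_error(sprintf("unknown state symbol '%s' (taxon %s, character %d)",
                           intersect(strsplit(cells[bad], "/")[[1L]], unknown)[1L], taxa[i], j))
  }
  if (all(grepl("^[0-9]$", symbols))) {
    state_of <- stats::setNames(as.integer(symbols), symbols)
  } else {
    state_of <- stats::setNames(seq_along(symbols) - 1L, symbols)
  }
  if (is.null(ordered)) ordered <- rep(FALSE, n_char)
  if (length(ordered) != n_char) pf_input_error("ordered flags must have one entry per character")
  if (is.null(is_gap)) is_gap <- matrix(FALSE, length(taxa), n_char)
  if (any(!is.na(cells) & !nzchar(cells))) pf_input_error("empty cell token in character matrix")
  structure(list(taxa = taxa, n_char = n_char, cells = cells,
                 is_gap = is_gap, symbols = symbols, state_of = state_of,
                 ordered = as.logical(ordered)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (%d ordered), symbols {%s}\n",
              length(x$taxa), x$n_char, sum(x$ordered), paste(x$symbols, collapse = "")))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) c(length(x$taxa), x$n_char)

#' Mark characters as ordered
#'
#' Ordered multistate characters are costed linearly (`|i - j|`); the list of
#' ordered characters is supplied by the user (1-based indices) rather than
#' parsed from NEXUS ASSUMPTIONS blocks, whose dialects vary.
#'
#' @param cm a `char_matrix`.
#' @param idx integer vector of 1-based character indices.
#' @return the updated `char_matrix`.
#' @export
set_ordered <- function(cm, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > cm$n_char)) pf_input_error("ordered character index out of range")
  cm$ordered[idx] <- TRUE
  cm
}

# state sets of one character: list over taxa of integer vectors; NULL for
# missing (interpreted as the full state universe)
.char_state_sets <- function(cm, j) {
  tok <- cm$cells[, j]
  lapply(tok, function(t) {
    if (is.na(t)) return(NULL)
    unname(cm$state_of[strsplit(t, "/", fixed = TRUE)[[1L]]])
  })
}

.char_universe <- function(sets) sort(unique(unlist(sets)))

#' Read a character matrix from a NEXUS DATA/CHARACTERS block
#'
#' Uses [ape::read.nexus.data()] for the MATRIX body (interleaved or flat),
#' then validates declared dimensions, row lengths and state symbols against
#' the FORMAT line, and converts cells: `?` to missing (full state universe
#' downstream), `{..}`/`(..)` polymorphisms to state sets, the gap symbol to
#' missing (recorded in `is_gap`).
#'
#' @param path path to a NEXUS file.
#' @param ordered optional 1-based indices of ordered characters.
#' @return a `char_matrix`.
#' @export
read_nexus_matrix <- function(path, ordered = NULL) {
  if (!file.exists(path)) pf_input_error(paste0("file not found: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  up <- toupper(txt)
  ntax <- .nexus_dim(up, "NTAX")
  nchar_ <- .nexus_dim(up, "NCHAR")
  fmt <- regmatches(up, regexpr("FORMAT[^;]*;", up))
  sym <- NULL
  missing_sym <- "?"
  gap_sym <- "-"
  if (length(fmt)) {
    m <- regmatches(fmt, regexpr("SYMBOLS\\s*=\\s*\"[^\"]*\"", fmt))
    if (length(m)) sym <- strsplit(gsub("\\s", "", sub(".*\"([^\"]*)\".*", "\\1", m)), "")[[1L]]
    m <- regmatches(fmt, regexpr("MISSING\\s*=\\s*\\S", fmt))
    if (length(m)) missing_sym <- substring(m, nchar(m))
    m <- regmatches(fmt, regexpr("GAP\\s*=\\s*\\S", fmt))
    if (length(m)) gap_sym <- substring(m, nchar(m))
  }
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) {
                    pf_parse_error(paste0(path, ": declared NTAX/NCHAR inconsistent with the MATRIX body, or malformed block (",
                                          conditionMessage(e), ")"))
                  })
  if (!is.na(ntax) && length(dat) != ntax) {
    pf_parse_error(sprintf("%s: NTAX=%d declared but %d taxa in matrix body", path, ntax, length(dat)))
  }
  lens <- vapply(dat, length, 0L)
  if (is.na(nchar_)) nchar_ <- lens[1L]
  bad <- names(dat)[lens != nchar_]
  if (length(bad)) {
    pf_parse_error(sprintf("%s: row for taxon %s has %d characters, NCHAR=%d declared",
                           path, bad[1L], lens[names(dat) == bad[1L]][1L], nchar_))
  }
  cells <- matrix(NA_character_, length(dat), nchar_)
  gap <- matrix(FALSE, length(dat), nchar_)
  for (i in seq_along(dat)) {
    tok <- toupper(dat[[i]])
    is_miss <- tok == toupper(missing_sym) | tok == "?"
    is_gap_i <- tok == gap_sym | tok == "-"
    tok[is_miss | is_gap_i] <- NA_character_
    cells[i, ] <- tok
    gap[i, ] <- is_gap_i
  }
  cm <- char_matrix(names(dat), cells, symbols = sym, is_gap = gap)
  if (!is.null(ordered)) cm <- set_ordered(cm, ordered)
  cm
}

.nexus_dim <- function(up, key) {
  m <- regmatches(up, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), up))
  if (!length(m)) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

#' Write a character matrix as a NEXUS file
#'
#' Writes a flat (non-interleaved) DATA block; polymorphic cells are written
#' as `{..}`, missing cells as `?`, gap cells as `-`.
#'
#' @param cm a `char_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(cm, path) {
  rows <- vapply(seq_along(cm$taxa), function(i) {
    tok <- cm$cells[i, ]
    out <- ifelse(is.na(tok), ifelse(cm$is_gap[i, ], "-", "?"),
                  ifelse(grepl("/", tok, fixed = TRUE),
                         paste0("{", gsub("/", "", tok, fixed = TRUE), "}"), tok))
    paste0(format(cm$taxa[i], width = max(nchar(cm$taxa)) + 2L), paste(out, collapse = ""))
  }, "")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(cm$taxa), cm$n_char),
               sprintf("FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;", paste(cm$symbols, collapse = "")),
               "MATRIX", rows, ";", "END;"), path)
  invisible(path)
}
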