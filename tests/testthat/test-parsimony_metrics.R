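balanced <- parse_newick("((A,B),(C,D));")
taxa4 <- c("A", "B", "C", "D")

test_that("character length matches hand-enumerated toy cases", {
  cm <- char_matrix(taxa4, matrix(c("0", "1", "0", "1"), 4L))
  expect_equal(character_length(balanced, cm, 1L), 2)

  cherry <- parse_newick("(A,B);")
  cm02 <- char_matrix(c("A", "B"), matrix(c("0", "2"), 2L), symbols = c("0", "1", "2"))
  expect_equal(character_length(cherry, cm02, 1L), 1)        # unordered
  expect_equal(character_length(cherry, set_ordered(cm02, 1L), 1L), 2)  # ordered

  star <- parse_newick("(A,B,C,D);")
  cm_star <- char_matrix(taxa4, matrix(c("0", "0", "1", "2"), 4L))
  expect_equal(character_length(star, cm_star, 1L), 2)

  # missing and polymorphism relax the optimum
  cm_poly <- char_matrix(taxa4, matrix(c("0/1", "1", NA, "0"), 4L),
                         symbols = c("0", "1"))
  sets <- .char_state_sets(cm_poly, 1L)
  expect_equal(character_length(balanced, cm_poly, 1L),
               brute_char_length(balanced, sets, 0:1, FALSE))

  # all-missing and constant characters cost nothing
  cm_na <- char_matrix(taxa4, matrix(NA_character_, 4L, 1L), symbols = "0")
  expect_equal(character_length(balanced, cm_na, 1L), 0)
  cm_const <- char_matrix(taxa4, matrix("1", 4L, 1L))
  expect_equal(character_length(balanced, cm_const, 1L), 0)
})

test_that("tree length is additive over characters", {
  cm <- char_matrix(taxa4, matrix(c("0", "1", "0", "1",
                                    "0", "0", "1", "1"), 4L))
  expect_equal(tree_length(balanced, cm), 3)
  cm_const <- char_matrix(taxa4, matrix("0", 4L, 3L))
  expect_equal(tree_length(balanced, cm_const), 0)
})

test_that("per-character minima handle polymorphism and ordering", {
  cm <- char_matrix(c("A", "B", "C"), matrix(c("0", "1", "2"), 3L))
  expect_equal(char_min_steps(cm, 1L), 2)
  cm_poly <- char_matrix(c("A", "B"), matrix(c("0", "0/1"), 2L))
  expect_equal(char_min_steps(cm_poly, 1L), 0)
  cm_ord <- set_ordered(char_matrix(c("A", "B"), matrix(c("0", "3"), 2L),
                                    symbols = as.character(0:3)), 1L)
  expect_equal(char_min_steps(cm_ord, 1L), 3)
})

test_that("per-character maxima equal exact star-tree evaluation", {
  cm <- char_matrix(paste0("t", 1:6),
                    matrix(c("0", "0", "0", "1", "1", "2"), 6L))
  expect_equal(char_max_steps(cm, 1L), 3)   # 6 taxa minus 3 in the majority state
  cm_ord <- set_ordered(char_matrix(c("A", "B", "C"), matrix(c("0", "1", "3"), 3L),
                                    symbols = as.character(0:3)), 1L)
  expect_equal(char_max_steps(cm_ord, 1L), 3)  # root at 1: 1 + 0 + 2
  cm_const <- char_matrix(taxa4, matrix("1", 4L, 1L))
  expect_equal(char_max_steps(cm_const, 1L), 0)
})

test_that("ensemble fit indices assemble from per-character s, m, g", {
  cm <- char_matrix(taxa4, matrix(c("0", "1", "0", "1",
                                    "0", "0", "1", "1"), 4L))
  fit <- tree_fit_indices(balanced, cm)
  expect_equal(fit$length, 3)
  expect_equal(fit$CI, 2 / 3)
  expect_equal(fit$RI, 0.5)
  expect_equal(fit$HI, 1 / 3)
  expect_equal(fit$RC, fit$CI * fit$RI)
  expect_equal(fit$per_character$s, c(2, 1))
  expect_equal(fit$per_character$m, c(1, 1))
  expect_equal(fit$per_character$g, c(2, 2))

  # clean matrix: no homoplasy
  clean <- char_matrix(taxa4, matrix(c("0", "0", "1", "1"), 4L))
  fit2 <- tree_fit_indices(balanced, clean)
  expect_equal(fit2$CI, 1)
  expect_equal(fit2$RI, 1)
  expect_equal(fit2$HI, 0)

  # maximally homoplastic informative character: RI = 0
  anti <- char_matrix(taxa4, matrix(c("0", "1", "0", "1"), 4L))
  expect_equal(tree_fit_indices(balanced, anti)$RI, 0)

  # uninformative characters: excluded from RI; CI exclusion behind the flag
  mix <- char_matrix(taxa4, matrix(c("0", "1", "0", "1",
                                     "0", "0", "0", "1"), 4L))
  with_u <- tree_fit_indices(balanced, mix)
  without_u <- tree_fit_indices(balanced, mix, exclude_uninformative = TRUE)
  expect_equal(with_u$length, without_u$length)
  expect_equal(with_u$CI, 2 / 3)       # (1 + 1) / (2 + 1)
  expect_equal(without_u$CI, 1 / 2)    # autapomorphy dropped from both sums
  expect_equal(with_u$RI, without_u$RI)
})

test_that("unambiguous synapomorphies follow the constrained-branch rule", {
  # basal cherry: the single change can sit on either root-adjacent branch,
  # so no reconstruction-proof synapomorphy exists (enumeration oracle agrees)
  cm <- char_matrix(taxa4, matrix(c("0", "0", "1", "1"), 4L))
  expect_equal(nrow(unambiguous_synapomorphies(balanced, cm, c("C", "D"))), 0L)

  # an outgroup pins the root side: the change becomes unambiguous
  tr5 <- parse_newick("(O,((A,B),(C,D)));")
  cm5 <- char_matrix(c("O", taxa4), matrix(c("0", "0", "0", "1", "1"), 5L))
  syn <- unambiguous_synapomorphies(tr5, cm5, c("C", "D"))
  expect_equal(syn$char, 1L)
  expect_equal(syn$state, "1")

  # homoplastic character: optimal reconstructions disagree
  cm_h <- char_matrix(c("O", taxa4), matrix(c("0", "0", "1", "0", "1"), 5L))
  expect_equal(nrow(unambiguous_synapomorphies(tr5, cm_h, c("C", "D"))), 0L)

  # constant characters support nothing
  cm_c <- char_matrix(c("O", taxa4), matrix("0", 5L, 1L))
  expect_equal(nrow(unambiguous_synapomorphies(tr5, cm_c, c("C", "D"))), 0L)

  expect_error(unambiguous_synapomorphies(tr5, cm5, length(tr5$tip.label) + 1L),
               "root", class = "paleofit_input_error")
})

test_that("synapomorphy detection agrees with labeling enumeration", {
  withr::with_seed(31, {
    for (i in 1:60) {
      n <- sample(4:6, 1L)
      tr <- random_binary_tree(n)
      sets <- random_char_sets(n, sample(2:3, 1L))
      uni <- .char_universe(sets)
      if (length(uni) < 2L) next
      ordered <- runif(1) < 0.3
      cm <- sets_to_char_matrix(tr$tip.label, sets, ordered = ordered)
      non_root <- setdiff(seq(n + 2L, n + tr$Nnode), integer(0))
      if (!length(non_root)) next
      nd <- sample(non_root, 1L)
      expect_equal(nrow(unambiguous_synapomorphies(tr, cm, nd)) > 0L,
                   brute_unambiguous(tr, sets, uni, ordered, nd))
    }
  })
})

test_that("Sankoff DP equals exhaustive enumeration on random instances", {
  withr::with_seed(23, {
    for (i in 1:400) {
      n <- sample(3:6, 1L)
      tr <- if (runif(1) < 0.3) random_polytomous_tree(n) else random_binary_tree(n)
      k <- sample(2:4, 1L)
      sets <- random_char_sets(n, k)
      ordered <- runif(1) < 0.5
      cm <- sets_to_char_matrix(tr$tip.label, sets, ordered = ordered)
      expect_equal(character_length(tr, cm, 1L),
                   brute_char_length(tr, sets, 0:(k - 1L), ordered))
    }
  })
})

test_that("DP agrees with phangorn on clean matrices (independent route)", {
  skip_if_not_installed("phangorn")
  withr::with_seed(29, {
    for (i in 1:25) {
      n <- sample(5:10, 1L)
      tr <- random_binary_tree(n)
      k <- sample(2:4, 1L)
      mat <- matrix(sample(0:(k - 1L), n * 8L, replace = TRUE), n, 8L)
      cm <- char_matrix(tr$tip.label, matrix(as.character(mat), n, 8L),
                        symbols = as.character(0:(k - 1L)))
      matc <- matrix(as.character(mat), n, 8L,
                     dimnames = list(tr$tip.label, NULL))
      pd <- phangorn::phyDat(matc, type = "USER",
                             levels = as.character(0:(k - 1L)))
      expect_equal(tree_length(tr, cm),
                   as.numeric(phangorn::parsimony(tr, pd, method = "fitch")))
      # ordered costs via phangorn's sankoff with a linear step matrix
      cmo <- set_ordered(cm, seq_len(8L))
      cost <- abs(outer(0:(k - 1L), 0:(k - 1L), "-"))
      dimnames(cost) <- list(as.character(0:(k - 1L)), as.character(0:(k - 1L)))
      expect_equal(tree_length(tr, cmo),
                   as.numeric(phangorn::parsimony(tr, pd, method = "sankoff", cost = cost)))
    }
  })
})

test_that("structural inequalities hold on random instances", {
  withr::with_seed(37, {
    for (i in 1:40) {
      n <- sample(4:8, 1L)
      tr <- random_binary_tree(n)
      k <- sample(2:4, 1L)
      sets <- random_char_sets(n, k)
      cm_u <- sets_to_char_matrix(tr$tip.label, sets, ordered = FALSE)
      cm_o <- sets_to_char_matrix(tr$tip.label, sets, ordered = TRUE)
      s_u <- character_length(tr, cm_u, 1L)
      s_o <- character_length(tr, cm_o, 1L)
      expect_gte(s_o, s_u)  # ordered optimization can never be cheaper
      for (cm in list(cm_u, cm_o)) {
        s <- character_length(tr, cm, 1L)
        m <- char_min_steps(cm, 1L)
        g <- char_max_steps(cm, 1L)
        expect_lte(m, s)
        expect_lte(s, g)
      }
      # collapsing an internal edge (losing resolution) never decreases steps
      if (tr$Nnode > 1L) {
        e <- sample(which(tr$edge[, 2L] > n), 1L)
        tr2 <- ape::compute.brlen(tr, 1)
        tr2$edge.length[e] <- 0
        coll <- ape::di2multi(tr2, tol = 1e-8)
        expect_gte(character_length(coll, cm_u, 1L), s_u)
      }
    }
  })
})
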