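tree_with_supports <- function(txt) read_newick(write_tmp(txt, ".nwk"))

test_that("supported_clades emits both sides above a strict threshold", {
  tr <- tree_with_supports("(((A:1,B:1)0.9:1,C:1)0.5:1,(D:1,E:1)0.4:1,F:1);")
  sc <- supported_clades(tr)
  keys <- vapply(sc$leaves, paste, character(1), collapse = "")
  expect_true("AB" %in% keys)                       # 0.9 > 0.5
  expect_true("CDEF" %in% keys)                     # complement of {A,B}
  expect_false("ABC" %in% keys)                     # exactly 0.5: excluded
  expect_false("DE" %in% keys)                      # 0.4 below threshold
  star <- tree_with_supports("(A:1,B:1,C:1,D:1);")
  expect_error(supported_clades(star), "no branch supports")
})

test_that("consensus requires the clade in every tree", {
  # 8 leaves: the 5-leaf complement of {A,B,C} exceeds the 0.5 cap, so only
  # mid-depth clades are candidates
  t1 <- tree_with_supports(
    "(((A:1,B:1)0.9:1,C:1)0.9:1,(D:1,E:1)0.9:1,(F:1,(G:1,H:1)0.2:1):1);")
  t2 <- tree_with_supports(
    "(((A:1,B:1)0.9:1,C:1)0.9:1,(D:1,E:1)0.8:1,(F:1,(G:1,H:1)0.2:1):1);")
  t3 <- tree_with_supports(
    "(((A:1,B:1)0.9:1,C:1)0.9:1,D:1,(E:1,(F:1,(G:1,H:1)0.2:1)0.9:1):1);")
  part <- consensus_subfamilies(list(t1, t2, t3))
  td <- tidy(part)
  abc <- td$subfamily[td$leaf_id %in% c("A", "B", "C")]
  expect_equal(length(unique(abc)), 1)
  expect_false(unique(abc) == "UNASSIGNED")
  # {D,E} supported in only 2 of 3 trees
  expect_equal(td$subfamily[td$leaf_id == "D"], "UNASSIGNED")
  expect_equal(td$subfamily[td$leaf_id == "F"], "UNASSIGNED")
})

test_that("nested consistent clades resolve to the larger (greedy by size)", {
  txt <- "(((A:1,B:1)0.9:1,C:1)0.9:1,(D:1,E:1)0.2:1,(F:1,(G:1,H:1)0.3:1):1);"
  part <- consensus_subfamilies(list(tree_with_supports(txt),
                                     tree_with_supports(txt)))
  td <- tidy(part)
  expect_equal(unique(td$subfamily[td$leaf_id %in% c("A", "B", "C")]), "SF1")
  # {A,B} is nested inside the selected {A,B,C} and must not appear
  expect_equal(attr(part, "provenance")$size, 3L)
})

test_that("partition invariants hold and long branches stay unassigned", {
  fam <- simulate_family(family_spec(n_subfamilies = 3,
                                     leaves_per_subfamily = 5, length = 300,
                                     within_scale = 0.03, stem_scale = 0.7,
                                     seed = 21), n_replicates = 3)
  trees <- lapply(1:3, function(k) {
    a <- fam$alignments[[k]]
    bootstrap_supports(a, nj_tree(distance_matrix(a)), n = 40, seed = 100 + k)
  })
  part <- consensus_subfamilies(trees)
  expect_setequal(part$leaf_id, fam$truth$leaf_id)          # cover
  expect_equal(anyDuplicated(part$leaf_id), 0L)             # disjoint
  prov <- attr(part, "provenance")
  expect_true(all(prov$size >= 2))
  expect_true(all(prov$min_support > 0.5))
  g <- glance(part)
  expect_equal(g$n_assigned + g$n_unassigned, g$n_leaves)
})

test_that("adding a tree can only shrink or preserve the candidate set", {
  fam <- simulate_family(family_spec(n_subfamilies = 3,
                                     leaves_per_subfamily = 4, length = 250,
                                     seed = 33), n_replicates = 3)
  trees <- lapply(1:3, function(k) {
    a <- fam$alignments[[k]]
    bootstrap_supports(a, nj_tree(distance_matrix(a)), n = 30, seed = 200 + k)
  })
  keys_n <- function(trs) {
    Reduce(intersect, lapply(trs, function(t) supported_clades(t)$key))
  }
  k2 <- keys_n(trees[1:2])
  k3 <- keys_n(trees)
  expect_true(all(k3 %in% k2))
})

test_that("leaf-set mismatch between trees is reported with the difference", {
  t1 <- tree_with_supports("((A:1,B:1)0.9:1,C:1,D:1);")
  t2 <- tree_with_supports("((A:1,B:1)0.9:1,C:1,E:1);")
  expect_error(consensus_subfamilies(list(t1, t2)), "D, E")
})

test_that("assign_query places simulated queries and rejects noise", {
  fam <- simulate_family(family_spec(n_subfamilies = 2,
                                     leaves_per_subfamily = 4, length = 250,
                                     within_scale = 0.05, stem_scale = 0.5,
                                     seed = 12))
  part <- tibble::tibble(leaf_id = fam$truth$leaf_id,
                         subfamily = fam$truth$subfamily)
  class(part) <- c("subfam_partition", class(part))
  attr(part, "provenance") <- tibble::tibble(subfamily = unique(part$subfamily),
                                             size = 4L, min_support = 1)
  reps <- fam$alignment
  # identical to a representative
  q <- fam$sequences$seq[1]
  res <- assign_query(q, reps, part)
  expect_equal(res$subfamily, fam$truth$subfamily[1])
  expect_equal(res$identity, 100)
  # query evolved a bit further from an SF2 member
  set.seed(99)
  chars <- strsplit(fam$sequences$seq[6], "")[[1]]
  idx <- sample(length(chars), 12)
  chars[idx] <- sample(setdiff(subfamkit:::aa_alphabet(), "X"), 12,
                       replace = TRUE)
  res2 <- assign_query(paste(chars, collapse = ""), reps, part)
  expect_equal(res2$subfamily, fam$truth$subfamily[6])
  # random sequence: unassigned
  set.seed(100)
  res3 <- assign_query(random_seq(40), reps, part,
                       scheme = simple_scheme(match = 1, mismatch = -2,
                                              gap_open = 4, gap_extend = 2))
  expect_equal(res3$subfamily, "UNASSIGNED")
})
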