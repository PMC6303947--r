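test_that("find_motif matches wildcard and class patterns", {
  expect_equal(find_motif("GAAGAGAAG", "GXXGXGXXG"), 1L)
  expect_equal(find_motif("PFHP", "PF[HW]P"), 1L)
  expect_equal(find_motif("PFWP", "PF[HW]P"), 1L)
  expect_length(find_motif("PFAP", "PF[HW]P"), 0)
  expect_equal(find_motif("SRSAR", "[ST]R[ST]X[RK]"), 1L)
  # gaps in aligned rows are transparent; positions are on the ungapped seq
  expect_equal(find_motif("--S-RSAR", "[ST]R[ST]X[RK]"), 1L)
  expect_error(motif_pattern("A[ST"), "unclosed")
  expect_error(motif_pattern("A"), "at least 2")
})

test_that("find_motif agrees with the sliding-window oracle, overlaps included", {
  set.seed(15)
  patterns <- c("GXXG", "[ST]R[ST]X[RK]", "AA", "G[AG]G")
  for (i in 1:40) {
    seq <- random_seq(sample(5:50, 1), alphabet = c("A", "G", "S", "T", "R", "K"))
    for (p in patterns) {
      expect_equal(find_motif(seq, p), oracle_motif_positions(seq, p),
                   info = paste(seq, p))
    }
  }
})

# small synthetic alignment in which the reference row is gap-free, so
# reference numbering is the column index
toy_regions <- tibble::tibble(region = "betaB-alphaD", start = 11L,
                              end = 20L, key_position = 13L)

test_that("cofactor preference: aspartate rule, fingerprint rule, fall-through", {
  pad <- function(core) paste0(strrep("A", 10), core, strrep("A", 10))
  aln <- as_alignment(c(
    ref = pad("QQQQQQQQQQ"),
    nadh = pad("QQDQQQQQQQ"),        # D at reference 13
    nadph = pad("QTRSAKQQQQ"),       # [ST]R[ST]X[RK] inside the loop
    neither = pad("QQQQQQQQQQ"),
    gapped = paste0(strrep("A", 10), strrep("-", 10), strrep("A", 10))
  ))
  rm <- reference_numbering(aln, "ref")
  get <- function(id) cofactor_preference(id, rm, toy_regions, aln = aln)
  expect_equal(get("nadh")$call, "NADH")
  expect_equal(get("nadph")$call, "NADPH")
  expect_equal(get("neither")$call, "ambiguous")
  g <- get("gapped")
  expect_equal(g$call, "ambiguous")
  expect_equal(g$evidence, "no-coverage")
  # both signals present: conflict flag
  both <- as_alignment(c(ref = pad("QQQQQQQQQQ"), x = pad("TRSAKQQDQQ")))
  rm2 <- reference_numbering(both, "ref")
  b <- cofactor_preference("x", rm2,
                           tibble::tibble(region = "betaB-alphaD",
                                          start = 11L, end = 20L,
                                          key_position = 18L), aln = both)
  expect_equal(b$call, "ambiguous")
  expect_true(b$conflict)
})

test_that("cofactor calls are 100% correct on motif-injected subfamilies", {
  fam <- simulate_family(family_spec(n_subfamilies = 4,
                                     leaves_per_subfamily = 5, length = 300,
                                     seed = 61))
  aln <- fam$alignment
  rm <- reference_numbering(aln, aln_ids(aln)[1])  # gap-free: identity map
  regions <- tibble::tibble(region = "betaB-alphaD", start = 98L, end = 108L,
                            key_position = 103L)
  calls <- vapply(aln_ids(aln), function(id)
    cofactor_preference(id, rm, regions, aln = aln)$call, character(1))
  truth_call <- ifelse(as.integer(sub("SF(\\d+)_.*", "\\1",
                                      fam$truth$leaf_id)) %% 2 == 1,
                       "NADH", "NADPH")
  expect_equal(unname(calls[fam$truth$leaf_id]), truth_call)
})

test_that("triad check labels canonical residues and known substitutions", {
  L <- 300
  base <- strrep("A", L)
  set_at <- function(s, pos, res) {
    for (i in seq_along(pos)) substr(s, pos[i], pos[i]) <- res[i]
    s
  }
  canonical <- set_at(base, c(230, 259, 277), c("R", "E", "H"))
  fdh <- set_at(base, c(230, 259, 277), c("R", "Q", "H"))
  x4 <- set_at(base, c(230, 259, 277), c("R", "V", "W"))
  aln <- as_alignment(c(ref = canonical, canonical = canonical,
                        fdh = fdh, x4 = x4))
  rm <- reference_numbering(aln, "ref")
  tri <- function(id) triad_check(id, rm, aln = aln)
  t1 <- tri("canonical")
  expect_true(all(t1$canonical[t1$role == "catalytic triad"]))
  t2 <- tri("fdh")
  expect_equal(t2$label[t2$position == 259], "FDH-like")
  t3 <- tri("x4")
  expect_equal(t3$label[t3$position == 277],
               "X4-like, catalysis questionable")
  expect_equal(t3$label[t3$position == 259], "non-canonical")
  # exactly one entry per queried position
  expect_equal(nrow(t1), 9)
  expect_equal(anyDuplicated(t1$position), 0L)
  # gap reported as gap
  gapped <- as_alignment(c(ref = canonical,
                           g = set_at(canonical, 230, "-")))
  tg <- triad_check("g", reference_numbering(gapped, "ref"), aln = gapped)
  expect_equal(tg$observed[tg$position == 230], "gap")
})

test_that("conserved_scan applies the strict > 90% rule", {
  aln <- as_alignment(setNames(
    c(rep("GDA", 19), "GCA"),
    paste0("s", 1:20)))
  prof <- conservation(aln)
  hits <- conserved_scan(prof, 0.9)
  expect_true(1 %in% hits$column)          # 100% G
  expect_true(2 %in% hits$column)          # 95% D
  # exactly 90%: 18/20
  aln2 <- as_alignment(setNames(c(rep("D", 18), "C", "C"), paste0("t", 1:20)))
  expect_equal(nrow(conserved_scan(conservation(aln2), 0.9)), 0)
  # fully gapped column never reported
  aln3 <- as_alignment(c(a = "-A", b = "-A", c = "-A"))
  expect_false(1 %in% conserved_scan(conservation(aln3), 0.5)$column)
})
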