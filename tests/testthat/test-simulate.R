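no_motifs <- tibble::tibble(subfamily = character(), start = integer(),
                            instance = character())

test_that("zero within-subfamily scale gives identical subfamily members", {
  spec <- family_spec(n_subfamilies = 2, leaves_per_subfamily = 3,
                      length = 150, within_scale = 0, stem_scale = 0.5,
                      invariant_columns = c(`10` = "G"), motifs = no_motifs,
                      seed = 3)
  fam <- simulate_family(spec)
  for (sf in unique(fam$truth$subfamily)) {
    seqs <- fam$sequences$seq[fam$truth$subfamily == sf]
    expect_equal(length(unique(seqs)), 1)
  }
  # invariant column held everywhere
  expect_true(all(substr(fam$sequences$seq, 10, 10) == "G"))
  # stems separate the two subfamilies
  expect_gt(length(unique(fam$sequences$seq)), 1)
})

test_that("same seed reproduces the family exactly; replicates differ", {
  spec <- family_spec(n_subfamilies = 2, leaves_per_subfamily = 3,
                      length = 200, seed = 17)
  f1 <- simulate_family(spec)
  f2 <- simulate_family(spec)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  f3 <- simulate_family(spec, n_replicates = 2)
  expect_identical(unclass(f3$alignments[[1]]), unclass(f1$alignment))
  expect_false(identical(unclass(f3$alignments[[1]]),
                         unclass(f3$alignments[[2]])))
})

test_that("pairwise p-distance matches the substitution process closed form", {
  # cherries at within_scale w: leaf-to-leaf path 2w;
  # P(differ) = (19/20)(1 - exp(-(20/19) * 2w)) exactly under the process
  w <- 0.1
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 2 * w))
  obs <- vapply(1:100, function(r) {
    spec <- family_spec(n_subfamilies = 2, leaves_per_subfamily = 2,
                        length = 200, within_scale = w, stem_scale = 0.3,
                        invariant_columns = setNames(character(), character()),
                        motifs = no_motifs, seed = 1000 + r)
    fam <- simulate_family(spec)
    a <- strsplit(fam$sequences$seq[fam$truth$subfamily == "SF1"][1], "")[[1]]
    b <- strsplit(fam$sequences$seq[fam$truth$subfamily == "SF1"][2], "")[[1]]
    mean(a != b)
  }, numeric(1))
  se <- sqrt(p_exp * (1 - p_exp) / (200 * 100))
  expect_lt(abs(mean(obs) - p_exp), 5 * se)
})

test_that("impossible specs are rejected", {
  expect_error(family_spec(length = 100,
                           invariant_columns = c(`10` = "G"),
                           motifs = tibble::tibble(subfamily = "SF1",
                                                   start = 98L,
                                                   instance = "SRSAR")),
               "beyond the sequence")
  expect_error(family_spec(invariant_columns = c(`103` = "D")),
               "disjoint")
  expect_error(family_spec(n_subfamilies = 1, leaves_per_subfamily = 2),
               "at least 4")
})

test_that("simulate_kinetics: point-mass law, planted missingness, lognormal medians", {
  truth <- tibble::tibble(leaf_id = paste0("E", 1:10),
                          subfamily = rep(c("SF1", "SF2"), each = 5))
  point <- tibble::tibble(subfamily = c("SF1", "SF2"), substrate = "S",
                          median_efficiency = 1e5, sdlog = 0,
                          median_km_uM = 100)
  k1 <- simulate_kinetics(truth, point, seed = 2)
  expect_equal(glance(family_summary(k1))$median_best_efficiency, 1e5)

  # 7 enzymes with efficiency, 3 with an accepted substrate but no numbers
  t2 <- tibble::tibble(leaf_id = paste0("E", 1:10),
                       subfamily = rep(c("has", "lacks"), c(7, 3)))
  law2 <- tibble::tibble(subfamily = c("has", "lacks"), substrate = "S",
                         median_efficiency = c(1e5, NA), sdlog = 0,
                         median_km_uM = 100)
  k2 <- simulate_kinetics(t2, law2, seed = 2)
  expect_equal(glance(family_summary(k2))$n_pairs_with_efficiency, 7)

  # log-normal law: sample median within a few standard errors
  big <- tibble::tibble(leaf_id = paste0("E", 1:400), subfamily = "SF1")
  law3 <- tibble::tibble(subfamily = "SF1", substrate = "S",
                         median_efficiency = 2e5, sdlog = 0.5,
                         median_km_uM = 300)
  k3 <- simulate_kinetics(big, law3, seed = 9)
  med <- median(k3$kcat_over_km_per_M_per_s)
  expect_lt(abs(log(med) - log(2e5)), 3 * 0.5 * sqrt(pi / (2 * 400)))
  # unit consistency of generated rows
  expect_equal(k3$kcat_per_s / (k3$km_uM * 1e-6),
               k3$kcat_over_km_per_M_per_s, tolerance = 1e-9)
})

test_that("simulate_complex edge cases: empty map and exact-boundary residue", {
  cx0 <- simulate_complex(0, radius = 5, seed = 1, n_noncontacts = 0)
  cm0 <- substrate_contacts(cx0$model, cx0$ligand, radius = 5)
  expect_equal(nrow(cm0), 0)
  cx1 <- simulate_complex(1, radius = 5, seed = 1)
  cm1 <- substrate_contacts(cx1$model, cx1$ligand, radius = 5)
  expect_equal(cm1$min_dist, 5)  # placed exactly at the radius, included
})

test_that("injected gappy columns are exactly what trimming removes", {
  fam <- simulate_family(family_spec(n_subfamilies = 2,
                                     leaves_per_subfamily = 5, length = 220,
                                     seed = 14))
  gapped <- inject_gaps(fam$alignment, n_columns = 8, gap_fraction = 0.9,
                        seed = 2)
  expect_equal(aln_ncol(gapped), 228)
  trimmed <- trim_columns(gapped, 0.8)
  expect_equal(removed_columns(trimmed), attr(gapped, "injected_columns"))
  expect_equal(unclass(trimmed), unclass(fam$alignment), ignore_attr = TRUE)
})

test_that("support degrades as within-subfamily scale approaches the stem scale", {
  min_planted_support <- function(w) {
    spec <- family_spec(n_subfamilies = 3, leaves_per_subfamily = 4,
                        length = 250, within_scale = w, stem_scale = 0.6,
                        seed = 5)
    fam <- simulate_family(spec)
    a <- fam$alignment
    bt <- bootstrap_supports(a, nj_tree(distance_matrix(a)), n = 40, seed = 6)
    bp <- bipartitions(bt)
    vapply(unique(fam$truth$subfamily), function(sf) {
      members <- fam$truth$leaf_id[fam$truth$subfamily == sf]
      hit <- vapply(bp$tips, function(x) setequal(x, members) ||
                      setequal(x, setdiff(fam$truth$leaf_id, members)),
                    logical(1))
      if (any(hit)) max(bp$support[hit]) else 0
    }, numeric(1)) |> min()
  }
  s <- vapply(c(0.05, 0.3, 0.6), min_planted_support, numeric(1))
  expect_true(s[1] >= s[3])  # trend over the grid
  expect_equal(s[1], 1.0)
})
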