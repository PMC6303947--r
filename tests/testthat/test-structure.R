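make_model <- function(atoms) {
  structure(list(structure_id = "toy", atoms = atoms),
            class = "structure_model")
}

toy_atom <- function(record = "ATOM", atom = "CA", resname = "ALA",
                     chain = "A", resno = 1L, x = 0, y = 0, z = 0,
                     element = "C", het = identical(record, "HETATM")) {
  tibble::tibble(record = record, serial = NA_integer_, atom = atom,
                 altloc = "", resname = resname, chain = chain,
                 resno = as.integer(resno), ins = "", x = x, y = y, z = z,
                 occ = 1, element = element, het = het,
                 is_water = resname == "HOH",
                 is_hydrogen = element %in% c("H", "D"))
}

test_that("ligand classification: cofactors, exclusions, candidates", {
  m <- make_model(dplyr::bind_rows(
    toy_atom(),
    toy_atom("HETATM", "C1", "NAD", resno = 2),
    toy_atom("HETATM", "C1", "LAC", resno = 3),
    toy_atom("HETATM", "O", "HOH", resno = 4, element = "O"),
    toy_atom("HETATM", "S", "SO4", resno = 5, element = "S")
  ))
  cls <- classify_ligands(m)
  expect_equal(cls$role[cls$resname == "NAD"], "cofactor")
  expect_equal(cls$role[cls$resname == "LAC"], "candidate_substrate")
  expect_equal(cls$role[cls$resname == "HOH"], "excluded")
  expect_equal(cls$role[cls$resname == "SO4"], "excluded")
})

test_that("contacts respect the inclusive 5 A boundary and skip hydrogens", {
  m <- make_model(dplyr::bind_rows(
    toy_atom(resno = 1, z = 4.9),
    toy_atom(resno = 2, z = 5.1),
    toy_atom(resno = 3, z = 5.0),
    toy_atom(atom = "H", resno = 2, z = 1, element = "H"),
    toy_atom("HETATM", "C1", "LIG", resno = 9)
  ))
  cm <- substrate_contacts(m, list(chain = "A", resno = 9), radius = 5)
  expect_setequal(cm$resno, c(1L, 3L))
  expect_equal(cm$min_dist[cm$resno == 1], 4.9)
  expect_equal(cm$min_dist[cm$resno == 3], 5.0)
  expect_error(substrate_contacts(m, list(chain = "A", resno = 99)),
               "no heavy atoms")
})

test_that("contacts match the all-pairs oracle on simulated complexes", {
  for (seed in 1:15) {
    n <- sample(0:6, 1)
    cx <- simulate_complex(n, radius = 5, seed = seed)
    cm <- substrate_contacts(cx$model, cx$ligand, radius = 5)
    orc <- oracle_contacts(cx$model, cx$ligand, 5)
    expect_equal(nrow(cm), nrow(orc))
    expect_equal(sort(cm$resno), cx$expected$resno)
    expect_equal(cm$min_dist[order(cm$resno)], cx$expected$dist,
                 tolerance = 1e-9)
  }
})

test_that("contact sets are invariant under rigid-body motion and radius monotone", {
  cx <- simulate_complex(5, radius = 5, seed = 77)
  cm0 <- substrate_contacts(cx$model, cx$ligand, radius = 5)
  # rotate about z by 35 deg and translate
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(cx$model$atoms[, c("x", "y", "z")]) %*% t(R)
  m2 <- cx$model
  m2$atoms$x <- xyz[, 1] + 10
  m2$atoms$y <- xyz[, 2] - 4
  m2$atoms$z <- xyz[, 3] + 2.5
  cm1 <- substrate_contacts(m2, cx$ligand, radius = 5)
  expect_equal(sort(cm1$resno), sort(cm0$resno))
  expect_equal(cm1$min_dist[order(cm1$resno)],
               cm0$min_dist[order(cm0$resno)], tolerance = 1e-9)
  # shrinking the radius never adds contacts
  cm_small <- substrate_contacts(cx$model, cx$ligand, radius = 3)
  expect_true(all(cm_small$resno %in% cm0$resno))
})

test_that("other-subunit contacts are flagged", {
  m <- make_model(dplyr::bind_rows(
    toy_atom(chain = "A", resno = 1, z = 3),
    toy_atom(chain = "B", resno = 7, z = -3),
    toy_atom("HETATM", "C1", "LIG", chain = "A", resno = 9)
  ))
  cm <- substrate_contacts(m, list(chain = "A", resno = 9))
  expect_false(cm$other_subunit[cm$chain == "A"])
  expect_true(cm$other_subunit[cm$chain == "B"])
})

test_that("complex states follow the redox pairing rule", {
  rx <- redox_table()
  lig <- function(...) {
    codes <- c(...)
    tibble::tibble(chain = "A", resno = seq_along(codes), ins = "",
                   resname = codes,
                   role = ifelse(codes %in% default_cofactor_codes(),
                                 "cofactor",
                                 ifelse(codes %in% default_exclude_codes(),
                                        "excluded", "candidate_substrate")))
  }
  expect_equal(complex_state(lig("NAI", "LAC"), rx)$state, "true_ternary")
  expect_equal(complex_state(lig("NAD", "LAC"), rx)$state, "ternary")
  expect_equal(complex_state(lig("NAD"), rx)$state, "binary")
  expect_equal(complex_state(lig("HOH"), rx)$state, "apo")
  unk <- complex_state(lig("NAD", "ZZZ"), rx)
  expect_equal(unk$state, "ternary")
  expect_match(unk$note, "unknown")
})

test_that("contacts project onto regions through the reference map", {
  # reference row gap-free, so column = reference number
  L <- 100
  aln <- as_alignment(c(ref = strrep("A", L), chainrow = strrep("A", L)))
  rm <- reference_numbering(aln, "ref")
  regions <- tibble::tibble(region = c("beta4-alpha4", "alpha5"),
                            start = c(70L, 90L), end = c(78L, 95L))
  m <- make_model(dplyr::bind_rows(
    toy_atom(chain = "A", resno = 73, z = 3),
    toy_atom(chain = "A", resno = 85, z = 3.5),
    toy_atom(chain = "B", resno = 91, z = -3),
    toy_atom(chain = "C", resno = 5, z = 2),   # unmapped chain
    toy_atom("HETATM", "C1", "LIG", chain = "A", resno = 900)
  ))
  cm <- substrate_contacts(m, list(chain = "A", resno = 900))
  chain_map <- tibble::tibble(chain = c("A", "B"),
                              row_id = c("chainrow", "chainrow"))
  counts <- contacts_to_regions(cm, aln, rm, regions, chain_map)
  detail <- attr(counts, "detail")
  expect_equal(detail$region[detail$resno == 73], "beta4-alpha4")
  expect_equal(detail$region[detail$resno == 85], "outside named regions")
  expect_equal(detail$region[detail$resno == 91], "alpha5'")  # partner chain
  expect_equal(detail$region[detail$resno == 5], "unmapped")
  expect_equal(sum(counts$n_contacts), nrow(cm))
})
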