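#' Specification of a synthetic protein family
#'
#' Describes a planted family used to give every pipeline stage ground
#' truth: a star of subfamily stems (length `stem_scale` substitutions/site)
#' each carrying a random binary subtree whose edges all have length
#' `within_scale`; site-wise amino-acid substitution under a 20-state
#' symmetric (Poisson-style) process; a set of near-invariant "catalytic"
#' columns that are never substituted; and per-subfamily motif injections
#' (diagnostic fingerprint strings written into fixed columns at each
#' subfamily root and held fixed below it).
#'
#' Defaults emulate a family of 6 subfamilies of 8 members over 300
#' columns, strongly separated stems (0.8) with shallow within-subfamily
#' divergence (0.05), four invariant active-site columns, and alternating
#' cofactor fingerprints (aspartate vs the NADPH motif instance `SRSAR`)
#' around column 101.
#'
#' @param n_subfamilies,leaves_per_subfamily Family shape.
#' @param length Sequence length (columns).
#' @param within_scale,stem_scale Branch lengths in substitutions/site.
#' @param invariant_columns Named character vector: names are column
#'   indices, values single residues.
#' @param motifs Tibble with columns `subfamily`, `start`, `instance`:
#'   the instance string is written at the given columns at that
#'   subfamily's root.
#' @param seed Integer seed.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_subfamilies = 6, leaves_per_subfamily = 8,
                        length = 300, within_scale = 0.05, stem_scale = 0.8,
                        invariant_columns = c(`50` = "G", `120` = "R",
                                              `150` = "E", `200` = "H"),
                        motifs = NULL, seed = 42L) {
  if (is.null(motifs)) {
    motifs <- purrr::map_dfr(seq_len(n_subfamilies), function(i) {
      if (i %% 2 == 1) {
        tibble(subfamily = paste0("SF", i), start = 103L, instance = "D")
      } else {
        tibble(subfamily = paste0("SF", i), start = 101L, instance = "SRSAR")
      }
    })
  }
  spec <- list(n_subfamilies = n_subfamilies,
               leaves_per_subfamily = leaves_per_subfamily,
               length = length, within_scale = within_scale,
               stem_scale = stem_scale,
               invariant_columns = invariant_columns,
               motifs = motifs, seed = as.integer(seed))
  validate_family_spec(spec)
  spec
}

validate_family_spec <- function(spec) {
  if (spec$n_subfamilies * spec$leaves_per_subfamily < 4) {
    abort("need at least 4 leaves in total")
  }
  if (spec$within_scale < 0 || spec$stem_scale < 0) {
    abort("branch scales must be non-negative")
  }
  inv_cols <- as.integer(names(spec$invariant_columns))
  if (any(inv_cols < 1 | inv_cols > spec$length)) {
    abort("invariant column outside sequence")
  }
  motif_cols <- unlist(purrr::map2(spec$motifs$start,
                                   nchar(spec$motifs$instance),
                                   function(s, w) s:(s + w - 1)))
  if (any(motif_cols > spec$length)) {
    abort("motif extends beyond the sequence (motif longer than its region)")
  }
  if (length(intersect(inv_cols, motif_cols))) {
    abort("invariant and motif columns must be disjoint")
  }
  invisible(spec)
}

# P(residue changes) over a branch of length t under the 20-state symmetric
# process with one expected substitution event per site per unit length;
# aggregated Markov transition, exact for any t.
p_change <- function(t) (19 / 20) * (1 - exp(-(20 / 19) * t))

mutate_seq <- function(chars, t, frozen, alphabet) {
  if (t <= 0) return(chars)
  free <- setdiff(seq_along(chars), frozen)
  hit <- free[runif(length(free)) < p_change(t)]
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  }
  chars
}

#' Simulate a planted protein family
#'
#' Generates the family described by a [family_spec()]: the true tree (a
#' star of subfamily stems, each a random binary subtree), ungapped
#' sequences evolved site-wise along it, and the subfamily truth map. The
#' alignment of the output is trivially the identity (no indels are
#' simulated), so downstream stages can be scored against exact truth.
#' Reproducible given the spec's seed.
#'
#' When `n_replicates > 1`, additional independent sequence realisations are
#' evolved along the *same* planted tree (the analogue of independent data
#' underlying independently inferred trees of the same proteins); each
#' replicate uses a seed derived deterministically from the spec's seed.
#'
#' @param spec A [family_spec()].
#' @param n_replicates Number of independent sequence realisations
#'   (default 1).
#' @return A list: `tree` (phylo), `sequences` (tibble id/seq, first
#'   replicate), `alignment` (`subfam_aln`, first replicate), `alignments`
#'   (list of all replicates), `truth` (tibble leaf_id/subfamily), `spec`.
#' @export
simulate_family <- function(spec = family_spec(), n_replicates = 1L) {
  validate_family_spec(spec)
  ab <- setdiff(aa_alphabet(), "X")
  with_local_seed(spec$seed, {
    subtrees <- lapply(seq_len(spec$n_subfamilies), function(i) {
      k <- spec$leaves_per_subfamily
      labels <- sprintf("SF%d_%02d", i, seq_len(k))
      if (k == 1) return(sprintf("%s:%.10g", labels, spec$within_scale))
      tr <- ape::rtree(k, rooted = TRUE, tip.label = labels, br = NULL)
      tr$edge.length <- rep(spec$within_scale, nrow(tr$edge))
      sub(";$", "", ape::write.tree(tr))
    })
    nwk <- sprintf("(%s);", paste(sprintf("%s:%.10g", unlist(subtrees),
                                          spec$stem_scale), collapse = ","))
    tree <- ape::read.tree(text = nwk)
  })
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  sf_children <- tree$edge[tree$edge[, 1] == root, 2]
  sf_of_node <- rep(NA_integer_, ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    sf_of_node[child] <- if (parent == root) match(child, sf_children) else
      sf_of_node[parent]
  }
  truth <- tibble(leaf_id = tree$tip.label,
                  subfamily = paste0("SF", sf_of_node[seq_len(ntip)]))
  alignments <- lapply(seq_len(n_replicates), function(r) {
    evolve_on_tree(tree, spec, ab, seed = spec$seed + 7919L * r,
                   sf_of_node = sf_of_node)
  })
  list(tree = tree, sequences = as_tibble(alignments[[1]]),
       alignment = alignments[[1]], alignments = alignments,
       truth = truth, spec = spec)
}

evolve_on_tree <- function(tree, spec, ab, seed, sf_of_node) {
  inv_cols <- as.integer(names(spec$invariant_columns))
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  with_local_seed(seed, {
    root_seq <- sample(ab, spec$length, replace = TRUE)
    root_seq[inv_cols] <- spec$invariant_columns
    seqs <- vector("list", ntip + tree$Nnode)
    frozen_of_node <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- root_seq
    frozen_of_node[[root]] <- inv_cols
    for (e in seq_len(nrow(tree$edge))) {  # cladewise order: parents first
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      s <- mutate_seq(seqs[[parent]], tree$edge.length[e],
                      frozen_of_node[[parent]], ab)
      frozen <- frozen_of_node[[parent]]
      if (parent == root) {
        # inject this subfamily's motif at its root and freeze those columns
        sf <- sf_of_node[child]
        mrows <- spec$motifs[spec$motifs$subfamily == paste0("SF", sf), ]
        if (nrow(mrows)) {
          for (k in seq_len(nrow(mrows))) {
            cols <- mrows$start[k]:(mrows$start[k] + nchar(mrows$instance[k]) - 1)
            s[cols] <- strsplit(mrows$instance[k], "")[[1]]
            frozen <- union(frozen, cols)
          }
        }
      }
      seqs[[child]] <- s
      frozen_of_node[[child]] <- frozen
    }
    out <- as_alignment(setNames(
      vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
             character(1)),
      tree$tip.label))
  })
  out
}

#' Inject gappy columns into an alignment
#'
#' Optional gap-injection mode for the simulator: inserts `n_columns` new
#' columns at random positions, each gapped in a `gap_fraction` share of the
#' rows (residues drawn uniformly elsewhere). No indels are simulated by
#' default anywhere in the generator — this exists solely to exercise
#' gap-fraction trimming against a known answer.
#'
#' @param aln An alignment.
#' @param n_columns Number of columns to insert.
#' @param gap_fraction Fraction of rows gapped in each inserted column.
#' @param seed Integer seed.
#' @return The widened alignment; inserted (post-insertion) column indices
#'   in `attr(, "injected_columns")`.
#' @export
inject_gaps <- function(aln, n_columns = 10L, gap_fraction = 0.9, seed = 1L) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  ab <- setdiff(aa_alphabet(), "X")
  with_local_seed(seed, {
    at <- sort(sample.int(ncol(m) + 1, n_columns, replace = TRUE))
    n_gap <- max(1L, ceiling(gap_fraction * nrow(m)))
    newcols <- vapply(seq_len(n_columns), function(k) {
      col <- sample(ab, nrow(m), replace = TRUE)
      col[sample.int(nrow(m), n_gap)] <- "-"
      col
    }, character(nrow(m)))
  })
  pieces <- list()
  prev <- 0L
  inserted <- integer(n_columns)
  for (k in seq_len(n_columns)) {
    pieces[[length(pieces) + 1]] <- m[, seq_len(at[k] - 1)[seq_len(at[k] - 1) > prev],
                                      drop = FALSE]
    pieces[[length(pieces) + 1]] <- newcols[, k, drop = FALSE]
    prev <- at[k] - 1L
  }
  pieces[[length(pieces) + 1]] <- m[, seq_len(ncol(m))[seq_len(ncol(m)) > prev],
                                    drop = FALSE]
  full <- do.call(cbind, pieces)
  inserted <- at + seq_len(n_columns) - 1L
  out <- as_alignment(setNames(apply(full, 1, paste, collapse = ""),
                               rownames(m)))
  attr(out, "injected_columns") <- inserted
  out
}

#' Simulate a kinetics table with known statistics
#'
#' Builds a table in the curated kinetics schema from a subfamily truth map
#' and a per-(subfamily, substrate) efficiency law: efficiencies are drawn
#' log-normally around `median_efficiency` with log-sd `sdlog` (a point
#' mass when `sdlog = 0`), KM log-normally around `median_km_uM`, and kcat
#' derived for unit consistency. Law rows with `NA` median produce records
#' without kinetic constants (accepted substrate, efficiency undetermined).
#'
#' The default law emulates a moderately efficient family: each
#' subfamily's primary substrate has a median efficiency log-spaced around
#' 1.45e5 1/(M s) with a median KM around 600 uM (the family-typical
#' best-substrate affinity), plus a secondary substrate tenfold less
#' efficient.
#'
#' @param truth A tibble `leaf_id`/`subfamily` ([simulate_family()] truth).
#' @param law A tibble: `subfamily, substrate, median_efficiency, sdlog,
#'   median_km_uM, cofactor`; `NULL` for the default law.
#' @param seed Integer seed.
#' @return A kinetics tibble in the [read_table()] schema.
#' @export
simulate_kinetics <- function(truth, law = NULL, seed = 1L) {
  sfs <- sort(unique(truth$subfamily))
  if (is.null(law)) {
    k <- length(sfs)
    # symmetric spread in log10 so the family median of best substrates sits
    # at the planted centre
    spread <- if (k > 1) seq(-0.6, 0.6, length.out = k) else 0
    law <- bind_rows(
      tibble(subfamily = sfs, substrate = "substrate_A",
             median_efficiency = 1.45e5 * 10^spread, sdlog = 0.3,
             median_km_uM = 600, cofactor = "NADH"),
      tibble(subfamily = sfs, substrate = "substrate_B",
             median_efficiency = 1.45e4 * 10^spread, sdlog = 0.3,
             median_km_uM = 1200, cofactor = "NADH")
    )
  }
  if (!"cofactor" %in% names(law)) law$cofactor <- "NADH"
  with_local_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      rows <- law[law$subfamily == truth$subfamily[i], ]
      if (nrow(rows) == 0) return(NULL)
      purrr::map_dfr(seq_len(nrow(rows)), function(r) {
        if (is.na(rows$median_efficiency[r])) {
          return(tibble(enzyme_id = truth$leaf_id[i],
                        subfamily = truth$subfamily[i],
                        substrate = rows$substrate[r],
                        cofactor = rows$cofactor[r],
                        kcat_per_s = NA_real_, km_uM = NA_real_,
                        kcat_over_km_per_M_per_s = NA_real_))
        }
        eff <- rlnorm(1, log(rows$median_efficiency[r]), rows$sdlog[r])
        km <- rlnorm(1, log(rows$median_km_uM[r]), rows$sdlog[r])
        tibble(enzyme_id = truth$leaf_id[i], subfamily = truth$subfamily[i],
               substrate = rows$substrate[r], cofactor = rows$cofactor[r],
               kcat_per_s = eff * km * 1e-6, km_uM = km,
               kcat_over_km_per_M_per_s = eff)
      })
    })
  })
  out
}

#' Simulate an active-site complex with known contacts
#'
#' Places a single-heavy-atom ligand (`LIG`) at the origin and alanine
#' residues at controlled distances straddling the contact radius:
#' `n_contacts` residues inside (the first exactly at the radius, testing
#' the inclusive boundary), and `n_noncontacts` residues outside. Each
#' non-contact residue also carries a hydrogen inside the radius, so a
#' correct heavy-atom rule must ignore it.
#'
#' @param n_contacts Number of contact residues (>= 0).
#' @param radius Contact radius in angstroms.
#' @param seed Integer seed for the placement directions.
#' @param n_noncontacts Number of residues placed outside the radius.
#' @return A list: `model` (`structure_model`), `expected` (tibble
#'   `resno`/`dist` of true contacts), `ligand` (selector for
#'   [substrate_contacts()]).
#' @export
simulate_complex <- function(n_contacts, radius = 5.0, seed = 1L,
                             n_noncontacts = 3L) {
  stopifnot(n_contacts >= 0, radius > 0)
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  with_local_seed(seed, {
    dists_in <- if (n_contacts > 0) {
      c(radius, if (n_contacts > 1) runif(n_contacts - 1, 0.3 * radius,
                                          0.98 * radius))
    } else numeric()
    dists_out <- runif(n_noncontacts, radius + 0.2, radius + 5)
    place <- function(resno, d, element, atom, axis = FALSE) {
      # axis-aligned placement keeps the distance exactly d in floating point
      p <- if (axis) c(d, 0, 0) else rand_dir() * d
      tibble(record = "ATOM", serial = NA_integer_, atom = atom, altloc = "",
             resname = "ALA", chain = "A", resno = resno, ins = "",
             x = p[1], y = p[2], z = p[3], occ = 1, element = element,
             het = FALSE, is_water = FALSE, is_hydrogen = element == "H")
    }
    prot <- list()
    for (i in seq_len(n_contacts)) {
      prot[[length(prot) + 1]] <- place(i, dists_in[i], "C", "CA",
                                        axis = i == 1)
    }
    for (j in seq_len(n_noncontacts)) {
      prot[[length(prot) + 1]] <- place(n_contacts + j, dists_out[j], "C", "CA")
      # decoy hydrogen inside the radius on the non-contact residue
      prot[[length(prot) + 1]] <- place(n_contacts + j,
                                        runif(1, 0.3 * radius, 0.9 * radius),
                                        "H", "H")
    }
  })
  lig <- tibble(record = "HETATM", serial = NA_integer_, atom = "C1",
                altloc = "", resname = "LIG", chain = "A", resno = 900L,
                ins = "", x = 0, y = 0, z = 0, occ = 1, element = "C",
                het = TRUE, is_water = FALSE, is_hydrogen = FALSE)
  atoms <- bind_rows(c(prot, list(lig)))
  model <- structure(list(structure_id = "synthetic_complex", atoms = atoms),
                     class = "structure_model")
  expected <- tibble(resno = seq_len(n_contacts),
                     dist = if (n_contacts > 0) dists_in else numeric())
  list(model = model,
       expected = arrange(expected, .data$resno),
       ligand = list(chain = "A", resno = 900L))
}
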