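#' Default cofactor and exclusion codes for ligand classification
#'
#' Cofactors cover the nicotinamide dinucleotides in both redox states
#' (NAD/NAI/NAJ for NAD(H), NAP/NDP/TAP for NADP(H)); the exclusion list
#' holds waters and common crystallisation-cocktail compounds and ions,
#' which are not substrates.
#' @export
default_cofactor_codes <- function() c("NAD", "NAI", "NAJ", "NAP", "NDP", "TAP")

#' @rdname default_cofactor_codes
#' @export
default_exclude_codes <- function() {
  c("HOH", "SO4", "PO4", "GOL", "EDO", "CL", "NA", "MG", "K", "ZN")
}

#' Split heteroatom residues into cofactors and candidate substrates
#'
#' Heteroatom (HETATM) residues of a model are classified as cofactor
#' (code in `cofactor_codes`), excluded (water or listed
#' crystallisation-cocktail compound), or candidate substrate (everything
#' else).
#'
#' @param model A `structure_model`.
#' @param cofactor_codes Residue codes treated as cofactors.
#' @param exclude Residue codes excluded from substrate candidacy.
#' @return A tibble: `chain, resno, ins, resname, role`.
#' @export
classify_ligands <- function(model, cofactor_codes = default_cofactor_codes(),
                             exclude = default_exclude_codes()) {
  res <- structure_residues(model)
  het <- filter(res, .data$het)
  mutate(het, role = dplyr::case_when(
    .data$resname %in% cofactor_codes ~ "cofactor",
    .data$resname %in% exclude | .data$resname == "HOH" ~ "excluded",
    TRUE ~ "candidate_substrate"
  )) |>
    select("chain", "resno", "ins", "resname", "role")
}

#' Residues contacting a bound ligand
#'
#' A protein residue contacts the ligand iff any of its heavy atoms lies
#' within `radius` angstroms (inclusive) of any ligand heavy atom.
#' Hydrogens are ignored on both sides; the minimum heavy-atom distance is
#' reported per residue, and residues contributed by a chain other than the
#' ligand's are flagged as coming from the partner subunit.
#'
#' @param model A `structure_model`.
#' @param ligand A list or one-row tibble identifying the ligand residue
#'   (`chain`, `resno`, optionally `ins`).
#' @param radius Contact radius in angstroms (default 5).
#' @return A `contact_map` tibble: `chain, resno, ins, resname, min_dist,
#'   other_subunit`, with structure id, ligand and radius as attributes.
#' @export
substrate_contacts <- function(model, ligand, radius = 5.0) {
  a <- model$atoms
  ins <- if (!is.null(ligand$ins)) ligand$ins else ""
  lig_sel <- a$chain == ligand$chain & a$resno == ligand$resno & a$ins == ins &
    a$het
  lig <- filter(a, lig_sel, !.data$is_hydrogen)
  if (nrow(lig) == 0) {
    abort(sprintf("ligand %s/%s has no heavy atoms (or is absent)",
                  ligand$chain, ligand$resno))
  }
  prot <- filter(a, !.data$het, !.data$is_hydrogen)
  if (nrow(prot) == 0) {
    out <- tibble(chain = character(), resno = integer(), ins = character(),
                  resname = character(), min_dist = numeric(),
                  other_subunit = logical())
  } else {
    lx <- as.matrix(lig[, c("x", "y", "z")])
    px <- as.matrix(prot[, c("x", "y", "z")])
    # min distance of each protein atom to any ligand heavy atom
    d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * px %*% t(lx)
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    prot$d <- mind
    out <- prot |>
      group_by(.data$chain, .data$resno, .data$ins, .data$resname) |>
      summarise(min_dist = min(.data$d), .groups = "drop") |>
      filter(.data$min_dist <= radius) |>
      mutate(other_subunit = .data$chain != ligand$chain) |>
      arrange(.data$chain, .data$resno)
  }
  attr(out, "structure_id") <- model$structure_id
  attr(out, "ligand") <- list(chain = ligand$chain, resno = ligand$resno,
                              ins = ins,
                              resname = lig$resname[1])
  attr(out, "radius") <- radius
  class(out) <- c("contact_map", class(out))
  out
}

#' Default redox-state table for ligand codes
#'
#' Packaged mapping of residue codes to redox states used by
#' [complex_state()] (reduced cofactor NADH/NADPH vs oxidised NAD+/NADP+,
#' and common substrate/product codes). Curated defaults; codes absent from
#' the table are treated as unknown.
#'
#' @param path Optional CSV with columns `code`, `redox`.
#' @return A tibble.
#' @export
redox_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "redox_codes.csv",
                                package = "subfamkit", mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("code", "redox") %in% names(x))) {
    abort("redox table needs columns code, redox")
  }
  x
}

#' Complex-state classification of a structure
#'
#' Classifies a model as `apo` (neither cofactor nor substrate candidate),
#' `binary` (cofactor only), `ternary` (both), or `true_ternary`: a ternary
#' complex whose cofactor and substrate redox states pair up (reduced
#' cofactor with reduced substrate, or oxidised with oxidised). Unknown
#' redox codes yield a ternary state with a "redox unknown" note — never a
#' silent true ternary.
#'
#' @param ligands A [classify_ligands()] tibble.
#' @param redox A [redox_table()] tibble.
#' @return A one-row tibble: `state, cofactor_code, substrate_codes, note`.
#' @export
complex_state <- function(ligands, redox = redox_table()) {
  cof <- filter(ligands, .data$role == "cofactor")
  sub <- filter(ligands, .data$role == "candidate_substrate")
  if (nrow(cof) == 0 && nrow(sub) == 0) {
    return(tibble(state = "apo", cofactor_code = NA_character_,
                  substrate_codes = NA_character_, note = ""))
  }
  if (nrow(cof) > 0 && nrow(sub) == 0) {
    return(tibble(state = "binary", cofactor_code = cof$resname[1],
                  substrate_codes = NA_character_, note = ""))
  }
  if (nrow(cof) == 0) {
    return(tibble(state = "apo", cofactor_code = NA_character_,
                  substrate_codes = paste(unique(sub$resname), collapse = ";"),
                  note = "substrate-like ligand without cofactor"))
  }
  lookup <- setNames(redox$redox, redox$code)
  cof_rx <- unname(lookup[cof$resname])
  sub_rx <- unname(lookup[sub$resname])
  known_pairing <- !is.na(cof_rx) & cof_rx %in% c("reduced", "oxidized")
  sub_known <- !is.na(sub_rx) & sub_rx %in% c("reduced", "oxidized")
  if (!any(known_pairing) || !any(sub_known)) {
    return(tibble(state = "ternary", cofactor_code = cof$resname[1],
                  substrate_codes = paste(unique(sub$resname), collapse = ";"),
                  note = "redox unknown"))
  }
  matched <- any(outer(cof_rx[known_pairing], sub_rx[sub_known], "=="))
  tibble(state = if (matched) "true_ternary" else "ternary",
         cofactor_code = cof$resname[1],
         substrate_codes = paste(unique(sub$resname), collapse = ";"),
         note = if (matched) "matched redox pairing" else "redox mismatch")
}

#' Project ligand contacts onto sequence regions
#'
#' Maps each contact residue into the named sequence regions (in reference
#' numbering) through the alignment: structure residue number -> position in
#' the mapped alignment row -> alignment column -> reference number ->
#' region interval. Contacts from the partner subunit are reported under
#' primed region names (e.g. `alphaBp-betaAp'`). Residues that cannot be
#' mapped are listed separately under region `"unmapped"`, and mapped
#' residues outside every interval under `"outside named regions"`.
#'
#' @param contacts A [substrate_contacts()] map.
#' @param aln The family alignment.
#' @param refmap A [reference_numbering()] map on `aln`.
#' @param regions A [region_definitions()] tibble.
#' @param chain_map A tibble mapping structure chains to alignment rows:
#'   columns `chain`, `row_id` and optionally `offset` (structure residue
#'   number + offset = 1-based position in the ungapped row; default 0).
#' @return A tibble of per-region contact counts, with the per-contact
#'   detail in `attr(, "detail")`.
#' @export
contacts_to_regions <- function(contacts, aln, refmap, regions, chain_map) {
  aln <- as_alignment(aln)
  if (!"offset" %in% names(chain_map)) chain_map$offset <- 0L
  detail <- purrr::map_dfr(seq_len(nrow(contacts)), function(k) {
    ct <- contacts[k, ]
    cm <- chain_map[chain_map$chain == ct$chain, ]
    if (nrow(cm) != 1 || !cm$row_id %in% aln_ids(aln)) {
      return(mutate(ct, ref_number = NA_integer_, region = "unmapped"))
    }
    row <- unclass(aln)[[cm$row_id]]
    pos <- ct$resno + cm$offset
    nongap_cols <- which(strsplit(row, "")[[1]] != "-")
    if (pos < 1 || pos > length(nongap_cols)) {
      return(mutate(ct, ref_number = NA_integer_, region = "unmapped"))
    }
    refn <- column_to_ref(refmap, nongap_cols[pos])
    if (is.na(refn)) {
      return(mutate(ct, ref_number = NA_integer_, region = "unmapped"))
    }
    hit <- regions[regions$start <= refn & regions$end >= refn, ]
    reg <- if (nrow(hit)) hit$region[1] else "outside named regions"
    if (ct$other_subunit && nrow(hit)) reg <- paste0(reg, "'")
    mutate(ct, ref_number = as.integer(refn), region = reg)
  })
  counts <- detail |>
    count(.data$region, name = "n_contacts") |>
    arrange(dplyr::desc(.data$n_contacts))
  attr(counts, "detail") <- detail
  counts
}
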