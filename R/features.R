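#' Motif patterns over residue classes
#'
#' A motif pattern is a string of positions, each either a residue letter,
#' the wildcard `X`, or a bracketed residue class such as `[ST]`. Examples
#' from the family: the pyrophosphate-binding `GXXGXGXXG` of Rossmann-fold
#' dinucleotide binders, and the NADPH-specificity fingerprint
#' `[ST]R[ST]X[RK]`.
#'
#' @param pattern Pattern string.
#' @param name Optional display name.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(pattern, name = pattern) {
  toks <- tokenize_motif(pattern)
  if (length(toks) < 2) abort("motif must have at least 2 positions")
  structure(list(pattern = pattern, name = name, tokens = toks,
                 regex = motif_regex(toks)),
            class = "motif_pattern")
}

tokenize_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  toks <- character()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close)) {
        abort(sprintf("malformed motif pattern: unclosed '[' at offset %d", i))
      }
      close <- close[1]
      inner <- paste(chars[(i + 1):(close - 1)], collapse = "")
      if (!nzchar(inner) || grepl("[^A-Z]", inner)) {
        abort(sprintf("malformed motif pattern: bad residue class at offset %d", i))
      }
      toks <- c(toks, paste0("[", inner, "]"))
      i <- close + 1
    } else if (grepl("[A-Z]", ch)) {
      toks <- c(toks, ch)
      i <- i + 1
    } else {
      abort(sprintf("malformed motif pattern: unexpected '%s' at offset %d", ch, i))
    }
  }
  toks
}

motif_regex <- function(tokens) {
  paste(vapply(tokens, function(t) if (t == "X") "[A-Z]" else t, character(1)),
        collapse = "")
}

#' Find motif matches in a sequence
#'
#' Reports all (possibly overlapping) match start positions, 1-based on the
#' ungapped sequence; gaps in an aligned row are skipped transparently.
#'
#' @param seq A sequence string (gapped rows allowed) or one-row tibble.
#' @param motif A [motif_pattern()] or pattern string.
#' @return Integer vector of match start positions.
#' @examples
#' find_motif("GAAGAGAAG", "GXXGXGXXG")
#' @export
find_motif <- function(seq, motif) {
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif)
  seq <- degap(seq_from_input(seq))
  hits <- gregexpr(paste0("(?=", motif$regex, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

#' Region definitions in reference numbering
#'
#' Named sequence regions (loops implicated in cofactor binding and
#' substrate specificity) as inclusive residue intervals in the numbering of
#' the reference enzyme (GHRB representative Q92LZ4_RHIME, PDB 5v7n). The
#' packaged default boundaries are curator-supplied approximations anchored
#' on well-described residues (GXXGXGXXG at 146-154, the catalytic triad
#' 230/259/277); precise loop limits are configuration, not ground truth.
#'
#' @param path CSV with columns `region`, `start`, `end` (and optionally
#'   `key_position`); `NULL` loads the packaged defaults.
#' @return A tibble of regions.
#' @export
region_definitions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "regions.csv",
                                package = "subfamkit", mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("region", "start", "end") %in% names(x))) {
    abort("regions table needs columns region, start, end")
  }
  if (anyDuplicated(x$region)) abort("region names must be unique")
  if (any(x$end < x$start)) abort("region end before start")
  as_tibble(x)
}

row_residue_at_ref <- function(row, refmap, ref_number) {
  col <- ref_to_column(refmap, ref_number)
  if (is.na(col)) return(NA_character_)
  substr(row, col, col)
}

region_segment <- function(row, refmap, start, end) {
  cols <- ref_to_column(refmap, start:end)
  cols <- cols[!is.na(cols)]
  if (!length(cols)) return("")
  degap(paste(strsplit(row, "")[[1]][cols], collapse = ""))
}

#' Cofactor-specificity call from the adenine-binding loop
#'
#' The loop between strand betaB and helix alphaD binds the adenine and
#' ribose moieties of the cofactor and effectively decides NAD(H) versus
#' NADP(H) preference: a conserved aspartate at the key loop position
#' corresponds to NADH preference, whereas the `[ST]R[ST]X[RK]` fingerprint
#' inside the loop corresponds to NADPH preference. A row showing neither
#' (or both, flagged as a conflict) is called ambiguous.
#'
#' @param row An aligned row (gapped string) or its id plus alignment via
#'   `aln`.
#' @param refmap A [reference_numbering()] map on the same alignment.
#' @param regions A [region_definitions()] tibble containing a
#'   `betaB-alphaD` row.
#' @param key_position Reference position of the aspartate rule; defaults to
#'   the region's `key_position` column.
#' @param aln Optional alignment when `row` is an id.
#' @return A one-row tibble: `call` (NADH/NADPH/ambiguous), `evidence`,
#'   `conflict`.
#' @export
cofactor_preference <- function(row, refmap, regions = region_definitions(),
                                key_position = NULL, aln = NULL) {
  if (!is.null(aln)) {
    aln <- as_alignment(aln)
    row <- unclass(aln)[[row]]
  }
  reg <- regions[regions$region == "betaB-alphaD", ]
  if (nrow(reg) != 1) abort("regions table must define 'betaB-alphaD'")
  key_position <- key_position %||%
    (if ("key_position" %in% names(reg)) reg$key_position else NULL)
  if (is.null(key_position) || is.na(key_position)) {
    abort("key_position for the aspartate rule is required")
  }
  seg <- region_segment(row, refmap, reg$start, reg$end)
  if (!nzchar(seg)) {
    return(tibble(call = "ambiguous", evidence = "no-coverage",
                  conflict = FALSE))
  }
  key_res <- row_residue_at_ref(row, refmap, key_position)
  has_asp <- !is.na(key_res) && key_res == "D"
  has_fp <- length(find_motif(seg, nadph_fingerprint())) > 0
  if (has_asp && has_fp) {
    tibble(call = "ambiguous",
           evidence = "aspartate and NADPH fingerprint both present",
           conflict = TRUE)
  } else if (has_asp) {
    tibble(call = "NADH", evidence = sprintf("Asp at reference %d", key_position),
           conflict = FALSE)
  } else if (has_fp) {
    tibble(call = "NADPH", evidence = "[ST]R[ST]X[RK] fingerprint in loop",
           conflict = FALSE)
  } else {
    tibble(call = "ambiguous", evidence = "no diagnostic signal",
           conflict = FALSE)
  }
}

#' @rdname cofactor_preference
#' @export
nadph_fingerprint <- function() motif_pattern("[ST]R[ST]X[RK]", "NADPH fingerprint")

triad_canonical <- function() c(`230` = "R", `259` = "E", `277` = "H")

triad_auxiliary <- function() {
  c(`72` = "V", `73` = "G", `195` = "D", `227` = "N", `229` = "G", `231` = "G")
}

#' Catalytic-triad check in reference numbering
#'
#' Inspects the catalytic triad Arg230/Glu259/His277 plus auxiliary
#' active-site and structural positions (72, 73, 195, 227, 229, 231). Known
#' substitutions are labelled: Glu259Gln "FDH-like", His277Lys
#' "SERA-IIIK-like", His277Trp "X4-like, catalysis questionable". Other
#' mismatches are "non-canonical"; a gapped position reports "gap". Exactly
#' one entry (and at most one label) is produced per queried position.
#'
#' @inheritParams cofactor_preference
#' @return A `triad_report` tibble: `position, expected, observed,
#'   canonical, label, role`.
#' @export
triad_check <- function(row, refmap, aln = NULL) {
  if (!is.null(aln)) {
    aln <- as_alignment(aln)
    row <- unclass(aln)[[row]]
  }
  canon <- triad_canonical()
  aux <- triad_auxiliary()
  known <- list(`259` = c(Q = "FDH-like"),
                `277` = c(K = "SERA-IIIK-like",
                          W = "X4-like, catalysis questionable"),
                `195` = c(R = "Arg-substituted structural site"))
  all_pos <- c(canon, aux)
  out <- purrr::map_dfr(names(all_pos), function(pn) {
    pos <- as.integer(pn)
    expected <- all_pos[[pn]]
    obs <- row_residue_at_ref(row, refmap, pos)
    if (is.na(obs) || obs == "-") {
      return(tibble(position = pos, expected = expected, observed = "gap",
                    canonical = FALSE, label = "gap"))
    }
    canonical <- obs == expected
    label <- if (canonical) "none" else {
      kl <- known[[pn]]
      if (!is.null(kl) && obs %in% names(kl)) unname(kl[obs]) else "non-canonical"
    }
    tibble(position = pos, expected = expected, observed = obs,
           canonical = canonical, label = label)
  })
  out$role <- ifelse(out$position %in% as.integer(names(canon)),
                     "catalytic triad", "auxiliary")
  out <- arrange(out, .data$position)
  class(out) <- c("triad_report", class(out))
  out
}

#' Highly conserved columns
#'
#' Columns whose modal residue frequency is strictly greater than
#' `threshold` (default 0.9, the "more than 90% of sequences" convention);
#' a column at exactly the threshold is not reported, and fully gapped
#' columns never are. Reference numbering is attached where mapped.
#'
#' @param profile A [conservation()] profile.
#' @param threshold Strict frequency threshold.
#' @param refmap Optional [reference_numbering()] map.
#' @return A tibble: `column, residue, frequency, ref_number`.
#' @export
conserved_scan <- function(profile, threshold = 0.9, refmap = NULL) {
  hits <- profile |>
    filter(!is.na(.data$modal_residue), .data$modal_freq > threshold) |>
    select(column = "column", residue = "modal_residue",
           frequency = "modal_freq")
  hits$ref_number <- if (!is.null(refmap)) {
    column_to_ref(refmap, hits$column)
  } else {
    NA_integer_
  }
  hits
}

#' Annotate every row of an alignment
#'
#' Convenience wrapper producing one annotation record per row: cofactor
#' call, triad summary, and positions of the Rossmann GXXGXGXXG motif.
#'
#' @param aln An alignment.
#' @param ref_id Reference row id for numbering.
#' @param regions A [region_definitions()] tibble.
#' @param key_position Key position for the aspartate rule (see
#'   [cofactor_preference()]).
#' @return A tibble with one row per sequence.
#' @export
annotate_alignment <- function(aln, ref_id, regions = region_definitions(),
                               key_position = NULL) {
  aln <- as_alignment(aln)
  refmap <- reference_numbering(aln, ref_id)
  purrr::map_dfr(aln_ids(aln), function(id) {
    row <- unclass(aln)[[id]]
    cof <- cofactor_preference(row, refmap, regions, key_position)
    triad <- triad_check(row, refmap)
    triad_ok <- all(triad$canonical[triad$role == "catalytic triad"])
    labels <- triad$label[!triad$label %in% c("none", "gap")]
    gxx <- find_motif(row, "GXXGXGXXG")
    tibble(id = id, cofactor_call = cof$call, cofactor_evidence = cof$evidence,
           triad_canonical = triad_ok,
           triad_labels = paste(unique(labels), collapse = ";"),
           rossmann_motif_at = if (length(gxx)) gxx[1] else NA_integer_)
  })
}
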