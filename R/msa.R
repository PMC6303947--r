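#' Align new sequences to a seed alignment
#'
#' Each new sequence is aligned independently to the seed profile with an
#' affine-gap dynamic program: the score of placing residue r in column j is
#' the mean substitution score of r against the column's residues, with gap
#' rows contributing `-gap_extend`. Seed columns are never changed; residues
#' of a new sequence that fall in insertions relative to the seed are
#' discarded and logged (length-preserving extension, which keeps reference
#' numbering and region definitions stable across the pipeline).
#'
#' @param seed An alignment ([as_alignment()]).
#' @param new_seqs A tibble with `id` and `seq` columns (ungapped), possibly
#'   empty.
#' @param scheme A [scoring_scheme()].
#' @return The extended alignment; dropped-residue positions are recorded in
#'   `attr(, "dropped")` (a tibble id/position) and reported via a message.
#' @export
add_to_seed <- function(seed, new_seqs, scheme = scoring_scheme()) {
  seed <- as_alignment(seed)
  if (length(seed) == 0) abort("seed alignment is empty")
  if (is.null(new_seqs) || nrow(new_seqs) == 0) {
    attr(seed, "dropped") <- tibble(id = character(), position = integer())
    return(seed)
  }
  clash <- intersect(new_seqs$id, aln_ids(seed))
  if (length(clash)) {
    abort(paste0("new sequence ids collide with seed rows: ",
                 paste(clash, collapse = ", ")))
  }
  cs <- profile_colscores(seed, scheme)
  rows <- unclass(seed)
  dropped <- list()
  for (i in seq_len(nrow(new_seqs))) {
    res <- profile_align_cpp(toupper(new_seqs$seq[i]), cs,
                             scheme$gap_open, scheme$gap_extend)
    rows[[new_seqs$id[i]]] <- res$row
    if (length(res$dropped)) {
      dropped[[new_seqs$id[i]]] <- tibble(id = new_seqs$id[i],
                                          position = as.integer(res$dropped))
    }
  }
  out <- as_alignment(unlist(rows))
  drop_tbl <- if (length(dropped)) bind_rows(dropped) else
    tibble(id = character(), position = integer())
  if (nrow(drop_tbl)) {
    inform(sprintf("add_to_seed: dropped %d residue(s) falling in insertions relative to the seed (%s)",
                   nrow(drop_tbl), paste(unique(drop_tbl$id), collapse = ", ")))
  }
  attr(out, "dropped") <- drop_tbl
  out
}

# (n_columns x 128) ASCII-indexed profile score matrix
profile_colscores <- function(seed, scheme) {
  m <- aln_matrix(seed)
  L <- ncol(m)
  ab <- rownames(scheme$sub)
  cs <- matrix(NA_real_, L, 128)
  per_letter <- matrix(0, L, length(ab), dimnames = list(NULL, ab))
  for (j in seq_len(L)) {
    col <- m[, j]
    gapn <- sum(col == "-")
    res <- col[col != "-"]
    for (r in ab) {
      s <- if (length(res)) sum(scheme$sub[r, res]) else 0
      per_letter[j, r] <- (s - gapn * scheme$gap_extend) / length(col)
    }
  }
  for (r in ab) cs[, utf8ToInt(r) + 1L] <- per_letter[, r]  # 0-based in C++
  cs
}

#' Trim alignment columns by gap fraction
#'
#' A column is removed iff its gap fraction is at least `max_gap_fraction`
#' (default 0.8, i.e. columns with gaps in at least 80% of the rows go).
#' The boundary is inclusive by design, matching a removal rule phrased as
#' "at least"; row order is preserved and the operation is idempotent.
#'
#' @param aln An alignment.
#' @param max_gap_fraction Removal threshold in (0, 1].
#' @return The trimmed alignment, with removed 1-based input column indices
#'   in `attr(, "removed_columns")` (also retrievable with
#'   [removed_columns()]).
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.8) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  drop <- which(gap_frac >= max_gap_fraction)
  if (length(drop) == ncol(m)) abort("trimming would remove all columns")
  keep <- setdiff(seq_len(ncol(m)), drop)
  out <- as_alignment(setNames(
    apply(m[, keep, drop = FALSE], 1, paste, collapse = ""), rownames(m)))
  attr(out, "removed_columns") <- as.integer(drop)
  out
}

#' @rdname trim_columns
#' @export
removed_columns <- function(aln) {
  attr(aln, "removed_columns") %||% integer()
}

#' Per-column conservation profile
#'
#' For every column: the modal residue, its frequency, the gap fraction and
#' the information content in bits. By default the modal frequency uses all
#' rows in the denominator, so gaps count against conservation (the
#' `"nongap"` mode restricts the denominator to occupied rows). Information
#' content is log2(20) minus the Shannon entropy of residue frequencies
#' renormalised over non-gap rows, with no small-sample correction.
#'
#' @param aln An alignment.
#' @param denominator `"all"` (default) or `"nongap"`.
#' @return A `conservation_profile` tibble: `column, modal_residue,
#'   modal_freq, gap_fraction, information`.
#' @export
conservation <- function(aln, denominator = c("all", "nongap")) {
  denominator <- match.arg(denominator)
  aln <- as_alignment(aln)
  if (length(aln) == 0) abort("empty alignment")
  m <- aln_matrix(aln)
  nrows <- nrow(m)
  prof <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    gap_fraction <- 1 - length(res) / nrows
    if (length(res) == 0) {
      return(tibble(column = j, modal_residue = NA_character_,
                    modal_freq = 0, gap_fraction = 1,
                    information = NA_real_))
    }
    tabres <- sort(table(res), decreasing = TRUE)
    modal <- names(tabres)[1]
    den <- if (denominator == "all") nrows else length(res)
    p <- as.numeric(tabres) / length(res)
    info <- log2(20) + sum(p * log2(p))
    tibble(column = j, modal_residue = modal,
           modal_freq = as.numeric(tabres[1]) / den,
           gap_fraction = gap_fraction,
           information = max(0, info))
  })
  class(prof) <- c("conservation_profile", class(prof))
  prof
}

#' Columns eligible for subfamily sequence logos
#'
#' A column is included iff at least one subfamily has a non-gap fraction of
#' at least `min_nongap` (default 0.9) in it, i.e. at least 90% of that
#' subfamily's members possess an amino acid there. Residue frequencies are
#' normalised per included column within each subfamily.
#'
#' @param aln An alignment.
#' @param partition A subfamily partition ([consensus_subfamilies()]) or a
#'   tibble with `leaf_id` and `subfamily` columns; the UNASSIGNED pool is
#'   ignored.
#' @param min_nongap Inclusion threshold on the non-gap fraction.
#' @return A list with `included_columns` (integer) and `frequencies` (a
#'   long tibble: subfamily, column, residue, freq).
#' @export
logo_columns <- function(aln, partition, min_nongap = 0.9) {
  aln <- as_alignment(aln)
  part <- as_tibble(partition)
  part <- filter(part, .data$subfamily != "UNASSIGNED")
  missing_rows <- setdiff(part$leaf_id, aln_ids(aln))
  if (length(missing_rows)) {
    abort(paste0("partition members absent from alignment: ",
                 paste(missing_rows, collapse = ", ")))
  }
  m <- aln_matrix(aln)
  groups <- split(part$leaf_id, part$subfamily)
  if (any(lengths(groups) == 0)) abort("subfamily with zero rows")
  nongap <- vapply(groups, function(ids)
    colMeans(m[ids, , drop = FALSE] != "-"), numeric(ncol(m)))
  included <- which(apply(nongap >= min_nongap, 1, any))
  freqs <- purrr::map_dfr(names(groups), function(sf) {
    sub <- m[groups[[sf]], , drop = FALSE]
    purrr::map_dfr(included, function(j) {
      res <- sub[, j][sub[, j] != "-"]
      if (length(res) == 0) return(NULL)
      tab <- table(res)
      tibble(subfamily = sf, column = j, residue = names(tab),
             freq = as.numeric(tab) / length(res))
    })
  })
  list(included_columns = as.integer(included), frequencies = freqs)
}

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap column of the reference row maps to residue number k
#' (1-based over the ungapped reference); columns where the reference is
#' gapped are unmapped.
#'
#' @param aln An alignment.
#' @param ref_id Row id of the reference sequence.
#' @return A `reference_map` tibble (`column`, `ref_number`) with the
#'   reference id in `attr(, "ref_id")`.
#' @export
reference_numbering <- function(aln, ref_id) {
  aln <- as_alignment(aln)
  if (!ref_id %in% aln_ids(aln)) {
    abort(sprintf("reference row '%s' not found in alignment", ref_id))
  }
  chars <- strsplit(unclass(aln)[[ref_id]], "")[[1]]
  cols <- which(chars != "-")
  out <- tibble(column = as.integer(cols), ref_number = seq_along(cols))
  attr(out, "ref_id") <- ref_id
  class(out) <- c("reference_map", class(out))
  out
}

#' Translate reference residue numbers to alignment columns (and back)
#'
#' @param refmap A [reference_numbering()] map.
#' @param ref_number Reference residue numbers.
#' @return Alignment column indices (`NA` where unmapped).
#' @export
ref_to_column <- function(refmap, ref_number) {
  refmap$column[match(ref_number, refmap$ref_number)]
}

#' @rdname ref_to_column
#' @param column Alignment column indices.
#' @export
column_to_ref <- function(refmap, column) {
  refmap$ref_number[match(column, refmap$column)]
}
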