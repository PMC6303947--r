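#' Read and write FASTA sequence files
#'
#' `read_fasta()` parses a FASTA file into a tibble with one row per record
#' (columns `id`, `desc`, `seq`). Residues are uppercased, line wrapping is
#' removed and `.` gap characters are normalised to `-`. The `id` is the first
#' whitespace-delimited token of the header; the remainder is the description.
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; this wrapper adds
#' the validation contracts used throughout the package: ids must be unique
#' and non-empty, sequences non-empty, and residues restricted to the 20
#' amino-acid letters plus `X` and the gap character.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(sprintf("failed to parse FASTA '%s' (invalid layout or non-amino-acid characters): %s",
                    path, conditionMessage(e)))
    }
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- gsub(".", "-", toupper(as.character(set)), fixed = TRUE)
  if (any(!nzchar(ids))) abort("empty sequence id in FASTA header")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for id: ", ids[!nzchar(seqs)][1]))
  }
  pat <- sprintf("[^%s-]", aa_alphabet_string())
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr(pat, seqs[i])
    abort(sprintf("non-amino-acid character '%s' in sequence '%s' at position %d",
                  substr(seqs[i], pos, pos), ids[i], as.integer(pos)))
  }
  tibble(id = unname(ids), desc = unname(desc), seq = unname(seqs))
}

#' @rdname read_fasta
#' @param x A tibble with columns `id` and `seq` (optionally `desc`), a named
#'   character vector, or an alignment.
#' @param width Line-wrapping width for sequence lines.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "subfam_aln")) x <- as_tibble(x)
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(id = names(x), seq = unname(x))
  }
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("write_fasta() needs a tibble with columns `id` and `seq`")
  }
  hdr <- if ("desc" %in% names(x)) {
    ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  } else {
    x$id
  }
  set <- Biostrings::AAStringSet(setNames(x$seq, hdr))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
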