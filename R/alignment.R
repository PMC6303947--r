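#' Alignment and sequence containers
#'
#' Sequence sets are plain tibbles with columns `id`, `desc` and `seq`.
#' An alignment (`subfam_aln`) is a named character vector of equal-length
#' gapped rows, the substrate of trimming, conservation, logo and distance
#' computations. `as_alignment()` accepts such a tibble, a named character
#' vector, or an existing alignment.
#'
#' Residues are the 20 amino-acid letters plus `X` (unknown); the only gap
#' character is `-` (`.` is normalised to `-` on read).
#'
#' @param x A named character vector of gapped sequences or a tibble with
#'   columns `id` and `seq`.
#' @return An object of class `subfam_aln`.
#' @examples
#' aln <- as_alignment(c(a = "MK-V", b = "MKAV"))
#' aln_ncol(aln)
#' @export
as_alignment <- function(x) {
  if (inherits(x, "subfam_aln")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      abort("alignment tibble needs columns `id` and `seq`")
    }
    x <- setNames(toupper(x$seq), x$id)
  }
  if (!is.character(x) || is.null(names(x))) {
    abort("alignment must be a named character vector or a tibble(id, seq)")
  }
  x <- gsub(".", "-", toupper(x), fixed = TRUE)
  ids <- names(x)
  if (any(!nzchar(ids))) abort("alignment row ids must be non-empty")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate row ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(unique(nchar(x))) > 1) {
    abort("alignment rows must have equal length")
  }
  bad <- grepl(sprintf("[^%s-]", aa_alphabet_string()), x)
  if (any(bad)) {
    row <- which(bad)[1]
    pos <- regexpr(sprintf("[^%s-]", aa_alphabet_string()), x[row])
    abort(sprintf("invalid residue character '%s' in row '%s' at position %d",
                  substr(x[row], pos, pos), ids[row], as.integer(pos)))
  }
  structure(x, class = "subfam_aln")
}

aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

aa_alphabet_string <- function() "ACDEFGHIKLMNPQRSTVWYX"

#' @rdname as_alignment
#' @param aln An alignment.
#' @export
aln_ids <- function(aln) names(unclass(as_alignment(aln)))

#' @rdname as_alignment
#' @export
aln_ncol <- function(aln) {
  aln <- as_alignment(aln)
  if (length(aln) == 0) 0L else nchar(unclass(aln)[[1]])
}

#' @rdname as_alignment
#' @export
aln_matrix <- function(aln) {
  aln <- as_alignment(aln)
  x <- unclass(aln)
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- names(x)
  m
}

#' @export
as_tibble.subfam_aln <- function(x, ...) {
  tibble(id = names(unclass(x)), seq = unname(unclass(x)))
}

#' @export
print.subfam_aln <- function(x, ...) {
  cat(sprintf("<alignment: %d rows x %d columns>\n", length(x), aln_ncol(x)))
  ids <- aln_ids(x)
  show <- head(seq_along(ids), 8)
  for (i in show) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-15s %s%s\n", ids[i], substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(ids) > 8) cat(sprintf("  ... and %d more rows\n", length(ids) - 8))
  invisible(x)
}

#' Remove gaps from an aligned row
#' @param seq A (possibly gapped) sequence string.
#' @return The ungapped sequence.
#' @export
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)
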