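#' Scoring scheme for pairwise and profile alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties and the
#' Karlin-Altschul parameters used for E-values. The default is BLOSUM62
#' (taken from Biostrings, restricted to the 20 amino acids plus `X`) with
#' gap open 10, gap extend 0.5, and the conventional gapped constants
#' lambda = 0.267 (nats per score unit) and K = 0.041.
#'
#' A gap of length k costs `gap_open + (k - 1) * gap_extend`: the first
#' gapped residue pays the opening penalty.
#'
#' @param matrix A symmetric substitution matrix with residue dimnames, or
#'   `"BLOSUM62"`.
#' @param gap_open,gap_extend Non-negative gap penalties,
#'   `gap_extend <= gap_open`.
#' @param lambda,K Positive Karlin-Altschul parameters.
#' @return A `scoring_scheme` object.
#' @examples
#' s <- scoring_scheme()
#' s$sub["A", "A"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5, lambda = 0.267, K = 0.041) {
  if (is.character(matrix) && length(matrix) == 1) {
    if (!identical(matrix, "BLOSUM62")) abort("only 'BLOSUM62' is built in")
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    keep <- aa_alphabet()
    matrix <- env$BLOSUM62[keep, keep]
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix))) {
    abort("substitution matrix must be square with matching dimnames")
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    abort("substitution matrix must be symmetric")
  }
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open) {
    abort("need 0 <= gap_extend <= gap_open")
  }
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  structure(list(sub = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Simple match/mismatch scoring scheme
#'
#' Convenience constructor used in tests and small examples.
#' @param match,mismatch Scores for identical / differing residues.
#' @inheritParams scoring_scheme
#' @export
simple_scheme <- function(match = 1, mismatch = -1, gap_open = 1,
                          gap_extend = 1, lambda = 0.267, K = 0.041) {
  ab <- aa_alphabet()
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  scoring_scheme(m, gap_open, gap_extend, lambda, K)
}

seq_from_input <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1 || !"seq" %in% names(x)) {
      abort(sprintf("%s must be a string or a one-row tibble with a `seq` column", what))
    }
    x <- x$seq
  }
  x <- toupper(as.character(x))
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  x
}

align_pair <- function(a, b, scheme, local) {
  a <- seq_from_input(a, "a")
  b <- seq_from_input(b, "b")
  res <- align_pair_cpp(a, b, scheme$sub, scheme$gap_open, scheme$gap_extend,
                        local)
  structure(
    list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
         score = res$score, mode = if (local) "local" else "global",
         a_span = c(res$a_start, res$a_end),
         b_span = c(res$b_start, res$b_end)),
    class = "pairwise_alignment"
  )
}

#' Optimal pairwise alignment with affine gaps
#'
#' `global_align()` computes the optimal Needleman-Wunsch global alignment,
#' `local_align()` the optimal Smith-Waterman local alignment (score floored
#' at zero; an empty alignment is returned when every alignment scores
#' negatively). Traceback ties are broken deterministically (diagonal, then
#' gap in `b`, then gap in `a`).
#'
#' @param a,b Sequences: strings or one-row tibbles with a `seq` column.
#' @param scheme A [scoring_scheme()].
#' @return A `pairwise_alignment` with gapped rows, score, mode and 0-based
#'   half-open spans on each input.
#' @examples
#' global_align("MKV", "MV", simple_scheme())
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  align_pair(a, b, scheme, local = FALSE)
}

#' @rdname global_align
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  align_pair(a, b, scheme, local = TRUE)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment, score %.4g>\n", x$mode, x$score))
  cat("  ", x$aligned_a, "\n  ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x (identical columns) / (total alignment columns, gaps included),
#' reported to 0.1%. The denominator convention is configurable because
#' published identity figures rarely state it: `"alignment"` (default, all
#' columns including terminal gaps), `"shorter"` (length of the shorter
#' ungapped sequence) or `"ungapped"` (columns where neither row is gapped).
#'
#' @param aln A `pairwise_alignment`.
#' @param denominator Denominator convention, see Details.
#' @return Identity percentage, rounded to one decimal.
#' @export
percent_identity <- function(aln, denominator = c("alignment", "shorter", "ungapped")) {
  denominator <- match.arg(denominator)
  if (!inherits(aln, "pairwise_alignment")) abort("need a pairwise_alignment")
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  if (length(ca) == 0) abort("empty alignment")
  ident <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
    alignment = length(ca),
    shorter = min(sum(ca != "-"), sum(cb != "-")),
    ungapped = sum(ca != "-" & cb != "-")
  )
  if (den == 0) abort("empty alignment")
  round(100 * ident / den, 1)
}

#' Karlin-Altschul expectation of a local alignment score
#'
#' E = K m n exp(-lambda S), the expected number of chance local alignments
#' scoring at least S between sequences of lengths m and n.
#'
#' @param score Alignment score (finite).
#' @param m,n Sequence lengths (>= 1).
#' @param scheme A [scoring_scheme()] carrying lambda and K.
#' @return The expectation value.
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (!is.finite(score)) abort("score must be finite")
  if (m < 1 || n < 1) abort("m and n must be >= 1")
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Collect homologs of a query set from a sequence database
#'
#' Re-implementation of a BLAST-style reference-set extension as exact local
#' alignment plus Karlin-Altschul statistics: a database entry is kept iff
#' some query aligns to it with E-value below `e_max` and the aligned query
#' span covers at least `cov_min` of the query length.
#'
#' @param queries,database Tibbles with columns `id` and `seq` (as returned
#'   by [read_fasta()]).
#' @param scheme A [scoring_scheme()].
#' @param e_max Maximum E-value (default 1e-3).
#' @param cov_min Minimum query coverage fraction (default 0.9).
#' @return A tibble of accepted hits: `db_id, best_query, score, evalue,
#'   coverage, identity`.
#' @export
collect_homologs <- function(queries, database, scheme = scoring_scheme(),
                             e_max = 1e-3, cov_min = 0.9) {
  if (!is.data.frame(queries) || nrow(queries) == 0 ||
      !is.data.frame(database) || nrow(database) == 0) {
    abort("queries and database must be non-empty tibbles with id/seq columns")
  }
  hits <- purrr::map_dfr(seq_len(nrow(database)), function(j) {
    best <- NULL
    for (i in seq_len(nrow(queries))) {
      al <- local_align(queries$seq[i], database$seq[j], scheme)
      ev <- evalue(al$score, nchar(queries$seq[i]), nchar(database$seq[j]),
                   scheme)
      cov <- (al$a_span[2] - al$a_span[1]) / nchar(queries$seq[i])
      cand <- list(q = queries$id[i], al = al, ev = ev, cov = cov)
      if (is.null(best) || cand$al$score > best$al$score) best <- cand
    }
    ok <- best$ev < e_max && best$cov >= cov_min
    if (!ok) return(NULL)
    tibble(db_id = database$id[j], best_query = best$q,
           score = best$al$score, evalue = best$ev, coverage = best$cov,
           identity = if (nchar(best$al$aligned_a) > 0)
             percent_identity(best$al) else NA_real_)
  })
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(db_id = character(), best_query = character(),
                  score = numeric(), evalue = numeric(), coverage = numeric(),
                  identity = numeric()))
  }
  hits
}
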