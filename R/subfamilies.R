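#' Supported clades of a tree
#'
#' For each internal edge whose support is strictly greater than
#' `min_support`, both sides of the induced bipartition are emitted as
#' candidate leaf sets (the tree is treated as unrooted). Singletons and the
#' full leaf set are excluded. An edge with support exactly equal to the
#' threshold is not emitted.
#'
#' @param tree A `phylo` tree with numeric supports in `node.label`.
#' @param min_support Strict support threshold (default 0.5).
#' @return A tibble: `leaves` (list-column of leaf sets), `support`, `key`
#'   (canonical set key).
#' @export
supported_clades <- function(tree, min_support = 0.5) {
  sup <- node_supports(tree)
  if (all(is.na(sup))) abort("tree has no branch supports")
  bp <- bipartitions(tree)
  all_leaves <- tree$tip.label
  out <- purrr::map_dfr(seq_len(nrow(bp)), function(k) {
    s <- bp$support[k]
    if (is.na(s) || s <= min_support) return(NULL)
    sides <- list(bp$tips[[k]], setdiff(all_leaves, bp$tips[[k]]))
    purrr::map_dfr(sides, function(side) {
      if (length(side) < 2 || length(side) >= length(all_leaves)) return(NULL)
      tibble(leaves = list(sort(side)), support = s,
             key = paste(sort(side), collapse = "\r"))
    })
  })
  if (nrow(out) == 0) {
    return(tibble(leaves = list(), support = numeric(), key = character()))
  }
  # a set can be emitted by several edges; keep its best support
  out |>
    group_by(.data$key) |>
    slice(which.max(.data$support)) |>
    ungroup()
}

#' Consensus subfamily extraction across trees
#'
#' The core inference: a subfamily is a group of proteins that appears as a
#' supported clade (support strictly above `min_support`) consistently in
#' every input tree, where "appears as a clade" is read strictly as
#' bipartition equality of leaf sets on the unrooted trees. Candidates are
#' selected greedily by decreasing size (ties broken by the
#' lexicographically smallest member), skipping any candidate that overlaps
#' an already selected subfamily or exceeds `max_fraction` of all leaves
#' (a cap that stands in for manual curation of near-root bipartitions).
#' Remaining leaves, including single long branches that never sit inside a
#' consistent supported clade, form the UNASSIGNED pool.
#'
#' @param trees A list of `phylo` trees over the identical leaf set, each
#'   with supports.
#' @param min_support Strict support threshold (default 0.5).
#' @param min_size Minimum subfamily size (default 2; singletons are long
#'   branches left outside the classification).
#' @param max_fraction Maximum subfamily size as a fraction of all leaves
#'   (default 0.5).
#' @param names_map Optional named character vector mapping a subfamily's
#'   smallest member id to a display name; otherwise subfamilies are
#'   labelled SF1, SF2, ... in order of decreasing size.
#' @return A `subfam_partition` tibble (`leaf_id`, `subfamily`, UNASSIGNED
#'   included), with per-subfamily provenance (size, minimum support across
#'   trees) in `attr(, "provenance")`.
#' @export
consensus_subfamilies <- function(trees, min_support = 0.5, min_size = 2,
                                  max_fraction = 0.5, names_map = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 2) abort("need at least 2 trees")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  base <- leafsets[[1]]
  for (k in seq_along(leafsets)[-1]) {
    if (!identical(leafsets[[k]], base)) {
      dif <- c(setdiff(base, leafsets[[k]]), setdiff(leafsets[[k]], base))
      abort(paste0("trees disagree on the leaf set; symmetric difference: ",
                   paste(dif, collapse = ", ")))
    }
  }
  per_tree <- lapply(trees, supported_clades, min_support = min_support)
  keys <- Reduce(intersect, lapply(per_tree, function(x) x$key))
  if (length(keys)) {
    cand <- purrr::map_dfr(keys, function(k) {
      sups <- vapply(per_tree, function(x) x$support[match(k, x$key)],
                     numeric(1))
      lv <- per_tree[[1]]$leaves[[match(k, per_tree[[1]]$key)]]
      sz <- length(lv)
      tibble(key = k, leaves = list(lv), size = sz, min_support = min(sups))
    })
  } else {
    cand <- tibble(key = character(), leaves = list(), size = integer(),
                   min_support = numeric())
  }
  first_member <- vapply(cand$leaves, function(x) x[1], character(1))
  cand <- cand[order(-cand$size, first_member), ]
  taken <- character()
  chosen <- list()
  cap <- max_fraction * length(base)
  for (k in seq_len(nrow(cand))) {
    lv <- cand$leaves[[k]]
    if (length(lv) < min_size || length(lv) > cap) next
    if (length(intersect(lv, taken))) next
    chosen[[length(chosen) + 1]] <- cand[k, ]
    taken <- c(taken, lv)
  }
  assignments <- tibble(leaf_id = base, subfamily = "UNASSIGNED")
  prov <- tibble(subfamily = character(), size = integer(),
                 min_support = numeric())
  if (length(chosen)) {
    chosen <- bind_rows(chosen)
    sf_names <- paste0("SF", seq_len(nrow(chosen)))
    if (!is.null(names_map)) {
      anchors <- vapply(chosen$leaves, function(x) x[1], character(1))
      hit <- !is.na(names_map[anchors])
      sf_names[hit] <- names_map[anchors][hit]
    }
    for (k in seq_len(nrow(chosen))) {
      assignments$subfamily[assignments$leaf_id %in% chosen$leaves[[k]]] <-
        sf_names[k]
    }
    prov <- tibble(subfamily = sf_names, size = chosen$size,
                   min_support = chosen$min_support)
  }
  attr(assignments, "provenance") <- prov
  class(assignments) <- c("subfam_partition", class(assignments))
  assignments
}

#' @export
print.subfam_partition <- function(x, ...) {
  prov <- attr(x, "provenance")
  n_un <- sum(x$subfamily == "UNASSIGNED")
  cat(sprintf("<subfamily partition: %d leaves, %d subfamilies, %d unassigned>\n",
              nrow(x), nrow(prov), n_un))
  if (nrow(prov)) print(as_tibble(prov))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.subfam_partition <- function(x, ...) {
  tibble(leaf_id = x$leaf_id, subfamily = x$subfamily)
}

#' @export
glance.subfam_partition <- function(x, ...) {
  prov <- attr(x, "provenance")
  tibble(n_leaves = nrow(x), n_subfamilies = nrow(prov),
         n_assigned = sum(x$subfamily != "UNASSIGNED"),
         n_unassigned = sum(x$subfamily == "UNASSIGNED"),
         min_support = if (nrow(prov)) min(prov$min_support) else NA_real_)
}

#' Classify a query sequence into a subfamily
#'
#' The query is locally aligned against every representative row; the best
#' scoring representative determines the subfamily if the alignment identity
#' reaches `min_identity` and its E-value is below `e_max`, otherwise the
#' query is UNASSIGNED (with the best hit still reported).
#'
#' @param query A sequence string or one-row tibble with a `seq` column.
#' @param representatives An alignment of classified representatives.
#' @param partition A `subfam_partition` covering the representative ids.
#' @param scheme A [scoring_scheme()].
#' @param min_identity Minimum percent identity (default 30).
#' @param e_max Maximum E-value (default 1e-3).
#' @return A one-row tibble: `subfamily, best_hit, identity, evalue, score`.
#' @export
assign_query <- function(query, representatives, partition,
                         scheme = scoring_scheme(), min_identity = 30,
                         e_max = 1e-3) {
  query <- seq_from_input(query, "query")
  representatives <- as_alignment(representatives)
  if (length(representatives) == 0) abort("no representatives")
  ids <- aln_ids(representatives)
  best <- NULL
  for (id in ids) {
    rep_seq <- degap(unclass(representatives)[[id]])
    al <- local_align(query, rep_seq, scheme)
    if (is.null(best) || al$score > best$al$score) {
      best <- list(id = id, al = al)
    }
  }
  ev <- evalue(best$al$score, nchar(query),
               sum(nchar(degap(unclass(representatives)))), scheme)
  ident <- if (nchar(best$al$aligned_a) > 0) percent_identity(best$al) else 0
  sf <- partition$subfamily[match(best$id, partition$leaf_id)]
  ok <- !is.na(sf) && ident >= min_identity && ev < e_max
  tibble(subfamily = if (ok) sf else "UNASSIGNED", best_hit = best$id,
         identity = ident, evalue = ev, score = best$al$score)
}
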