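#' Pairwise evolutionary distances from an alignment
#'
#' Observed-proportion (`"p"`) or Poisson-corrected (`"poisson"`,
#' d = -ln(1 - p)) distances under pairwise deletion: for each pair, p is the
#' number of mismatches over the columns where both rows are non-gapped.
#'
#' Saturated pairs (p >= 0.99 under the Poisson model, p = 1 under the p
#' model) are an error by default; with `on_saturation = "clamp"` they are
#' clamped (d = 5 substitutions/site for Poisson, d = 1 for p) with a
#' warning.
#'
#' @param aln An alignment with at least 3 rows.
#' @param model `"poisson"` (default) or `"p"`.
#' @param on_saturation `"error"` or `"clamp"`.
#' @return A symmetric numeric matrix with row/column names; the number of
#'   shared columns per pair is attached as `attr(, "shared")`.
#' @export
distance_matrix <- function(aln, model = c("poisson", "p"),
                            on_saturation = c("error", "clamp")) {
  model <- match.arg(model)
  on_saturation <- match.arg(on_saturation)
  aln <- as_alignment(aln)
  if (length(aln) < 3) abort("need at least 3 rows")
  res <- pdist_cpp(unclass(aln))
  p <- res$p
  shared <- res$shared
  ids <- aln_ids(aln)
  dimnames(p) <- dimnames(shared) <- list(ids, ids)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    abort(sprintf("no shared non-gap columns for pair %s / %s",
                  ids[idx[1]], ids[idx[2]]))
  }
  sat_lim <- if (model == "poisson") 0.99 else 1
  sat <- p >= sat_lim & upper.tri(p)
  if (any(sat)) {
    if (on_saturation == "error") {
      idx <- which(sat, arr.ind = TRUE)[1, ]
      abort(sprintf("saturated pair %s / %s (p = %.3f); set on_saturation = 'clamp' to proceed",
                    ids[idx[1]], ids[idx[2]], p[idx[1], idx[2]]))
    }
    warn(sprintf("%d saturated pair(s) clamped", sum(sat)))
  }
  d <- if (model == "poisson") {
    out <- -log(1 - pmin(p, sat_lim - 1e-12))
    out[p >= sat_lim] <- 5
    out
  } else {
    out <- p
    out[p >= 1] <- 1
    out
  }
  diag(d) <- 0
  attr(d, "shared") <- shared
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor-joining agglomeration under the Q-criterion. Ties in Q
#' are broken by the lexicographically smallest pair of cluster labels (a
#' cluster is labelled by its smallest leaf). Negative branch-length
#' estimates are clamped to 0 and the total deficit recorded in
#' `attr(, "clamped_deficit")`. The result is unrooted (trifurcating root).
#' A matrix that is identically zero off the diagonal yields a star tree.
#'
#' @param D A symmetric distance matrix with labels (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @examples
#' D <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
#' nj_tree(D)
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be a square matrix")
  if (is.null(rownames(D))) abort("D must have labels")
  if (!isTRUE(all.equal(unname(D), unname(t(D)), tolerance = 1e-10))) {
    abort("distance matrix is not symmetric")
  }
  n <- nrow(D)
  if (n < 3) abort("need at least 3 taxa")
  labels <- rownames(D)
  if (all(abs(D[upper.tri(D)]) < 1e-15)) {
    nwk <- paste0("(", paste0(labels, ":0", collapse = ","), ");")
    tr <- ape::read.tree(text = nwk)
    attr(tr, "clamped_deficit") <- 0
    return(tr)
  }
  # cluster bookkeeping: newick fragments plus representative (smallest) leaf
  frag <- labels
  rep_leaf <- labels
  act <- seq_len(n)
  d <- D
  deficit <- 0
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (length(act) > 3) {
    m <- length(act)
    dd <- d[act, act]
    rs <- rowSums(dd)
    Q <- (m - 2) * dd - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(ij) {
        pr <- sort(c(rep_leaf[act[ij[1]]], rep_leaf[act[ij[2]]]))
        paste(pr, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- act[cand[1, 1]]
    j <- act[cand[1, 2]]
    dij <- d[i, j]
    li <- dij / 2 + (rs[cand[1, 1]] - rs[cand[1, 2]]) / (2 * (m - 2))
    lj <- dij - li
    deficit <- deficit + max(0, -li) + max(0, -lj)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    # distances to the new node
    others <- setdiff(act, c(i, j))
    dnew <- (d[i, others] + d[j, others] - dij) / 2
    d <- rbind(cbind(d, 0), 0)
    k <- nrow(d)
    d[k, others] <- dnew
    d[others, k] <- dnew
    frag <- c(frag, new_frag)
    rep_leaf <- c(rep_leaf, min(rep_leaf[i], rep_leaf[j]))
    act <- c(others, k)
  }
  a <- act[order(rep_leaf[act])]
  # three-point formulas for the final trifurcation
  l1 <- (d[a[1], a[2]] + d[a[1], a[3]] - d[a[2], a[3]]) / 2
  l2 <- (d[a[1], a[2]] + d[a[2], a[3]] - d[a[1], a[3]]) / 2
  l3 <- (d[a[1], a[3]] + d[a[2], a[3]] - d[a[1], a[2]]) / 2
  deficit <- deficit + sum(pmax(0, -c(l1, l2, l3)))
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a[1]], fmt(l1),
                 frag[a[2]], fmt(l2), frag[a[3]], fmt(l3))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped_deficit") <- deficit
  tr
}

# canonical bipartition key: the side not containing the reference leaf
# (lexicographically smallest over the full leaf set)
canonical_split_key <- function(leaves, all_leaves) {
  anchor <- min(all_leaves)
  side <- if (anchor %in% leaves) setdiff(all_leaves, leaves) else leaves
  paste(sort(side), collapse = "\r")
}

#' Internal-edge bipartitions of a tree
#'
#' One row per internal edge (clades descending from non-root internal
#' nodes), with the tip set, its canonical unrooted key and the node's
#' support where present.
#'
#' @param tree A `phylo` object.
#' @return A tibble: `node`, `tips` (list-column), `key`, `support`.
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (tree$Nnode < 2) {
    return(tibble(node = integer(), tips = list(), key = character(),
                  support = numeric()))
  }
  pp <- ape::prop.part(tree)
  sup <- node_supports(tree)
  all_leaves <- tree$tip.label
  purrr::map_dfr(seq_along(pp)[-1], function(k) {
    clade_tips <- all_leaves[pp[[k]]]
    key <- canonical_split_key(clade_tips, all_leaves)
    tibble(node = ntip + k, tips = list(clade_tips), key = key,
           support = sup[k])
  })
}

#' Bootstrap supports for a reference tree
#'
#' Columns of the alignment are resampled with replacement (`n` replicates of
#' the original length); a distance matrix and NJ tree are computed per
#' replicate, and the support of each internal edge of the reference tree is
#' the fraction of replicate trees containing the same unrooted bipartition
#' of the leaf set. Replicates producing a saturated pair are skipped and
#' counted; more than 20% skipped is an error. Results are reproducible
#' given `seed`.
#'
#' @param aln The alignment the reference tree was built from.
#' @param reference A `phylo` tree over exactly the alignment's rows.
#' @param n Number of bootstrap replicates (default 100).
#' @param model Distance model, as in [distance_matrix()].
#' @param seed Integer seed controlling the resampling.
#' @return The reference tree with supports written to `node.label`
#'   (root label empty); skipped-replicate count in `attr(, "skipped")`.
#' @export
bootstrap_supports <- function(aln, reference, n = 100,
                               model = c("poisson", "p"), seed = 1L) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  if (!setequal(aln_ids(aln), reference$tip.label)) {
    abort("reference tree leaves must match alignment rows")
  }
  m <- aln_matrix(aln)
  L <- ncol(m)
  counts <- new.env(parent = emptyenv())
  skipped <- 0
  used <- 0
  with_local_seed(seed, {
    for (b in seq_len(n)) {
      cols <- sample.int(L, L, replace = TRUE)
      rows <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                       rownames(m))
      rep_aln <- as_alignment(rows)
      D <- tryCatch(distance_matrix(rep_aln, model = model),
                    error = function(e) NULL)
      if (is.null(D)) { skipped <- skipped + 1; next }
      tr <- nj_tree(D)
      used <- used + 1
      for (key in bipartitions(tr)$key) {
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  })
  if (skipped > 0.2 * n) {
    abort(sprintf("%d of %d bootstrap replicates skipped (saturated pairs)",
                  skipped, n))
  }
  bp <- bipartitions(reference)
  sup <- rep(NA_real_, reference$Nnode)
  if (used > 0 && nrow(bp) > 0) {
    for (k in seq_len(nrow(bp))) {
      sup[bp$node[k] - length(reference$tip.label)] <-
        (counts[[bp$key[k]]] %||% 0) / used
    }
  }
  out <- reference
  out$node.label <- format_support(sup)
  attr(out, "skipped") <- skipped
  out
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (delegating to [phangorn::midpoint()] after validation).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return The rooted tree.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2) abort("need at least 2 leaves")
  if (is.null(tree$edge.length)) abort("branch lengths required")
  if (all(tree$edge.length == 0)) abort("all branch lengths are zero")
  phangorn::midpoint(tree)
}
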