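# Independent brute-force oracles. These deliberately avoid the package's
# Gotoh/affine decomposition, kd-free contact logic and regex machinery:
# explicit gap-length loops, all-pairs distance scans, sliding windows.

gapcost <- function(k, open, ext) ifelse(k <= 0, 0, open + (k - 1) * ext)

# O(n*m*(n+m)) global alignment score with explicit gap-length maximisation
oracle_global_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  open <- scheme$gap_open; ext <- scheme$gap_extend
  M <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) M[i + 1, 1] <- -gapcost(i, open, ext)
  for (j in seq_len(m)) M[1, j + 1] <- -gapcost(j, open, ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- M[i, j] + scheme$sub[A[i], B[j]]
      for (k in seq_len(i)) {
        cand <- M[i - k + 1, j + 1] - gapcost(k, open, ext)
        if (cand > best) best <- cand
      }
      for (k in seq_len(j)) {
        cand <- M[i + 1, j - k + 1] - gapcost(k, open, ext)
        if (cand > best) best <- cand
      }
      M[i + 1, j + 1] <- best
    }
  }
  M[n + 1, m + 1]
}

# Local optimum: best score of an alignment starting and ending with an
# aligned pair (trailing/leading gaps never help for positive gap costs);
# internal gaps enumerated explicitly, including adjacent gap-in-a/gap-in-b
# runs (each run pays its own opening).
oracle_local_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  open <- scheme$gap_open; ext <- scheme$gap_extend
  P <- matrix(-Inf, n, m)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- scheme$sub[A[i], B[j]]
      pred <- 0
      for (pi in seq_len(i - 1)) {
        for (pj in seq_len(j - 1)) {
          ga <- i - pi - 1
          gb <- j - pj - 1
          cand <- P[pi, pj] - gapcost(ga, open, ext) - gapcost(gb, open, ext)
          if (cand > pred) pred <- cand
        }
      }
      P[i, j] <- s + pred
      if (P[i, j] > best) best <- P[i, j]
    }
  }
  best
}

random_seq <- function(len, alphabet = setdiff(subfamkit:::aa_alphabet(), "X")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random unrooted additive tree and its exact leaf-to-leaf distance matrix
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = sample(LETTERS, n_taxa))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  D <- cophenetic(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# exhaustive least-squares topology oracle: the best-fitting topology over
# all unrooted candidates must match, with ~zero residual for additive input
oracle_best_topology_rss <- function(D) {
  labels <- rownames(D)
  cands <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  rss <- vapply(cands, function(tr) {
    fit <- phangorn::nnls.tree(as.dist(D), tr)
    P <- cophenetic(fit)[labels, labels]
    sum((P - D)^2)
  }, numeric(1))
  cands[[which.min(rss)]]
}

# all-pairs heavy-atom contact scan
oracle_contacts <- function(model, ligand, radius) {
  a <- model$atoms
  ins <- if (!is.null(ligand$ins)) ligand$ins else ""
  lig <- a[a$chain == ligand$chain & a$resno == ligand$resno & a$ins == ins &
             a$het & !a$is_hydrogen, ]
  prot <- a[!a$het & !a$is_hydrogen, ]
  hits <- list()
  if (nrow(prot)) {
    for (i in seq_len(nrow(prot))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                    (prot$z[i] - lig$z[j])^2)
        key <- paste(prot$chain[i], prot$resno[i], prot$ins[i])
        if (is.null(hits[[key]]) || d < hits[[key]]) hits[[key]] <- d
      }
    }
  }
  keep <- Filter(function(d) d <= radius, hits)
  out <- tibble::tibble(
    key = names(keep),
    min_dist = unlist(keep, use.names = FALSE) %||% numeric()
  )
  out[order(out$key), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sliding-window motif matcher over explicit token sets
oracle_motif_positions <- function(seq, pattern) {
  toks <- subfamkit:::tokenize_motif(pattern)
  sets <- lapply(toks, function(t) {
    if (t == "X") LETTERS
    else if (startsWith(t, "[")) strsplit(gsub("\\[|\\]", "", t), "")[[1]]
    else t
  })
  chars <- strsplit(gsub("-", "", seq, fixed = TRUE), "")[[1]]
  L <- length(sets)
  hits <- integer()
  if (length(chars) >= L) {
    for (start in seq_len(length(chars) - L + 1)) {
      ok <- TRUE
      for (k in seq_len(L)) {
        if (!chars[start + k - 1] %in% sets[[k]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, start)
    }
  }
  hits
}

# tiny fixture builders -------------------------------------------------

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(record = "ATOM", serial = 1, atom = "CA",
                          altloc = " ", resname = "ALA", chain = "A",
                          resno = 1, ins = " ", x = 0, y = 0, z = 0,
                          occ = 1, element = "C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(atom) < 4, paste0(" ", atom), atom),
          altloc, resname, chain, resno, ins, x, y, z, occ, 0, element)
}
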