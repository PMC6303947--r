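#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end analysis. Input paths may be
#' `NULL` where a stage is to be skipped (e.g. no kinetics table). All
#' thresholds are validated up front; referenced files must exist at run
#' start.
#'
#' @param seed_alignment Path to the seed alignment (aligned FASTA).
#' @param database Path to the sequence database (FASTA) searched for
#'   homologs; `NULL` to skip the search/extension stage.
#' @param trees Character vector of Newick paths with externally computed
#'   trees; `NULL` to infer bootstrapped NJ trees internally.
#' @param kinetics Path to a kinetics CSV; optional.
#' @param structure_annotations Path to a structure-annotation CSV; optional.
#' @param regions Path to a region-definition CSV; `NULL` for packaged
#'   defaults.
#' @param ref_id Reference row id for numbering; optional (annotation stage
#'   skipped when absent).
#' @param out_dir Output directory.
#' @param e_max,coverage,gap_fraction,support,conservation,radius,bootstrap
#'   Stage thresholds (defaults 1e-3, 0.9, 0.8, 0.5, 0.9, 5.0, 100).
#' @param n_tree_sets Number of independent bootstrapped NJ tree sets used
#'   for the consensus when no external trees are given (default 3).
#' @param seed Integer seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed_alignment, database = NULL, trees = NULL,
                            kinetics = NULL, structure_annotations = NULL,
                            regions = NULL, ref_id = NULL,
                            out_dir = tempfile("subfamkit_run_"),
                            e_max = 1e-3, coverage = 0.9, gap_fraction = 0.8,
                            support = 0.5, conservation = 0.9, radius = 5.0,
                            bootstrap = 100L, n_tree_sets = 3L, seed = 42L) {
  cfg <- list(seed_alignment = seed_alignment, database = database,
              trees = trees, kinetics = kinetics,
              structure_annotations = structure_annotations,
              regions = regions, ref_id = ref_id, out_dir = out_dir,
              e_max = e_max, coverage = coverage,
              gap_fraction = gap_fraction, support = support,
              conservation = conservation, radius = radius,
              bootstrap = as.integer(bootstrap),
              n_tree_sets = as.integer(n_tree_sets), seed = as.integer(seed))
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!frac_ok(cfg$coverage)) abort("coverage must be in (0, 1]")
  if (!frac_ok(cfg$gap_fraction)) abort("gap_fraction must be in (0, 1]")
  if (!frac_ok(cfg$support)) abort("support must be in (0, 1]")
  if (!frac_ok(cfg$conservation)) abort("conservation must be in (0, 1]")
  if (cfg$e_max <= 0) abort("e_max must be positive")
  if (cfg$radius <= 0) abort("radius must be positive")
  if (cfg$bootstrap < 1 || cfg$n_tree_sets < 1) {
    abort("bootstrap and n_tree_sets must be positive")
  }
  for (p in c(cfg$seed_alignment, cfg$database, cfg$trees, cfg$kinetics,
              cfg$structure_annotations, cfg$regions)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input not found: %s", p))
  }
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(log, stage, ...) {
  entry <- tibble(stage = stage, detail = sprintf(...))
  inform(sprintf("[%s] %s", stage, entry$detail))
  bind_rows(log, entry)
}

#' Run the end-to-end subfamily analysis
#'
#' Executes the stages in order: homolog search, seed extension, gap
#' trimming, distance + NJ + bootstrap (or import of external trees),
#' consensus subfamily extraction, sequence annotation, kinetics summary,
#' and knowledgebase export. Every stage logs its row/column counts; a
#' re-run with an identical configuration and seed writes byte-identical
#' CSV/JSON outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the partition, trees, annotations,
#'   kinetics summary, knowledgebase bundle, stage log and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- tibble(stage = character(), detail = character())
  seed_aln <- as_alignment(read_fasta(cfg$seed_alignment))
  log <- log_stage(log, "seed", "%d rows x %d columns", length(seed_aln),
                   aln_ncol(seed_aln))
  scheme <- scoring_scheme()
  aln <- seed_aln
  if (!is.null(cfg$database)) {
    db <- read_fasta(cfg$database)
    queries <- tibble(id = aln_ids(seed_aln),
                      seq = degap(unclass(seed_aln)))
    hits <- collect_homologs(queries, db, scheme, e_max = cfg$e_max,
                             cov_min = cfg$coverage)
    log <- log_stage(log, "search", "%d of %d database sequences accepted",
                     nrow(hits), nrow(db))
    readr::write_csv(hits, file.path(cfg$out_dir, "hits.csv"))
    new_seqs <- db[db$id %in% setdiff(hits$db_id, aln_ids(seed_aln)), ]
    aln <- add_to_seed(seed_aln, new_seqs, scheme)
    log <- log_stage(log, "extend", "alignment now %d rows", length(aln))
  }
  trimmed <- trim_columns(aln, cfg$gap_fraction)
  log <- log_stage(log, "trim", "%d columns removed, %d kept",
                   length(removed_columns(trimmed)), aln_ncol(trimmed))
  write_fasta(trimmed, file.path(cfg$out_dir, "alignment_trimmed.fasta"))
  if (!is.null(cfg$trees)) {
    trees <- unlist(lapply(cfg$trees, read_newick, simplify = FALSE),
                    recursive = FALSE)
    log <- log_stage(log, "trees", "%d external trees imported", length(trees))
  } else {
    trees <- lapply(seq_len(cfg$n_tree_sets), function(k) {
      D <- distance_matrix(trimmed, model = "poisson")
      ref <- nj_tree(D)
      bootstrap_supports(trimmed, ref, n = cfg$bootstrap,
                         seed = cfg$seed + k)
    })
    log <- log_stage(log, "trees", "%d bootstrapped NJ tree sets (n = %d)",
                     length(trees), cfg$bootstrap)
    for (k in seq_along(trees)) {
      write_newick(trees[[k]],
                   file.path(cfg$out_dir, sprintf("nj_bootstrap_%d.nwk", k)))
    }
  }
  partition <- consensus_subfamilies(trees, min_support = cfg$support)
  log <- log_stage(log, "subfamilies", "%d subfamilies, %d of %d leaves assigned",
                   nrow(attr(partition, "provenance")),
                   sum(partition$subfamily != "UNASSIGNED"), nrow(partition))
  readr::write_csv(tidy(partition), file.path(cfg$out_dir, "partition.csv"))
  annotations <- NULL
  if (!is.null(cfg$ref_id) && cfg$ref_id %in% aln_ids(trimmed)) {
    regions <- region_definitions(cfg$regions)
    annotations <- annotate_alignment(trimmed, cfg$ref_id, regions)
    log <- log_stage(log, "annotate", "%d rows annotated", nrow(annotations))
    readr::write_csv(annotations, file.path(cfg$out_dir, "annotations.csv"))
  }
  kin <- NULL
  if (!is.null(cfg$kinetics)) {
    records <- read_table(cfg$kinetics, "kinetics")
    kin <- family_summary(records)
    log <- log_stage(log, "kinetics", "%d records, %d enzymes",
                     nrow(kin$records), kin$summary$n_enzymes)
    readr::write_csv(tidy(kin), file.path(cfg$out_dir, "kinetics_by_subfamily.csv"))
  }
  bundle <- export_knowledgebase(partition, annotations, kin, trees[[1]],
                                 out_dir = cfg$out_dir)
  log <- log_stage(log, "export", "bundle with %d annotation records",
                   length(bundle$proteins))
  readr::write_csv(log, file.path(cfg$out_dir, "stage_log.csv"))
  cfg_out <- cfg
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(partition = partition, trees = trees,
                 annotations = annotations, kinetics = kin, bundle = bundle,
                 log = log, out_dir = cfg$out_dir))
}

#' Export a knowledgebase bundle
#'
#' Joins the partition, per-protein annotations, kinetics summary and tree
#' into one JSON document (plus flat CSVs when `out_dir` is given). Every
#' annotated protein must be part of the partition's namespace (orphans are
#' an error); proteins present in the kinetics table but absent from the
#' tree are flagged external rather than dropped.
#'
#' @param partition A `subfam_partition`.
#' @param annotations Optional [annotate_alignment()] tibble.
#' @param kinetics Optional [family_summary()].
#' @param tree A `phylo` tree of the classified proteins.
#' @param out_dir Optional output directory for `knowledgebase.json`.
#' @return The bundle list (invisibly when written).
#' @export
export_knowledgebase <- function(partition, annotations = NULL,
                                 kinetics = NULL, tree = NULL,
                                 out_dir = NULL) {
  ids <- partition$leaf_id
  if (!is.null(annotations)) {
    orphans <- setdiff(annotations$id, ids)
    if (length(orphans)) {
      abort(paste0("annotation ids not in partition: ",
                   paste(orphans, collapse = ", ")))
    }
  }
  kin_ids <- if (!is.null(kinetics)) unique(kinetics$records$enzyme_id) else character()
  external <- setdiff(kin_ids, ids)
  proteins <- lapply(union(ids, kin_ids), function(id) {
    rec <- list(id = id,
                subfamily = partition$subfamily[match(id, ids)] %||% NA,
                external = id %in% external)
    if (is.na(rec$subfamily) && rec$external) rec$subfamily <- "EXTERNAL"
    if (!is.null(annotations) && id %in% annotations$id) {
      rec$annotation <- as.list(annotations[annotations$id == id, ])
    }
    if (!is.null(kinetics)) {
      kr <- kinetics$records[kinetics$records$enzyme_id == id, ]
      if (nrow(kr)) {
        rec$kinetics <- list(
          substrates = unique(kr$substrate),
          best_substrate = kr$substrate[kr$best][1] %||% NA,
          best_efficiency = kr$kcat_over_km_per_M_per_s[kr$best][1] %||% NA
        )
      }
    }
    rec
  })
  bundle <- list(
    schema_version = "1.0",
    tree_newick = if (!is.null(tree)) ape::write.tree(tree) else NULL,
    subfamilies = as.list(attr(partition, "provenance") |>
                            (\(p) split(p, seq_len(nrow(p))))() |>
                            lapply(as.list)),
    proteins = proteins,
    provenance = list(generated_by = "subfamkit",
                      n_leaves = length(ids))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(bundle, file.path(out_dir, "knowledgebase.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    invisible(bundle)
  } else {
    bundle
  }
}
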