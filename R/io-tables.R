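#' Read curated kinetics or structure-annotation CSV tables
#'
#' Validating readers for the two curated spreadsheet schemas consumed by the
#' pipeline. Empty cells become missing values and numeric columns accept
#' scientific notation.
#'
#' Schemas:
#' * `kinetics`: `enzyme_id, subfamily, substrate, cofactor, kcat_per_s,
#'   km_uM, kcat_over_km_per_M_per_s` (one enzyme-substrate-cofactor
#'   measurement per row; kcat in 1/s, KM in micromolar, efficiency in
#'   1/(M s)).
#' * `structure_annotations`: `pdb_id, protein_id, ligand_codes,
#'   cofactor_code, cofactor_redox, ligand_redox`.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema One of `"kinetics"` or `"structure_annotations"`.
#' @return A typed tibble.
#' @export
read_table <- function(path, schema = c("kinetics", "structure_annotations")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  required <- switch(schema,
    kinetics = c("enzyme_id", "subfamily", "substrate", "cofactor",
                 "kcat_per_s", "km_uM", "kcat_over_km_per_M_per_s"),
    structure_annotations = c("pdb_id", "protein_id", "ligand_codes",
                              "cofactor_code", "cofactor_redox", "ligand_redox")
  )
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (schema == "kinetics") {
    for (col in c("kcat_per_s", "km_uM", "kcat_over_km_per_M_per_s")) {
      x[[col]] <- as.numeric(x[[col]])
      neg <- !is.na(x[[col]]) & x[[col]] <= 0
      if (any(neg)) {
        abort(sprintf("non-positive value in kinetic column '%s' (row %d)",
                      col, which(neg)[1]))
      }
    }
    x <- mutate(x, across(c("enzyme_id", "subfamily", "substrate", "cofactor"),
                          as.character))
  } else {
    x <- mutate(x, across(dplyr::all_of(required), as.character))
  }
  as_tibble(x)
}
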