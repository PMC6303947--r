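#' Read PDB-format macromolecular coordinates
#'
#' Parses `ATOM`/`HETATM` records of a PDB-format text file into a structure
#' model. Only the first model of a multi-model file is read. Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' the alphabetically first altloc id), so at most one atom survives per
#' (residue, atom name). Hydrogens and waters are retained but flagged.
#'
#' The fixed-column reader is deliberately strict: an unparsable coordinate
#' field reports its line number, and a file without any atom record is an
#' error.
#'
#' @param path Path to a PDB-format file.
#' @param structure_id Identifier for the model; defaults to the file name
#'   without extension.
#' @return A `structure_model`: a list with `structure_id` and an `atoms`
#'   tibble (record, serial, atom, altloc, resname, chain, resno, ins, x, y,
#'   z, occ, element, het, is_water, is_hydrogen).
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) abort(sprintf("no ATOM/HETATM records in '%s'", path))
  ln <- which(sel)
  rec <- lines[sel]
  fld <- function(from, to) trimws(substr(rec, from, to))
  num <- function(from, to, what) {
    raw <- substr(rec, from, to)
    out <- suppressWarnings(as.numeric(raw))
    bad <- is.na(out) & nzchar(trimws(raw))
    if (any(bad) || any(!nzchar(trimws(raw)))) {
      i <- which(is.na(out))[1]
      abort(sprintf("unparsable %s field at line %d of '%s'", what, ln[i], path))
    }
    out
  }
  occ_raw <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  occ_raw[is.na(occ_raw)] <- 1
  atoms <- tibble(
    record = fld(1, 6),
    serial = suppressWarnings(as.integer(fld(7, 11))),
    atom = fld(13, 16),
    altloc = fld(17, 17),
    resname = fld(18, 20),
    chain = fld(22, 22),
    resno = suppressWarnings(as.integer(fld(23, 26))),
    ins = fld(27, 27),
    x = num(31, 38, "x-coordinate"),
    y = num(39, 46, "y-coordinate"),
    z = num(47, 54, "z-coordinate"),
    occ = occ_raw,
    element = toupper(fld(77, 78)),
    line = ln
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    abort(sprintf("occupancy outside [0, 1] at line %d",
                  atoms$line[which(atoms$occ < 0 | atoms$occ > 1)[1]]))
  }
  # element fallback from the atom-name column when columns 77-78 are blank
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[^A-Za-z].*$", "",
                                      gsub("^[0-9]+", "", atoms$atom[blank])), 1, 1)
  atoms$element <- toupper(atoms$element)
  # altloc resolution: per (chain, resno, ins, resname, atom name) keep the
  # highest occupancy; ties go to the alphabetically first altloc id
  atoms <- atoms |>
    arrange(.data$chain, .data$resno, .data$ins, .data$resname, .data$atom,
            dplyr::desc(.data$occ), .data$altloc) |>
    distinct(.data$chain, .data$resno, .data$ins, .data$resname, .data$atom,
             .keep_all = TRUE) |>
    arrange(.data$line)
  atoms <- atoms |>
    mutate(
      het = .data$record == "HETATM",
      is_water = .data$resname == "HOH",
      is_hydrogen = .data$element %in% c("H", "D")
    ) |>
    select(-"line")
  structure(
    list(structure_id = structure_id %||% sub("\\.[^.]*$", "", basename(path)),
         atoms = atoms),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  res <- dplyr::distinct(x$atoms, .data$chain, .data$resno, .data$ins, .data$resname)
  cat(sprintf("<structure_model %s: %d atoms, %d residues, chains %s>\n",
              x$structure_id, nrow(x$atoms), nrow(res),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Write a structure model as PDB-format text
#'
#' Minimal fixed-column writer used mainly to serialise synthetic complexes
#' from [simulate_complex()].
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    "", a$resname, a$chain, a$resno, ifelse(nzchar(a$ins), a$ins, " "),
    a$x, a$y, a$z, a$occ, 0, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Residues of a structure model
#'
#' @param model A `structure_model`.
#' @return A tibble with one row per residue (chain, resno, ins, resname, het).
#' @export
structure_residues <- function(model) {
  model$atoms |>
    distinct(.data$chain, .data$resno, .data$ins, .data$resname, .data$het)
}
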