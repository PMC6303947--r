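#' Derive catalytic efficiency and check unit consistency
#'
#' Catalytic efficiency is kcat/KM in 1/(M s); KM is carried in micromolar,
#' so efficiency = kcat / (KM * 1e-6). For each record the missing member of
#' {kcat, KM, efficiency} is filled from the other two. Records carrying all
#' three are checked for unit consistency: a relative discrepancy above 5%
#' flags the record (`inconsistent`), keeping the reported efficiency.
#' Records with fewer than two quantities are left untouched. The operation
#' is idempotent.
#'
#' @param records A kinetics tibble ([read_table()] schema).
#' @return The tibble with filled values and an `inconsistent` flag column.
#' @examples
#' r <- tibble::tibble(enzyme_id = "E1", subfamily = "LDHD",
#'   substrate = "pyruvate", cofactor = "NADH", kcat_per_s = 100,
#'   km_uM = 50, kcat_over_km_per_M_per_s = NA_real_)
#' derive_efficiency(r)$kcat_over_km_per_M_per_s  # 2e6
#' @export
derive_efficiency <- function(records) {
  k <- records$kcat_per_s
  km <- records$km_uM
  eff <- records$kcat_over_km_per_M_per_s
  implied <- k / (km * 1e-6)
  fill_eff <- is.na(eff) & !is.na(k) & !is.na(km)
  eff[fill_eff] <- implied[fill_eff]
  fill_k <- is.na(k) & !is.na(eff) & !is.na(km)
  k[fill_k] <- eff[fill_k] * km[fill_k] * 1e-6
  fill_km <- is.na(km) & !is.na(eff) & !is.na(k)
  km[fill_km] <- k[fill_km] / eff[fill_km] * 1e6
  inconsistent <- !is.na(records$kcat_per_s) & !is.na(records$km_uM) &
    !is.na(records$kcat_over_km_per_M_per_s) &
    abs(implied - records$kcat_over_km_per_M_per_s) >
      0.05 * records$kcat_over_km_per_M_per_s
  records$kcat_per_s <- k
  records$km_uM <- km
  records$kcat_over_km_per_M_per_s <- eff
  records$inconsistent <- inconsistent
  records
}

#' Flag the best substrate of each enzyme
#'
#' Duplicated measurements of the same enzyme/substrate/cofactor are first
#' reconciled by keeping the highest-efficiency row (conflicts logged via a
#' message). Per enzyme, the substrate with maximal efficiency is flagged
#' best; ties are broken by smaller KM, then alphabetically. Enzymes with no
#' efficiency value are excluded from best-flagging and listed in
#' `attr(, "excluded_enzymes")`.
#'
#' @param records A kinetics tibble.
#' @return The (deduplicated) tibble with a logical `best` column.
#' @export
best_substrates <- function(records) {
  records <- derive_efficiency(records)
  n0 <- nrow(records)
  records <- records |>
    group_by(.data$enzyme_id, .data$substrate, .data$cofactor) |>
    arrange(dplyr::desc(!is.na(.data$kcat_over_km_per_M_per_s)),
            dplyr::desc(.data$kcat_over_km_per_M_per_s), .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  if (nrow(records) < n0) {
    inform(sprintf("best_substrates: %d conflicting duplicate measurement(s) dropped (kept highest efficiency)",
                   n0 - nrow(records)))
  }
  with_eff <- filter(records, !is.na(.data$kcat_over_km_per_M_per_s))
  best_rows <- with_eff |>
    group_by(.data$enzyme_id) |>
    arrange(dplyr::desc(.data$kcat_over_km_per_M_per_s), .data$km_uM,
            .data$substrate, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  records$best <- paste(records$enzyme_id, records$substrate, records$cofactor) %in%
    paste(best_rows$enzyme_id, best_rows$substrate, best_rows$cofactor)
  attr(records, "excluded_enzymes") <-
    setdiff(unique(records$enzyme_id), unique(with_eff$enzyme_id))
  records
}

#' Family-level kinetics summary
#'
#' Aggregates a kinetics table into the family's headline statistics:
#' medians of catalytic efficiency and KM over best-flagged records, the
#' number of enzyme-substrate pairs with a determined efficiency, the number
#' of distinct accepted compounds (any substrate row with measured
#' activity), the number of distinct best compounds, and per-subfamily
#' medians. The median of an even-sized set is the mean of the central
#' pair.
#'
#' @param records A kinetics tibble.
#' @return A `family_summary` object; see [glance.family_summary()] and
#'   [tidy.family_summary()].
#' @export
family_summary <- function(records) {
  if (nrow(records) == 0) abort("empty kinetics table")
  records <- best_substrates(records)
  best <- filter(records, .data$best)
  with_eff <- filter(records, !is.na(.data$kcat_over_km_per_M_per_s))
  summary <- tibble(
    median_best_efficiency = median(best$kcat_over_km_per_M_per_s),
    median_best_km_uM = median(best$km_uM, na.rm = TRUE),
    n_pairs_with_efficiency = nrow(distinct(with_eff, .data$enzyme_id,
                                            .data$substrate)),
    n_accepted_compounds = dplyr::n_distinct(records$substrate),
    n_best_compounds = dplyr::n_distinct(best$substrate),
    n_enzymes = dplyr::n_distinct(records$enzyme_id)
  )
  per_subfamily <- best |>
    group_by(.data$subfamily) |>
    summarise(n_enzymes = dplyr::n_distinct(.data$enzyme_id),
              median_best_efficiency = median(.data$kcat_over_km_per_M_per_s),
              median_best_km_uM = median(.data$km_uM, na.rm = TRUE),
              .groups = "drop")
  structure(list(summary = summary, per_subfamily = per_subfamily,
                 records = records),
            class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat("<family kinetics summary>\n")
  print(x$summary)
  cat("per subfamily:\n")
  print(x$per_subfamily)
  invisible(x)
}

#' @rdname family_summary
#' @param x A `family_summary`.
#' @param ... Unused.
#' @export
glance.family_summary <- function(x, ...) x$summary

#' @rdname family_summary
#' @export
tidy.family_summary <- function(x, ...) x$per_subfamily
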