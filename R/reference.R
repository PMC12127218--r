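reference_columns <- c(
  table_id = "character", procedure = "character", processed_food = "character",
  display_name = "character", raw_commodity = "character",
  compartment = "character", method = "character", value = "numeric",
  sd = "numeric", n_samples = "integer", partition_ratio = "numeric",
  mean_reverse_yield = "numeric", reverse_yield_sd = "numeric",
  component = "character", plant_part = "character",
  raw_content_mg_gae_per_g = "numeric", consumable = "logical",
  note = "character"
)

#' Load the bundled PRCF reference table
#'
#' The package ships a machine-readable transcription of the published
#' reference tables: 120 processed-to-raw conversion factors (32 pure
#' percentage-yield, 50 partition-corrected, 38 migration-rate) together with
#' the partition-only co-product rows (husk, juicing pulps, oil cakes) that
#' have no finished consumable product and therefore no factor of their own.
#' Those extra rows are flagged `consumable = FALSE`; they carry the
#' partition ratios needed for mass-balance validation.
#'
#' @param path Path to a reference file, or `NULL` for the bundled copy.
#'   CSV and JSON (the bundled mirror format) are detected by extension.
#' @param include_partition_only If `TRUE`, include the non-consumable
#'   partition-only rows; the default returns exactly the 120 factors.
#' @return A data.frame of class `prcf_reference`, one row per record.
#' @export
#' @examples
#' ref <- load_reference()
#' nrow(ref) # 120
load_reference <- function(path = NULL, include_partition_only = FALSE) {
  fmt <- NULL
  if (is.null(path)) {
    path <- system.file("extdata", "prcf_reference.csv", package = "prcf")
    fmt <- "csv"
  } else {
    fmt <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop_prcf(sprintf("reference file not found: %s", path), "prcf_io_error")
  }
  rows <- if (fmt == "json") {
    out <- jsonlite::fromJSON(path)
    as.data.frame(out, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), encoding = "UTF-8")
  }
  missing_cols <- setdiff(names(reference_columns), names(rows))
  if (length(missing_cols) > 0) {
    stop_prcf(sprintf("reference file is corrupt: missing columns %s",
                      paste(missing_cols, collapse = ", ")),
              "prcf_data_corruption")
  }
  rows <- rows[, names(reference_columns)]
  for (col in names(reference_columns)) {
    rows[[col]] <- switch(reference_columns[[col]],
                          character = as.character(rows[[col]]),
                          numeric = as.numeric(rows[[col]]),
                          integer = as.integer(rows[[col]]),
                          logical = as.logical(rows[[col]]))
  }
  if (anyNA(rows$value[rows$consumable]) ||
      any(rows$value[rows$consumable] <= 0)) {
    stop_prcf("reference file is corrupt: consumable rows need positive factors",
              "prcf_data_corruption")
  }
  if (!include_partition_only) rows <- rows[rows$consumable, ]
  rownames(rows) <- NULL
  class(rows) <- c("prcf_reference", "data.frame")
  rows
}

#' Write a reference table to CSV or JSON
#'
#' Serializes a reference table in either of the two bundled formats. A
#' write/load round trip reproduces the rows exactly.
#'
#' @param rows A `prcf_reference` data.frame.
#' @param path Output path; format chosen by extension (`.json` or CSV).
#' @return `path`, invisibly.
#' @export
write_reference <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

# One unit of the last printed digit of the factor, widened by the printed
# rounding of the reverse-yield mean: the published factors were computed
# from unrounded means, so the product of the *printed* ratio and yield can
# sit slightly outside one unit of the factor's last digit (e.g. butter
# 0.10 x 22 = 2.2 printed as 2.1, skim milk powder 0.90 x 11 = 9.9 printed
# as 9.7).
eq2_tolerance <- function(value, partition_ratio, mean_reverse_yield) {
  unit_last_digit(value) +
    partition_ratio * unit_last_digit(mean_reverse_yield) / 2
}

#' Validate the integrity of a PRCF reference table
#'
#' Runs three checks and reports every violation rather than raising errors:
#' \itemize{
#'   \item category counts: 120 consumable factors split 32 pure-yield /
#'     50 partitioned / 38 migration;
#'   \item mass balance: within each (procedure, raw commodity) group of the
#'     partition table, the distinct compartment ratios sum to 1 ± `tol`;
#'   \item partition consistency: each consumable partitioned row satisfies
#'     value ≈ partition_ratio × mean_reverse_yield within one unit of the
#'     factor's last printed digit (widened for the yield's own printed
#'     rounding).
#' }
#'
#' The bundled table carries one known printed inconsistency: the milling
#' partition ratios for whole grains (bran 0.18, germ 0.04, endosperm 0.88)
#' sum to 1.10 and are reported as a mass-balance failure.
#'
#' @param rows Reference rows including the partition-only co-product rows,
#'   as returned by `load_reference(include_partition_only = TRUE)`; mass
#'   balance is only meaningful with the co-products present.
#' @param expected_counts Named vector of expected category counts.
#' @param tol Mass-balance tolerance on the ratio sum (default 0.02).
#' @return An object of class `prcf_validation_report`.
#' @export
validate_reference <- function(rows = load_reference(include_partition_only = TRUE),
                               expected_counts = c(total = 120, pure_yield = 32,
                                                   partitioned = 50,
                                                   migration = 38),
                               tol = 0.02) {
  cons <- rows[rows$consumable, ]
  counts <- c(
    total = nrow(cons),
    pure_yield = sum(cons$method == "percentage_yield"),
    partitioned = sum(cons$method == "partitioned_yield"),
    migration = sum(cons$method == "migration_rate")
  )
  counts_ok <- identical(unname(counts[names(expected_counts)]),
                         unname(as.integer(expected_counts)))

  part <- rows[rows$method == "partitioned_yield" & !is.na(rows$partition_ratio), ]
  mass_balance_failures <- character(0)
  if (nrow(part) > 0) {
    key <- paste(part$procedure, part$raw_commodity, sep = " | ")
    for (grp in unique(key)) {
      sub <- part[key == grp, c("compartment", "partition_ratio")]
      sub <- sub[!duplicated(sub$compartment), ]
      s <- sum(sub$partition_ratio)
      if (abs(s - 1) > tol) {
        mass_balance_failures <- c(mass_balance_failures,
                                   sprintf("%s (sum = %.2f)", grp, s))
      }
    }
  }

  cp <- part[part$consumable & !is.na(part$value) &
               !is.na(part$mean_reverse_yield), ]
  dev <- abs(cp$value - cp$partition_ratio * cp$mean_reverse_yield)
  bad <- dev > eq2_tolerance(cp$value, cp$partition_ratio, cp$mean_reverse_yield)
  eq2_inconsistencies <- cp[bad, c("procedure", "processed_food", "value",
                                   "partition_ratio", "mean_reverse_yield")]
  rownames(eq2_inconsistencies) <- NULL

  status <- if (counts_ok && length(mass_balance_failures) == 0 &&
                nrow(eq2_inconsistencies) == 0) "pass" else "fail"
  structure(
    list(count_total = unname(counts[["total"]]),
         count_pure_yield = unname(counts[["pure_yield"]]),
         count_partitioned = unname(counts[["partitioned"]]),
         count_migration = unname(counts[["migration"]]),
         counts_ok = counts_ok,
         mass_balance_failures = mass_balance_failures,
         eq2_inconsistencies = eq2_inconsistencies,
         status = status),
    class = "prcf_validation_report"
  )
}

#' @export
print.prcf_validation_report <- function(x, ...) {
  cat("PRCF reference validation\n")
  cat(sprintf("  factors: %d total = %d pure yield + %d partitioned + %d migration%s\n",
              x$count_total, x$count_pure_yield, x$count_partitioned,
              x$count_migration, if (x$counts_ok) "" else "  [MISMATCH]"))
  if (length(x$mass_balance_failures) == 0) {
    cat("  mass balance: all partition groups sum to 1 within tolerance\n")
  } else {
    cat("  mass-balance failures:\n")
    for (f in x$mass_balance_failures) cat("    -", f, "\n")
  }
  if (nrow(x$eq2_inconsistencies) == 0) {
    cat("  partition consistency: all factors match ratio x reverse yield\n")
  } else {
    cat(sprintf("  partition inconsistencies: %d rows\n",
                nrow(x$eq2_inconsistencies)))
    print(x$eq2_inconsistencies)
  }
  cat(sprintf("  status: %s\n", toupper(x$status)))
  invisible(x)
}

#' Look up a conversion factor by procedure and processed food
#'
#' Matching is case-insensitive and whitespace-insensitive on the canonical
#' names. When no row matches, the error lists the nearest names by edit
#' distance as suggestions.
#'
#' @param procedure Processing-procedure name (e.g. `"Cheese production"`).
#' @param processed_food Processed-food name (e.g. `"Gouda cheese"`).
#' @param rows Reference rows, defaulting to the bundled table.
#' @return A [conversion_factor()].
#' @export
#' @examples
#' lookup_factor("cheese production", "gouda cheese")$value # 1.0
lookup_factor <- function(procedure, processed_food, rows = load_reference()) {
  cons <- rows[rows$consumable, ]
  hit <- normalize_name(cons$procedure) == normalize_name(procedure) &
    normalize_name(cons$processed_food) == normalize_name(processed_food)
  if (!any(hit)) {
    cand <- unique(cons$processed_food)
    d <- utils::adist(normalize_name(processed_food), normalize_name(cand))[1, ]
    nearest <- cand[order(d)][seq_len(min(3, length(cand)))]
    stop_prcf(sprintf(
      "no conversion factor for '%s' under procedure '%s'; nearest names: %s",
      processed_food, procedure, paste(nearest, collapse = ", ")),
      "prcf_not_found")
  }
  row <- cons[which(hit)[1], ]
  conversion_factor(
    value = row$value, processed_food = row$processed_food,
    raw_commodity = row$raw_commodity, procedure = row$procedure,
    method = row$method, sd = row$sd, n_samples = row$n_samples,
    partition_ratio = row$partition_ratio,
    mean_reverse_yield = row$mean_reverse_yield
  )
}

#' Partition scheme of a raw commodity from the reference table
#'
#' Collects the distinct compartments and partition ratios recorded for one
#' (procedure, raw commodity) combination into a [partition_scheme()].
#'
#' @inheritParams lookup_factor
#' @param raw_commodity Raw-commodity name (e.g. `"Eggs"`).
#' @param tol Tolerance forwarded to [partition_scheme()].
#' @return A [partition_scheme()].
#' @export
#' @examples
#' reference_partition_scheme("Powdered egg product production", "Eggs")
reference_partition_scheme <- function(procedure, raw_commodity,
                                       rows = load_reference(include_partition_only = TRUE),
                                       tol = 0.02) {
  sub <- rows[rows$method == "partitioned_yield" &
                normalize_name(rows$procedure) == normalize_name(procedure) &
                normalize_name(rows$raw_commodity) == normalize_name(raw_commodity) &
                !is.na(rows$partition_ratio), ]
  if (nrow(sub) == 0) {
    stop_prcf(sprintf("no partition data for '%s' under procedure '%s'",
                      raw_commodity, procedure), "prcf_not_found")
  }
  sub <- sub[!duplicated(sub$compartment), ]
  ratios <- sub$partition_ratio
  names(ratios) <- sub$compartment
  partition_scheme(sub$raw_commodity[1], ratios, tol = tol)
}
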