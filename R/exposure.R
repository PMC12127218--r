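#' Convert one consumption amount to raw-commodity equivalent
#'
#' Multiplies a consumed processed-food mass by a conversion factor; when the
#' factor carries a standard deviation, first-order uncertainty scaling gives
#' the raw-equivalent SD. The classic worked example: a whole egg split into
#' 0.67 g white and 0.33 g yolk converts back to 1 g of egg with
#' partition-corrected factors, but to 2 g with naive reverse yields.
#'
#' @param amount Consumed mass, g/day (non-negative).
#' @param factor A [conversion_factor()] or a bare numeric factor value.
#' @param processed_food Optional food label checked against the factor's
#'   own label; a mismatch is a pairing error.
#' @return A one-row data.frame with `raw_commodity`, `raw_equivalent_g`,
#'   and `raw_equivalent_sd_g`.
#' @export
convert_record <- function(amount, factor, processed_food = NULL) {
  if (is.numeric(factor)) factor <- conversion_factor(factor)
  if (!inherits(factor, "conversion_factor")) {
    stop_prcf("factor must be a conversion_factor or numeric", "prcf_pairing_error")
  }
  if (!is.null(processed_food) && !is.na(factor$processed_food) &&
      normalize_name(processed_food) != normalize_name(factor$processed_food)) {
    stop_prcf(sprintf("factor for '%s' paired with record for '%s'",
                      factor$processed_food, processed_food),
              "prcf_pairing_error")
  }
  if (anyNA(amount) || any(amount < 0)) {
    stop_prcf("amount must be non-negative", "prcf_invalid_observation")
  }
  data.frame(
    raw_commodity = factor$raw_commodity,
    raw_equivalent_g = amount * factor$value,
    raw_equivalent_sd_g = if (is.na(factor$sd)) NA_real_ else amount * factor$sd,
    stringsAsFactors = FALSE
  )
}

resolve_diary <- function(diary, rows, strict) {
  needed <- c("subject_id", "processed_food", "procedure", "amount_g")
  missing_cols <- setdiff(needed, names(diary))
  if (length(missing_cols) > 0) {
    stop_prcf(sprintf("diary is missing columns: %s",
                      paste(missing_cols, collapse = ", ")), "prcf_io_error")
  }
  n <- nrow(diary)
  out <- data.frame(
    subject_id = as.character(diary$subject_id),
    processed_food = as.character(diary$processed_food),
    procedure = as.character(diary$procedure),
    amount_g = as.numeric(diary$amount_g),
    raw_commodity = rep(NA_character_, n), factor = rep(NA_real_, n),
    factor_sd = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  skipped <- character(0)
  for (i in seq_len(n)) {
    cf <- tryCatch(
      lookup_factor(out$procedure[i], out$processed_food[i], rows),
      prcf_not_found = function(e) e
    )
    if (inherits(cf, "prcf_not_found")) {
      if (strict) stop_prcf(conditionMessage(cf), "prcf_not_found")
      skipped <- c(skipped, sprintf("row %d: %s", i, conditionMessage(cf)))
      next
    }
    out$raw_commodity[i] <- cf$raw_commodity
    out$factor[i] <- cf$value
    out$factor_sd[i] <- cf$sd
  }
  attr(out, "skipped") <- skipped
  out
}

#' Convert a consumption diary to raw-commodity intake
#'
#' Resolves each diary record to a conversion factor from the reference table
#' and multiplies. In lenient mode (default) unresolvable foods are dropped
#' and listed in the `"skipped"` attribute of the result; in strict mode they
#' abort the conversion.
#'
#' @param diary Data.frame with columns `subject_id`, `processed_food`,
#'   `procedure`, `amount_g`.
#' @param rows Reference rows, defaulting to the bundled table.
#' @param strict Abort on unresolvable foods instead of skipping them.
#' @return Data.frame with one row per resolved record: the diary columns
#'   plus `raw_commodity`, `factor`, `raw_equivalent_g`,
#'   `raw_equivalent_sd_g`; skipped records in `attr(, "skipped")`.
#' @export
convert_diary <- function(diary, rows = load_reference(), strict = FALSE) {
  res <- resolve_diary(diary, rows, strict)
  skipped <- attr(res, "skipped")
  res <- res[!is.na(res$factor), , drop = FALSE]
  res$raw_equivalent_g <- res$amount_g * res$factor
  res$raw_equivalent_sd_g <- res$amount_g * res$factor_sd
  res$factor_sd <- NULL
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Chemical profile of a raw commodity
#'
#' Couples a chemical's concentration in a raw commodity with optional
#' compartment-specific migration ratios. When processing splits the
#' commodity, a chemical confined to one compartment (cholesterol in egg
#' yolk, say) has migration ratio 1 there and 0 elsewhere; chemicals that
#' follow mass keep the partition ratios themselves.
#'
#' @param chemical Chemical name.
#' @param raw_commodity Raw-commodity name.
#' @param concentration Concentration in the raw commodity, ug per g.
#' @param compartment_migration Optional named numeric vector of migration
#'   ratios in \[0, 1\], one per compartment.
#' @return An object of class `chemical_profile`.
#' @export
chemical_profile <- function(chemical, raw_commodity, concentration,
                             compartment_migration = NULL) {
  if (is.na(concentration) || concentration < 0) {
    stop_prcf("concentration must be non-negative", "prcf_domain_error")
  }
  if (!is.null(compartment_migration)) {
    if (is.null(names(compartment_migration)) ||
        any(compartment_migration < 0) || any(compartment_migration > 1)) {
      stop_prcf("compartment_migration must be named ratios in [0, 1]",
                "prcf_schema_error")
    }
  }
  structure(list(chemical = chemical, raw_commodity = raw_commodity,
                 concentration = concentration,
                 compartment_migration = compartment_migration),
            class = "chemical_profile")
}

#' Chemical-adjusted conversion factor for one compartment
#'
#' Replaces the mass partition ratio in the partition-corrected factor with a
#' chemical's migration ratio for the compartment. With migration 1 the
#' compartment carries the commodity's whole burden of the chemical (1 g of
#' egg yolk "equals" 3 g of egg for cholesterol); with migration 0 the factor
#' is 0 because the chemical never reaches that compartment. With no profile
#' the mass partition ratio is used and the result is the ordinary
#' partition-corrected factor.
#'
#' @param partition A [partition_scheme()].
#' @param compartment Compartment name within the scheme.
#' @param mean_reverse_yield Mean reverse yield of the processed product
#'   relative to its compartment.
#' @param profile Optional [chemical_profile()] supplying migration ratios.
#' @param migration_ratio Optional explicit migration ratio in \[0, 1\],
#'   taking precedence over `profile`.
#' @return A [conversion_factor()] (or a zero-valued plain list when the
#'   migration ratio is 0, since a conversion factor proper must be
#'   positive — the `value` element is 0 and `method` is reported the same
#'   way).
#' @export
#' @examples
#' eggs <- partition_scheme("eggs", c(`egg white` = 0.67, `egg yolk` = 0.33))
#' chemical_adjusted_factor(eggs, "egg yolk", 3.0, migration_ratio = 1)$value # 3
chemical_adjusted_factor <- function(partition, compartment, mean_reverse_yield,
                                     profile = NULL, migration_ratio = NULL) {
  if (!inherits(partition, "partition_scheme")) {
    stop_prcf("partition must be a partition_scheme", "prcf_schema_error")
  }
  if (!compartment %in% names(partition$compartments)) {
    stop_prcf(sprintf("unknown compartment '%s' (scheme has: %s)", compartment,
                      paste(names(partition$compartments), collapse = ", ")),
              "prcf_schema_error")
  }
  ratio <- partition$compartments[[compartment]]
  if (!is.null(profile) && !is.null(profile$compartment_migration) &&
      compartment %in% names(profile$compartment_migration)) {
    ratio <- profile$compartment_migration[[compartment]]
  }
  if (!is.null(migration_ratio)) {
    if (migration_ratio < 0 || migration_ratio > 1) {
      stop_prcf("migration_ratio must lie in [0, 1]", "prcf_schema_error")
    }
    ratio <- migration_ratio
  }
  value <- ratio * mean_reverse_yield
  if (value == 0) {
    # a chemical absent from the compartment: legitimate zero factor
    return(structure(
      list(processed_food = NA_character_,
           raw_commodity = partition$raw_commodity, procedure = NA_character_,
           method = "partitioned_yield", value = 0, sd = NA_real_,
           n_samples = 1L, partition_ratio = ratio,
           mean_reverse_yield = mean_reverse_yield),
      class = "conversion_factor"
    ))
  }
  conversion_factor(value, raw_commodity = partition$raw_commodity,
                    method = "partitioned_yield", partition_ratio = ratio,
                    mean_reverse_yield = mean_reverse_yield)
}

#' Estimate chemical exposure from a consumption diary
#'
#' Converts each diary record to raw-commodity equivalents and multiplies by
#' raw-commodity chemical concentrations: exposure (ug/day) = consumed amount
#' (g/day) x conversion factor x concentration (ug/g). Exposure is linear in
#' amounts and concentrations, and subjects are independent.
#'
#' @inheritParams convert_diary
#' @param concentrations Data.frame with columns `chemical`, `raw_commodity`,
#'   `concentration_ug_per_g`.
#' @return Data.frame with columns `subject_id`, `chemical`, `raw_commodity`,
#'   `raw_equivalent_g`, `exposure_ug` (one row per subject, chemical, and
#'   commodity); records skipped for missing factors or concentrations are
#'   listed in `attr(, "skipped")`.
#' @export
estimate_exposure <- function(diary, concentrations, rows = load_reference(),
                              strict = FALSE) {
  needed <- c("chemical", "raw_commodity", "concentration_ug_per_g")
  missing_cols <- setdiff(needed, names(concentrations))
  if (length(missing_cols) > 0) {
    stop_prcf(sprintf("concentration table is missing columns: %s",
                      paste(missing_cols, collapse = ", ")), "prcf_io_error")
  }
  conv <- convert_diary(diary, rows, strict)
  skipped <- attr(conv, "skipped")
  empty <- data.frame(subject_id = character(0), chemical = character(0),
                      raw_commodity = character(0),
                      raw_equivalent_g = numeric(0), exposure_ug = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(conv) == 0) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  conc <- concentrations
  conc$.key <- normalize_name(conc$raw_commodity)
  conv$.key <- normalize_name(conv$raw_commodity)
  merged <- merge(conv, conc[, c("chemical", "concentration_ug_per_g", ".key")],
                  by = ".key")
  unmatched <- setdiff(conv$.key, conc$.key)
  if (length(unmatched) > 0) {
    msg <- sprintf("no concentration for raw commodity: %s",
                   paste(unique(conv$raw_commodity[conv$.key %in% unmatched]),
                         collapse = ", "))
    if (strict) stop_prcf(msg, "prcf_not_found")
    skipped <- c(skipped, msg)
  }
  if (nrow(merged) == 0) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  merged$exposure_ug <- merged$raw_equivalent_g * merged$concentration_ug_per_g
  agg <- stats::aggregate(
    cbind(raw_equivalent_g, exposure_ug) ~ subject_id + chemical + raw_commodity,
    data = merged, FUN = sum
  )
  agg <- agg[order(agg$subject_id, agg$chemical, agg$raw_commodity), ]
  rownames(agg) <- NULL
  attr(agg, "skipped") <- skipped
  agg
}
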