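read_prcf_csv <- function(path, needed, what) {
  if (!file.exists(path)) {
    stop_prcf(sprintf("cannot read %s file: %s", what, path), "prcf_io_error")
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                       encoding = "UTF-8")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop_prcf(sprintf("%s file %s is missing columns: %s", what, path,
                      paste(missing_cols, collapse = ", ")), "prcf_io_error")
  }
  x
}

#' Read a yield-observation CSV
#'
#' Columns: `study_id`, `procedure`, `food_group`, `initial_weight_g`,
#' `final_weight_g`, `source`. Decimal-point numbers, UTF-8, header required.
#'
#' @param path CSV path.
#' @return Data.frame of yield observations.
#' @export
read_yield_observations <- function(path) {
  read_prcf_csv(path, c("study_id", "procedure", "food_group",
                        "initial_weight_g", "final_weight_g"), "yield")
}

#' Read a migration-observation CSV
#'
#' Columns: `study_id`, `component`, `content_raw_per100`,
#' `content_processed_per100`, `fermentation_yield`, `source`. The
#' fermentation yield is required (and checked) only for the fermented
#' components `carbohydrate_alcohol` (0.51) and `carbohydrate_acetic` (0.67).
#'
#' @param path CSV path.
#' @return Data.frame of migration observations.
#' @export
read_migration_observations <- function(path) {
  x <- read_prcf_csv(path, c("study_id", "component", "content_raw_per100",
                             "content_processed_per100"), "migration")
  if (is.null(x$fermentation_yield)) x$fermentation_yield <- NA_real_
  x
}

migration_components <- c("carbohydrate_alcohol", "carbohydrate_acetic",
                          "alpha_acid", "total_solid", "total_polyphenol")

migration_rate_obs <- function(component, content_raw, content_processed,
                               fermentation_yield = NA_real_) {
  if (!component %in% migration_components) {
    stop_prcf(sprintf("unknown migration component '%s'", component),
              "prcf_configuration_error")
  }
  fermented <- component %in% names(fermentation_yields)
  if (fermented) {
    theoretical <- unname(fermentation_yields[component])
    if (!is.na(fermentation_yield) &&
        abs(fermentation_yield - theoretical) > 1e-9) {
      stop_prcf(sprintf(
        "component '%s' pairs with theoretical fermentation yield %.2f, got %.4g",
        component, theoretical, fermentation_yield), "prcf_configuration_error")
    }
    migration_rate_fermented(content_raw, content_processed, component)
  } else {
    if (!is.na(fermentation_yield)) {
      stop_prcf(sprintf(
        "component '%s' takes no fermentation yield", component),
        "prcf_configuration_error")
    }
    migration_rate(content_raw, content_processed)
  }
}

#' Derive aggregated conversion factors from per-study observations
#'
#' Computes a per-observation factor for every row (reverse percentage yield
#' for yield observations; component migration rate for migration
#' observations, with the theoretical fermentation yield applied to the
#' fermented components) and averages within groups, reproducing the
#' published mean-and-SD table structure. Yield observations group by
#' (procedure, food group); migration observations group by component.
#'
#' @param yields Data.frame of yield observations
#'   (see [read_yield_observations()]), or `NULL`.
#' @param migrations Data.frame of migration observations
#'   (see [read_migration_observations()]), or `NULL`.
#' @return Data.frame with one aggregated factor per group: `procedure`,
#'   `food_group`, `method`, `component`, `value`, `sd`, `n_samples`.
#' @export
derive_factors <- function(yields = NULL, migrations = NULL) {
  if (is.null(yields) && is.null(migrations)) {
    stop_prcf("supply at least one of yields or migrations", "prcf_io_error")
  }
  out <- list()
  if (!is.null(yields)) {
    if (nrow(yields) == 0) {
      stop_prcf("yield table has no observations", "prcf_io_error")
    }
    fac <- reverse_percentage_yield(yields$initial_weight_g,
                                    yields$final_weight_g)
    key <- paste(yields$procedure, yields$food_group, sep = "\r")
    for (grp in unique(key)) {
      v <- fac[key == grp]
      meta <- strsplit(grp, "\r", fixed = TRUE)[[1]]
      cf <- aggregate_factors(v, procedure = meta[1], processed_food = meta[2],
                              method = "percentage_yield")
      out[[length(out) + 1]] <- data.frame(
        procedure = meta[1], food_group = meta[2], method = "percentage_yield",
        component = NA_character_, value = cf$value, sd = cf$sd,
        n_samples = cf$n_samples, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(migrations)) {
    if (nrow(migrations) == 0) {
      stop_prcf("migration table has no observations", "prcf_io_error")
    }
    rates <- vapply(seq_len(nrow(migrations)), function(i) {
      migration_rate_obs(migrations$component[i],
                         migrations$content_raw_per100[i],
                         migrations$content_processed_per100[i],
                         migrations$fermentation_yield[i])
    }, numeric(1))
    # zero rates are legitimate here (no component in the product), so the
    # mean/SD is taken directly rather than through aggregate_factors()
    for (comp in unique(migrations$component)) {
      v <- rates[migrations$component == comp]
      out[[length(out) + 1]] <- data.frame(
        procedure = NA_character_, food_group = NA_character_,
        method = "migration_rate", component = comp,
        value = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_samples = length(v), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
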