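#' Reverse percentage yield of a processing step
#'
#' The reverse percentage yield is the weight of the initial edible-portion
#' raw ingredient divided by the weight of the finished processed food. Used
#' directly, it is the processed-to-raw conversion factor (PRCF) for foods
#' processed whole (soaking, boiling, dehydration, ...): multiplying a
#' consumed processed mass by it recovers the raw-ingredient mass.
#'
#' Weights are edible-portion weights; inedible parts removed before
#' processing are never part of `initial_weight`. When a recipe adds water
#' before a separation step (e.g. soy products), the added water belongs in
#' `initial_weight` — that is the caller's responsibility.
#'
#' @param initial_weight Numeric vector, mass (g) of the edible portion of the
#'   raw ingredient entering processing.
#' @param final_weight Numeric vector, mass (g) of the finished processed food.
#' @return Numeric vector of dimensionless factors (g raw per g processed).
#' @export
#' @examples
#' reverse_percentage_yield(1.0, 0.67) # whole egg -> egg white, ~1.49
reverse_percentage_yield <- function(initial_weight, final_weight) {
  if (!is.numeric(initial_weight) || !is.numeric(final_weight)) {
    stop_prcf("weights must be numeric", "prcf_invalid_observation")
  }
  if (anyNA(initial_weight) || anyNA(final_weight) ||
      any(initial_weight <= 0) || any(final_weight <= 0)) {
    stop_prcf(
      "invalid yield observation: initial and final weights must be positive",
      "prcf_invalid_observation"
    )
  }
  initial_weight / final_weight
}

#' Partition-corrected conversion factor
#'
#' When processing splits a raw commodity into several co-products (egg ->
#' white/yolk, milk -> cream/skim, grain -> bran/germ/endosperm), converting
#' each product back with its plain reverse yield double-counts the raw
#' commodity. The partition-corrected factor multiplies the mean reverse
#' yield by the mass fraction (partition ratio) of the commodity that feeds
#' the product, so that summing converted co-products recovers the raw mass
#' exactly once.
#'
#' For a pure physical separation the reverse yield of each compartment is
#' the reciprocal of its partition ratio and the corrected factor is 1.
#'
#' @param partition_ratio Numeric vector in (0, 1]: mass fraction of the raw
#'   commodity allocated to the product's compartment.
#' @param mean_reverse_yield Positive numeric vector: mean reverse percentage
#'   yield of the product relative to its compartment.
#' @return Numeric vector of dimensionless conversion factors.
#' @export
#' @examples
#' partitioned_factor(0.33, 5.9) # egg yolk powder, 1.947 (printed 1.9)
partitioned_factor <- function(partition_ratio, mean_reverse_yield) {
  if (anyNA(partition_ratio) || any(partition_ratio <= 0) ||
      any(partition_ratio > 1)) {
    stop_prcf("partition_ratio must lie in (0, 1]", "prcf_domain_error")
  }
  if (anyNA(mean_reverse_yield) || any(mean_reverse_yield <= 0)) {
    stop_prcf("mean_reverse_yield must be positive", "prcf_domain_error")
  }
  partition_ratio * mean_reverse_yield
}

#' Component migration rate
#'
#' For processed foods whose weight change cannot be traced (extracts,
#' infusions, stocks), the conversion factor is the migration rate of a
#' traceable component: its content per 100 g of finished food divided by its
#' content per 100 g of the edible raw ingredient. Beverages are treated on a
#' density-1 convention, so per-100-mL and per-100-g contents coincide.
#'
#' @param content_raw Positive numeric vector: component content per 100 g of
#'   the edible raw ingredient (e.g. g carbohydrate, mg GAE).
#' @param content_processed Non-negative numeric vector: component content per
#'   100 g of the finished processed food, in the same units.
#' @return Numeric vector of dimensionless migration rates.
#' @seealso [migration_rate_fermented()] for alcoholic beverages and vinegars.
#' @export
migration_rate <- function(content_raw, content_processed) {
  if (anyNA(content_raw) || any(content_raw <= 0)) {
    stop_prcf(
      "content_raw must be positive: migration rate divides by the raw-ingredient content",
      "prcf_division_error"
    )
  }
  if (anyNA(content_processed) || any(content_processed < 0)) {
    stop_prcf("content_processed must be non-negative", "prcf_invalid_observation")
  }
  content_processed / content_raw
}

#' Theoretical fermentation yields of ethanol and acetic acid
#'
#' Stoichiometric mass fractions of fermentable carbohydrate converted to
#' product: 0.51 for ethanol, 0.67 for acetic acid.
#' @format Named numeric vector.
#' @export
fermentation_yields <- c(carbohydrate_alcohol = 0.51, carbohydrate_acetic = 0.67)

#' Migration rate for fermented products (alcoholic beverages and vinegars)
#'
#' During fermentation the raw ingredient's carbohydrate is assumed fully
#' hydrolysed and converted, so the traceable amount in the denominator is the
#' carbohydrate content multiplied by the theoretical fermentation yield
#' (0.51 for ethanol, 0.67 for acetic acid). The numerator is the product
#' strength: percent alcohol by volume for beverages or percent acetic acid
#' for vinegar, both treated per 100 g at density 1.
#'
#' @param content_raw Positive numeric: g carbohydrate per 100 g edible raw
#'   ingredient.
#' @param content_processed Non-negative numeric: percent ABV of the beverage
#'   or percent acetic acid of the vinegar.
#' @param component `"carbohydrate_alcohol"` or `"carbohydrate_acetic"`.
#' @param fermentation_yield Theoretical yield; defaults to the component's
#'   stoichiometric value from [fermentation_yields]. Override only for
#'   sensitivity analyses (with yield 1 the computation reduces to
#'   [migration_rate()]).
#' @return Numeric vector of dimensionless migration rates.
#' @export
#' @examples
#' migration_rate_fermented(18, 12, "carbohydrate_alcohol") # 12 / (18 * 0.51)
migration_rate_fermented <- function(content_raw, content_processed,
                                     component = c("carbohydrate_alcohol",
                                                   "carbohydrate_acetic"),
                                     fermentation_yield = NULL) {
  component <- tryCatch(match.arg(component),
                        error = function(e) stop_prcf(
                          "fermented migration requires component 'carbohydrate_alcohol' or 'carbohydrate_acetic'",
                          "prcf_configuration_error"))
  if (is.null(fermentation_yield)) {
    fermentation_yield <- unname(fermentation_yields[component])
  }
  if (!is.numeric(fermentation_yield) || anyNA(fermentation_yield) ||
      any(fermentation_yield <= 0)) {
    stop_prcf("fermentation_yield must be positive", "prcf_configuration_error")
  }
  migration_rate(content_raw * fermentation_yield, content_processed)
}

#' Construct a conversion factor record
#'
#' A `conversion_factor` couples a factor value with its derivation method
#' and provenance metadata. [aggregate_factors()] builds one from per-study
#' values; [lookup_factor()] returns one from the bundled reference table.
#'
#' @param value Positive factor value (g raw per g processed).
#' @param processed_food,raw_commodity,procedure Identifying labels.
#' @param method One of `"percentage_yield"`, `"partitioned_yield"`,
#'   `"migration_rate"`.
#' @param sd Sample standard deviation of the per-study values, or `NA` when
#'   only one value exists.
#' @param n_samples Number of per-study values averaged.
#' @param partition_ratio,mean_reverse_yield Components of a
#'   partition-corrected factor, `NA` otherwise.
#' @return An object of class `conversion_factor`.
#' @export
conversion_factor <- function(value, processed_food = NA_character_,
                              raw_commodity = NA_character_,
                              procedure = NA_character_,
                              method = c("percentage_yield", "partitioned_yield",
                                         "migration_rate"),
                              sd = NA_real_, n_samples = 1L,
                              partition_ratio = NA_real_,
                              mean_reverse_yield = NA_real_) {
  method <- match.arg(method)
  stopifnot(is.numeric(value), length(value) == 1)
  if (is.na(value) || value <= 0) {
    stop_prcf("conversion factor value must be positive", "prcf_domain_error")
  }
  if (is.na(n_samples) || n_samples < 1) {
    stop_prcf("n_samples must be >= 1", "prcf_domain_error")
  }
  structure(
    list(processed_food = processed_food, raw_commodity = raw_commodity,
         procedure = procedure, method = method, value = as.numeric(value),
         sd = as.numeric(sd), n_samples = as.integer(n_samples),
         partition_ratio = as.numeric(partition_ratio),
         mean_reverse_yield = as.numeric(mean_reverse_yield)),
    class = "conversion_factor"
  )
}

#' @export
print.conversion_factor <- function(x, ...) {
  lab <- if (is.na(x$processed_food)) "" else paste0(" [", x$processed_food, "]")
  sd <- if (is.na(x$sd)) "" else sprintf(" ± %.4g", x$sd)
  cat(sprintf("PRCF%s: %.4g%s (%s, n = %d)\n", lab, x$value, sd, x$method,
              x$n_samples))
  if (!is.na(x$partition_ratio)) {
    cat(sprintf("  partition ratio %.2f × mean reverse yield %.4g\n",
                x$partition_ratio, x$mean_reverse_yield))
  }
  invisible(x)
}

#' @export
format.conversion_factor <- function(x, ...) {
  sprintf("%.4g (%s, n=%d)", x$value, x$method, x$n_samples)
}

#' Average per-study factors into a published-style conversion factor
#'
#' Per-study factor values for one (procedure, food type) combination are
#' averaged to absorb inter-study variation in processing conditions. The
#' result carries the arithmetic mean, the sample standard deviation (absent
#' when only one study contributed), and the number of studies.
#'
#' @param values Non-empty numeric vector of per-study factor values.
#' @param ... Metadata passed on to [conversion_factor()] (`processed_food`,
#'   `procedure`, `method`, ...).
#' @return A [conversion_factor()].
#' @export
#' @examples
#' aggregate_factors(c(1, 3), processed_food = "example")
aggregate_factors <- function(values, ...) {
  if (length(values) == 0) {
    stop_prcf("cannot aggregate an empty list of factor values",
              "prcf_aggregation_error")
  }
  if (anyNA(values) || any(values <= 0)) {
    stop_prcf("factor values must be positive and non-missing",
              "prcf_aggregation_error")
  }
  conversion_factor(
    value = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else NA_real_,
    n_samples = length(values),
    ...
  )
}

#' Construct a partition scheme
#'
#' A partition scheme records how processing splits a raw commodity into
#' compartments and the mass fraction of each. Fractions must each lie in
#' (0, 1] and sum to 1 within a tolerance that accommodates printed rounding.
#'
#' @param raw_commodity Name of the raw commodity.
#' @param compartments Named numeric vector of partition ratios, or a
#'   data.frame with columns `compartment` and `partition_ratio`.
#' @param tol Allowed deviation of the ratio sum from 1 (default 0.02,
#'   matching two-decimal printed rounding).
#' @return An object of class `partition_scheme`.
#' @export
#' @examples
#' partition_scheme("eggs", c(`egg white` = 0.67, `egg yolk` = 0.33))
partition_scheme <- function(raw_commodity, compartments, tol = 0.02) {
  if (is.data.frame(compartments)) {
    ratios <- compartments$partition_ratio
    names(ratios) <- compartments$compartment
    compartments <- ratios
  }
  if (is.null(names(compartments)) || any(!nzchar(names(compartments)))) {
    stop_prcf("compartments must be named", "prcf_domain_error")
  }
  if (anyNA(compartments) || any(compartments <= 0) || any(compartments > 1)) {
    stop_prcf("partition ratios must lie in (0, 1]", "prcf_domain_error")
  }
  if (abs(sum(compartments) - 1) > tol) {
    stop_prcf(sprintf("partition ratios sum to %.4f, not 1 ± %.2f",
                      sum(compartments), tol), "prcf_mass_balance_error")
  }
  structure(list(raw_commodity = raw_commodity, compartments = compartments),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("Partition scheme for %s:\n", x$raw_commodity))
  for (nm in names(x$compartments)) {
    cat(sprintf("  %-20s %.4f\n", nm, x$compartments[[nm]]))
  }
  invisible(x)
}
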