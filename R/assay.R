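#' Fit a gallic acid standard curve
#'
#' Ordinary least-squares line through Folin-Ciocalteu standard readings,
#' absorbance at 765 nm against gallic acid concentration (mg/mL). The
#' intercept is left free: reagent blanks give a nonzero baseline.
#'
#' @param concentration Gallic acid concentrations, mg/mL (>= 3 distinct
#'   values required).
#' @param absorbance Optical densities at 765 nm, same length.
#' @return An object of class `gae_curve` with elements `slope`, `intercept`,
#'   `r_squared`, `se_slope`, `absorbance_range`, `n`, and the underlying
#'   `stats::lm` fit.
#' @export
#' @examples
#' fit_standard_curve(c(0, 0.02, 0.04, 0.08), c(0.05, 0.09, 0.13, 0.21))
fit_standard_curve <- function(concentration, absorbance) {
  if (is.data.frame(concentration)) {
    absorbance <- concentration$absorbance
    concentration <- concentration[[1]]
  }
  ok <- is.finite(concentration) & is.finite(absorbance)
  if (any(!ok)) stop_prcf("standard-curve points must be finite", "prcf_fit_error")
  if (any(concentration < 0)) {
    stop_prcf("gallic acid concentrations must be non-negative", "prcf_fit_error")
  }
  if (length(unique(concentration)) < 3) {
    stop_prcf("standard curve needs at least 3 distinct concentrations",
              "prcf_fit_error")
  }
  fit <- stats::lm(absorbance ~ concentration)
  # dispersion summaries computed directly so that an exactly linear ladder
  # (r2 = 1, zero residual) is handled without fuss
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((absorbance - mean(absorbance))^2)
  sxx <- sum((concentration - mean(concentration))^2)
  n <- length(concentration)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         se_slope = sqrt(rss / (n - 2) / sxx),
         absorbance_range = range(absorbance),
         n = length(concentration),
         fit = fit),
    class = "gae_curve"
  )
}

#' @export
print.gae_curve <- function(x, ...) {
  cat(sprintf("Gallic acid standard curve: A765 = %.4g x conc + %.4g (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Total polyphenol content in gallic acid equivalents
#'
#' Back-calculates the gallic acid equivalent concentration of a sample from
#' its (triplicate) absorbances via the standard curve, corrects for
#' dilution, and scales by extract volume over sample mass to express the
#' result per gram of tested material: content (mg GAE/g) =
#' (mean A - intercept) / slope x dilution x volume / mass. The raw-material
#' extraction convention pools three extractions of 0.2 g into a final
#' volume of 15 mL; an infusion measured as-is uses its own aliquot mass and
#' volume (density 1, so per-mL and per-g coincide).
#'
#' @param absorbances Numeric vector of replicate optical densities (usually
#'   triplicates), averaged before back-calculation.
#' @param curve A `gae_curve` from [fit_standard_curve()].
#' @param sample_mass Mass of tested material, g.
#' @param extract_volume Final extract volume, mL (15 mL for raw extracts).
#' @param dilution_factor Dilution applied before reading (>= 1).
#' @return Content in mg GAE per g of tested sample.
#' @export
gae_content <- function(absorbances, curve, sample_mass, extract_volume = 15,
                        dilution_factor = 1) {
  if (!inherits(curve, "gae_curve")) {
    stop_prcf("curve must come from fit_standard_curve()", "prcf_invalid_curve")
  }
  if (curve$slope <= 0) {
    stop_prcf("standard curve slope must be positive", "prcf_invalid_curve")
  }
  if (length(absorbances) < 1 || anyNA(absorbances)) {
    stop_prcf("at least one finite absorbance is required",
              "prcf_invalid_observation")
  }
  if (dilution_factor < 1) {
    stop_prcf("dilution_factor must be >= 1", "prcf_invalid_observation")
  }
  if (sample_mass <= 0 || extract_volume <= 0) {
    stop_prcf("sample_mass and extract_volume must be positive",
              "prcf_invalid_observation")
  }
  a <- mean(absorbances)
  rng <- curve$absorbance_range
  if (a < rng[1] - 1e-9 || a > rng[2] + 1e-9) {
    warning(sprintf(
      "mean absorbance %.4g outside the fitted standard range [%.4g, %.4g]; extrapolating",
      a, rng[1], rng[2]))
  }
  conc <- (a - curve$intercept) / curve$slope * dilution_factor  # mg/mL
  conc * extract_volume / sample_mass
}

#' Total polyphenol contents for a plate of samples
#'
#' Vectorized [gae_content()] over a samples table in the assay CSV dialect,
#' carrying the replicate standard deviation through to a per-sample content
#' SD (same back-calculation applied to each replicate).
#'
#' @param samples Data.frame with columns `sample_id`, `abs1`, `abs2`, `abs3`
#'   (replicates; `NA`s allowed beyond the first), `dilution_factor`,
#'   `sample_mass_g`, `extract_volume_ml`.
#' @param curve A `gae_curve`.
#' @return Data.frame with `sample_id`, `content_mg_gae_per_g`,
#'   `content_sd`, `n_replicates`.
#' @export
gae_table <- function(samples, curve) {
  needed <- c("sample_id", "abs1", "dilution_factor", "sample_mass_g",
              "extract_volume_ml")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols) > 0) {
    stop_prcf(sprintf("samples table is missing columns: %s",
                      paste(missing_cols, collapse = ", ")), "prcf_io_error")
  }
  abs_cols <- intersect(c("abs1", "abs2", "abs3"), names(samples))
  out <- lapply(seq_len(nrow(samples)), function(i) {
    reps <- stats::na.omit(as.numeric(samples[i, abs_cols]))
    content <- gae_content(reps, curve,
                           sample_mass = samples$sample_mass_g[i],
                           extract_volume = samples$extract_volume_ml[i],
                           dilution_factor = samples$dilution_factor[i])
    per_rep <- vapply(reps, function(a) {
      gae_content(a, curve, sample_mass = samples$sample_mass_g[i],
                  extract_volume = samples$extract_volume_ml[i],
                  dilution_factor = samples$dilution_factor[i])
    }, numeric(1))
    data.frame(sample_id = samples$sample_id[i],
               content_mg_gae_per_g = content,
               content_sd = if (length(reps) > 1) stats::sd(per_rep) else NA_real_,
               n_replicates = length(reps), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Polyphenol migration rate of an infusion or stock
#'
#' Ratio of the total polyphenol content per gram of prepared infusion (or
#' stock; density-1 convention) to the content per gram of the dry raw
#' material. This is the per-100-g component migration rate specialised to
#' total polyphenols, and is the conversion factor for brewed teas and
#' spice stocks.
#'
#' @param raw_content mg GAE per g of dry raw material (> 0).
#' @param infusion_content mg GAE per g of prepared infusion (>= 0).
#' @return Dimensionless migration rate.
#' @export
#' @examples
#' polyphenol_migration_rate(98.1, 0.7456) # ~0.0076, black-tea scale
polyphenol_migration_rate <- function(raw_content, infusion_content) {
  migration_rate(raw_content, infusion_content)
}
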