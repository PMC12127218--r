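#' Simulate a multi-study yield collection with known ground truth
#'
#' Draws per-study reverse yields lognormally around a true conversion
#' factor: log factors are normal with standard deviation
#' sqrt(log(1 + cv^2)) and the mean offset chosen so the expected factor is
#' exactly `true_factor` (at cv = 0 every observation is exact). Final
#' weights are `initial_weight / factor`, so aggregating the per-study
#' reverse yields recovers the truth within about 3 cv / sqrt(n) relative
#' error. Lognormal noise keeps weights positive.
#'
#' @param true_factor True conversion factor (> 0).
#' @param cv Coefficient of variation of per-study factors (>= 0).
#' @param n Number of studies (>= 1).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param initial_weight Initial edible-portion weight per study, g.
#' @param procedure,food_group Labels copied into the output.
#' @return Data.frame in the yield-observation CSV dialect: `study_id`,
#'   `procedure`, `food_group`, `initial_weight_g`, `final_weight_g`,
#'   `source`.
#' @export
#' @examples
#' obs <- gen_yield_study(2.2, cv = 0.1, n = 30, seed = 1)
#' mean(obs$initial_weight_g / obs$final_weight_g)
gen_yield_study <- function(true_factor, cv, n, seed, initial_weight = 100,
                            procedure = "simulated",
                            food_group = "simulated food") {
  if (!is.numeric(true_factor) || true_factor <= 0 || cv < 0 || n < 1) {
    stop_prcf("need true_factor > 0, cv >= 0, n >= 1", "prcf_spec_error")
  }
  sdlog <- sqrt(log1p(cv^2))
  factors <- withr::with_seed(seed, {
    exp(stats::rnorm(n, mean = log(true_factor) - sdlog^2 / 2, sd = sdlog))
  })
  data.frame(
    study_id = sprintf("S%03d", seq_len(n)),
    procedure = procedure,
    food_group = food_group,
    initial_weight_g = initial_weight,
    final_weight_g = initial_weight / factors,
    source = sprintf("synthetic study %d (seed %d)", seq_len(n), seed),
    stringsAsFactors = FALSE
  )
}

#' Simulate a pure physical separation into k compartments
#'
#' Generates a random partition of a raw commodity (flat Dirichlet ratios)
#' and, for each compartment, a yield observation of an exact physical
#' separation: the final weight is the initial weight times the compartment's
#' ratio, so each reverse yield is exactly 1/ratio and each
#' partition-corrected factor is exactly 1.
#'
#' @param k Number of compartments, 2 to 6.
#' @param seed Integer seed.
#' @param initial_weight Raw-commodity weight, g.
#' @return List with `scheme` (a [partition_scheme()]) and `observations`
#'   (a yield data.frame with a `compartment` column).
#' @export
gen_partition_separation <- function(k, seed, initial_weight = 100) {
  if (!is.numeric(k) || k < 2 || k > 6) {
    stop_prcf("k must be between 2 and 6", "prcf_spec_error")
  }
  ratios <- withr::with_seed(seed, {
    g <- stats::rexp(k)
    g / sum(g)
  })
  names(ratios) <- sprintf("compartment_%d", seq_len(k))
  scheme <- partition_scheme(sprintf("synthetic commodity (seed %d)", seed),
                             ratios, tol = 1e-9)
  obs <- data.frame(
    study_id = sprintf("SEP%02d", seq_len(k)),
    procedure = "simulated separation",
    food_group = names(ratios),
    compartment = names(ratios),
    initial_weight_g = initial_weight,
    final_weight_g = initial_weight * ratios,
    source = sprintf("synthetic separation (seed %d)", seed),
    stringsAsFactors = FALSE
  )
  rownames(obs) <- NULL
  list(scheme = scheme, observations = obs)
}

#' Simulate a consumption diary
#'
#' Gamma-distributed daily amounts for every subject-food combination:
#' right-skewed and non-negative, the usual shape of daily intake amounts.
#'
#' @param n_subjects Number of subjects (0 gives an empty diary).
#' @param foods Data.frame with columns `processed_food` and `procedure`
#'   (e.g. rows of [load_reference()]), or a character vector of processed
#'   foods resolved against the bundled table.
#' @param seed Integer seed.
#' @param mean_amount Mean daily amount per food, g/day.
#' @param shape Gamma shape parameter (2 gives moderate right skew).
#' @return Data.frame with `subject_id`, `processed_food`, `procedure`,
#'   `amount_g` — one row per subject and food.
#' @export
gen_diary <- function(n_subjects, foods, seed, mean_amount = 50, shape = 2) {
  if (is.character(foods)) {
    ref <- load_reference()
    idx <- match(normalize_name(foods), normalize_name(ref$processed_food))
    if (anyNA(idx)) {
      stop_prcf(sprintf("unknown foods: %s",
                        paste(foods[is.na(idx)], collapse = ", ")),
                "prcf_spec_error")
    }
    foods <- ref[idx, c("processed_food", "procedure")]
  }
  if (!is.data.frame(foods) || nrow(foods) == 0) {
    stop_prcf("foods must be a non-empty data.frame or character vector",
              "prcf_spec_error")
  }
  if (n_subjects == 0) {
    return(data.frame(subject_id = character(0), processed_food = character(0),
                      procedure = character(0), amount_g = numeric(0),
                      stringsAsFactors = FALSE))
  }
  nf <- nrow(foods)
  amounts <- withr::with_seed(seed, {
    stats::rgamma(n_subjects * nf, shape = shape, rate = shape / mean_amount)
  })
  data.frame(
    subject_id = rep(sprintf("subj%03d", seq_len(n_subjects)), each = nf),
    processed_food = rep(foods$processed_food, times = n_subjects),
    procedure = rep(foods$procedure, times = n_subjects),
    amount_g = amounts,
    stringsAsFactors = FALSE
  )
}

#' Simulate a raw-commodity concentration table
#'
#' Lognormal concentrations (ug/g) for one chemical across raw commodities.
#'
#' @param chemical Chemical name.
#' @param raw_commodities Character vector of commodity names.
#' @param seed Integer seed.
#' @param meanlog,sdlog Lognormal parameters of the concentrations.
#' @return Data.frame with `chemical`, `raw_commodity`,
#'   `concentration_ug_per_g`.
#' @export
gen_concentrations <- function(chemical, raw_commodities, seed,
                               meanlog = log(10), sdlog = 0.5) {
  if (length(raw_commodities) == 0) {
    stop_prcf("raw_commodities must be non-empty", "prcf_spec_error")
  }
  conc <- withr::with_seed(seed, {
    stats::rlnorm(length(raw_commodities), meanlog, sdlog)
  })
  data.frame(chemical = chemical, raw_commodity = raw_commodities,
             concentration_ug_per_g = conc, stringsAsFactors = FALSE)
}

#' Simulate a Folin-Ciocalteu assay plate with known contents
#'
#' Builds a gallic acid standard ladder and triplicate sample readings whose
#' absorbances are synthesized from known true contents through a known
#' line, optionally with Gaussian read noise. Used to test that the
#' back-calculation in [gae_content()] recovers the truth.
#'
#' @param true_contents Named numeric vector of true contents, mg GAE/g.
#' @param seed Integer seed.
#' @param slope,intercept True standard-curve parameters.
#' @param noise_sd Gaussian absorbance noise (0 for exact synthesis).
#' @param sample_mass,extract_volume,dilution_factor Bookkeeping used to map
#'   content to solution concentration (defaults: 0.2 g in 15 mL, read neat).
#' @param standards Gallic acid ladder concentrations, mg/mL.
#' @return List with `curve_points` (standards data.frame) and `samples`
#'   (the assay-samples CSV dialect).
#' @export
gen_assay_plate <- function(true_contents, seed, slope = 2.0, intercept = 0.05,
                            noise_sd = 0, sample_mass = 0.2,
                            extract_volume = 15, dilution_factor = 1,
                            standards = c(0, 0.01, 0.02, 0.04, 0.06, 0.08)) {
  if (length(true_contents) == 0 || is.null(names(true_contents))) {
    stop_prcf("true_contents must be a named numeric vector", "prcf_spec_error")
  }
  n <- length(true_contents)
  withr::with_seed(seed, {
    curve_points <- data.frame(
      gallic_acid_mg_per_ml = standards,
      absorbance = intercept + slope * standards +
        stats::rnorm(length(standards), 0, noise_sd)
    )
    conc <- true_contents * sample_mass / extract_volume / dilution_factor
    reps <- vapply(conc, function(cc) {
      intercept + slope * cc + stats::rnorm(3, 0, noise_sd)
    }, numeric(3))
    samples <- data.frame(
      sample_id = names(true_contents),
      abs1 = reps[1, ], abs2 = reps[2, ], abs3 = reps[3, ],
      dilution_factor = dilution_factor,
      sample_mass_g = sample_mass,
      extract_volume_ml = extract_volume,
      stringsAsFactors = FALSE
    )
    rownames(samples) <- NULL
    list(curve_points = curve_points, samples = samples)
  })
}
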