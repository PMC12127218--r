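test_that("partition correction recovers 1 g of egg where naive doubles it", {
  egg <- egg_example()
  naive <- sum(egg$diary$amount_g * egg$reverse_yield[egg$diary$processed_food])
  expect_equal(round(naive, 1), 2.0)  # double counting
  corrected_factors <- partitioned_factor(
    egg$partition[egg$diary$processed_food],
    egg$reverse_yield[egg$diary$processed_food])
  corrected <- sum(egg$diary$amount_g * corrected_factors)
  expect_equal(round(corrected, 1), 1.0)
})

test_that("convert_record scales amount, SD, and rejects mismatched pairs", {
  cf <- lookup_factor("Dehydration", "Jerky")
  out <- convert_record(100, cf, processed_food = "jerky")
  expect_equal(out$raw_equivalent_g, 100 * 2.2)
  expect_equal(out$raw_equivalent_sd_g, 100 * 0.16)
  expect_equal(out$raw_commodity, "Meat")
  expect_equal(convert_record(0, cf)$raw_equivalent_g, 0)
  expect_error(convert_record(5, cf, processed_food = "butter"),
               class = "prcf_pairing_error")
  expect_error(convert_record(-1, cf), class = "prcf_invalid_observation")
})

test_that("diary conversion resolves against the bundled table", {
  egg <- egg_example()
  conv <- convert_diary(egg$diary)
  # bundled egg rows have assigned factor 1 (pure physical separation)
  expect_equal(conv$raw_equivalent_g, c(0.67, 0.33))
  expect_equal(unique(conv$raw_commodity), "Eggs")

  diary <- rbind(egg$diary,
                 data.frame(subject_id = "s1", processed_food = "unobtainium",
                            procedure = "dehydration", amount_g = 10))
  lenient <- convert_diary(diary)
  expect_equal(nrow(lenient), 2)
  expect_length(attr(lenient, "skipped"), 1)
  expect_error(convert_diary(diary, strict = TRUE), class = "prcf_not_found")
})

test_that("double counting is exactly k-fold for pure separations", {
  withr::with_seed(31, {
    for (k in 2:6) {
      sep <- gen_partition_separation(k, seed = sample.int(1e6, 1))
      obs <- sep$observations
      ry <- reverse_percentage_yield(obs$initial_weight_g, obs$final_weight_g)
      # the whole commodity consumed as its k separated parts
      consumed <- obs$final_weight_g
      naive <- sum(consumed * ry)
      corrected <- sum(consumed * partitioned_factor(
        sep$scheme$compartments[obs$compartment], ry))
      true_raw <- obs$initial_weight_g[1]
      expect_equal(naive, k * true_raw)
      expect_equal(corrected, true_raw)
    }
  })
})

test_that("chemical-adjusted factors substitute migration for mass share", {
  eggs <- partition_scheme("eggs", c(`Egg white` = 0.67, `Egg yolk` = 0.33))
  # cholesterol sits entirely in the yolk: 1 g yolk "is" 3 g egg
  chol <- chemical_adjusted_factor(eggs, "Egg yolk", 3.0, migration_ratio = 1)
  expect_equal(chol$value, 3.0)
  none <- chemical_adjusted_factor(eggs, "Egg white", 1.49, migration_ratio = 0)
  expect_equal(none$value, 0)
  # default: reduces to the ordinary partition-corrected factor
  dflt <- chemical_adjusted_factor(eggs, "Egg yolk", 5.9)
  expect_equal(dflt$value, partitioned_factor(0.33, 5.9))
  profile <- chemical_profile("cholesterol", "eggs", 12,
                              compartment_migration = c(`Egg yolk` = 1,
                                                        `Egg white` = 0))
  expect_equal(chemical_adjusted_factor(eggs, "Egg yolk", 3.0,
                                        profile = profile)$value, 3.0)
  expect_error(chemical_adjusted_factor(eggs, "shell", 1),
               class = "prcf_schema_error")
  expect_error(chemical_adjusted_factor(eggs, "Egg yolk", 3,
                                        migration_ratio = 2),
               class = "prcf_schema_error")
})

test_that("migration-substituted factors reproduce the bundled partition factors", {
  ref <- load_reference()
  part <- ref[ref$method == "partitioned_yield", ]
  for (i in seq_len(nrow(part))) {
    scheme <- reference_partition_scheme(
      part$procedure[i], part$raw_commodity[i], tol = 0.15) # milling prints 1.10
    cf <- chemical_adjusted_factor(scheme, part$compartment[i],
                                   part$mean_reverse_yield[i])
    tol <- unit_last_digit(part$value[i]) +
      part$partition_ratio[i] * unit_last_digit(part$mean_reverse_yield[i]) / 2
    expect_lt(abs(cf$value - part$value[i]), tol + 1e-9)
  }
})

test_that("exposure is the diary-weighted product of factor and concentration", {
  diary <- data.frame(subject_id = "s1",
                      processed_food = "Broth/stock (beef bones)",
                      procedure = "Broth/stock production", amount_g = 100,
                      stringsAsFactors = FALSE)
  conc <- data.frame(chemical = "lead", raw_commodity = "Beef bones",
                     concentration_ug_per_g = 10, stringsAsFactors = FALSE)
  exp_tab <- estimate_exposure(diary, conc)
  expect_equal(exp_tab$raw_equivalent_g, 100 * 0.0156)
  expect_equal(exp_tab$exposure_ug, 15.6)  # 100 g x 0.0156 x 10 ug/g

  empty <- estimate_exposure(diary[0, ], conc)
  expect_equal(nrow(empty), 0)
})

test_that("exposure is linear in amounts and concentrations", {
  withr::with_seed(9, {
    foods <- load_reference()[sample.int(120, 4), ]
    diary <- gen_diary(3, foods, seed = 14)
    conc <- gen_concentrations("cadmium", unique(foods$raw_commodity), seed = 15)
    base <- estimate_exposure(diary, conc)
    scaled_diary <- diary
    scaled_diary$amount_g <- 3 * scaled_diary$amount_g
    scaled_conc <- conc
    scaled_conc$concentration_ug_per_g <- 2 * scaled_conc$concentration_ug_per_g
    both <- estimate_exposure(scaled_diary, scaled_conc)
    expect_equal(both$exposure_ug, 6 * base$exposure_ug)
    expect_equal(both$raw_equivalent_g, 3 * base$raw_equivalent_g)
  })
})

test_that("subjects are independent: permuting records leaves exposure unchanged", {
  foods <- load_reference()[c(5, 18), ]
  diary <- gen_diary(2, foods, seed = 23)
  conc <- gen_concentrations("arsenic", unique(foods$raw_commodity), seed = 24)
  a <- estimate_exposure(diary, conc)
  b <- estimate_exposure(diary[rev(seq_len(nrow(diary))), ], conc)
  expect_equal(a, b, ignore_attr = TRUE)
})
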