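ref_all <- load_reference(include_partition_only = TRUE)
ref <- load_reference()

test_that("the bundled table carries 120 factors split 32/50/38 by method", {
  expect_equal(nrow(ref), 120)
  expect_true(all(ref$consumable))
  expect_equal(sum(ref$method == "percentage_yield"), 32)
  expect_equal(sum(ref$method == "partitioned_yield"), 50)
  expect_equal(sum(ref$method == "migration_rate"), 38)
  expect_true(all(ref$value > 0))
  # lookup key is unique across consumable rows
  key <- paste(normalize_name(ref$procedure), normalize_name(ref$processed_food))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("partitioned rows carry their components and migration rows theirs", {
  part <- ref[ref$method == "partitioned_yield", ]
  expect_true(all(!is.na(part$partition_ratio)))
  expect_true(all(!is.na(part$mean_reverse_yield)))
  mig <- ref[ref$method == "migration_rate", ]
  expect_true(all(!is.na(mig$component)))
  expect_setequal(unique(mig$component),
                  c("carbohydrate_alcohol", "alpha_acid", "carbohydrate_acetic",
                    "total_solid", "total_polyphenol"))
  # partition-only co-products ship without a factor, flagged non-consumable
  extra <- ref_all[!ref_all$consumable, ]
  expect_gt(nrow(extra), 0)
  expect_true(all(is.na(extra$value)))
})

test_that("validation reports the one known printed mass-balance anomaly", {
  report <- validate_reference(ref_all)
  expect_equal(report$count_total, 120)
  expect_equal(report$count_pure_yield, 32)
  expect_equal(report$count_partitioned, 50)
  expect_equal(report$count_migration, 38)
  expect_true(report$counts_ok)
  # every partitioned factor is consistent with ratio x reverse yield
  expect_equal(nrow(report$eq2_inconsistencies), 0)
  # the milling ratios are printed as 0.18 + 0.04 + 0.88 = 1.10; the
  # validator reports the group and nothing else
  expect_length(report$mass_balance_failures, 1)
  expect_match(report$mass_balance_failures, "Milling")
  expect_equal(report$status, "fail")
})

test_that("validation flags injected faults", {
  mutated <- ref_all
  i <- which(mutated$processed_food == "Egg yolk powder")
  mutated$value[i] <- 2.9  # no longer ~0.33 x 5.9
  report <- validate_reference(mutated)
  expect_equal(report$status, "fail")
  expect_equal(report$eq2_inconsistencies$processed_food, "Egg yolk powder")

  unbalanced <- ref_all
  unbalanced$partition_ratio[unbalanced$compartment == "Curd"] <- 0.70
  report <- validate_reference(unbalanced)  # curd + whey now 1.60
  expect_true(any(grepl("Cheese production", report$mass_balance_failures)))

  low <- ref_all
  low$partition_ratio[low$compartment == "Egg white"] <- 0.47  # sum 0.80
  expect_true(any(grepl("egg", validate_reference(low)$mass_balance_failures,
                        ignore.case = TRUE)))
})

test_that("count expectations are part of the pass condition", {
  report <- validate_reference(ref_all[ref_all$table_id != "T2", ])
  expect_false(report$counts_ok)
  expect_equal(report$status, "fail")
})

test_that("lookup returns printed factors, case- and space-insensitively", {
  expect_equal(lookup_factor("cheese production", "Gouda cheese")$value, 1.0)
  expect_equal(lookup_factor("Dehydration", "  jerky ")$value, 2.2)
  expect_equal(lookup_factor("DEHYDRATION", "Milk powder")$value, 5.52)
  gouda <- lookup_factor("Cheese production", "gouda   CHEESE")
  expect_s3_class(gouda, "conversion_factor")
  expect_equal(gouda$partition_ratio, 0.10)
  expect_equal(gouda$mean_reverse_yield, 10)
  err <- tryCatch(lookup_factor("dehydration", "unobtainium"), error = identity)
  expect_s3_class(err, "prcf_not_found")
  expect_match(conditionMessage(err), "nearest names")
})

test_that("reference partition schemes assemble from the bundled rows", {
  eggs <- reference_partition_scheme("Powdered egg product production", "Eggs")
  expect_equal(unname(eggs$compartments[c("Egg white", "Egg yolk")]),
               c(0.67, 0.33))
  rice <- reference_partition_scheme(
    "Vegetable oil production via solvent extraction", "Rice bran")
  expect_equal(sum(rice$compartments), 1.00)  # 0.07 oil + 0.93 cake
})

test_that("save/load round trips are exact in both formats", {
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_reference(ref_all, path)
    back <- load_reference(path, include_partition_only = TRUE)
    expect_identical(as.data.frame(back), as.data.frame(ref_all))
  }
})

test_that("the bundled JSON mirror matches the CSV exactly", {
  json_path <- system.file("extdata", "prcf_reference.json", package = "prcf")
  expect_true(nzchar(json_path))
  mirror <- load_reference(json_path, include_partition_only = TRUE)
  expect_identical(as.data.frame(mirror), as.data.frame(ref_all))
})

test_that("corrupt reference files raise data-corruption errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(load_reference(path), class = "prcf_data_corruption")
  expect_error(load_reference("/nonexistent/ref.csv"), class = "prcf_io_error")
})
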