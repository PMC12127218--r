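# Shared fixture builders; everything is generated in code.

# The classic worked example: one egg split into white and yolk, both fully
# consumed. Reverse yields are the printed 1.49 (white) and 3.03 (yolk);
# partition ratios 0.67 / 0.33.
egg_example <- function() {
  list(
    diary = data.frame(
      subject_id = "s1",
      processed_food = c("Egg white", "Egg yolk"),
      procedure = "Powdered egg product production",
      amount_g = c(0.67, 0.33),
      stringsAsFactors = FALSE
    ),
    partition = c(`Egg white` = 0.67, `Egg yolk` = 0.33),
    reverse_yield = c(`Egg white` = 1.49, `Egg yolk` = 3.03)
  )
}

# Two-pass mean/SD oracle used against aggregate_factors()
mean_sd_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_
  list(mean = m, sd = s, n = n)
}

# Closed-form OLS oracle for the standard curve
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
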