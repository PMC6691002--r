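fixture <- load_conifer_census_fixture()
cen <- build_census(fixture$counts, fixture$transcriptome_sizes)

test_that("the packaged conifer census reproduces its printed statistics", {
  expect_equal(unname(cen$distribution_pct[c("TNL", "CNL", "CNL2", "RNL")]),
               c(63, 22, 6, 9))
  expect_equal(unname(cen$total_nlr["A_balsamea"]), 338)
  expect_equal(unname(cen$nlr_ratio_pct["A_balsamea"]), 0.73)
  expect_equal(unname(cen$nlr_ratio_pct["P_glauca"]), 1.35)
  expect_equal(unname(cen$subfamily_ratio_pct["RNL", "P_banksiana"]), 0.12)
})

test_that("the census partition invariant holds for every species", {
  for (s in cen$species) {
    expect_equal(unname(cen$total_nlr[s]),
                 sum(cen$subfamily_totals[, s]))
  }
  # distribution computed over assigned categories sums to ~100
  expect_lte(abs(sum(cen$distribution_pct) - 100), 2)
})

test_that("an empty input yields an all-zero census", {
  empty <- build_census(data.frame(category = character(), row = character()),
                        c(spA = 1000))
  expect_equal(unname(empty$total_nlr), 0)
  expect_equal(unname(empty$nlr_ratio_pct), 0)
  expect_equal(unname(empty$distribution_pct), rep(0, 4))
})

test_that("census aggregation from calls matches the row system", {
  sp <- synth_proteome(c(CNL = 5, CNL2 = 4, RNL = 10, TNL = 10,
                         ATYPICAL = 2, EXCLUDED = 3),
                       mutation_rate = 0, seed = 66)
  calls <- classify_records(sp$records, sp$hits)
  counts <- census_counts_from_calls(calls)
  # per-row counts equal the generator's truth rows
  truth_tab <- table(factor(sp$truth$census_row, levels = counts$row))
  expect_equal(counts$synthetic, unname(as.integer(truth_tab[counts$row])))
  cen2 <- build_census(counts, c(synthetic = 1000))
  expect_equal(unname(cen2$total_nlr), 31) # everything except EXCLUDED
})

test_that("transcriptome ratios round half-up to two decimals", {
  expect_equal(nlr_ratio(338, 46178), 0.73)
  expect_equal(nlr_ratio(506, 37491), 1.35)
  expect_equal(nlr_ratio(0, 5000), 0)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(8.5, 0), 9)
})

test_that("chi-square homogeneity matches hand computation", {
  same <- matrix(c(10, 10, 20, 20), 2, 2)
  r <- chi_square_homogeneity(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  prop <- matrix(c(10, 20, 20, 40), 2, 2, byrow = TRUE)
  expect_equal(chi_square_homogeneity(prop)$statistic, 0)
  # hand-computed Pearson value for (10,20 / 30,10)
  tab <- matrix(c(10, 20, 30, 10), 2, 2, byrow = TRUE)
  r2 <- chi_square_homogeneity(tab)
  expect_equal(r2$statistic, 12.152778, tolerance = 1e-6)
  expect_equal(r2$df, 1)
  expect_equal(rowSums(r2$expected), rowSums(tab), ignore_attr = TRUE)
  expect_equal(colSums(r2$expected), colSums(tab), ignore_attr = TRUE)
  expect_error(chi_square_homogeneity(matrix(c(0, 0, 5, 5), 2, 2)),
               "degenerate")
})

test_that("chi-square p decreases as the statistic grows at fixed df", {
  stats <- c(0.5, 2, 5, 10, 20)
  ps <- pchisq(stats, df = 3, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  # and the similar-species comparison yields a p near 1
  sub <- fixture$counts[, c("L_laricina", "P_glauca", "P_mariana")]
  tab <- rbind(CNL = colSums(sub[fixture$counts$category == "CNL", ]),
               CNL2 = colSums(sub[fixture$counts$category == "CNL2", ]),
               RNL = colSums(sub[fixture$counts$category == "RNL", ]),
               TNL = colSums(sub[fixture$counts$category == "TNL", ]))
  r <- chi_square_homogeneity(t(tab))
  expect_gt(r$p_value, 0.5)
})

test_that("OLS regression: exact fit, F identity and closed-form slope", {
  x <- seq(10, 100, by = 10)
  fit <- suppressWarnings(ols_regression(x, 0.1 * x)) # perfect-fit warning
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$r_squared, 1)
  set.seed(10)
  xs <- rnorm(30, 50, 10)
  ys <- 0.3 * xs + rnorm(30)
  f2 <- ols_regression(xs, ys)
  # F = R^2 / (1 - R^2) * (n - 2)
  expect_equal(f2$f_statistic,
               f2$r_squared / (1 - f2$r_squared) * (f2$n - 2),
               tolerance = 1e-9)
  expect_equal(f2$slope, sum((xs - mean(xs)) * (ys - mean(ys))) /
                 sum((xs - mean(xs))^2), tolerance = 1e-9)
})

test_that("synthetic species panels recover the planted slope", {
  panel <- synth_species_panel(n_species = 49, slope = 0.1, seed = 2024)
  fit <- ols_regression(panel$TNL, panel$RNL)
  expect_lt(abs(fit$slope - 0.1), 0.02)
  expect_lt(fit$p_value, 1e-6)
  # independent CNL counts show no relationship
  null_fit <- ols_regression(panel$CNL, panel$RNL)
  expect_lt(null_fit$r_squared, 0.2)
  # zero-noise panel: exact recovery
  exact <- synth_species_panel(n_species = 20, slope = 0.1, noise_sd = 0,
                               seed = 3)
  fe <- ols_regression(exact$TNL, exact$RNL)
  expect_equal(fe$slope, 0.1, tolerance = 0.02)
  expect_gt(fe$r_squared, 0.99)
})
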