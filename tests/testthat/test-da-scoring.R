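# Categorical scoring rules and homolog-asymmetry statistics.

test_that("the 16-pair decision table classifies per the scoring rules", {
  cats <- intensity_categories()
  expected <- matrix(c(
    # cat2:  bright        intermediate  dim          nil        (cat1 rows)
    "equivalent", "DA",         "DA",        "DA",       # bright
    "DA",         "equivalent", "DA",        "DA",       # intermediate
    "DA",         "DA",         "excluded",  "excluded", # dim
    "DA",         "DA",         "excluded",  "excluded"  # nil
  ), nrow = 4, byrow = TRUE, dimnames = list(cats, cats))
  for (c1 in cats) for (c2 in cats) {
    expect_identical(score_cell(c1, c2), expected[c1, c2],
                     label = paste(c1, c2))
  }
  # classification is symmetric in the two homologs
  grid <- expand.grid(c1 = cats, c2 = cats, stringsAsFactors = FALSE)
  expect_identical(score_cell(grid$c1, grid$c2),
                   score_cell(grid$c2, grid$c1))
  expect_error(score_cell("bright", "vivid"), "unknown intensity category")
})

test_that("normalized ratio matches hand arithmetic and its invariants", {
  expect_equal(normalized_ratio(100, 100), 0)
  expect_equal(normalized_ratio(250, 0), 1)
  expect_equal(normalized_ratio(935, 65), 0.87)
  expect_error(normalized_ratio(0, 0), "no signal")
  expect_error(normalized_ratio(-1, 5), "non-negative")

  set.seed(20)
  a <- runif(200, 0, 1e4); b <- runif(200, 0, 1e4)
  ok <- a + b > 0
  a <- a[ok]; b <- b[ok]
  r <- normalized_ratio(a, b)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r, normalized_ratio(b, a))                  # symmetry
  expect_equal(r, normalized_ratio(3.7 * a, 3.7 * b))      # scale invariance
})

test_that("two-proportion z-test matches closed form and the exact test", {
  # perfect balance
  b <- two_proportion_z_test(20, 40)
  expect_equal(b$z, 0)
  expect_equal(b$p, 1)
  expect_false(b$nonrandom)

  # the 80%-of-40 regime: closed-form z and agreement with binomial oracle
  r <- two_proportion_z_test(32, 40)
  z_closed <- (0.8 - 0.2) / sqrt(2 * 0.25 * (2 / 40))
  expect_equal(r$z, z_closed, tolerance = 1e-12)
  expect_lt(r$p, 0.05)
  expect_true(r$nonrandom)
  exact <- stats::binom.test(32, 40, 0.5)$p.value
  expect_lt(exact, 0.05)                       # same decision as the oracle
  expect_equal(two_proportion_z_test(32, 40, method = "binomial")$p, exact)

  # |z| increases monotonically away from balance; k = n is maximal
  zs <- vapply(0:40, function(k) abs(two_proportion_z_test(k, 40)$z),
               numeric(1))
  expect_equal(zs[41], max(zs))
  expect_true(all(diff(zs[21:41]) > 0))
  expect_error(two_proportion_z_test(5, 0), "n >= 1")
  expect_error(two_proportion_z_test(9, 4), "k <= n")

  # the dependence-corrected complementary form coincides with one-sample
  r1 <- two_proportion_z_test(32, 40, method = "one_sample")
  expect_equal(r$z, r1$z, tolerance = 1e-12)
})

test_that("Bartlett wrapper agrees with the textbook formula", {
  g <- list(c(1, 2, 3, 4, 5, 4, 3, 2, 1, 3),
            c(2, 5, 1, 6, 0, 7, 2, 5, 8, 0))
  got <- bartlett_test(g)
  want <- bartlett_oracle(g)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)

  # identical groups: statistic 0, p = 1
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  got0 <- bartlett_test(same)
  expect_equal(got0$statistic, 0, tolerance = 1e-12)
  expect_equal(got0$p, 1)

  expect_error(bartlett_test(list(1:5)), ">= 2")
  expect_error(bartlett_test(list(1:5, 3)), ">= 2 observations")

  # type-I error near alpha under the null
  set.seed(99)
  rej <- mean(vapply(1:1000, function(i) {
    bartlett_test(list(rnorm(10), rnorm(10), rnorm(10)))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.08)
})

test_that("ratio-group comparison summarizes and tests correctly", {
  set.seed(31)
  da <- pmin(pmax(rnorm(60, 0.7, 0.2), 0), 1)
  eq <- pmin(pmax(rnorm(60, 0.2, 0.1), 0), 1)
  cmp <- compare_ratio_groups(da, eq)
  expect_equal(cmp$summaries$group, c("DA", "equivalent"))
  expect_gt(cmp$summaries$median[1], cmp$summaries$median[2])
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$summaries$mean[1], mean(da))
  expect_equal(cmp$summaries$variance[2], var(eq))

  # identical groups with internal spread: t = 0, p = 1
  x <- c(0.2, 0.4, 0.6, 0.8)
  same <- compare_ratio_groups(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # shared constant in both groups is degenerate
  expect_error(compare_ratio_groups(rep(0.5, 5), rep(0.5, 5)), "degenerate")
  expect_error(compare_ratio_groups(0.5, c(0.1, 0.2)), ">= 2")
})

test_that("simulated DA and equivalent probes separate end to end", {
  ratios <- function(delta, seed_base) {
    vapply(1:25, function(s) {
      sim <- simulate_metaphase_image(asymmetry_delta = delta,
                                      seed = seed_base + s)
      q <- suppressWarnings(quantify_probes(sim$probe, sim$truth$rois))
      normalized_ratio(q$integrated_intensity[1], q$integrated_intensity[2])
    }, numeric(1))
  }
  da <- ratios(0.8, 5000)
  eq <- ratios(0.05, 6000)
  cmp <- compare_ratio_groups(da, eq)
  expect_gt(cmp$summaries$median[1], cmp$summaries$median[2])
  expect_lt(cmp$p, 0.05)
})

test_that("assess_sample aggregates scoring and flags non-random bias", {
  tab <- simulate_cell_scores(n_cells = 40, bias = 0.85, seed = 7)
  rep <- assess_sample(tab)
  expect_equal(rep$n_cells, 40L)
  expect_equal(rep$n_scored + rep$n_excluded, 40L)
  # reported fraction within the binomial 95% interval around 0.85
  ci <- stats::binom.test(round(0.85 * rep$bias$n_scoreable),
                          rep$bias$n_scoreable)$conf.int
  expect_gte(rep$bias$fraction, ci[1])
  expect_lte(rep$bias$fraction, ci[2])
  expect_true(rep$bias$nonrandom)

  # a table of only excluded pairs errors
  bad <- data.frame(cat1 = c("dim", "dim", "nil"),
                    cat2 = c("dim", "nil", "nil"))
  expect_error(assess_sample(bad), "all cells excluded")

  # intensity-mode input is categorized automatically
  it <- data.frame(i1 = c(900, 850, 40, 500), i2 = c(100, 80, 35, 480))
  expect_s3_class(suppressWarnings(assess_sample(it)), "sample_report")
})

test_that("intensity categorization respects the noise floor and tertiles", {
  x <- c(0, 2, 10, 20, 30, 40, 50, 60, 70, 80, 90)
  cats <- categorize_intensity(x, noise_floor = 5)
  expect_equal(cats[1:2], c("nil", "nil"))
  expect_true(all(cats[x > 5] %in% c("dim", "intermediate", "bright")))
  expect_equal(categorize_intensity(c(1, 2), noise_floor = 5),
               c("nil", "nil"))
  # explicit breaks
  expect_equal(categorize_intensity(c(1, 11, 51, 91),
                                    breaks = c(5, 30, 70)),
               c("nil", "dim", "intermediate", "bright"))
})
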