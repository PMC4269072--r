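# Generators: determinism, ground-truth contracts, closed-form checks.

test_that("metaphase image simulator honors the asymmetry contract", {
  # delta = 0: equal spots, true ratio 0
  s0 <- simulate_metaphase_image(asymmetry_delta = 0, seed = 1)
  expect_equal(s0$truth$i1, s0$truth$i2)
  expect_equal(s0$truth$ratio, 0)
  # delta = 1: homolog-2 spot absent
  s1 <- simulate_metaphase_image(asymmetry_delta = 1, seed = 1)
  expect_equal(s1$truth$i2, 0)
  expect_equal(s1$truth$ratio, 1)
  expect_false(any(s1$truth$spot_masks[[2]]))
  # true ratio follows delta / (2 - delta); I2 strictly decreasing in delta
  deltas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  i2s <- vapply(deltas, function(d) {
    sim <- simulate_metaphase_image(asymmetry_delta = d, seed = 2)
    expect_equal(sim$truth$ratio, d / (2 - d), tolerance = 1e-10)
    sim$truth$i2
  }, numeric(1))
  expect_true(all(diff(i2s) < 0))
})

test_that("identical seeds give bit-identical simulator output", {
  a <- simulate_metaphase_image(seed = 42)
  b <- simulate_metaphase_image(seed = 42)
  expect_identical(a$probe, b$probe)
  expect_identical(a$counterstain, b$counterstain)
  c1 <- simulate_metaphase_image(seed = 43)
  expect_false(identical(a$probe, c1$probe))

  sa <- simulate_probe_stack(seed = 7)
  sb <- simulate_probe_stack(seed = 7)
  expect_identical(sa$stack$intensity, sb$stack$intensity)

  ta <- simulate_cell_scores(seed = 5)
  tb <- simulate_cell_scores(seed = 5)
  expect_identical(ta$cat1, tb$cat1)

  iv <- data.frame(chrom = "chr1", start = 1, end = 400)
  ka <- simulate_signal_track(iv, level = 3, noise_sigma = 1, seed = 9)
  kb <- simulate_signal_track(iv, level = 3, noise_sigma = 1, seed = 9)
  expect_identical(ka$track$score, kb$track$score)
})

test_that("spot photon conservation matches the analytic Gaussian integral", {
  sim <- simulate_metaphase_image(probe_intensity = 300, psf_sigma = 2,
                                  asymmetry_delta = 0.4, seed = 3)
  analytic <- 300 * 2 * pi * 2^2
  expect_equal(sim$truth$i1, analytic, tolerance = 0.01)
  expect_equal(sim$truth$i2, 0.6 * analytic, tolerance = 0.01)
})

test_that("spots outside the image raise an error", {
  expect_error(
    simulate_metaphase_image(spot_centers = cbind(c(2, 60), c(2, 40))),
    "outside")
  expect_error(simulate_metaphase_image(asymmetry_delta = 1.2), "asymmetry")
})

test_that("probe stack ground truth matches the closed-form profile", {
  # noiseless stack equals background + ellipsoidal profile exactly
  ss <- simulate_probe_stack(n_sections = 21, frame = c(32, 32),
                             spot_center = c(16, 16, 11),
                             spot_radii = c(5, 4, 6.5), amplitude = 80,
                             background = 12, noise_sigma = 0, seed = 1)
  d <- dim(ss$stack$intensity)
  zi <- rep(seq_len(d[1]), times = d[2] * d[3])
  yi <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  xi <- rep(seq_len(d[3]), each = d[1] * d[2])
  d2 <- ((xi - 16) / 5)^2 + ((yi - 16) / 4)^2 + ((zi - 11) / 6.5)^2
  expect_equal(as.vector(ss$stack$intensity),
               12 + 80 * exp(-log(2) * d2), tolerance = 1e-12)
  # half-max truth equals the ellipsoid interior
  expect_equal(ss$truth$voxel_count, sum(d2 < 1))

  # rz spanning exactly 15 sections -> z extent 15
  s15 <- simulate_probe_stack(n_sections = 18, frame = c(24, 24),
                              spot_center = c(12, 12, 10),
                              spot_radii = c(4, 4, 7.5), seed = 2)
  expect_equal(s15$truth$z_extent_sections, 15L)

  # amplitude 0 -> background noise only
  s0 <- simulate_probe_stack(amplitude = 0, background = 10,
                             noise_sigma = 1.5, seed = 3)
  expect_equal(mean(s0$stack$intensity), 10, tolerance = 0.05)
  expect_equal(s0$truth$voxel_count, 0L)

  expect_error(simulate_probe_stack(spot_center = c(2, 2, 2),
                                    spot_radii = c(6, 6, 6)),
               "fit inside")
})

test_that("cell-score simulator reproduces its bias and exclusion rates", {
  # null model: brighter-homolog fraction near 0.5
  tab <- simulate_cell_scores(n_cells = 10000, bias = 0.5,
                              excluded_fraction = 0, seed = 11)
  cls <- score_cell(tab$cat1, tab$cat2)
  bh <- brighter_homolog(tab$cat1[cls == "DA"], tab$cat2[cls == "DA"])
  frac <- mean(bh == 1)
  se <- sqrt(0.25 / length(bh))
  expect_lt(abs(frac - 0.5), 3 * se)

  # forced bias: every DA cell favors the designated homolog
  tb <- simulate_cell_scores(n_cells = 500, bias = 1, seed = 12)
  clsb <- score_cell(tb$cat1, tb$cat2)
  bhb <- brighter_homolog(tb$cat1[clsb == "DA"], tb$cat2[clsb == "DA"])
  expect_true(all(bhb == 1L))

  # exclusion rate is binomial around its parameter
  tc <- simulate_cell_scores(n_cells = 5000, excluded_fraction = 0.2,
                             seed = 13)
  n_ex <- sum(score_cell(tc$cat1, tc$cat2) == "excluded")
  expect_lt(abs(n_ex / 5000 - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  excl_pairs <- paste(tc$cat1, tc$cat2)[score_cell(tc$cat1, tc$cat2) ==
                                          "excluded"]
  expect_true(all(excl_pairs %in% c("dim dim", "dim nil")))

  expect_error(simulate_cell_scores(bias = 0.3), "bias")
  expect_error(simulate_cell_scores(category_mix = c("bright/odd" = 1)),
               "invalid category pair")
})

test_that("signal-track sums follow the closed form and recover under noise", {
  iv <- data.frame(chrom = "chr2", start = 101, end = 300)
  # level 0, no noise -> zero
  z <- simulate_signal_track(iv, level = 0, spacing = 20, seed = 1)
  expect_equal(sum_signal(z, iv), 0)
  # 10 datapoints of 2 -> 20, exactly
  t2 <- simulate_signal_track(iv, level = 2, spacing = 20, seed = 1)
  expect_equal(t2$expected$n_datapoints, 10L)
  expect_equal(sum_signal(t2, iv), 20)
  # Monte Carlo: mean recovered sum within 3 SE of expectation
  reps <- vapply(1:300, function(s) {
    tr <- simulate_signal_track(iv, level = 2, spacing = 20,
                                noise_sigma = 1, seed = s)
    sum_signal(tr, iv)
  }, numeric(1))
  se <- sqrt(10 * 1^2) / sqrt(300)
  expect_lt(abs(mean(reps) - 20), 3 * se)
})
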