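# GVF edge maps, field diffusion, snake evolution, intensity integration.

test_that("edge map is zero on constants and peaks on edges", {
  expect_true(all(compute_edge_map(matrix(7, 20, 20))$f == 0))

  step_img <- cbind(matrix(0, 24, 12), matrix(10, 24, 12))
  f <- compute_edge_map(step_img, sigma = 1)$f
  peak_cols <- apply(f[5:20, ], 1, which.max)
  expect_true(all(peak_cols %in% 12:13))      # ridge along the step line

  expect_error(compute_edge_map(array(1, c(3, 3, 3))), "matrix")
})

test_that("edge-map ridge of a Gaussian spot sits at the inflection radius", {
  # spot sigma s, smoothing sigma g: |grad| of the blurred spot peaks at
  # r = sqrt(s^2 + g^2) (closed form for a Gaussian profile)
  n <- 41; s <- 3; g <- 1
  xg <- matrix(rep(1:n, each = n), n); yg <- matrix(rep(1:n, n), n)
  img <- 100 * exp(-((xg - 21)^2 + (yg - 21)^2) / (2 * s^2))
  f <- compute_edge_map(img, sigma = g)$f
  r <- sqrt((xg - 21)^2 + (yg - 21)^2)
  r_peak <- r[which.max(f)]
  expect_equal(r_peak, sqrt(s^2 + g^2), tolerance = 0.2)
})

test_that("GVF field has the analytic fixed points", {
  # f == 0 -> field identically zero
  g0 <- compute_gvf_field(matrix(0, 16, 16), mu = 0.2, n_iter = 20)
  expect_true(all(g0$u == 0) && all(g0$v == 0))

  # residual decreases with iteration count
  set.seed(1)
  em <- compute_edge_map(matrix(rnorm(900), 30), sigma = 1.5)
  g_short <- compute_gvf_field(em, n_iter = 20)
  g_long <- compute_gvf_field(em, n_iter = 40)
  expect_lte(tail(g_long$residual_history, 1),
             tail(g_short$residual_history, 1))

  # with mu -> 0, u converges to f_x where |grad f| is non-zero
  f <- matrix(0, 15, 15); f[8, 8] <- 1
  gr <- homologDA:::.gradient2d(f)
  gm <- compute_gvf_field(f, mu = 1e-8, n_iter = 5000, tol = 0)
  strong <- (gr$gx^2 + gr$gy^2) > 0.05
  expect_lt(max(abs(gm$u[strong] - gr$gx[strong])), 1e-6)
})

test_that("unstable user time-steps raise; default converges to fixed point", {
  em <- compute_edge_map(cbind(matrix(0, 20, 10), matrix(5, 20, 10)))
  expect_error(compute_gvf_field(em, mu = 0.2, dt = 2), "unstable time-step")
  g <- compute_gvf_field(em, mu = 0.2, n_iter = 8000, tol = 1e-10)
  expect_lt(gvf_residual(g, em), 1e-4)
})

test_that("snake recovers a disk boundary and collapses without a field", {
  n <- 48
  xg <- matrix(rep(1:n, each = n), n); yg <- matrix(rep(1:n, n), n)
  disk <- 1 * (((xg - 24)^2 + (yg - 24)^2) <= 10^2)
  em <- compute_edge_map(disk, sigma = 1)
  g <- compute_gvf_field(em, n_iter = 150)
  snk <- evolve_snake(g, list(x = 24, y = 24, r = 16), max_iter = 400)
  expect_equal(snk$area, sum(disk), tolerance = 0.1)

  # zero field: tension shrinks the contour to collapse
  zero <- list(u = matrix(0, n, n), v = matrix(0, n, n))
  expect_error(evolve_snake(zero, list(x = 24, y = 24, r = 10),
                            alpha = 0.5, n_points = 16, max_iter = 5000,
                            tol = 0),
               "degenerate contour")
})

test_that("GVF extends the capture range beyond the raw gradient", {
  n <- 64
  xg <- matrix(rep(1:n, each = n), n); yg <- matrix(rep(1:n, n), n)
  disk <- 1 * (((xg - 32)^2 + (yg - 32)^2) <= 8^2)
  em <- compute_edge_map(disk, sigma = 1)
  # plain gradient-of-edge-map force: zero a few pixels from the boundary
  gr <- homologDA:::.gradient2d(em$f)
  plain <- list(u = gr$gx, v = gr$gy)
  gvf <- compute_gvf_field(em, n_iter = 400)

  init <- list(x = 32, y = 32, r = 26)     # far outside the gradient support
  truth <- disk > 0
  iou <- function(m) sum(m & truth) / sum(m | truth)

  snk_gvf <- evolve_snake(gvf, init, max_iter = 600)
  expect_gt(iou(snk_gvf$mask), 0.8)        # converged onto the disk

  snk_plain <- tryCatch(
    evolve_snake(plain, init, max_iter = 600),
    error = function(e) NULL)              # collapse counts as failure too
  if (!is.null(snk_plain)) {
    expect_lt(iou(snk_plain$mask), 0.5)    # stuck or collapsed, not captured
  } else {
    succeed("plain-gradient snake collapsed (no capture range)")
  }
})

test_that("recovered contour is equivariant under 90-degree rotation", {
  sim <- simulate_metaphase_image(asymmetry_delta = 0, noise_sigma = 0,
                                  seed = 4)
  roi <- sim$truth$rois[1, ]
  crop <- sim$probe[(roi$y - 12):(roi$y + 12), (roi$x - 12):(roi$x + 12)]
  run_snake <- function(img) {
    em <- compute_edge_map(img - 50, sigma = 1)
    g <- compute_gvf_field(em, n_iter = 120)
    evolve_snake(g, list(x = 13, y = 13, r = 8), max_iter = 300)$mask
  }
  m <- run_snake(crop)
  rot90 <- function(m) t(m)[, nrow(m):1]           # counter-clockwise
  m_rot <- run_snake(rot90(crop))
  # rotate the recovered mask back and compare
  unrot <- t(m_rot[nrow(m_rot):1, ])
  iou <- sum(m & unrot) / sum(m | unrot)
  expect_gte(iou, 0.95)
})

test_that("integrated intensity sums background-corrected pixels", {
  img <- matrix(6, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:6, 3:6] <- TRUE
  expect_equal(integrated_intensity(img, mask, background = 0), 6 * 16)
  expect_equal(integrated_intensity(img, mask, background = 6), 0)  # floor
  expect_equal(integrated_intensity(img, mask, background = 10), 0)
  expect_error(integrated_intensity(img, matrix(FALSE, 10, 10)), "empty mask")
  expect_error(integrated_intensity(img, mask[1:5, ]), "identical dimensions")

  # function result matches a brute-force sum over the ground-truth mask
  sim <- simulate_metaphase_image(asymmetry_delta = 0.3, seed = 6)
  tm <- sim$truth$spot_masks[[1]]
  manual <- sum(sim$probe[tm] - 50)
  expect_equal(integrated_intensity(sim$probe, tm, background = 50),
               manual, tolerance = 1e-12)
})

test_that("pair quantification recovers the intensity ratio within 5%", {
  sim <- simulate_metaphase_image(asymmetry_delta = 0.5, seed = 8)
  q <- suppressWarnings(quantify_probes(sim$probe, sim$truth$rois))
  expect_equal(nrow(q), 2L)
  i2_over_i1 <- q$integrated_intensity[2] / q$integrated_intensity[1]
  expect_equal(i2_over_i1, 0.5, tolerance = 0.05)
})
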