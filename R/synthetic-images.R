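#' Simulate a two-channel metaphase FISH image with known spot intensities
#'
#' Renders a pair of homologous chromosome bodies (counterstain channel) and
#' one Gaussian hybridization spot per homolog (probe channel).  The spot on
#' homolog 2 has amplitude `(1 - asymmetry_delta)` times that of homolog 1,
#' so the true normalized intensity ratio
#' \eqn{|I_1 - I_2| / (I_1 + I_2) = \delta / (2 - \delta)}.
#' Ground truth (noiseless integrated spot intensities, half-max spot masks,
#' suggested regions of interest) is returned alongside the images so that
#' segmentation accuracy can be measured without re-deriving truth from the
#' noisy data.
#'
#' The point-spread function is modelled as an isotropic Gaussian; this is
#' adequate for testing boundary detection and ratio recovery, and
#' `psf_sigma` is a free parameter.  Noise is additive Gaussian with optional
#' Poisson shot noise on the clean signal.
#'
#' @param image_size integer `c(height, width)` in pixels.
#' @param chromosome_size numeric `c(length, width)` of each chromosome body
#'   in pixels (counterstain channel only).
#' @param probe_intensity peak amplitude of the homolog-1 spot (a.u.).
#' @param asymmetry_delta fraction in `[0, 1]`; homolog-2 spot amplitude is
#'   `(1 - asymmetry_delta) * probe_intensity`.
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param background constant background level (a.u.) added to both channels.
#' @param noise_sigma standard deviation of additive Gaussian noise (a.u.).
#' @param poisson logical; add Poisson shot noise on the clean signal.
#' @param spot_centers optional 2x2 matrix of spot centers, rows
#'   `(x, y)` per homolog; defaults to a band position on each chromosome
#'   axis.
#' @param seed integer; fully determines the output.
#' @return An object of class `"metaphase_sim"`: a list with elements
#'   `probe` and `counterstain` (numeric matrices, `image_size`), and
#'   `truth`, a list with `i1`, `i2` (noiseless integrated spot intensities),
#'   `ratio` (true normalized intensity ratio), `spot_masks` (list of two
#'   logical matrices, noiseless spot above half max), `centers`, and `rois`
#'   (data frame `cell_id, homolog_id, x, y, radius`).
#' @examples
#' sim <- simulate_metaphase_image(asymmetry_delta = 0.5, seed = 1)
#' sim$truth$ratio  # 0.5 / 1.5
#' @export
simulate_metaphase_image <- function(image_size = c(96L, 128L),
                                     chromosome_size = c(48, 12),
                                     probe_intensity = 500,
                                     asymmetry_delta = 0.93,
                                     psf_sigma = 1.5,
                                     background = 50,
                                     noise_sigma = 5,
                                     poisson = FALSE,
                                     spot_centers = NULL,
                                     seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16))
  if (!is.numeric(asymmetry_delta) || length(asymmetry_delta) != 1L ||
      asymmetry_delta < 0 || asymmetry_delta > 1) {
    stop("'asymmetry_delta' must be a single value in [0, 1]")
  }
  stopifnot(probe_intensity >= 0, psf_sigma > 0, noise_sigma >= 0)
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])

  cx <- c(round(w / 3), round(2 * w / 3))
  cy <- round(h / 2)
  if (is.null(spot_centers)) {
    # band at 1/4 of the chromosome length above the centromere position
    band_y <- cy - round(chromosome_size[1] / 4)
    spot_centers <- cbind(x = cx, y = c(band_y, band_y))
  }
  spot_centers <- matrix(as.numeric(spot_centers), ncol = 2L,
                         dimnames = list(NULL, c("x", "y")))
  margin <- 3 * psf_sigma
  if (any(spot_centers[, "x"] < 1 + margin | spot_centers[, "x"] > w - margin |
          spot_centers[, "y"] < 1 + margin | spot_centers[, "y"] > h - margin)) {
    stop("probe spot lies outside the image (allow a 3*psf_sigma margin)")
  }

  xg <- matrix(rep(seq_len(w), each = h), nrow = h)
  yg <- matrix(rep(seq_len(h), times = w), nrow = h)

  gauss_spot <- function(amp, x0, y0) {
    amp * exp(-((xg - x0)^2 + (yg - y0)^2) / (2 * psf_sigma^2))
  }
  amps <- probe_intensity * c(1, 1 - asymmetry_delta)
  spots <- lapply(1:2, function(i) {
    gauss_spot(amps[i], spot_centers[i, "x"], spot_centers[i, "y"])
  })
  probe_clean <- spots[[1]] + spots[[2]]

  # counterstain: two soft-edged elliptical chromosome bodies
  body <- function(x0, y0) {
    d2 <- ((xg - x0) / (chromosome_size[2] / 2))^2 +
      ((yg - y0) / (chromosome_size[1] / 2))^2
    200 / (1 + exp(8 * (d2 - 1)))
  }
  counter_clean <- body(cx[1], cy) + body(cx[2], cy)

  set.seed(as.integer(seed))
  add_noise <- function(clean) {
    out <- clean + background
    if (poisson) out <- matrix(rpois(length(out), pmax(out, 0)), nrow = h)
    out + matrix(rnorm(length(out), sd = noise_sigma), nrow = h)
  }
  probe <- add_noise(probe_clean)
  counterstain <- add_noise(counter_clean)

  spot_masks <- lapply(1:2, function(i) {
    if (amps[i] <= 0) {
      matrix(FALSE, h, w)
    } else {
      spots[[i]] > amps[i] / 2
    }
  })
  i1 <- sum(spots[[1]]); i2 <- sum(spots[[2]])
  roi_r <- max(8, ceiling(6 * psf_sigma))
  truth <- list(
    i1 = i1, i2 = i2,
    ratio = if (i1 + i2 > 0) abs(i1 - i2) / (i1 + i2) else NA_real_,
    spot_masks = spot_masks,
    centers = spot_centers,
    rois = data.frame(cell_id = 1L, homolog_id = 1:2,
                      x = spot_centers[, "x"], y = spot_centers[, "y"],
                      radius = roi_r)
  )
  structure(list(probe = probe, counterstain = counterstain, truth = truth,
                 params = list(image_size = c(h, w),
                               probe_intensity = probe_intensity,
                               asymmetry_delta = asymmetry_delta,
                               psf_sigma = psf_sigma, background = background,
                               noise_sigma = noise_sigma, poisson = poisson,
                               seed = seed)),
            class = "metaphase_sim")
}

#' Simulate a reconstructed 3D probe-fluorescence stack
#'
#' Generates an ellipsoidal Gaussian-profile probe signal inside a voxel
#' stack with physical voxel dimensions, emulating a reconstructed optical
#' sectioning series (z-step 0.1 um by default).  The profile is
#' \eqn{A \exp(-\ln 2 \, d^2)} with
#' \eqn{d^2 = ((x-c_x)/r_x)^2 + ((y-c_y)/r_y)^2 + ((z-c_z)/r_z)^2},
#' so the half-maximum surface is exactly the ellipsoid `d = 1`; ground
#' truth (voxel count above half max, z-extent in sections) follows in
#' closed form and is returned as a sidecar.
#'
#' @param n_sections number of optical sections (z planes).
#' @param frame integer `c(ny, nx)` lateral size in voxels.
#' @param z_step section spacing in micrometres (default 0.1).
#' @param lateral_pixel lateral voxel size in micrometres.
#' @param spot_center numeric `c(x, y, z)` in voxel coordinates; default is
#'   the stack center.
#' @param spot_radii numeric `c(rx, ry, rz)` half-max semi-axes in voxels.
#' @param amplitude peak signal amplitude (a.u.).
#' @param background constant background (a.u.).
#' @param noise_sigma additive Gaussian noise sd (a.u.).
#' @param poisson logical; add Poisson shot noise.
#' @param seed integer seed; fully determines the output.
#' @return A list of class `"stack_sim"` with elements `stack` (a
#'   [voxel_stack()]), `clean` (noiseless array including background), and
#'   `truth` (list: `voxel_count` above half max, `z_extent_sections`,
#'   `volume_um3`, `center`, `radii`, `amplitude`).
#' @examples
#' ss <- simulate_probe_stack(n_sections = 21, spot_radii = c(5, 5, 7.5))
#' ss$truth$z_extent_sections
#' @export
simulate_probe_stack <- function(n_sections = 21L,
                                 frame = c(48L, 48L),
                                 z_step = 0.1,
                                 lateral_pixel = 0.04,
                                 spot_center = NULL,
                                 spot_radii = c(6, 6, 7.5),
                                 amplitude = 100,
                                 background = 10,
                                 noise_sigma = 2,
                                 poisson = FALSE,
                                 seed = 1L) {
  stopifnot(n_sections >= 1, z_step > 0, lateral_pixel > 0,
            length(spot_radii) == 3L, all(spot_radii > 0),
            amplitude >= 0, noise_sigma >= 0)
  ny <- as.integer(frame[1]); nx <- as.integer(frame[2])
  nz <- as.integer(n_sections)
  if (is.null(spot_center)) {
    spot_center <- c((nx + 1) / 2, (ny + 1) / 2, (nz + 1) / 2)
  }
  stopifnot(length(spot_center) == 3L)
  lo <- spot_center - spot_radii[c(1, 2, 3)]
  hi <- spot_center + spot_radii[c(1, 2, 3)]
  if (lo[1] < 1 || lo[2] < 1 || lo[3] < 1 ||
      hi[1] > nx || hi[2] > ny || hi[3] > nz) {
    stop("probe spot (center +/- radii) does not fit inside the stack")
  }

  zi <- rep(seq_len(nz), times = ny * nx)
  yi <- rep(rep(seq_len(ny), each = nz), times = nx)
  xi <- rep(seq_len(nx), each = nz * ny)
  d2 <- ((xi - spot_center[1]) / spot_radii[1])^2 +
    ((yi - spot_center[2]) / spot_radii[2])^2 +
    ((zi - spot_center[3]) / spot_radii[3])^2
  profile <- array(amplitude * exp(-log(2) * d2), dim = c(nz, ny, nx))
  clean <- profile + background

  set.seed(as.integer(seed))
  noisy <- clean
  if (poisson) {
    noisy <- array(rpois(length(noisy), pmax(noisy, 0)), dim = dim(noisy))
  }
  noisy <- noisy + array(rnorm(length(noisy), sd = noise_sigma),
                         dim = dim(noisy))

  above <- amplitude > 0 & array(d2, dim = c(nz, ny, nx)) < 1
  zs <- which(apply(above, 1, any))
  truth <- list(
    voxel_count = sum(above),
    z_extent_sections = length(zs),
    volume_um3 = sum(above) * lateral_pixel^2 * z_step,
    center = spot_center, radii = spot_radii, amplitude = amplitude
  )
  structure(list(stack = voxel_stack(noisy, lateral_pixel = lateral_pixel,
                                     z_step = z_step),
                 clean = clean, truth = truth,
                 params = list(seed = seed, background = background,
                               noise_sigma = noise_sigma, poisson = poisson)),
            class = "stack_sim")
}

# default mixture over scoreable category pairs: DA-type pairs dominate,
# mirroring probes for which most informative cells show a homolog difference
.default_category_mix <- c(
  "bright/intermediate" = 0.16,
  "bright/dim"          = 0.16,
  "bright/nil"          = 0.16,
  "intermediate/dim"    = 0.16,
  "intermediate/nil"    = 0.16,
  "bright/bright"                 = 0.10,
  "intermediate/intermediate"     = 0.10
)

#' Simulate per-cell categorical homolog intensity scores
#'
#' Draws `n_cells` cells.  Each cell is first excluded (failed
#' hybridization: `dim/dim` or `dim/nil`) with probability
#' `excluded_fraction`; otherwise a category pair is drawn from
#' `category_mix`.  For DA-type pairs the brighter category is assigned to
#' the designated homolog (homolog 1) with probability `bias`, so the
#' expected fraction of DA cells whose brighter signal lies on the
#' designated homolog equals `bias`.
#'
#' @param n_cells number of cells to draw.
#' @param bias probability in `[0.5, 1]` that the designated homolog carries
#'   the brighter signal of a DA pair.  0.5 is the null (random) model.
#' @param category_mix named probabilities over scoreable category pairs
#'   (names `"a/b"` with `a` brighter or equal); normalized internally.
#' @param excluded_fraction probability that a cell is an excluded pair.
#' @param seed integer seed.
#' @return A data frame (`cell_score_table`) with columns `cell_id`,
#'   `cat1`, `cat2` (categories on the designated homolog 1 and on
#'   homolog 2).  The generating parameters are attached as attribute
#'   `"params"`.
#' @examples
#' tab <- simulate_cell_scores(n_cells = 40, bias = 0.85, seed = 7)
#' table(tab$cat1, tab$cat2)
#' @export
simulate_cell_scores <- function(n_cells = 35L,
                                 bias = 0.8,
                                 category_mix = NULL,
                                 excluded_fraction = 0.05,
                                 seed = 1L) {
  stopifnot(n_cells >= 1)
  if (!is.numeric(bias) || length(bias) != 1L || bias < 0.5 || bias > 1) {
    stop("'bias' must be a single probability in [0.5, 1]")
  }
  if (excluded_fraction < 0 || excluded_fraction >= 1) {
    stop("'excluded_fraction' must be in [0, 1)")
  }
  if (is.null(category_mix)) category_mix <- .default_category_mix
  if (is.null(names(category_mix)) || any(category_mix < 0) ||
      sum(category_mix) <= 0) {
    stop("'category_mix' must be named non-negative probabilities")
  }
  pairs <- strsplit(names(category_mix), "/", fixed = TRUE)
  bad <- !vapply(pairs, function(p) {
    length(p) == 2L && all(p %in% intensity_categories())
  }, logical(1))
  if (any(bad)) {
    stop("invalid category pair name(s): ",
         paste(names(category_mix)[bad], collapse = ", "))
  }
  mix <- category_mix / sum(category_mix)

  set.seed(as.integer(seed))
  excluded <- runif(n_cells) < excluded_fraction
  pair_idx <- sample.int(length(mix), n_cells, replace = TRUE, prob = mix)
  excl_pairs <- list(c("dim", "dim"), c("dim", "nil"))
  cat1 <- character(n_cells); cat2 <- character(n_cells)
  flip_to_h1 <- runif(n_cells) < bias
  for (i in seq_len(n_cells)) {
    if (excluded[i]) {
      p <- excl_pairs[[sample.int(2L, 1L)]]
      cat1[i] <- p[1]; cat2[i] <- p[2]
      next
    }
    p <- pairs[[pair_idx[i]]]
    if (p[1] == p[2]) {               # equivalent pair, no orientation
      cat1[i] <- p[1]; cat2[i] <- p[2]
    } else if (flip_to_h1[i]) {       # brighter category on homolog 1
      cat1[i] <- p[1]; cat2[i] <- p[2]
    } else {
      cat1[i] <- p[2]; cat2[i] <- p[1]
    }
  }
  out <- data.frame(cell_id = seq_len(n_cells), cat1 = cat1, cat2 = cat2,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_cells = n_cells, bias = bias,
                              category_mix = mix,
                              excluded_fraction = excluded_fraction,
                              seed = seed)
  class(out) <- c("cell_score_table", "data.frame")
  out
}

#' Simulate a piecewise-constant signal track over probe intervals
#'
#' Emits one track record per datapoint: within each interval, datapoints
#' are laid down every `spacing` bp from the interval start, each covering
#' `spacing` bp and carrying `level (+ noise)`.  The expected sum of
#' datapoint values over an interval is therefore
#' `level * floor(width / spacing)`, returned alongside the track.
#'
#' @param intervals a `GRanges`, or a data frame with columns
#'   `chrom, start, end` (1-based, inclusive).
#' @param level signal level per datapoint (a.u.); scalar or one value per
#'   interval.
#' @param spacing datapoint spacing in bp (> 0).
#' @param noise_sigma Gaussian noise sd added independently per datapoint.
#' @param seed integer seed.
#' @return List of class `"track_sim"`: `track` (a `GRanges` with a `score`
#'   column, one range per datapoint) and `expected` (data frame with
#'   `n_datapoints` and `expected_sum` per interval).
#' @examples
#' iv <- data.frame(chrom = "chr1", start = 101, end = 300)
#' ts <- simulate_signal_track(iv, level = 2, spacing = 20)
#' ts$expected$expected_sum  # 2 * 10
#' @export
simulate_signal_track <- function(intervals, level = 1, spacing = 20L,
                                  noise_sigma = 0, seed = 1L) {
  stopifnot(spacing > 0, noise_sigma >= 0)
  gr <- as_probe_granges(intervals)
  n <- length(gr)
  level <- rep_len(level, n)
  set.seed(as.integer(seed))
  recs <- lapply(seq_len(n), function(i) {
    k <- (end(gr[i]) - start(gr[i]) + 1L) %/% spacing
    if (k < 1L) return(NULL)
    pos <- start(gr[i]) + spacing * (seq_len(k) - 1L)
    GenomicRanges::GRanges(
      seqnames = as.character(seqnames(gr[i])),
      ranges = IRanges::IRanges(start = pos, width = spacing),
      score = level[i] + rnorm(k, sd = noise_sigma)
    )
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  track <- if (length(recs)) do.call(c, recs) else
    GenomicRanges::GRanges(score = numeric(0))
  k_all <- (end(gr) - start(gr) + 1L) %/% spacing
  expected <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    n_datapoints = as.integer(k_all),
    expected_sum = level * k_all
  )
  structure(list(track = track, expected = expected,
                 params = list(level = level, spacing = spacing,
                               noise_sigma = noise_sigma, seed = seed)),
            class = "track_sim")
}
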