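# Gradient-vector-flow active contours for probe-boundary detection.
#
# The external force field is the gradient vector flow of Xu & Prince: the
# vector field (u, v) minimizing
#   E = integral mu*(|grad u|^2 + |grad v|^2) + |grad f|^2 |(u,v) - grad f|^2
# where f is an edge map of the image.  Near edges (|grad f| large) the
# field equals grad f; elsewhere it is a smooth diffusion of the edge
# gradient, which extends the capture range of the snake well beyond the
# support of the raw image gradient.

# central-difference gradients with replicated (Neumann) borders
.gradient2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # x = column direction, y = row direction
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

.laplacian2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(2:nr, nr), ] + m[c(1, 1:(nr - 1)), ] +
    m[, c(2:nc, nc)] + m[, c(1, 1:(nc - 1))] - 4 * m
}

#' Compute the squared-gradient edge map of a grayscale image
#'
#' The edge map is \eqn{f = |\nabla (G_\sigma * I)|^2}: the image is
#' smoothed with a Gaussian of standard deviation `sigma`, and the squared
#' gradient magnitude of the result is returned, optionally normalized to
#' `[0, 1]` (the usual convention before gradient-vector-flow diffusion).
#'
#' @param image 2D numeric matrix (grayscale).
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param normalize logical; scale `f` so `max(f) == 1` (no-op on a
#'   constant image).
#' @return Object of class `"edge_map"`: list with `f` (matrix, >= 0
#'   everywhere) and `sigma`.
#' @examples
#' em <- compute_edge_map(matrix(rnorm(400), 20), sigma = 1)
#' range(em$f)
#' @export
compute_edge_map <- function(image, sigma = 1, normalize = TRUE) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a 2D numeric matrix")
  }
  stopifnot(sigma > 0)
  sm <- if (sigma > 0) EBImage::gblur(image, sigma = sigma) else image
  sm <- matrix(sm, nrow = nrow(image))
  g <- .gradient2d(sm)
  f <- g$gx^2 + g$gy^2
  if (normalize && max(f) > 0) f <- f / max(f)
  structure(list(f = f, sigma = sigma), class = "edge_map")
}

#' Compute the gradient vector flow (GVF) field of an edge map
#'
#' Solves the GVF equations by explicit diffusion iteration
#' \deqn{u_{t+1} = u_t + dt\,[\mu \nabla^2 u_t - (u_t - f_x)(f_x^2+f_y^2)]}
#' (and analogously for `v`), starting from \eqn{(u, v) = \nabla f}.
#' The time step must satisfy the standard stability bound
#' `dt <= 1 / (4 * mu)`; a larger user-supplied `dt` raises an error
#' rather than being clamped silently.
#'
#' @param edge an [compute_edge_map()] result, or a plain numeric matrix
#'   taken as the edge map `f`.
#' @param mu regularization weight (> 0); larger values give a smoother
#'   field.
#' @param n_iter maximum number of diffusion iterations (>= 1).
#' @param dt explicit time step; default
#'   `min(1 / (4 * mu), 1 / max(fx^2 + fy^2))`.
#' @param tol optional early-stopping tolerance on the maximum update
#'   magnitude per iteration.
#' @return Object of class `"gvf_field"`: `u`, `v` (matrices), `mu`, `dt`,
#'   `n_iterations` (performed), and `residual_history` (max absolute
#'   update per iteration).
#' @seealso [gvf_residual()] for the fixed-point residual at convergence.
#' @export
compute_gvf_field <- function(edge, mu = 0.2, n_iter = 80L, dt = NULL,
                              tol = NULL) {
  f <- if (inherits(edge, "edge_map")) edge$f else edge
  if (!is.matrix(f)) stop("'edge' must be an edge_map or a numeric matrix")
  stopifnot(mu > 0, n_iter >= 1)
  g <- .gradient2d(f)
  fx <- g$gx; fy <- g$gy
  b <- fx^2 + fy^2
  # joint stability of diffusion + reaction for the explicit scheme:
  # the worst Fourier mode has gain 1 - dt*(8*mu + b); dt = 1/(4*mu + max(b))
  # keeps |gain| < 1.  1/(4*mu) is the classical diffusion-only bound and the
  # hard ceiling for user-supplied steps.
  dt_stab <- 1 / (4 * mu)
  if (is.null(dt)) {
    dt <- 1 / (4 * mu + max(b))
  } else if (dt > dt_stab + 1e-12) {
    stop(sprintf(
      "unstable time-step: dt = %g exceeds the diffusion stability bound 1/(4*mu) = %g",
      dt, dt_stab))
  }
  u <- fx; v <- fy
  hist <- numeric(0)
  for (it in seq_len(n_iter)) {
    du <- dt * (mu * .laplacian2d(u) - (u - fx) * b)
    dv <- dt * (mu * .laplacian2d(v) - (v - fy) * b)
    u <- u + du
    v <- v + dv
    delta <- max(abs(du), abs(dv))
    hist <- c(hist, delta)
    if (!is.finite(delta) ||
        (it > 5 && delta > 1e3 * (hist[1] + .Machine$double.eps))) {
      stop(sprintf(
        "GVF iteration diverged at step %d (time-step dt = %g)", it, dt))
    }
    if (!is.null(tol) && delta < tol) break
  }
  structure(list(u = u, v = v, mu = mu, dt = dt, n_iterations = it,
                 residual_history = hist),
            class = "gvf_field")
}

#' Fixed-point residual of a GVF field
#'
#' At convergence the GVF field satisfies
#' \eqn{\mu \nabla^2 u = (u - f_x)(f_x^2 + f_y^2)} at every interior pixel
#' (and analogously for `v`).  This returns the maximum absolute residual
#' of both equations over interior pixels -- an assertable convergence
#' check.
#'
#' @param field a [compute_gvf_field()] result.
#' @param edge the edge map the field was computed from.
#' @return Maximum absolute interior residual (scalar).
#' @export
gvf_residual <- function(field, edge) {
  stopifnot(inherits(field, "gvf_field"))
  f <- if (inherits(edge, "edge_map")) edge$f else edge
  g <- .gradient2d(f)
  b <- g$gx^2 + g$gy^2
  ru <- field$mu * .laplacian2d(field$u) - (field$u - g$gx) * b
  rv <- field$mu * .laplacian2d(field$v) - (field$v - g$gy) * b
  nr <- nrow(f); nc <- ncol(f)
  inner <- cbind(ru, rv)[2:(nr - 1), c(2:(nc - 1), nc + 2:(nc - 1)), drop = FALSE]
  max(abs(inner))
}

# bilinear interpolation of matrix m at (x = column, y = row) positions
.interp2 <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  dx <- x - x0; dy <- y - y0
  m[cbind(y0, x0)] * (1 - dx) * (1 - dy) +
    m[cbind(y0, x0 + 1)] * dx * (1 - dy) +
    m[cbind(y0 + 1, x0)] * (1 - dx) * dy +
    m[cbind(y0 + 1, x0 + 1)] * dx * dy
}

# rasterize a closed polygon (cols x, y) into a logical mask by the
# crossing-number (even-odd) rule, evaluated at pixel centers
.polygon_mask <- function(poly, nrow, ncol) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  xr <- range(xs); yr <- range(ys)
  cols <- max(1, floor(xr[1])):min(ncol, ceiling(xr[2]))
  rows <- max(1, floor(yr[1])):min(nrow, ceiling(yr[2]))
  if (!length(cols) || !length(rows)) return(matrix(FALSE, nrow, ncol))
  px <- rep(cols, each = length(rows))
  py <- rep(rows, times = length(cols))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  mask <- matrix(FALSE, nrow, ncol)
  mask[cbind(py[inside], px[inside])] <- TRUE
  mask
}

#' Evolve an active contour (snake) under internal and GVF external forces
#'
#' A closed parametric snake with tension `alpha` and rigidity `beta` is
#' evolved semi-implicitly: internal forces are solved implicitly through
#' the usual pentadiagonal system, the external force (the GVF field,
#' normalized to unit vectors where non-negligible) explicitly.  Iteration
#' stops when the mean point displacement falls below `tol` or after
#' `max_iter` steps.  The final contour is rasterized to a binary mask.
#'
#' @param field a [compute_gvf_field()] result (or a list with matrices
#'   `u`, `v`).  Pass a zero field to evolve under internal forces alone.
#' @param init either a list `list(x, y, r)` describing a seed circle, or
#'   a two-column matrix of initial polygon vertices `(x, y)`.
#' @param alpha snake tension (first-derivative) weight.
#' @param beta snake rigidity (second-derivative) weight.
#' @param step time step (gamma) of the snake evolution.
#' @param max_iter maximum iterations.
#' @param n_points number of contour points for a circle initialization.
#' @param tol mean-displacement stopping tolerance in pixels.
#' @param force_normalization `"global"` (default; scale the field by its
#'   maximum magnitude, preserving the smooth zero crossing at the object
#'   boundary so the snake settles there), `"unit"` (per-vector unit
#'   normalization), or `"none"` (raw field).
#' @return Object of class `"contour_mask"`: `mask` (logical matrix),
#'   `polygon` (final vertices), `area` (pixels), `iterations`.
#' @export
evolve_snake <- function(field, init, alpha = 0.1, beta = 0.1, step = 0.5,
                         max_iter = 200L, n_points = 80L, tol = 0.02,
                         force_normalization = c("global", "unit", "none")) {
  force_normalization <- match.arg(force_normalization)
  u <- field$u; v <- field$v
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  nr <- nrow(u); nc <- ncol(u)
  if (force_normalization == "global") {
    maxmag <- sqrt(max(u^2 + v^2))
    if (maxmag > 0) { u <- u / maxmag; v <- v / maxmag }
  }
  if (is.list(init) && !is.null(init$r)) {
    th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    x <- init$x + init$r * cos(th)
    y <- init$y + init$r * sin(th)
  } else {
    init <- as.matrix(init)
    stopifnot(ncol(init) == 2L, nrow(init) >= 3L)
    x <- init[, 1]; y <- init[, 2]
  }
  n <- length(x)

  # pentadiagonal internal-force matrix (circulant): alpha*D2 - beta*D4
  a <- beta
  b2 <- -alpha - 4 * beta
  c2 <- 2 * alpha + 6 * beta
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, idx(i - 2)] <- A[i, idx(i - 2)] + a
    A[i, idx(i - 1)] <- A[i, idx(i - 1)] + b2
    A[i, i] <- A[i, i] + c2
    A[i, idx(i + 1)] <- A[i, idx(i + 1)] + b2
    A[i, idx(i + 2)] <- A[i, idx(i + 2)] + a
  }
  M <- solve(diag(n) + step * A)

  for (it in seq_len(max_iter)) {
    fx <- .interp2(u, x, y)
    fy <- .interp2(v, x, y)
    if (force_normalization == "unit") {
      mag <- sqrt(fx^2 + fy^2)
      big <- mag > 1e-8
      fx[big] <- fx[big] / mag[big]; fy[big] <- fy[big] / mag[big]
      fx[!big] <- 0; fy[!big] <- 0
    }
    xn <- as.vector(M %*% (x + step * fx))
    yn <- as.vector(M %*% (y + step * fy))
    xn <- pmin(pmax(xn, 1), nc); yn <- pmin(pmax(yn, 1), nr)
    moved <- mean(sqrt((xn - x)^2 + (yn - y)^2))
    x <- xn; y <- yn
    if (moved < tol) break
  }
  poly <- cbind(x = x, y = y)
  mask <- .polygon_mask(poly, nr, nc)
  area <- sum(mask)
  if (area < 3) stop("degenerate contour: snake collapsed to < 3 pixels")
  structure(list(mask = mask, polygon = poly, area = area, iterations = it),
            class = "contour_mask")
}

#' Background-corrected integrated intensity within a contour mask
#'
#' Sums `image - background` over the mask; a negative total (background
#' exceeding signal) is floored at zero.
#'
#' @param image 2D numeric matrix.
#' @param mask logical matrix of the same dimensions, or a
#'   [evolve_snake()] result.
#' @param background scalar background level (a.u.) subtracted per pixel.
#' @return Scalar integrated intensity (a.u.), >= 0.
#' @examples
#' img <- matrix(10, 5, 5)
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' integrated_intensity(img, m, background = 4)  # (10-4)*9
#' @export
integrated_intensity <- function(image, mask, background = 0) {
  if (inherits(mask, "contour_mask")) mask <- mask$mask
  if (!is.matrix(image) || !is.logical(mask) ||
      !all(dim(image) == dim(mask))) {
    stop("'image' and 'mask' must be matrices of identical dimensions")
  }
  if (!any(mask)) stop("empty mask: no pixels to integrate")
  max(sum(image[mask] - background), 0)
}

# median background in an annulus [r_in, r_out] around (x0, y0)
.annulus_background <- function(image, x0, y0, r_in, r_out) {
  nr <- nrow(image); nc <- ncol(image)
  xg <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
  yg <- matrix(rep(seq_len(nr), times = nc), nrow = nr)
  d <- sqrt((xg - x0)^2 + (yg - y0)^2)
  sel <- d >= r_in & d <= r_out
  if (!any(sel)) sel <- d >= r_in        # image smaller than the annulus
  if (!any(sel)) return(stats::median(image))
  stats::median(image[sel])
}

#' Quantify probe fluorescence per homolog by GVF active contours
#'
#' For each region of interest (one homolog each), the brightest local
#' maximum inside the ROI seeds a circle at 1.5 times the spot's half-max
#' radius; local background is the median over an annulus at 2-3 times the
#' seed radius; a GVF snake is evolved on the edge map of the
#' background-subtracted ROI, delineating the hybridization boundary.
#'
#' Because the two homolog signals of a cell can differ greatly in
#' brightness, intensities are integrated over *matched apertures*: within
#' each cell, both homologs use a circular aperture of the same radius
#' (`aperture_scale` times the largest equivalent contour radius among the
#' cell's homologs, clipped to the ROI radius), centered on each homolog's
#' peak.  This keeps the captured flux fraction identical across homologs,
#' so the normalized intensity ratio is unbiased even for strongly
#' asymmetric pairs.  Set `aperture_scale = NULL` to integrate over each
#' raw contour instead.
#'
#' If an ROI contains more than one prominent interior local maximum the
#' brighter one is used and a warning is issued.
#'
#' @param image 2D numeric probe-channel matrix.
#' @param rois data frame with columns `cell_id`, `homolog_id`, `x`, `y`,
#'   `radius` (ROI circle per homolog, e.g. from simulator metadata).
#' @param edge_sigma edge-map smoothing sigma (pixels).
#' @param mu,gvf_iter GVF regularization weight and iteration count.
#' @param alpha,beta,step snake parameters, see [evolve_snake()].
#' @param snake_iter maximum snake iterations.
#' @param aperture_scale matched-aperture radius as a multiple of the
#'   largest equivalent contour radius in the cell (default 2), or `NULL`
#'   for raw-contour integration.
#' @return Data frame with one row per ROI: `cell_id`, `homolog_id`,
#'   `integrated_intensity`, `area_px` (converged contour area),
#'   `aperture_px` (pixels integrated), `background`.
#' @examples
#' sim <- simulate_metaphase_image(asymmetry_delta = 0.6, seed = 3)
#' quantify_probes(sim$probe, sim$truth$rois)
#' @export
quantify_probes <- function(image, rois, edge_sigma = 1, mu = 0.2,
                            gvf_iter = 80L, alpha = 0.1, beta = 0.1,
                            step = 0.5, snake_iter = 200L,
                            aperture_scale = 2) {
  stopifnot(is.matrix(image),
            all(c("cell_id", "homolog_id", "x", "y", "radius") %in%
                  names(rois)))
  nr <- nrow(image); nc <- ncol(image)
  fits <- vector("list", nrow(rois))
  for (k in seq_len(nrow(rois))) {
    roi <- rois[k, ]
    r <- roi$radius
    # crop a padded window around the ROI
    x0 <- max(1L, floor(roi$x - 2 * r)); x1 <- min(nc, ceiling(roi$x + 2 * r))
    y0 <- max(1L, floor(roi$y - 2 * r)); y1 <- min(nr, ceiling(roi$y + 2 * r))
    sub <- image[y0:y1, x0:x1, drop = FALSE]
    cx <- roi$x - x0 + 1; cy <- roi$y - y0 + 1

    xg <- matrix(rep(seq_len(ncol(sub)), each = nrow(sub)), nrow = nrow(sub))
    yg <- matrix(rep(seq_len(nrow(sub)), times = ncol(sub)), nrow = nrow(sub))
    in_roi <- (xg - cx)^2 + (yg - cy)^2 <= r^2

    sm <- matrix(EBImage::gblur(sub, sigma = max(edge_sigma, 1)),
                 nrow = nrow(sub))
    bg0 <- stats::median(sub[!in_roi])
    if (is.na(bg0)) bg0 <- stats::median(sub)
    peaks <- .local_maxima(sm, in_roi)
    if (nrow(peaks) > 1L) {
      # only prominent maxima count as competing spot candidates
      prom <- peaks$value >= bg0 + 0.5 * (max(peaks$value) - bg0)
      if (sum(prom) > 1L) {
        warning(sprintf(
          "ROI %d/%s: %d competing local maxima; using the brightest",
          roi$cell_id, roi$homolog_id, sum(prom)))
      }
    }
    if (nrow(peaks) == 0L) {            # flat ROI: fall back to the center
      px <- cx; py <- cy
    } else {
      best <- which.max(peaks$value)
      px <- peaks$x[best]; py <- peaks$y[best]
    }
    peak_val <- sm[py, px]
    # half-max footprint: connected component of the smoothed spot that
    # contains the peak (stray noise pixels above half max are dropped)
    half <- sm > bg0 + (peak_val - bg0) / 2 & in_roi
    if (any(half) && half[py, px]) {
      lab <- EBImage::bwlabel(half)
      half <- lab == lab[py, px]
    }
    r_half <- max(sqrt(sum(half) / pi), 1.5)
    seed_r <- min(1.5 * r_half, r)
    background <- .annulus_background(sub, px, py, 2 * seed_r, 3 * seed_r)

    em <- compute_edge_map(sub - background, sigma = edge_sigma)
    gvf <- compute_gvf_field(em, mu = mu, n_iter = gvf_iter)
    mask <- tryCatch({
      snk <- evolve_snake(gvf, list(x = px, y = py, r = seed_r),
                          alpha = alpha, beta = beta, step = step,
                          max_iter = snake_iter)
      snk$mask
    }, error = function(e) {
      # faint spots can leave the contour unsupported; fall back to the
      # half-maximum footprint, which matches the snake's equilibrium
      # region under the default edge smoothing
      warning(sprintf(
        "ROI %d/%s: active contour degenerate (%s); using half-max footprint",
        roi$cell_id, roi$homolog_id, conditionMessage(e)))
      fb <- half
      if (!any(fb)) {
        fb <- (xg - px)^2 + (yg - py)^2 <= max(seed_r, 2)^2
      }
      fb
    })
    fits[[k]] <- list(cell_id = roi$cell_id, homolog_id = roi$homolog_id,
                      sub = sub, mask = mask, background = background,
                      px = px, py = py, xg = xg, yg = yg,
                      roi_radius = r)
  }

  # matched-aperture integration per cell
  cells <- split(seq_len(nrow(rois)), rois$cell_id)
  out <- vector("list", nrow(rois))
  for (cell in cells) {
    r_eq <- vapply(fits[cell], function(f) sqrt(sum(f$mask) / pi),
                   numeric(1))
    for (k in cell) {
      f <- fits[[k]]
      if (is.null(aperture_scale)) {
        ap <- f$mask
      } else {
        r_ap <- min(aperture_scale * max(r_eq), f$roi_radius)
        ap <- (f$xg - f$px)^2 + (f$yg - f$py)^2 <= r_ap^2
      }
      ii <- integrated_intensity(f$sub, ap, background = f$background)
      out[[k]] <- data.frame(cell_id = f$cell_id,
                             homolog_id = f$homolog_id,
                             integrated_intensity = ii,
                             area_px = sum(f$mask),
                             aperture_px = sum(ap),
                             background = f$background)
    }
  }
  do.call(rbind, out)
}

# interior local maxima of matrix m restricted to a logical region
.local_maxima <- function(m, region) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(data.frame(x = integer(), y = integer(),
                                          value = numeric()))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= m[1:(nr - 2), 2:(nc - 1)] &
    core >= m[3:nr, 2:(nc - 1)] &
    core >= m[2:(nr - 1), 1:(nc - 2)] &
    core >= m[2:(nr - 1), 3:nc] &
    core >= m[1:(nr - 2), 1:(nc - 2)] &
    core >= m[1:(nr - 2), 3:nc] &
    core >= m[3:nr, 1:(nc - 2)] &
    core >= m[3:nr, 3:nc] &
    core > min(m)                        # exclude flat background plateaus
  w <- which(is_max & region[2:(nr - 1), 2:(nc - 1)], arr.ind = TRUE)
  if (!nrow(w)) return(data.frame(x = integer(), y = integer(),
                                  value = numeric()))
  data.frame(x = w[, 2] + 1L, y = w[, 1] + 1L,
             value = core[w])
}
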