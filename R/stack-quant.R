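# Probe volume and axial depth from reconstructed 3D optical sections.

#' Construct a voxel stack with physical voxel dimensions
#'
#' @param intensity 3D numeric array indexed `(z, y, x)`.
#' @param lateral_pixel lateral voxel size in micrometres (> 0).
#' @param z_step optical-section spacing in micrometres (> 0, default 0.1).
#' @return Object of class `"voxel_stack"`.
#' @export
voxel_stack <- function(intensity, lateral_pixel, z_step = 0.1) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L) {
    stop("'intensity' must be a 3D array (z, y, x)")
  }
  stopifnot(lateral_pixel > 0, z_step > 0, dim(intensity)[1] >= 1)
  structure(list(intensity = intensity, lateral_pixel = lateral_pixel,
                 z_step = z_step),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "voxel_stack: %d sections x %d x %d voxels (%.3f um lateral, %.2f um z-step)\n",
    d[1], d[2], d[3], x$lateral_pixel, x$z_step))
  invisible(x)
}

#' Threshold a voxel stack into a binary probe mask
#'
#' Converts the grayscale probe signal into a binary contour by global
#' thresholding.  `method = "otsu"` picks the threshold maximizing
#' between-class variance of the intensity histogram (computed within
#' `roi` when given); `method = "fixed"` uses the supplied `value`.
#' Voxels strictly above the threshold are foreground.
#'
#' @param stack a [voxel_stack()] (or plain 3D array).
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @param roi optional 3D box `list(z = c(z0, z1), y = c(y0, y1),
#'   x = c(x0, x1))`; statistics (and the mask) are restricted to it.
#' @return List of class `"stack_mask"`: `mask` (logical 3D array, same
#'   dimensions as the stack; `FALSE` outside `roi`), `threshold`,
#'   `method`.  An all-background result yields an empty mask with a
#'   warning, not an error.
#' @export
threshold_stack <- function(stack, method = c("otsu", "fixed"),
                            value = NULL, roi = NULL) {
  method <- match.arg(method)
  arr <- if (inherits(stack, "voxel_stack")) stack$intensity else stack
  if (!is.array(arr) || length(dim(arr)) != 3L || !length(arr)) {
    stop("'stack' must be a non-empty 3D array or voxel_stack")
  }
  sel <- array(TRUE, dim(arr))
  if (!is.null(roi)) {
    sel[] <- FALSE
    sel[roi$z[1]:roi$z[2], roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]] <- TRUE
  }
  vals <- arr[sel]
  if (method == "otsu") {
    rng <- range(vals)
    if (diff(rng) <= 0) {
      thr <- rng[1]                      # constant stack: nothing above
    } else {
      thr <- EBImage::otsu(matrix(vals, ncol = 1), range = rng,
                           levels = 256L)
    }
  } else {
    if (is.null(value)) stop("method = 'fixed' requires a threshold 'value'")
    thr <- value
  }
  mask <- arr > thr & sel
  if (!any(mask)) {
    warning("no voxel above threshold: empty probe mask")
  }
  structure(list(mask = mask, threshold = thr, method = method),
            class = "stack_mask")
}

# linear indices of 26-connected components of a logical 3D mask;
# returns an integer array of component labels (0 = background)
.label_components_26 <- function(mask) {
  d <- dim(mask)
  occ <- which(mask)
  lab <- array(0L, d)
  if (!length(occ)) return(lab)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  zi <- (occ - 1L) %% nz + 1L
  yi <- ((occ - 1L) %/% nz) %% ny + 1L
  xi <- (occ - 1L) %/% (nz * ny) + 1L
  pos <- integer(prod(d)); pos[occ] <- seq_along(occ)
  edges <- vector("list", 13L); e <- 0L
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[with(offs, dx > 0 | (dx == 0 & dy > 0) |
                      (dx == 0 & dy == 0 & dz > 0)), ]   # half-space: 13 offsets
  for (k in seq_len(nrow(offs))) {
    z2 <- zi + offs$dz[k]; y2 <- yi + offs$dy[k]; x2 <- xi + offs$dx[k]
    ok <- z2 >= 1L & z2 <= nz & y2 >= 1L & y2 <= ny & x2 >= 1L & x2 <= nx
    if (!any(ok)) next
    nb <- (x2[ok] - 1L) * (nz * ny) + (y2[ok] - 1L) * nz + z2[ok]
    hit <- pos[nb] > 0L
    if (!any(hit)) next
    e <- e + 1L
    edges[[e]] <- cbind(which(ok)[hit], pos[nb[hit]])
  }
  if (e == 0L) {
    lab[occ] <- seq_along(occ)
    return(lab)
  }
  el <- do.call(rbind, edges[seq_len(e)])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(occ) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[occ] <- comp[seq_along(occ)]
  lab
}

#' Probe geometry (volume, axial depth) from a binary stack mask
#'
#' Measures the hybridized probe target over all reconstructed optical
#' sections.  By default only the largest 26-connected component is kept
#' (`component = "all"` merges every component, e.g. for multi-target
#' low-copy probes assessed as a single fluorescent target).  The volume
#' is `voxel_count * lateral_pixel^2 * z_step`; the number of sections
#' spanned counts all z-planes between the lowest and highest occupied
#' section inclusive; and the axial depth is
#' `(n_sections_spanned - 1) * z_step` -- the distance between the centers
#' of the two extreme occupied sections.
#'
#' @param mask a [threshold_stack()] result or logical 3D array `(z, y, x)`.
#' @param lateral_pixel,z_step voxel dimensions in micrometres.
#' @param component `"largest"` (default) or `"all"`.
#' @return Object of class `"probe_geometry"`: `volume` (um^3), `depth`
#'   (um), `n_sections_spanned`, `voxel_count`, `threshold_used`,
#'   `empty` flag.
#' @examples
#' m <- array(FALSE, c(21, 8, 8)); m[1:18, 4, 4] <- TRUE
#' probe_geometry(m, lateral_pixel = 0.04, z_step = 0.1)$depth  # 1.7
#' @export
probe_geometry <- function(mask, lateral_pixel, z_step = 0.1,
                           component = c("largest", "all")) {
  component <- match.arg(component)
  thr <- NA_real_
  if (inherits(mask, "stack_mask")) {
    thr <- mask$threshold
    mask <- mask$mask
  }
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stop("'mask' must be a logical 3D array (z, y, x)")
  }
  stopifnot(lateral_pixel > 0, z_step > 0)
  if (!any(mask)) {
    return(structure(list(volume = 0, depth = 0, n_sections_spanned = 0L,
                          voxel_count = 0L, threshold_used = thr,
                          empty = TRUE),
                     class = "probe_geometry"))
  }
  keep <- mask
  if (component == "largest") {
    lab <- .label_components_26(mask)
    tab <- tabulate(lab[lab > 0L])
    keep <- lab == which.max(tab)
  }
  zs <- which(apply(keep, 1, any))
  n_span <- max(zs) - min(zs) + 1L
  vc <- sum(keep)
  structure(list(volume = vc * lateral_pixel^2 * z_step,
                 depth = (n_span - 1L) * z_step,
                 n_sections_spanned = as.integer(n_span),
                 voxel_count = as.integer(vc),
                 threshold_used = thr,
                 empty = FALSE),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "probe_geometry: volume %.2f um^3 (%d voxels), depth %.2f um (%d sections)%s\n",
    x$volume, x$voxel_count, x$depth, x$n_sections_spanned,
    if (x$empty) " [empty mask]" else ""))
  invisible(x)
}

#' Compare probe geometry between homologs across cells
#'
#' Runs two-tailed t-tests (paired by cell by default) on probe volume and
#' axial depth between homolog 1 and homolog 2, and reports the fold
#' change of mean volumes (homolog 1 / homolog 2).
#'
#' @param geometries data frame with columns `cell_id`, `homolog_id`
#'   (values 1 and 2), `volume`, `depth`: one row per homolog per cell,
#'   both homologs present for every cell.
#' @param paired logical; paired (default) or unpaired t-tests.
#' @param alpha significance level.
#' @return List of class `"homolog_comparison"`: `n_cells`,
#'   `volume_test` and `depth_test` (each `list(t, df, p, significant)`),
#'   `fold_change_volume`, `mean_volume` and `mean_depth` per homolog.
#' @export
compare_homologs <- function(geometries, paired = TRUE, alpha = 0.05) {
  need <- c("cell_id", "homolog_id", "volume", "depth")
  if (!all(need %in% names(geometries))) {
    stop("'geometries' needs columns ", paste(need, collapse = ", "))
  }
  g1 <- geometries[geometries$homolog_id == 1, ]
  g2 <- geometries[geometries$homolog_id == 2, ]
  g1 <- g1[order(g1$cell_id), ]; g2 <- g2[order(g2$cell_id), ]
  if (nrow(g1) != nrow(g2) || !all(g1$cell_id == g2$cell_id)) {
    stop("unpaired input: every cell needs exactly one row per homolog")
  }
  if (nrow(g1) < 2L) stop("need >= 2 cells")

  run_test <- function(x, y) {
    if (paired && all(x == y)) {
      return(list(t = 0, df = length(x) - 1, p = 1, significant = FALSE))
    }
    tt <- stats::t.test(x, y, paired = paired)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, significant = tt$p.value < alpha)
  }
  vol <- run_test(g1$volume, g2$volume)
  dep <- run_test(g1$depth, g2$depth)
  m1 <- mean(g1$volume); m2 <- mean(g2$volume)
  structure(list(n_cells = nrow(g1),
                 volume_test = vol, depth_test = dep,
                 fold_change_volume = if (m2 > 0) m1 / m2 else NA_real_,
                 mean_volume = c(homolog1 = m1, homolog2 = m2),
                 mean_depth = c(homolog1 = mean(g1$depth),
                                homolog2 = mean(g2$depth)),
                 paired = paired, alpha = alpha),
            class = "homolog_comparison")
}

#' @export
print.homolog_comparison <- function(x, ...) {
  cat(sprintf("Homolog geometry comparison (%d cells, %s t-tests):\n",
              x$n_cells, if (x$paired) "paired" else "unpaired"))
  cat(sprintf("  volume: mean %.3f vs %.3f um^3 (fold %.2f), t = %.2f, p = %.3g\n",
              x$mean_volume[1], x$mean_volume[2], x$fold_change_volume,
              x$volume_test$t, x$volume_test$p))
  cat(sprintf("  depth:  mean %.2f vs %.2f um, t = %.2f, p = %.3g\n",
              x$mean_depth[1], x$mean_depth[2], x$depth_test$t,
              x$depth_test$p))
  invisible(x)
}
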