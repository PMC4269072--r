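# Independent oracles and small fixtures used across the suite.

# brute-force geometry of a 3D logical mask: scans every voxel, labels
# 26-connected components by iterative label propagation (no package code)
brute_geometry <- function(mask, lateral_pixel, z_step,
                           component = c("largest", "all")) {
  component <- match.arg(component)
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)   # columns: z, y, x
  if (nrow(idx) == 0) {
    return(list(volume = 0, depth = 0, n_sections_spanned = 0L,
                voxel_count = 0L))
  }
  lab <- seq_len(nrow(idx))
  if (component == "largest" && nrow(idx) > 1) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(idx))) {
        for (j in seq_len(nrow(idx))) {
          if (lab[j] < lab[i] &&
              all(abs(idx[i, ] - idx[j, ]) <= 1)) {
            lab[i] <- lab[j]; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    big <- as.integer(names(which.max(table(lab))))
    idx <- idx[lab == big, , drop = FALSE]
  }
  zs <- range(idx[, 1])
  list(volume = nrow(idx) * lateral_pixel^2 * z_step,
       depth = (zs[2] - zs[1]) * z_step,
       n_sections_spanned = as.integer(zs[2] - zs[1] + 1L),
       voxel_count = nrow(idx))
}

# textbook Bartlett statistic for a list of samples
bartlett_oracle <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  v <- vapply(groups, stats::var, numeric(1))
  N <- sum(n)
  sp2 <- sum((n - 1) * v) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(v))
  den <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- num / den
  list(statistic = stat, p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# from-scratch one-way ANOVA F for two groups of pooled values
anova_oracle_F <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  gm <- mean(c(g1, g2))
  ssb <- n1 * (mean(g1) - gm)^2 + n2 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  (ssb / 1) / (ssw / (N - 2))
}

# random 3D logical mask with controllable density
random_mask <- function(dim3, density, seed) {
  set.seed(seed)
  array(runif(prod(dim3)) < density, dim = dim3)
}
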