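# Categorical DA scoring and homolog-asymmetry statistics.

#' The closed vocabulary of probe-signal intensity categories
#'
#' Categories are ordered from brightest to absent:
#' `bright > intermediate > dim > nil`.
#'
#' @return Character vector of the four categories, brightest first.
#' @export
intensity_categories <- function() c("bright", "intermediate", "dim", "nil")

.cat_rank <- function(x) {
  r <- match(x, intensity_categories())
  if (anyNA(r)) {
    stop("unknown intensity category: ",
         paste(unique(x[is.na(r)]), collapse = ", "))
  }
  r
}

#' Classify a cell from its two homolog intensity categories
#'
#' A cell is scored **DA** when one homolog shows an `intermediate` or
#' `bright` signal and the other shows any different intensity
#' (bright/intermediate, bright/dim, bright/nil, intermediate/dim,
#' intermediate/nil); **equivalent** when both homologs show the same
#' scoreable intensity (bright/bright, intermediate/intermediate); and
#' **excluded** (failed hybridization) for dim/dim, dim/nil, and nil/nil.
#'
#' @param cat1,cat2 intensity categories of the two homologs (vectors are
#'   recycled element-wise).
#' @return Character vector: `"DA"`, `"equivalent"`, or `"excluded"`.
#' @examples
#' score_cell("bright", "dim")          # DA
#' score_cell("bright", "bright")       # equivalent
#' score_cell("dim", "nil")             # excluded
#' @export
score_cell <- function(cat1, cat2) {
  r1 <- .cat_rank(cat1); r2 <- .cat_rank(cat2)
  hi <- pmin(r1, r2)                     # rank of the brighter homolog
  ifelse(hi <= 2 & r1 != r2, "DA",
         ifelse(hi <= 2, "equivalent", "excluded"))
}

#' Identify the brighter homolog of a category pair
#'
#' @param cat1,cat2 intensity categories of homolog 1 and homolog 2.
#' @return Integer vector: `1` or `2` for the brighter homolog, `NA` for
#'   ties.
#' @export
brighter_homolog <- function(cat1, cat2) {
  r1 <- .cat_rank(cat1); r2 <- .cat_rank(cat2)
  ifelse(r1 < r2, 1L, ifelse(r2 < r1, 2L, NA_integer_))
}

#' Normalized homolog intensity ratio
#'
#' The per-cell asymmetry statistic
#' \deqn{R = |I_1 - I_2| / (I_1 + I_2) \in [0, 1],}
#' where \eqn{I_1, I_2} are the background-corrected integrated probe
#' intensities on the two homologs.  Values near 0 indicate equivalent
#' hybridization; values near 1 indicate strong differential
#' accessibility.  The statistic is symmetric in its arguments and
#' invariant to a common intensity scale.
#'
#' @param i1,i2 non-negative integrated intensities (vectors recycled).
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' normalized_ratio(935, 65)   # 0.87
#' @export
normalized_ratio <- function(i1, i2) {
  if (any(i1 < 0 | i2 < 0)) stop("intensities must be non-negative")
  s <- i1 + i2
  if (any(s <= 0)) stop("no signal: i1 + i2 must be positive")
  abs(i1 - i2) / s
}

#' Two-proportion z-test for non-random homolog preference
#'
#' Tests whether the proportion of DA cells whose brighter hybridization
#' lies on a designated homolog differs from the complementary proportion.
#' With `k` of `n` cells favoring the designated homolog, the default
#' (`method = "complementary"`) compares \eqn{\hat p_1 = k/n} against
#' \eqn{\hat p_2 = (n-k)/n} with the pooled standard error (the pooled
#' proportion is 0.5 by construction):
#' \deqn{z = (\hat p_1 - \hat p_2) / \sqrt{2 \cdot 0.25 \cdot (2/n)}.}
#' The doubled variance in the denominator accounts for the perfect
#' anti-dependence of the two complementary proportions, so this form
#' coincides numerically with `method = "one_sample"`, which tests
#' \eqn{\hat p_1} against 0.5 via
#' \eqn{z = (\hat p_1 - 0.5)/\sqrt{0.25/n}}; both are kept as named
#' methods for interface clarity.  `method = "binomial"` performs the
#' exact two-sided binomial test instead.
#'
#' @param k number of DA cells favoring the designated homolog.
#' @param n total number of DA (scoreable) cells; `n >= 1`.
#' @param alpha significance level (default 0.05).
#' @param method `"complementary"` (default), `"one_sample"`, or
#'   `"binomial"`.
#' @return Object of class `"bias_test"`: list with `n_scoreable`,
#'   `k_favoring_designated`, `fraction`, `z` (NA for the exact test),
#'   `p`, `alpha`, `nonrandom` (`p < alpha`), `method`.
#' @examples
#' two_proportion_z_test(32, 40)   # the 80%-of-40-cells regime
#' @export
two_proportion_z_test <- function(k, n, alpha = 0.05,
                                  method = c("complementary", "one_sample",
                                             "binomial")) {
  method <- match.arg(method)
  if (length(k) != 1L || length(n) != 1L || n < 1 || k < 0 || k > n) {
    stop("need scalar counts with 0 <= k <= n and n >= 1")
  }
  p1 <- k / n
  if (method == "binomial") {
    z <- NA_real_
    p <- stats::binom.test(k, n, p = 0.5)$p.value
  } else {
    se <- if (method == "complementary") sqrt(2 * 0.25 * (2 / n))
          else sqrt(0.25 / n)
    num <- if (method == "complementary") p1 - (n - k) / n else p1 - 0.5
    z <- num / se
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  structure(list(n_scoreable = as.integer(n),
                 k_favoring_designated = as.integer(k),
                 fraction = p1, z = z, p = p, alpha = alpha,
                 nonrandom = p < alpha, method = method),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf(
    "Two-proportion z-test (%s): %d/%d cells (%.1f%%) favor the designated homolog\n",
    x$method, x$k_favoring_designated, x$n_scoreable, 100 * x$fraction))
  cat(sprintf("  z = %s, p = %.3g -> %s at alpha = %g\n",
              ifelse(is.na(x$z), "NA", sprintf("%.3f", x$z)), x$p,
              if (x$nonrandom) "non-random" else "random", x$alpha))
  invisible(x)
}

#' Bartlett's test for equality of variances across samples
#'
#' Thin validated interface to the standard Bartlett statistic (chi-squared
#' reference distribution), used to ask whether the spread in the number of
#' DA cells reported per sample differs between samples or probes.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   observations).
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' bartlett_test(list(rnorm(10), rnorm(10, sd = 1.4)))
#' @export
bartlett_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of >= 2 numeric vectors")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs >= 2 observations")
  }
  ht <- stats::bartlett.test(groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Compare normalized-ratio distributions of DA and equivalent probes
#'
#' Summarizes each group (mean, variance, median, interquartile range) and
#' tests for a difference in mean normalized intensity ratio with a
#' two-tailed t-test (Welch by default; set `var_equal = TRUE` for the
#' pooled-variance form).
#'
#' @param da_ratios,eq_ratios numeric vectors of normalized intensity
#'   ratios in `[0, 1]` for the DA and equivalent probe groups (each
#'   `n >= 2`).
#' @param var_equal logical; pooled-variance t-test instead of Welch.
#' @return List of class `"ratio_comparison"`: `summaries` (data frame,
#'   one row per group: `group, n, mean, variance, median, iqr_low,
#'   iqr_high`), `t`, `df`, `p`, `method`.
#' @export
compare_ratio_groups <- function(da_ratios, eq_ratios, var_equal = FALSE) {
  if (length(da_ratios) < 2L || length(eq_ratios) < 2L) {
    stop("each group needs >= 2 ratio values")
  }
  if (any(c(da_ratios, eq_ratios) < 0 | c(da_ratios, eq_ratios) > 1)) {
    stop("normalized ratios must lie in [0, 1]")
  }
  summarize <- function(x, g) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    data.frame(group = g, n = length(x), mean = mean(x),
               variance = stats::var(x), median = stats::median(x),
               iqr_low = q[1], iqr_high = q[2])
  }
  summaries <- rbind(summarize(da_ratios, "DA"),
                     summarize(eq_ratios, "equivalent"))
  if (stats::var(da_ratios) == 0 && stats::var(eq_ratios) == 0) {
    if (mean(da_ratios) == mean(eq_ratios)) {
      stop("degenerate input: both groups are a shared constant")
    }
  }
  tt <- stats::t.test(da_ratios, eq_ratios, var.equal = var_equal)
  structure(list(summaries = summaries, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 method = tt$method),
            class = "ratio_comparison")
}

#' Score a sample's cell table and test for non-random homolog preference
#'
#' Applies [score_cell()] to every cell, tallies DA / equivalent /
#' excluded, and runs [two_proportion_z_test()] on the number of DA cells
#' whose brighter hybridization lies on homolog 1 (the designated,
#' e.g. cytogenetically marked, homolog).
#'
#' @param table data frame with columns `cat1`, `cat2` (categories on the
#'   designated homolog and its counterpart), e.g. from
#'   [simulate_cell_scores()].  Alternatively columns `i1`, `i2` with
#'   integrated intensities, which are categorized automatically with
#'   [categorize_intensity()].
#' @param alpha significance level for the bias test.
#' @param method z-test form, see [two_proportion_z_test()].
#' @param noise_floor for intensity input: background noise floor passed
#'   to [categorize_intensity()].
#' @return List of class `"sample_report"`: `n_cells`, `n_scored`,
#'   `n_excluded`, `n_da`, `n_equivalent`, `fraction_da` (among scored
#'   cells), `bias` (a `bias_test`, or `NA` when no cell is DA).
#' @examples
#' tab <- simulate_cell_scores(n_cells = 40, bias = 0.85, seed = 7)
#' assess_sample(tab)
#' @export
assess_sample <- function(table, alpha = 0.05,
                          method = c("complementary", "one_sample",
                                     "binomial"),
                          noise_floor = NULL) {
  method <- match.arg(method)
  if (!all(c("cat1", "cat2") %in% names(table))) {
    if (all(c("i1", "i2") %in% names(table))) {
      cats <- categorize_intensity(c(table$i1, table$i2),
                                   noise_floor = noise_floor)
      n <- nrow(table)
      table$cat1 <- cats[seq_len(n)]
      table$cat2 <- cats[n + seq_len(n)]
    } else {
      stop("'table' needs columns cat1/cat2 or i1/i2")
    }
  }
  cls <- score_cell(table$cat1, table$cat2)
  n_da <- sum(cls == "DA"); n_eq <- sum(cls == "equivalent")
  n_ex <- sum(cls == "excluded")
  if (n_da + n_eq == 0L) {
    stop("all cells excluded: nothing scoreable in this sample")
  }
  bias <- NA
  if (n_da > 0L) {
    bh <- brighter_homolog(table$cat1[cls == "DA"], table$cat2[cls == "DA"])
    bias <- two_proportion_z_test(sum(bh == 1L), n_da, alpha = alpha,
                                  method = method)
  } else {
    warning("no DA cells; homolog-preference test not performed")
  }
  structure(list(n_cells = nrow(table),
                 n_scored = n_da + n_eq,
                 n_excluded = n_ex,
                 n_da = n_da,
                 n_equivalent = n_eq,
                 fraction_da = n_da / (n_da + n_eq),
                 bias = bias),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf(
    "Sample: %d cells (%d scored, %d excluded); DA %d (%.1f%%), equivalent %d\n",
    x$n_cells, x$n_scored, x$n_excluded, x$n_da, 100 * x$fraction_da,
    x$n_equivalent))
  if (inherits(x$bias, "bias_test")) print(x$bias)
  invisible(x)
}

#' Categorize integrated intensities into bright / intermediate / dim / nil
#'
#' An automated surrogate for by-eye category calls: intensities at or
#' below the background noise floor are `nil`; the remaining values are
#' split at the tertiles of the positive intensities into `dim`,
#' `intermediate`, and `bright`.
#'
#' @param x numeric vector of background-corrected integrated intensities.
#' @param noise_floor threshold below which a signal counts as absent;
#'   default `3 * mad(x)` of the weakest tertile, or 0 when all values are
#'   positive signal.
#' @param breaks optional explicit category boundaries
#'   `c(nil_max, dim_max, intermediate_max)`.
#' @return Character vector of categories.
#' @export
categorize_intensity <- function(x, noise_floor = NULL, breaks = NULL) {
  stopifnot(is.numeric(x))
  if (is.null(breaks)) {
    if (is.null(noise_floor)) {
      noise_floor <- 0
    }
    pos <- x[x > noise_floor]
    if (!length(pos)) return(rep("nil", length(x)))
    q <- stats::quantile(pos, c(1 / 3, 2 / 3), names = FALSE)
    breaks <- c(noise_floor, q)
  }
  stopifnot(length(breaks) == 3L, !is.unsorted(breaks))
  out <- rep("bright", length(x))
  out[x <= breaks[3]] <- "intermediate"
  out[x <= breaks[2]] <- "dim"
  out[x <= breaks[1]] <- "nil"
  out
}
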