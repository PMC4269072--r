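# Open-chromatin signal aggregation over probe intervals and the
# DA-vs-equivalent group comparison.

#' Coerce probe intervals to GRanges
#'
#' @param x a `GRanges`, or a data frame with columns `chrom` (or
#'   `seqnames`/`chr`), `start`, `end`.
#' @param coords `"onebased"` (1-based, inclusive; the convention used for
#'   printed genomic coordinates) or `"bed"` (0-based, half-open); BED
#'   input is shifted to 1-based internally.
#' @return A `GRanges`; any extra columns are carried as metadata.
#' @export
as_probe_granges <- function(x, coords = c("onebased", "bed")) {
  coords <- match.arg(coords)
  if (inherits(x, "GRanges")) return(x)
  nm <- names(x)
  chrom_col <- intersect(c("chrom", "seqnames", "chr"), nm)[1]
  if (is.na(chrom_col) || !all(c("start", "end") %in% nm)) {
    stop("interval input needs columns chrom/start/end")
  }
  start <- x$start + if (coords == "bed") 1L else 0L
  if (any(start > x$end)) stop("interval start exceeds end")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x[[chrom_col]]),
    ranges = IRanges::IRanges(start = start, end = x$end))
  extra <- setdiff(nm, c(chrom_col, "start", "end"))
  for (cn in extra) S4Vectors::mcols(gr)[[cn]] <- x[[cn]]
  gr
}

#' Load the packaged single-copy probe region feature table
#'
#' Returns the packaged set of 93 single-copy FISH probe regions (GRCh37,
#' 1-based inclusive coordinates) with integrated ENCODE GM12878
#' open-chromatin signal intensities for six features (DNase I HS, FAIRE,
#' H3K4me, H3K9Ac, H3K27Ac, H3K4me2) and each region's metaphase
#' accessibility class (`DA` or `equivalent`).  The table was transcribed
#' from the published comparison of open-chromatin features between
#' regions with and without DA; see the package vignette for the
#' transcription notes.
#'
#' @param path path to an alternative TSV with the same schema.
#' @return Data frame of class `"region_features"` with columns `chrom`,
#'   `start`, `end`, `label`, `accessibility_class`, and the six feature
#'   columns `DNase_OS`, `FAIR_OS`, `H3K4me`, `H3K9Ac`, `H3K27Ac`,
#'   `H3K4me2`.
#' @examples
#' rf <- load_region_features()
#' table(rf$accessibility_class)
#' @export
load_region_features <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_features.tsv",
                        package = "homologDA", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "label", "accessibility_class",
            feature_columns())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("malformed region table: missing column(s) ",
                         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    row <- df[i, feature_columns()]
    if (any(!is.finite(as.numeric(row))) || any(as.numeric(row) < 0)) {
      stop(sprintf("malformed region table at row %d: %s", i,
                   "feature values must be non-negative numbers"))
    }
    if (!df$accessibility_class[i] %in% c("DA", "equivalent")) {
      stop(sprintf("malformed region table at row %d: bad class '%s'",
                   i, df$accessibility_class[i]))
    }
    if (!is.finite(df$start[i]) || !is.finite(df$end[i]) ||
        df$start[i] > df$end[i]) {
      stop(sprintf("malformed region table at row %d: bad coordinates", i))
    }
  }
  class(df) <- c("region_features", "data.frame")
  df
}

#' The six open-chromatin feature column names
#' @return Character vector of feature column names.
#' @export
feature_columns <- function() {
  c("DNase_OS", "FAIR_OS", "H3K4me", "H3K9Ac", "H3K27Ac", "H3K4me2")
}

#' Sum signal-track datapoints over probe intervals
#'
#' Sums the values of track datapoints falling within each interval.  A
#' datapoint is anchored at the start of its track record, so a partition
#' of an interval yields the same total as the whole interval
#' (linearity), and records abutting an interval boundary are counted on
#' exactly one side.
#'
#' @param track a `GRanges` with a numeric `score` column (one range per
#'   datapoint, e.g. a bedGraph read with [read_bedgraph()]), or a
#'   [simulate_signal_track()] result.
#' @param intervals intervals as in [as_probe_granges()].
#' @param coords coordinate convention of `intervals` when given as a
#'   data frame.
#' @return Numeric vector of integrated intensities, one per interval.
#'   Intervals on chromosomes absent from the track get 0 with a warning.
#' @export
sum_signal <- function(track, intervals, coords = c("onebased", "bed")) {
  if (inherits(track, "track_sim")) track <- track$track
  if (!inherits(track, "GRanges") || !"score" %in%
        names(S4Vectors::mcols(track))) {
    stop("'track' must be a GRanges with a 'score' column")
  }
  iv <- as_probe_granges(intervals, coords = match.arg(coords))
  out <- numeric(length(iv))
  if (!length(track) || !length(iv)) return(out)
  missing_chr <- setdiff(as.character(unique(seqnames(iv))),
                         as.character(unique(seqnames(track))))
  if (length(missing_chr)) {
    warning("chromosome(s) absent from track: ",
            paste(missing_chr, collapse = ", "))
  }
  anchors <- GenomicRanges::resize(track, width = 1L, fix = "start")
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(anchors, iv, ignore.strand = TRUE))
  if (length(ov)) {
    sums <- tapply(track$score[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov), sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Read / write bedGraph tracks
#'
#' Thin wrappers around `rtracklayer::import`/`export` in bedGraph
#' format (0-based half-open on disk, `GRanges` in memory).
#'
#' @param path file path.
#' @param track a `GRanges` with a `score` column.
#' @return `read_bedgraph()` returns a `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Compare open-chromatin signal between DA and equivalent regions
#'
#' Pools all region-by-feature integrated intensities within each
#' accessibility class and reports, per class, the pooled mean and the
#' mean of the six per-feature standard deviations, along with per-feature
#' group means and 95% confidence intervals.  Group difference is tested
#' by ANOVA with accessibility class as the factor: `design = "one_way"`
#' fits `value ~ class` on the pooled values; `design = "two_way"` fits
#' `value ~ class + feature` (feature as a blocking factor), reporting the
#' F statistic of the class term.  Because the feature intensities span
#' orders of magnitude, the ANOVA response can be log10-transformed
#' (`transform = "log10"`, using `log10(x + 1)`), which matches how these
#' distributions are usually displayed and analyzed; `"identity"` uses the
#' raw scale.
#'
#' @param regions a [load_region_features()] table (or any data frame with
#'   `accessibility_class` and the six feature columns).
#' @param design `"one_way"` or `"two_way"`.
#' @param transform `"log10"` or `"identity"` response scale for the
#'   ANOVA (group summaries are always on the raw scale).
#' @return List of class `"group_comparison"`: `group_stats` (data frame:
#'   `class, n_regions, n_values, mean, sd`), `per_feature` (data frame of
#'   per-class, per-feature means with 95% CI), `anova`
#'   (`list(F, df1, df2, p, design, transform)`).
#' @examples
#' gc <- compare_groups(load_region_features())
#' gc$group_stats
#' @export
compare_groups <- function(regions, design = c("one_way", "two_way"),
                           transform = c("log10", "identity")) {
  design <- match.arg(design)
  transform <- match.arg(transform)
  fc <- feature_columns()
  if (!all(c("accessibility_class", fc) %in% names(regions))) {
    stop("'regions' needs accessibility_class and the six feature columns")
  }
  cls <- unique(regions$accessibility_class)
  if (length(cls) < 2L) stop("both accessibility classes must be present")

  long <- data.frame(
    class = rep(regions$accessibility_class, times = length(fc)),
    feature = rep(fc, each = nrow(regions)),
    value = unlist(lapply(fc, function(f) regions[[f]]), use.names = FALSE)
  )

  group_stats <- do.call(rbind, lapply(split(long, long$class), function(d) {
    per_feat_sd <- vapply(split(d$value, d$feature), stats::sd, numeric(1))
    data.frame(class = d$class[1],
               n_regions = nrow(d) / length(fc),
               n_values = nrow(d),
               mean = mean(d$value),
               sd = mean(per_feat_sd))
  }))
  rownames(group_stats) <- NULL

  per_feature <- do.call(rbind, lapply(
    split(long, list(long$class, long$feature)), function(d) {
      n <- nrow(d); m <- mean(d$value); s <- stats::sd(d$value)
      half <- stats::qt(0.975, n - 1) * s / sqrt(n)
      data.frame(class = d$class[1], feature = d$feature[1], n = n,
                 mean = m, sd = s, ci_low = m - half, ci_high = m + half)
    }))
  rownames(per_feature) <- NULL

  y <- if (transform == "log10") log10(long$value + 1) else long$value
  dat <- data.frame(y = y, class = factor(long$class),
                    feature = factor(long$feature))
  fit <- if (design == "one_way") stats::aov(y ~ class, data = dat)
         else stats::aov(y ~ class + feature, data = dat)
  tab <- stats::anova(fit)
  i <- which(rownames(tab) == "class")
  anova_res <- list(F = tab$`F value`[i], df1 = tab$Df[i],
                    df2 = tab$Df[nrow(tab)], p = tab$`Pr(>F)`[i],
                    design = design, transform = transform)
  structure(list(group_stats = group_stats, per_feature = per_feature,
                 anova = anova_res),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Open-chromatin signal by accessibility class:\n")
  print(x$group_stats, row.names = FALSE)
  cat(sprintf("ANOVA (%s, %s): F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$design, x$anova$transform, x$anova$df1, x$anova$df2,
              x$anova$F, x$anova$p))
  invisible(x)
}

#' Permutation test of the class effect on the feature matrix
#'
#' Recomputes the ANOVA F statistic of [compare_groups()] under random
#' permutations of the accessibility labels and returns the fraction of
#' permutations reaching the observed F.
#'
#' @param regions as in [compare_groups()].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @inheritParams compare_groups
#' @return List: `F_observed`, `p_perm` (permutation p-value), `n_perm`.
#' @export
permutation_test_groups <- function(regions, n_perm = 1000L, seed = 1L,
                                    design = c("one_way", "two_way"),
                                    transform = c("log10", "identity")) {
  design <- match.arg(design); transform <- match.arg(transform)
  obs <- compare_groups(regions, design, transform)$anova$F
  set.seed(as.integer(seed))
  exceed <- 0L
  perm <- regions
  for (i in seq_len(n_perm)) {
    perm$accessibility_class <- sample(regions$accessibility_class)
    f <- compare_groups(perm, design, transform)$anova$F
    if (f >= obs) exceed <- exceed + 1L
  }
  list(F_observed = obs, p_perm = (exceed + 1) / (n_perm + 1),
       n_perm = n_perm)
}

#' Overlap probe intervals with copy-number-variant intervals
#'
#' Reports, per probe, every CNV interval it overlaps and the overlap
#' length in bp.  Both inputs follow [as_probe_granges()] conventions;
#' pass `coords = "bed"` for 0-based half-open input, in which case an
#' interval abutting a CNV end does not overlap it.
#'
#' @param probes,cnvs intervals (`GRanges` or data frame).
#' @param coords coordinate convention for data-frame input.
#' @return Data frame with one row per overlapping pair: `probe_index`,
#'   `probe_label` (if available), `cnv_index`, `overlap_bp`.  Zero rows
#'   when nothing overlaps.
#' @export
overlap_cnv <- function(probes, cnvs, coords = c("onebased", "bed")) {
  coords <- match.arg(coords)
  p <- as_probe_granges(probes, coords); v <- as_probe_granges(cnvs, coords)
  if (!length(p) || !length(v)) {
    return(data.frame(probe_index = integer(), probe_label = character(),
                      cnv_index = integer(), overlap_bp = integer()))
  }
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(p, v, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- suppressWarnings(GenomicRanges::pintersect(p[qi], v[si]))
  lab <- if ("label" %in% names(S4Vectors::mcols(p)))
    S4Vectors::mcols(p)$label[qi] else rep(NA_character_, length(qi))
  data.frame(probe_index = qi, probe_label = lab, cnv_index = si,
             overlap_bp = GenomicRanges::width(inter))
}

#' GC content of a probe sequence
#'
#' Fraction `(G + C) / (A + C + G + T)`; `N` and other ambiguity codes are
#' excluded from the denominator.  Case-insensitive; invariant under
#' reverse complement.
#'
#' @param sequence a character string, `DNAString`, or `DNAStringSet`.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content("ACGT")   # 0.5
#' @export
gc_content <- function(sequence) {
  if (is.character(sequence)) {
    if (!length(sequence) || any(!nzchar(sequence))) {
      stop("empty sequence")
    }
    sequence <- Biostrings::DNAStringSet(toupper(sequence))
  } else if (inherits(sequence, "DNAString")) {
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  freq <- Biostrings::letterFrequency(sequence, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  if (any(denom == 0)) stop("sequence contains no unambiguous A/C/G/T bases")
  unname((freq[, "G"] + freq[, "C"]) / denom)
}
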