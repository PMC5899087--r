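#' Allelic proportion and d-score of peaks
#'
#' For peaks with SNP read counts from both alleles, computes the allelic
#' proportion spretus / (spretus + BL6) and the d-score (proportion - 0.5,
#' so positive d-scores mean an Xa/spretus bias). Peaks covered by fewer
#' than `min_cov` total SNP reads are flagged `insufficient` and get
#' missing proportions.
#'
#' @param peaks Data frame with `snp_spretus` and `snp_bl6` columns.
#' @param min_cov Minimum total SNP reads for allelic analysis (default 5).
#' @return `peaks` with `allelic_proportion`, `d_score`, and `class`
#'   (`insufficient` where coverage is short, `NA` otherwise -- see
#'   [classify_peaks()]).
#' @export
peak_allelic_proportion <- function(peaks, min_cov = 5) {
  if (any(peaks$snp_spretus < 0) || any(peaks$snp_bl6 < 0))
    stop("negative SNP read counts")
  total <- peaks$snp_spretus + peaks$snp_bl6
  ok <- total >= min_cov
  peaks$allelic_proportion <- ifelse(ok, peaks$snp_spretus / total, NA_real_)
  peaks$d_score <- peaks$allelic_proportion - 0.5
  peaks$class <- ifelse(ok, NA_character_, "insufficient")
  peaks
}

#' Classify peaks by allelic proportion
#'
#' Proportions above 0.7 are spretus/Xa-specific, below 0.3 BL6/Xi-specific,
#' and within the closed interval \[0.3, 0.7\] common to both alleles.
#' Insufficient-coverage peaks pass through unchanged.
#'
#' @param peaks Output of [peak_allelic_proportion()].
#' @param lo,hi Class thresholds (closed common interval).
#' @return `peaks` with `class` filled in.
#' @export
classify_peaks <- function(peaks, lo = 0.3, hi = 0.7) {
  p <- peaks$allelic_proportion
  cls <- ifelse(p > hi, "spretus_specific",
                ifelse(p < lo, "bl6_specific", "common"))
  peaks$class <- ifelse(is.na(p), peaks$class, cls)
  peaks
}

#' Between-sample peak scale factor
#'
#' Depth differences between samples are corrected with the ratio of
#' autosomal SNP-covered (coverage >= `min_cov`) peak totals: reference
#' total over this sample's total.
#'
#' @param ref_peaks,sample_peaks Data frames of autosomal peaks with SNP
#'   counts.
#' @param min_cov Coverage threshold defining SNP-covered peaks.
#' @return Scalar factor to apply to the sample's binned densities.
#' @export
peak_scale_factor <- function(ref_peaks, sample_peaks, min_cov = 5) {
  covered <- function(p) sum(p$snp_spretus + p$snp_bl6 >= min_cov)
  ns <- covered(sample_peaks)
  if (ns == 0) stop("no autosomal SNP-covered peaks in sample")
  covered(ref_peaks) / ns
}

#' Binned peak density track
#'
#' Counts peaks of the selected classes per genomic bin (a peak belongs to
#' the bin containing its midpoint) and multiplies by a between-sample
#' scale factor. `classes = c("bl6_specific", "common")` gives the
#' Xi-associated density.
#'
#' @param peaks Classified peaks.
#' @param grid A [bin_grid()] (500 kb windows in the reference analyses).
#' @param classes Peak classes to count.
#' @param scale_factor Between-sample scaling (see [peak_scale_factor()]).
#' @return A [score_track()] of kind `"peak_density"`.
#' @export
binned_peak_density <- function(peaks, grid,
                                classes = c("bl6_specific", "common"),
                                scale_factor = 1) {
  sel <- peaks[!is.na(peaks$class) & peaks$class %in% classes &
                 peaks$chrom == grid$chrom, , drop = FALSE]
  counts <- numeric(grid$n_bins)
  if (nrow(sel)) {
    mid <- floor((sel$start + sel$end) / 2)
    bins <- coord_to_bin(grid, pmax(1, mid))
    t0 <- table(factor(bins, levels = 0:(grid$n_bins - 1)))
    counts <- as.numeric(t0)
  }
  score_track(counts * scale_factor, grid, kind = "peak_density",
              params = list(classes = classes, scale_factor = scale_factor))
}

#' Peak density per gene (promoter + body)
#'
#' Each gene interval is extended 10 kb upstream of the TSS (strand-aware)
#' through the TTS; density is the number of qualifying peak midpoints in
#' the extended interval per kb, times the between-sample scale factor.
#' Extensions past the chromosome start are clipped to position 1.
#'
#' @param peaks Classified peaks.
#' @param genes Data frame with `chrom`, `start`, `end`, `strand`, `id`.
#' @param classes Peak classes to count.
#' @param upstream Promoter extension in bp (default 10 kb).
#' @param scale_factor Between-sample scaling.
#' @return Data frame `id`, `density` (peaks per kb).
#' @export
gene_peak_density <- function(peaks, genes,
                              classes = c("bl6_specific", "common"),
                              upstream = 1e4, scale_factor = 1) {
  sel <- peaks[!is.na(peaks$class) & peaks$class %in% classes, , drop = FALSE]
  mid <- floor((sel$start + sel$end) / 2)
  ext_start <- ifelse(genes$strand == "+",
                      pmax(1, genes$start - upstream), genes$start)
  ext_end <- ifelse(genes$strand == "+",
                    genes$end, genes$end + upstream)
  dens <- vapply(seq_len(nrow(genes)), function(g) {
    hit <- sel$chrom == genes$chrom[g] & mid >= ext_start[g] &
      mid <= ext_end[g]
    sum(hit) / ((ext_end[g] - ext_start[g]) / 1e3) * scale_factor
  }, 0)
  data.frame(id = genes$id, density = dens, stringsAsFactors = FALSE)
}

#' One-sided paired Wilcoxon tests on per-gene density differences
#'
#' Tests, within each gene group (e.g. differentially expressed vs not),
#' whether paired per-gene density differences (edited minus wild type) are
#' shifted above zero, by the one-sample signed-rank test with alternative
#' "greater". Exact distribution for n <= 25 (zeros dropped, per the exact
#' test's convention; ties handled exactly through midranks), normal
#' approximation with continuity correction above. All-zero differences
#' give p = 1 (no evidence).
#'
#' @param diffs Numeric vector of per-gene paired differences.
#' @param labels Group label per gene.
#' @return Named vector of one-sided p-values per group.
#' @export
compare_density_groups <- function(diffs, labels) {
  stopifnot(length(diffs) == length(labels))
  vapply(split(diffs, labels), function(d) {
    if (length(d) < 5) stop("fewer than 5 genes in a group")
    signed_rank_greater(d)
  }, 0)
}

# one-sided (greater) signed-rank p-value. Exact for n <= 25 by dynamic
# programming over the rank-sum distribution (midranks doubled to stay
# integer, so ties are handled exactly, where wilcox.test falls back to the
# approximation); normal approximation with continuity correction above.
signed_rank_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    w <- as.integer(round(2 * r))
    dp <- 1
    for (wi in w) dp <- c(dp, numeric(wi)) + c(numeric(wi), dp)
    dp <- dp / 2^n
    v2 <- as.integer(round(2 * v))
    sum(dp[(v2 + 1):length(dp)])
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(sum(r^2) / 4)
    stats::pnorm((v - mu - 0.5) / sig, lower.tail = FALSE)
  }
}

#' Relative distance colocalization of two peak sets
#'
#' For every query (a) peak midpoint, the distance to the nearest reference
#' (b) midpoint is normalized by the spacing of the two reference midpoints
#' flanking it, giving a relative distance r in \[0, 0.5\]. Spatially
#' unassociated sets give a flat r distribution with mean 0.25; association
#' piles mass near 0. Query peaks outside the span of the reference set are
#' dropped.
#'
#' @param a,b Data frames with `chrom`, `start`, `end`; `b` needs >= 2
#'   peaks per chromosome.
#' @param breaks Histogram class width.
#' @return List with `r` (per-query values), `hist` (class proportions),
#'   and `mean`.
#' @export
relative_distance_colocalization <- function(a, b, breaks = 0.05) {
  if (nrow(b) < 2) stop("reference set must contain at least 2 peaks")
  r_all <- unlist(lapply(unique(a$chrom), function(ch) {
    am <- sort(floor((a$start + a$end) / 2)[a$chrom == ch])
    bm <- sort(floor((b$start + b$end) / 2)[b$chrom == ch])
    if (length(bm) < 2) stop("fewer than 2 reference peaks on ", ch)
    am <- am[am >= bm[1] & am <= bm[length(bm)]]
    if (!length(am)) return(numeric(0))
    right <- findInterval(am, bm, left.open = FALSE)
    right <- pmin(pmax(right, 1), length(bm) - 1)
    lo <- bm[right]; hi <- bm[right + 1]
    s <- hi - lo
    d <- pmin(am - lo, hi - am)
    ifelse(s > 0, d / s, 0)
  }))
  cls <- cut(r_all, breaks = seq(0, 0.5, by = breaks), include.lowest = TRUE)
  list(r = r_all, hist = as.numeric(table(cls)) / length(r_all),
       mean = mean(r_all))
}
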