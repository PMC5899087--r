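#' Transcripts per million from counts and lengths
#'
#' Standard TPM: the length-normalized count rate of each gene over the sum
#' of all rates, times 1e6. All-zero counts give all-zero TPMs.
#'
#' @param counts Read counts per gene.
#' @param lengths Transcript lengths in bp (> 0).
#' @return TPM vector summing to 1e6 (or all zero).
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) return(rep(0, length(counts)))
  1e6 * rate / tot
}

#' Distribute gene counts to alleles by SNP read proportion
#'
#' Genes with at least `min_cov` SNP reads get allelic counts
#' `total * proportion` (Xa/spretus) and `total * (1 - proportion)`
#' (Xi/BL6); allelic TPMs are computed against the diploid TPM denominator
#' so `tpm_xa + tpm_xi = tpm_diploid`. Genes below the coverage threshold
#' get missing allelic fields and are excluded from allelic analyses.
#'
#' @param genes Data frame with `total_count`, `length`, `snp_spretus`,
#'   `snp_bl6`.
#' @param min_cov Minimum total SNP reads (default 5).
#' @return `genes` with `allelic_proportion`, `count_xa`, `count_xi`,
#'   `tpm_diploid`, `tpm_xa`, `tpm_xi`.
#' @export
split_allelic <- function(genes, min_cov = 5) {
  snp_total <- genes$snp_spretus + genes$snp_bl6
  ok <- snp_total >= min_cov
  prop <- ifelse(ok, genes$snp_spretus / snp_total, NA_real_)
  genes$allelic_proportion <- prop
  genes$count_xa <- genes$total_count * prop
  genes$count_xi <- genes$total_count * (1 - prop)
  genes$tpm_diploid <- compute_tpm(genes$total_count, genes$length)
  # same denominator as the diploid TPM, so the allelic TPMs add up to it
  rate_tot <- sum(genes$total_count / genes$length)
  denom <- if (rate_tot > 0) rate_tot else 1
  genes$tpm_xa <- 1e6 * (genes$count_xa / genes$length) / denom
  genes$tpm_xi <- 1e6 * (genes$count_xi / genes$length) / denom
  genes
}

#' Exact (Clopper-Pearson) one-sided lower confidence bound
#'
#' Lower bound L on a binomial proportion given x successes of n, at level
#' `1 - alpha`: the smallest p for which observing >= x successes has
#' probability at least alpha. L(0, n) = 0 exactly.
#'
#' @param x Successes (Xi-assigned SNP reads).
#' @param n Trials (total SNP reads).
#' @param alpha One-sided error level (default 0.01 for a 99% bound).
#' @return Lower confidence bound(s) in \[0, 1\].
#' @export
clopper_pearson_lower <- function(x, n, alpha = 0.01) {
  if (any(x > n)) stop("successes cannot exceed trials")
  ifelse(x == 0, 0, stats::qbeta(alpha, x, n - x + 1))
}

#' Call escape from X inactivation, per sample
#'
#' A gene is called escaping when all four criteria hold: (1) the 99%
#' exact binomial lower confidence limit on its Xi read proportion exceeds
#' `baseline` (0.01), indicating some contribution from the Xi; (2) diploid
#' expression TPM >= 1; (3) Xi-TPM >= 0.1; and (4) SNP coverage >= 5. The
#' `baseline` is exposed so that residual skew in the expected Xi read
#' proportion can be tested against instead of the default.
#'
#' @param genes Output of [split_allelic()] with `snp_bl6` as Xi reads.
#' @param alpha Binomial error level (default 0.01).
#' @param baseline Escape-probability threshold the lower bound must exceed.
#' @param min_tpm,min_xi_tpm,min_cov Expression and coverage criteria.
#' @return Logical vector of per-gene escape calls (`FALSE` when coverage
#'   is insufficient).
#' @export
call_escape <- function(genes, alpha = 0.01, baseline = 0.01,
                        min_tpm = 1, min_xi_tpm = 0.1, min_cov = 5) {
  n <- genes$snp_spretus + genes$snp_bl6
  x <- genes$snp_bl6   # reads from the inactive (BL6) X
  lower <- clopper_pearson_lower(x, pmax(n, x), alpha)
  ok_cov <- n >= min_cov
  call <- ok_cov & lower > baseline &
    genes$tpm_diploid >= min_tpm &
    !is.na(genes$tpm_xi) & genes$tpm_xi >= min_xi_tpm
  call & !is.na(call)
}

#' Consensus escape call across samples
#'
#' A gene escapes by consensus when it is called escaping in at least 2/3
#' of the samples (exactly >= 2 of 3 for three samples).
#'
#' @param calls Logical matrix, genes x samples (>= 2 samples).
#' @return Logical vector of consensus calls.
#' @export
consensus_escape <- function(calls) {
  calls <- as.matrix(calls)
  if (ncol(calls) < 2) stop("need at least 2 samples")
  rowSums(calls) >= ceiling(2 / 3 * ncol(calls))
}
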