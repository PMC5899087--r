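#' Classify a read end by its SNP evidence
#'
#' A read end overlapping only BL6-specific SNPs is `BL6`, only
#' spretus-specific SNPs `SPRETUS`, none `AMBIGUOUS`, and SNPs from both
#' alleles `CONFLICT`. Conflicting ends are reported distinctly but treated
#' as ambiguous for pair retention.
#'
#' @param snp_hits Character vector of SNP allele hits for one end
#'   (`"BL6"` / `"SPRETUS"`), possibly empty.
#' @return One of `"BL6"`, `"SPRETUS"`, `"AMBIGUOUS"`, `"CONFLICT"`.
#' @export
classify_end <- function(snp_hits) {
  has_b <- any(snp_hits == "BL6")
  has_s <- any(snp_hits == "SPRETUS")
  if (has_b && has_s) "CONFLICT"
  else if (has_b) "BL6"
  else if (has_s) "SPRETUS"
  else "AMBIGUOUS"
}

#' Assign read pairs to alleles from per-end classifications
#'
#' A pair is retained for an allele when at least one end is specific to it
#' and no end is specific to the other: (BL6, AMBIGUOUS) and (BL6, BL6) are
#' BL6 pairs, symmetric for spretus. Pairs with both ends ambiguous are
#' discarded, as are pairs whose two ends disagree (one BL6, one spretus).
#' `CONFLICT` ends count as ambiguous here.
#'
#' @param allele1,allele2 Per-end classifications
#'   (`BL6`/`SPRETUS`/`AMBIGUOUS`/`CONFLICT`).
#' @return Character vector: `"BL6"`, `"SPRETUS"`, or `"discard"`.
#' @export
assign_pair <- function(allele1, allele2) {
  a1 <- ifelse(allele1 == "CONFLICT", "AMBIGUOUS", allele1)
  a2 <- ifelse(allele2 == "CONFLICT", "AMBIGUOUS", allele2)
  b <- (a1 == "BL6") | (a2 == "BL6")
  s <- (a1 == "SPRETUS") | (a2 == "SPRETUS")
  ifelse(b & !s, "BL6", ifelse(s & !b, "SPRETUS", "discard"))
}

#' Segregate a stream of read pairs into allelic sets
#'
#' Applies [assign_pair()] to a `.pairs` data frame and returns the retained
#' pairs with an `allele` column, plus QC counts of discarded categories
#' (both-ambiguous, conflicting BL6/spretus pairs, ends flagged CONFLICT).
#'
#' @param pairs Data frame with `allele1`, `allele2` columns.
#' @return The retained pairs with an `allele` column; QC counts in
#'   attribute `qc`.
#' @export
segregate_pairs <- function(pairs) {
  asg <- assign_pair(pairs$allele1, pairs$allele2)
  qc <- c(total = nrow(pairs),
          retained = sum(asg != "discard"),
          bl6 = sum(asg == "BL6"),
          spretus = sum(asg == "SPRETUS"),
          both_ambiguous = sum(pairs$allele1 %in% c("AMBIGUOUS", "CONFLICT") &
                                 pairs$allele2 %in% c("AMBIGUOUS", "CONFLICT")),
          cross_allele = sum(asg == "discard" &
                               !(pairs$allele1 %in% c("AMBIGUOUS", "CONFLICT") &
                                   pairs$allele2 %in% c("AMBIGUOUS", "CONFLICT"))),
          conflict_ends = sum(pairs$allele1 == "CONFLICT") +
            sum(pairs$allele2 == "CONFLICT"))
  out <- pairs[asg != "discard", , drop = FALSE]
  out$allele <- asg[asg != "discard"]
  attr(out, "qc") <- qc
  out
}

# order ends lexicographically by (chrom, pos) so that duplicates are
# recognized regardless of end order; swaps strand and allele columns along
normalize_pair_ends <- function(pairs) {
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom2 == pairs$chrom1 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    sw <- function(a, b) {
      tmp <- pairs[[a]][swap]
      pairs[[a]][swap] <<- pairs[[b]][swap]
      pairs[[b]][swap] <<- tmp
    }
    sw("chrom1", "chrom2"); sw("pos1", "pos2"); sw("strand1", "strand2")
    if (!is.null(pairs$allele1)) sw("allele1", "allele2")
  }
  pairs
}

#' Remove duplicate read pairs
#'
#' PCR duplicates are pairs whose two ends map to identical locations in the
#' same assembly. Ends are first normalized to lexicographic (chrom, pos)
#' order, then one representative per identical-coordinate group is kept.
#' The operation is idempotent.
#'
#' @param pairs `.pairs` data frame.
#' @return De-duplicated, end-normalized data frame.
#' @export
deduplicate_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  pairs <- normalize_pair_ends(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Allelic read-count tables by chromosome
#'
#' Reproduces the standard QC layout for segregated Hi-C pairs: per
#' chromosome and allele, counts of (1) all read-pair ends (cis + trans),
#' (2) trans-only ends, (3) cis pairs, and (4) cis pairs separated by at
#' least `cis_min_dist` bp; end-based counting for (1)-(2), pair-based for
#' (3)-(4). Allelic ratio is BL6/spretus, with the ratio relative to the
#' genome-wide ratio alongside; chromosomes with zero spretus counts get
#' `NA` ratios rather than an error.
#'
#' @param pairs Segregated pairs (with `allele` column).
#' @param cis_min_dist Distance threshold for the long-range cis category.
#' @return A list of four data frames (`cis_trans_ends`, `trans_ends`,
#'   `cis_pairs`, `cis_long_pairs`), each with per-chromosome BL6/spretus
#'   counts, `ratio`, and `rel_ratio`.
#' @export
tally_counts <- function(pairs, cis_min_dist = 2e4) {
  stopifnot(!is.null(pairs$allele))
  is_cis <- pairs$chrom1 == pairs$chrom2
  tab <- function(chroms, alleles) {
    t0 <- table(factor(chroms), factor(alleles, levels = c("BL6", "SPRETUS")))
    df <- data.frame(chrom = as.character(rownames(t0)),
                     bl6 = as.vector(t0[, "BL6"]),
                     spretus = as.vector(t0[, "SPRETUS"]),
                     stringsAsFactors = FALSE)
    gr <- sum(df$bl6) / sum(df$spretus)
    df$ratio <- ifelse(df$spretus > 0, df$bl6 / df$spretus, NA_real_)
    df$rel_ratio <- if (is.finite(gr)) df$ratio / gr else
      rep(NA_real_, nrow(df))
    df
  }
  ends <- function(sel) {
    tab(c(pairs$chrom1[sel], pairs$chrom2[sel]),
        c(pairs$allele[sel], pairs$allele[sel]))
  }
  pairs_tab <- function(sel) tab(pairs$chrom1[sel], pairs$allele[sel])
  long_cis <- is_cis & abs(pairs$pos1 - pairs$pos2) >= cis_min_dist
  list(cis_trans_ends = ends(rep(TRUE, nrow(pairs))),
       trans_ends = ends(!is_cis),
       cis_pairs = pairs_tab(is_cis),
       cis_long_pairs = pairs_tab(long_cis))
}
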