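#' Ground truth for a simulated chromosome
#'
#' Collects the structural features the simulator plants and downstream
#' analyses are expected to recover: the hinge bin separating the two Xi
#' superdomains, the direction of the contact "flame" emanating from the
#' hinge locus, A/B compartment labels and TAD boundaries (used for the
#' active-homolog control), the contact decay exponent, and (for peak and
#' expression simulations) the allelic classes and escape status.
#'
#' @param n_bins Number of bins on the simulated chromosome.
#' @param hinge_bin 0-based bin index of the hinge locus; must lie strictly
#'   inside the chromosome. `NA` for a chromosome with no hinge.
#' @param flame_direction `"telomeric"` (towards higher coordinates),
#'   `"centromeric"`, or `"none"`.
#' @param superdomain_boundary 0-based bin index of the superdomain seam;
#'   defaults to `hinge_bin`. Cells with one bin below and one at/above the
#'   seam are cross-superdomain.
#' @param compartment_labels Per-bin `"A"`/`"B"` labels, or `NULL` for no
#'   compartment structure.
#' @param tad_boundaries 0-based bin indices of TAD boundaries, or `NULL`.
#' @param decay_exponent Power-law contact decay exponent (alpha > 0).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(n_bins, hinge_bin = NA,
                      flame_direction = c("telomeric", "centromeric", "none"),
                      superdomain_boundary = hinge_bin,
                      compartment_labels = NULL, tad_boundaries = NULL,
                      decay_exponent = 1) {
  flame_direction <- match.arg(flame_direction)
  n_bins <- as.integer(n_bins)
  if (decay_exponent <= 0)
    stop("invalid-config: decay exponent must be > 0")
  if (!is.na(hinge_bin) && (hinge_bin <= 0 || hinge_bin >= n_bins - 1))
    stop("invalid-config: hinge_bin must lie strictly inside the chromosome")
  if (!is.null(compartment_labels)) {
    if (length(compartment_labels) != n_bins)
      stop("compartment_labels length must equal bin count")
    if (!all(compartment_labels %in% c("A", "B")))
      stop("compartment_labels must be 'A' or 'B'")
  }
  structure(list(n_bins = n_bins,
                 hinge_bin = as.integer(hinge_bin),
                 flame_direction = flame_direction,
                 superdomain_boundary = as.integer(superdomain_boundary),
                 compartment_labels = compartment_labels,
                 tad_boundaries = as.integer(tad_boundaries),
                 decay_exponent = decay_exponent),
            class = "sim_truth")
}

#' Simulation configuration
#'
#' Desk-scale defaults: a 100 Mb chromosome at 500 kb bins (200 bins) and
#' 2e5 read pairs. `superdomain_s` is the multiplicative suppression applied
#' to cross-superdomain contacts (< 1 for a bipartite map); `flame_boost`
#' multiplies the hinge locus's contacts on the flame side, overriding the
#' superdomain suppression there — the flame is a line of unidirectional
#' long-range contacts. One SNP per ~93 bp and a per-end ambiguity rate of
#' 0.6 emulate a hybrid cross where most ends carry no informative SNP.
#'
#' @param chrom_length Chromosome length, bp.
#' @param bin_size Bin width, bp.
#' @param n_pairs Expected total read-pair count.
#' @param snp_density SNPs per bp (annotation only; allele informativeness is
#'   governed by `ambiguity_rate`).
#' @param ambiguity_rate Probability that a read end carries no usable SNP.
#' @param dup_rate Fraction of emitted pairs duplicated (PCR duplicates).
#' @param seed Integer seed; fixes every emitted value.
#' @param edit `"none"`, `"deletion"` (hinge interval removed, superdomain
#'   suppression lifted) or `"inversion"` (flame direction mirrored).
#' @param edit_interval `c(start, end)` bp interval of the edit (1-based,
#'   inclusive); required for `"deletion"`.
#' @param superdomain_s Cross-superdomain suppression factor, in (0, 1].
#' @param flame_boost Multiplier (> 1) for hinge-row contacts on the flame
#'   side.
#' @param flame_width Flame width in bins (rows within `flame_width - 1` of
#'   the hinge bin carry the flame).
#' @param compartment_amp Checkerboard amplitude c: same-compartment cells
#'   scaled by 1 + c, opposite by 1 - c.
#' @param tad_boost Multiplier for within-TAD cells.
#' @param sparse_bin_frac Fraction of bins with strongly reduced visibility,
#'   emulating low-mappability regions (the intended targets of the
#'   low-coverage filter). Placed away from the hinge.
#' @param sparse_bin_factor Multiplicative visibility of sparse bins.
#' @param true_allele Allele of origin tagged onto simulated read pairs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_length = 1e8, bin_size = 5e5, n_pairs = 2e5,
                       snp_density = 1 / 93, ambiguity_rate = 0.6,
                       dup_rate = 0, seed = 1L,
                       edit = c("none", "deletion", "inversion"),
                       edit_interval = NULL,
                       superdomain_s = 0.1, flame_boost = 6, flame_width = 1,
                       compartment_amp = 0.3, tad_boost = 2,
                       sparse_bin_frac = 0.02, sparse_bin_factor = 0.05,
                       true_allele = "BL6") {
  edit <- match.arg(edit)
  if (superdomain_s >= 1 && superdomain_s != 1)
    stop("invalid-config: superdomain_s must be <= 1")
  if (superdomain_s <= 0)
    stop("invalid-config: superdomain_s must be > 0")
  if (ambiguity_rate < 0 || ambiguity_rate > 1)
    stop("invalid-config: ambiguity_rate must be in [0, 1]")
  if (edit == "deletion" && is.null(edit_interval))
    stop("invalid-config: deletion edit requires edit_interval")
  if (!is.null(edit_interval) &&
      (edit_interval[1] < 1 || edit_interval[2] > chrom_length ||
       edit_interval[1] > edit_interval[2]))
    stop("invalid-config: edit interval outside chromosome")
  structure(list(chrom_length = chrom_length, bin_size = bin_size,
                 n_pairs = n_pairs, snp_density = snp_density,
                 ambiguity_rate = ambiguity_rate, dup_rate = dup_rate,
                 seed = as.integer(seed), edit = edit,
                 edit_interval = edit_interval,
                 superdomain_s = superdomain_s, flame_boost = flame_boost,
                 flame_width = as.integer(flame_width),
                 compartment_amp = compartment_amp, tad_boost = tad_boost,
                 sparse_bin_frac = sparse_bin_frac,
                 sparse_bin_factor = sparse_bin_factor,
                 true_allele = true_allele),
            class = "sim_config")
}

#' Default bipartite-Xi truth for a config
#'
#' Hinge at the chromosome midpoint, telomeric flame, power-law decay with
#' exponent 1; no compartments or TADs (the Xi is largely devoid of both).
#'
#' @param config A [sim_config()].
#' @param ... Overrides passed to [sim_truth()].
#' @export
sim_truth_bipartite <- function(config, ...) {
  n <- as.integer(ceiling(config$chrom_length / config$bin_size))
  args <- list(n_bins = n, hinge_bin = n %/% 2, flame_direction = "telomeric")
  args[names(list(...))] <- list(...)
  do.call(sim_truth, args)
}

#' Default active-homolog (Xa-like) truth: compartments + TADs, no hinge
#'
#' Checkerboard A/B compartments in alternating blocks and evenly spaced TAD
#' boundaries; no superdomain structure.
#'
#' @param config A [sim_config()].
#' @param comp_block Compartment block width in bins.
#' @param n_tads Number of TADs (equally sized).
#' @export
sim_truth_control <- function(config, comp_block = 20, n_tads = 5) {
  n <- as.integer(ceiling(config$chrom_length / config$bin_size))
  labels <- rep(rep(c("A", "B"), length.out = ceiling(n / comp_block)),
                each = comp_block)[seq_len(n)]
  tb <- as.integer(round(seq_len(n_tads - 1) * n / n_tads))
  sim_truth(n, hinge_bin = NA, flame_direction = "none",
            compartment_labels = labels, tad_boundaries = tb)
}

# save/restore RNG state so sim_lambda stays side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# expected-count surface lambda(i, j), scaled so the upper triangle
# (diagonal included) sums to n_pairs; also applies edits to truth and
# returns the effective truth. Used by simulate_contact_map and directly
# by tests comparing empirical means against the generator model.
sim_lambda <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  alpha <- truth$decay_exponent
  s <- config$superdomain_s
  if (alpha <= 0) stop("invalid-config: decay exponent must be > 0")

  n <- truth$n_bins
  grid <- bin_grid(config$chrom_length, config$bin_size)
  if (grid$n_bins != n) stop("truth bin count does not match config grid")

  if (config$edit == "inversion") {
    truth$flame_direction <- switch(truth$flame_direction,
                                    telomeric = "centromeric",
                                    centromeric = "telomeric",
                                    none = "none")
  }
  del_bins <- integer(0)
  if (config$edit == "deletion") {
    del_bins <- unique(coord_to_bin(grid, config$edit_interval[1]):
                         coord_to_bin(grid, config$edit_interval[2]))
    # bipartite structure is lost: suppression lifted, flame gone
    s <- 1
    truth$flame_direction <- "none"
    keep <- setdiff(seq_len(n) - 1L, del_bins)
    shift <- function(b) {
      b <- b[!b %in% del_bins]
      as.integer(b - vapply(b, function(x) sum(del_bins < x), 0L))
    }
    truth$tad_boundaries <- shift(truth$tad_boundaries)
    if (!is.null(truth$compartment_labels))
      truth$compartment_labels <- truth$compartment_labels[keep + 1L]
    truth$hinge_bin <- NA_integer_
    truth$superdomain_boundary <- NA_integer_
    truth$n_bins <- n <- length(keep)
    grid <- bin_grid(grid$chrom_length - length(del_bins) * grid$bin_size,
                     grid$bin_size, grid$chrom)
  }

  idx <- seq_len(n) - 1L
  D <- abs(outer(idx, idx, "-"))
  lam <- pmax(D, 1)^(-alpha)

  if (!is.na(truth$superdomain_boundary) && s < 1) {
    b <- truth$superdomain_boundary
    if (b <= 0 || b >= n - 1)
      stop("invalid-config: hinge outside chromosome")
    lo <- idx < b
    cross <- outer(lo, !lo, "&") | outer(!lo, lo, "&")
    lam[cross] <- lam[cross] * s
  }
  if (!is.null(truth$compartment_labels)) {
    same <- outer(truth$compartment_labels, truth$compartment_labels, "==")
    lam <- lam * ifelse(same, 1 + config$compartment_amp,
                        1 - config$compartment_amp)
  }
  if (length(truth$tad_boundaries)) {
    tid <- findInterval(idx, truth$tad_boundaries)
    lam <- lam * ifelse(outer(tid, tid, "=="), config$tad_boost, 1)
  }
  if (truth$flame_direction != "none" && !is.na(truth$hinge_bin)) {
    h <- truth$hinge_bin
    w <- config$flame_width
    in_row <- abs(idx - h) < w
    on_side <- if (truth$flame_direction == "telomeric")
      idx > h + (w - 1L) else idx < h - (w - 1L)
    fl <- outer(in_row, on_side, "&")
    fl <- fl | t(fl)
    # the flame overrides superdomain suppression: the hinge locus contacts
    # the flame side strongly regardless of the seam
    lam[fl] <- pmax(D, 1)[fl]^(-alpha) * config$flame_boost
  }
  if (config$sparse_bin_frac > 0) {
    nsp <- round(config$sparse_bin_frac * n)
    eligible <- idx
    if (!is.na(truth$hinge_bin))
      eligible <- eligible[abs(eligible - truth$hinge_bin) > 3]
    old <- .Random.seed_save()
    set.seed(config$seed + 104729L)
    sp <- sort(sample(eligible, min(nsp, length(eligible))))
    .Random.seed_restore(old)
    lam[sp + 1L, ] <- lam[sp + 1L, ] * config$sparse_bin_factor
    lam[, sp + 1L] <- lam[, sp + 1L] * config$sparse_bin_factor
    truth$sparse_bins <- sp
  } else truth$sparse_bins <- integer(0)
  lam <- (lam + t(lam)) / 2
  lam <- lam * (config$n_pairs / sum(lam[upper.tri(lam, diag = TRUE)]))
  list(lambda = lam, truth = truth, grid = grid)
}

#' Simulate a binned allelic contact map with known structure
#'
#' Expected counts follow a power-law distance decay multiplied by
#' cross-superdomain suppression, an optional compartment checkerboard and
#' within-TAD boost, and a one-sided hinge flame; observed counts are
#' independent Poisson draws, symmetrized. Deletion edits remove the edited
#' bins and lift the superdomain suppression; inversion edits mirror the
#' flame direction and change nothing else.
#'
#' @param config A [sim_config()].
#' @param truth A [sim_truth()]; defaults to [sim_truth_bipartite()].
#' @return A raw-stage [contact_matrix()] whose `meta$truth` records the
#'   effective (post-edit) truth.
#' @export
simulate_contact_map <- function(config, truth = sim_truth_bipartite(config)) {
  mod <- sim_lambda(config, truth)
  n <- nrow(mod$lambda)
  set.seed(config$seed)
  up <- upper.tri(mod$lambda, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), mod$lambda[up])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, mod$grid, stage = "raw",
                 meta = list(truth = mod$truth, allele = config$true_allele,
                             config = config))
}

#' Simulate allele-tagged read pairs from a contact map
#'
#' Draws `n_pairs` pairs multinomially over matrix cells, places each end
#' uniformly within its bin, and tags each end with the matrix's allele of
#' origin with probability `1 - ambiguity_rate` (else `AMBIGUOUS`).
#' Duplicate pairs (identical coordinates) are appended at `dup_rate`.
#' The per-pair true allele is kept in a `truth` attribute, a side channel
#' never written into the `.pairs` columns themselves.
#'
#' @param m A raw [contact_matrix()].
#' @param config A [sim_config()].
#' @return A data frame in `.pairs` column order: `readID chrom1 pos1 chrom2
#'   pos2 strand1 strand2 allele1 allele2`, with attribute `truth`.
#' @export
simulate_read_pairs <- function(m, config) {
  stopifnot(inherits(m, "contact_matrix"), inherits(config, "sim_config"))
  v <- m$values
  if (sum(v) == 0) stop("empty matrix: no contacts to sample")
  set.seed(config$seed + 7919L)
  n <- nrow(v)
  up <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
  p <- v[upper.tri(v, diag = TRUE)]
  draw <- as.vector(stats::rmultinom(1, size = config$n_pairs, prob = p))
  cell <- rep.int(seq_along(draw), draw)
  i <- up[cell, 1] - 1L   # 0-based bins
  j <- up[cell, 2] - 1L
  bs <- m$grid$bin_size
  npair <- length(i)
  pos1 <- pmin(i * bs + sample.int(bs, npair, replace = TRUE),
               m$grid$chrom_length)
  pos2 <- pmin(j * bs + sample.int(bs, npair, replace = TRUE),
               m$grid$chrom_length)
  truth_allele <- rep(config$true_allele, npair)
  tag <- function() ifelse(stats::runif(npair) < config$ambiguity_rate,
                           "AMBIGUOUS", truth_allele)
  pairs <- data.frame(
    readID = sprintf("sim%08d", seq_len(npair)),
    chrom1 = m$grid$chrom, pos1 = pos1,
    chrom2 = m$grid$chrom, pos2 = pos2,
    strand1 = sample(c("+", "-"), npair, replace = TRUE),
    strand2 = sample(c("+", "-"), npair, replace = TRUE),
    allele1 = tag(), allele2 = tag(),
    stringsAsFactors = FALSE)
  truth <- truth_allele
  if (config$dup_rate > 0) {
    ndup <- floor(config$dup_rate * npair)
    if (ndup > 0) {
      dup <- sample.int(npair, ndup, replace = TRUE)
      extra <- pairs[dup, ]
      extra$readID <- sprintf("dup%08d", seq_len(ndup))
      pairs <- rbind(pairs, extra)
      truth <- c(truth, truth[dup])
    }
  }
  attr(pairs, "truth") <- truth
  pairs
}

#' Simulate allelic peak read counts with known class
#'
#' Per-peak SNP coverage is Poisson(`mean_cov`); spretus-allele reads are
#' Binomial(coverage, p) with class-specific p (Xa-specific 0.95, common
#' 0.5, Xi-specific 0.05 by default).
#'
#' @param n Number of peaks.
#' @param class_mix Proportions of (Xa-specific, common, Xi-specific) truth
#'   classes; must sum to 1.
#' @param mean_cov Mean SNP read coverage per peak.
#' @param p_class Spretus-read probability per truth class.
#' @param chrom,chrom_length Peak placement coordinates.
#' @param seed Integer seed.
#' @return Data frame with interval, counts, and `truth_class`.
#' @export
simulate_peaks <- function(n, class_mix = c(0.45, 0.35, 0.2), mean_cov = 30,
                           p_class = c(spretus_specific = 0.95, common = 0.5,
                                       bl6_specific = 0.05),
                           chrom = "chrX", chrom_length = 1e8, seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1")
  set.seed(seed)
  cls <- sample(names(p_class), n, replace = TRUE, prob = class_mix)
  cov <- stats::rpois(n, mean_cov)
  spret <- stats::rbinom(n, cov, p_class[cls])
  start <- sort(sample.int(chrom_length - 500L, n))
  data.frame(chrom = chrom, start = start, end = start + 500L,
             snp_spretus = spret, snp_bl6 = cov - spret,
             truth_class = cls, stringsAsFactors = FALSE)
}

#' Simulate allelic gene expression with known escapers
#'
#' Silenced genes have an Xi read fraction of 0; escapers express from the
#' Xi at `xi_frac_escape`. Gene expression levels are log-normal; total
#' counts scale with expression and gene length, SNP-covered reads with
#' expression alone (coverage ~ Poisson(`depth` x expression)), and
#' Xi-allele SNP reads are Binomial(coverage, xi_fraction).
#'
#' @param n_genes Number of genes.
#' @param escaper_frac Fraction of genes escaping XCI, in \[0, 1\].
#' @param xi_frac_escape Expected Xi read proportion for escapers.
#' @param depth Mean SNP read coverage for a gene of average expression.
#' @param length_range Gene length range, bp.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return Data frame of gene records with `truth_escape` and `xi_fraction`.
#' @export
simulate_expression <- function(n_genes = 1000, escaper_frac = 0.03,
                                xi_frac_escape = 0.2, depth = 60,
                                length_range = c(1e3, 1e5), chrom = "chrX",
                                seed = 1L) {
  if (escaper_frac < 0 || escaper_frac > 1)
    stop("escaper_frac must be in [0, 1]")
  set.seed(seed)
  esc <- stats::runif(n_genes) < escaper_frac
  xi_frac <- ifelse(esc, xi_frac_escape, 0)
  expr <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  len <- round(stats::runif(n_genes, length_range[1], length_range[2]))
  total <- stats::rpois(n_genes, expr * len / 1e3 * 5)
  snp_total <- stats::rpois(n_genes, expr * depth)
  snp_xi <- stats::rbinom(n_genes, snp_total, xi_frac)
  start <- sort(sample.int(9e7, n_genes))
  data.frame(id = sprintf("gene%04d", seq_len(n_genes)),
             chrom = chrom, start = start, end = start + len,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             length = len, total_count = total,
             snp_spretus = snp_total - snp_xi, snp_bl6 = snp_xi,
             truth_escape = esc, xi_fraction = xi_frac,
             stringsAsFactors = FALSE)
}

#' Preset simulations: wild type, hinge deletion, hinge inversion
#'
#' Convenience wrapper mirroring the three study designs: `"wt"` (bipartite
#' Xi with telomeric flame), `"del"` (hinge interval deleted, bipartite
#' structure lost), `"inv"` (flame mirrored to the centromeric side).
#'
#' @param preset One of `"wt"`, `"del"`, `"inv"`.
#' @param seed Integer seed.
#' @param ... Overrides for [sim_config()].
#' @return A raw [contact_matrix()] with truth in `meta$truth`.
#' @export
simulate_preset <- function(preset = c("wt", "del", "inv"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- list(seed = seed, ...)
  if (preset == "del") {
    base$edit <- "deletion"
    if (is.null(base$edit_interval)) {
      bs <- base$bin_size %||% 5e5
      cl <- base$chrom_length %||% 1e8
      h <- as.integer(ceiling(cl / bs)) %/% 2
      base$edit_interval <- c(h * bs + 1, (h + 1) * bs)
    }
  } else if (preset == "inv") {
    base$edit <- "inversion"
  }
  cfg <- do.call(sim_config, base)
  simulate_contact_map(cfg)
}
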