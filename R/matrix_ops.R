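#' Bin intrachromosomal read pairs into a raw contact matrix
#'
#' Counts, for one chromosome and allele, the number of pairs whose ends
#' fall in bins i and j (1-based positions map to 0-based bins as
#' `floor((pos - 1) / bin_size)`); storage is symmetric.
#'
#' @param pairs `.pairs` data frame (cis pairs on the grid's chromosome).
#' @param grid A [bin_grid()].
#' @return A raw-stage [contact_matrix()].
#' @export
bin_pairs <- function(pairs, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  keep <- pairs$chrom1 == grid$chrom & pairs$chrom2 == grid$chrom
  pairs <- pairs[keep, , drop = FALSE]
  n <- grid$n_bins
  v <- matrix(0, n, n)
  if (nrow(pairs)) {
    i <- coord_to_bin(grid, pairs$pos1)
    j <- coord_to_bin(grid, pairs$pos2)
    lo <- pmin(i, j); hi <- pmax(i, j)
    t0 <- table(lo * n + hi)
    idx <- as.numeric(names(t0))
    li <- idx %/% n; hj <- idx %% n
    for (k in seq_along(idx)) {
      v[li[k] + 1, hj[k] + 1] <- v[li[k] + 1, hj[k] + 1] + t0[k]
    }
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
  }
  contact_matrix(v, grid, stage = "raw")
}

#' Filter a raw contact matrix
#'
#' Zeroes cells on the diagonal, super-diagonal, and sub-diagonal (entries
#' dominated by self-ligation products), then masks bins whose marginal
#' coverage falls in the lowest `low_pct` fraction (sparsely populated bins
#' dominated by spurious contacts). The percentile is computed on marginals
#' after diagonal zeroing; ties at the threshold are all masked.
#'
#' @param m A raw [contact_matrix()].
#' @param low_pct Fraction of lowest-coverage bins to mask (default 0.02).
#' @return A filtered-stage [contact_matrix()] with updated `mask`.
#' @export
filter_matrix <- function(m, low_pct = 0.02) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  n <- nrow(v)
  d <- abs(row(v) - col(v))
  v[d <= 1] <- 0
  marg <- rowSums(v)
  k <- max(1L, ceiling(low_pct * n))
  thr <- sort(marg)[k]
  low <- which(marg <= thr) - 1L
  mask <- sort(unique(c(m$mask, low)))
  v[mask + 1L, ] <- 0
  v[, mask + 1L] <- 0
  cm_update(m, v, "filtered", mask = mask)
}

#' Iterative-correction (ICE) balancing
#'
#' Removes multiplicative per-bin biases so that unmasked rows and columns
#' have near-equal sums: each iteration divides by the square root of the
#' relative row sums, until the coefficient of variation of unmasked row
#' sums drops below `tol` or `max_iter` is reached (with a warning). Total
#' matrix mass is rescaled to the input total. The accumulated bias vector
#' is stored in `meta$ice_bias`: multiplying the output by `b_i b_j`
#' recovers the input.
#'
#' @param m A filtered [contact_matrix()].
#' @param tol Convergence tolerance on the row-sum CV.
#' @param max_iter Maximum number of iterations.
#' @return An iced-stage [contact_matrix()].
#' @export
ice_normalize <- function(m, tol = 1e-5, max_iter = 200) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  total_in <- sum(v)
  if (total_in == 0) stop("cannot balance an all-zero matrix")
  keep <- unmasked_bins(m) + 1L
  bias <- rep(NA_real_, nrow(v))
  b <- rep(1, length(keep))
  sub <- v[keep, keep, drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rs <- rowSums(sub)
    pos <- rs > 0
    cv <- stats::sd(rs[pos]) / mean(rs[pos])
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    db <- rep(1, length(rs))
    db[pos] <- sqrt(rs[pos] / mean(rs[pos]))
    sub <- sub / outer(db, db)
    b <- b * db
  }
  if (!converged)
    warning("ICE did not reach tol = ", tol, " within ", max_iter,
            " iterations")
  sc <- total_in / sum(sub)
  sub <- sub * sc
  b <- b / sqrt(sc)
  out <- matrix(0, nrow(v), ncol(v))
  out[keep, keep] <- sub
  bias[keep] <- b
  res <- cm_update(m, out, "iced")
  res$meta$ice_bias <- bias
  res
}

#' Quantile-normalize contact maps to one another
#'
#' Over the unmasked upper-triangle cells (zeros included), each matrix's
#' sorted values are replaced by the rank-wise mean across matrices, with
#' ties averaged; symmetry is restored afterwards. Matrices must share the
#' grid; the union of their masks is applied to all.
#'
#' @param ms List of [contact_matrix()] objects at the same stage.
#' @return List of quantile-stage matrices.
#' @export
quantile_normalize <- function(ms) {
  stopifnot(length(ms) >= 2)
  g <- ms[[1]]$grid
  for (m in ms) {
    if (!same_grid(m$grid, g)) stop("matrices must share a grid")
  }
  mask <- sort(unique(unlist(lapply(ms, function(m) m$mask))))
  keep <- setdiff(seq_len(g$n_bins) - 1L, mask) + 1L
  ut <- upper.tri(matrix(0, length(keep), length(keep)))
  x <- vapply(ms, function(m) m$values[keep, keep][ut],
              numeric(sum(ut)))
  xq <- limma::normalizeQuantiles(x, ties = TRUE)
  lapply(seq_along(ms), function(s) {
    sub <- matrix(0, length(keep), length(keep))
    sub[ut] <- xq[, s]
    sub <- sub + t(sub)
    full <- matrix(0, g$n_bins, g$n_bins)
    full[keep, keep] <- sub
    cm_update(ms[[s]], full, "quantile", mask = mask)
  })
}

#' Pearson-correlation transform of a contact map
#'
#' Entry (i, j) of the output is the Pearson correlation of matrix columns
#' i and j over unmasked bins, which accentuates the most probable contacts
#' and mitigates depth and sparsity differences. Applied to balanced (or
#' quantile-normalized) matrices rather than observed-over-expected so that
#' the distance effect is not normalized out. Masked bins and constant
#' columns give missing rows, never contaminating neighbours.
#'
#' @param m An iced-, quantile-, or oe-stage [contact_matrix()].
#' @return A pearson-stage [contact_matrix()] (values in \[-1, 1\] or `NA`).
#' @export
pearson_transform <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!m$stage %in% c("iced", "quantile", "oe"))
    stop("pearson_transform expects an iced, quantile, or oe matrix")
  keep <- unmasked_bins(m) + 1L
  sub <- m$values[keep, keep, drop = FALSE]
  const <- apply(sub, 2, function(x) stats::sd(x) == 0 || !all(is.finite(x)))
  cc <- suppressWarnings(stats::cor(sub))
  cc[const, ] <- NA
  cc[, const] <- NA
  diag(cc)[!const] <- 1
  full <- matrix(NA_real_, nrow(m$values), ncol(m$values))
  full[keep, keep] <- cc
  cm_update(m, full, "pearson")
}

#' Differential contact map
#'
#' Elementwise `a - b` for two matrices at the same stage and grid; loss or
#' gain of contacts in `a` versus `b` appear negative or positive. Intended
#' for Pearson-transformed quantile-normalized maps; raw-count differentials
#' are obtained by passing matrices at an earlier common stage. Missing
#' values propagate.
#'
#' @param a,b [contact_matrix()] objects at the same stage.
#' @return Numeric matrix of differences.
#' @export
differential_map <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!same_grid(a$grid, b$grid)) stop("matrices must share a grid")
  if (a$stage != b$stage) stop("stage mismatch: ", a$stage, " vs ", b$stage)
  a$values - b$values
}

#' Contact decay curve
#'
#' For each separation k (in bins), sums contacts over all unmasked cell
#' pairs (i, j) with |i - j| = k, optionally restricted to a region (both
#' ends inside). `prob` is the sum normalized by the total qualifying mass,
#' so the curve is a probability distribution over k; `mean` retains the
#' raw per-cell mean, whose log-log slope estimates the decay exponent.
#'
#' @param m An iced (or raw/filtered) [contact_matrix()].
#' @param region Optional 0-based bin interval `c(first, last)` (inclusive).
#' @return A data frame of class `decay_curve` with columns `k`, `sum`,
#'   `n_cells`, `mean`, `prob`.
#' @export
decay_curve <- function(m, region = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$grid$n_bins
  keep <- unmasked_bins(m)
  if (!is.null(region)) {
    if (length(region) != 2 || region[2] - region[1] < 1)
      stop("region must span at least 2 bins")
    keep <- keep[keep >= region[1] & keep <= region[2]]
  }
  v <- m$values[keep + 1L, keep + 1L, drop = FALSE]
  d <- abs(outer(keep, keep, "-"))
  ut <- upper.tri(v)
  kmax <- n - 1L
  sums <- vapply(seq_len(kmax), function(k) sum(v[ut][d[ut] == k]), 0)
  ncell <- vapply(seq_len(kmax), function(k) sum(d[ut] == k), 0)
  tot <- sum(sums)
  out <- data.frame(k = seq_len(kmax), sum = sums, n_cells = ncell,
                    mean = ifelse(ncell > 0, sums / ncell, NA_real_),
                    prob = if (tot > 0) sums / tot else rep(NA_real_, kmax))
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Fit the power-law decay exponent from a decay curve
#'
#' Linear fit of log(mean contact) on log(k) over a mid-range of
#' separations; returns the negated slope (the exponent alpha).
#'
#' @param curve A [decay_curve()].
#' @param k_range Range of k used; defaults to 2..(max k)/4.
#' @return Estimated exponent (positive for decaying contacts).
#' @export
fit_decay_exponent <- function(curve, k_range = NULL) {
  if (is.null(k_range)) k_range <- c(2, max(2, floor(max(curve$k) / 4)))
  sel <- curve$k >= k_range[1] & curve$k <= k_range[2] &
    is.finite(curve$mean) & curve$mean > 0
  if (sum(sel) < 3) stop("too few usable distance bins for a slope fit")
  fit <- stats::lm(log(curve$mean[sel]) ~ log(curve$k[sel]))
  -unname(stats::coef(fit)[2])
}

#' Scale-normalize decay curves by autosomal reference curves
#'
#' Library-preparation depth differences are removed by fitting, per
#' sample, the scalar that best matches its autosomal per-distance means to
#' a designated reference sample's (least squares), then applying those
#' autosomal factors to the X-chromosome curves of the same samples.
#'
#' @param x_curves Named list of X-chromosome [decay_curve()]s.
#' @param autosome_curves Named list of autosomal curves, same names and k
#'   support.
#' @param reference Name or index of the reference sample.
#' @return List with `curves` (scaled `sum`/`mean` columns) and `factors`.
#' @export
autosomal_scale <- function(x_curves, autosome_curves, reference = 1) {
  stopifnot(length(x_curves) == length(autosome_curves))
  ref <- autosome_curves[[reference]]$mean
  if (!any(is.finite(ref)) || sum(ref, na.rm = TRUE) == 0)
    stop("reference autosomal curve has zero mass")
  factors <- vapply(autosome_curves, function(cv) {
    x <- cv$mean
    ok <- is.finite(x) & is.finite(ref)
    if (sum(x[ok]^2) == 0) stop("autosomal curve has zero mass")
    sum(ref[ok] * x[ok]) / sum(x[ok]^2)
  }, 0)
  curves <- lapply(seq_along(x_curves), function(s) {
    cv <- x_curves[[s]]
    cv$sum <- cv$sum * factors[s]
    cv$mean <- cv$mean * factors[s]
    cv
  })
  names(curves) <- names(x_curves)
  list(curves = curves, factors = factors)
}

#' Virtual 4C profile from a contact map
#'
#' Per-bin contact profile of a viewpoint: the sum of matrix rows over the
#' viewpoint bins. Viewpoint bins themselves are reported missing. Any
#' display clamping of extreme values is presentation-only and never
#' applied to the data.
#'
#' @param m An iced or quantile [contact_matrix()].
#' @param viewpoint 0-based bin indices (a vector, e.g. `100` or `99:101`).
#' @return A [score_track()] of kind `"virtual4c"`.
#' @export
virtual_4c <- function(m, viewpoint) {
  stopifnot(inherits(m, "contact_matrix"))
  viewpoint <- as.integer(viewpoint)
  if (any(viewpoint < 0) || any(viewpoint >= m$grid$n_bins))
    stop("viewpoint outside grid")
  prof <- colSums(m$values[viewpoint + 1L, , drop = FALSE])
  prof[viewpoint + 1L] <- NA
  prof[m$mask + 1L] <- NA
  score_track(prof, m$grid, kind = "virtual4c",
              params = list(viewpoint = viewpoint))
}
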