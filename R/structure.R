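#' Compartment principal-component score tracks
#'
#' Decomposes a balanced contact map into principal components the standard
#' way for A/B compartment analysis: distance correction
#' (observed / expected, with expected(k) the mean unmasked contact at
#' separation k), Pearson correlation of the distance-corrected columns,
#' then eigendecomposition. Score track p is eigenvector p scaled by the
#' square root of its eigenvalue. On a bipartite chromosome PC1 captures
#' the superdomain structure as a single sign switch at the hinge rather
#' than A/B compartments.
#'
#' Sign convention: the largest-magnitude entry of each track is positive.
#' Per-PC explained-variance fractions are stored in each track's `params`.
#'
#' @param m An iced or quantile [contact_matrix()].
#' @param n_pcs Number of components to return.
#' @param oe_cap Upper clip on observed/expected ratios before the
#'   correlation step. Long-range distance bands have small expected
#'   counts, so single stray contacts produce huge ratios that dominate
#'   Pearson correlations; clipping stabilizes the decomposition on
#'   shallow maps. `Inf` disables.
#' @return List of [score_track()]s (`pc1` ... `pc4`).
#' @export
compartment_pcs <- function(m, n_pcs = 4, oe_cap = 5) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!m$stage %in% c("iced", "quantile"))
    stop("compartment_pcs expects an iced or quantile matrix")
  keep <- unmasked_bins(m) + 1L
  if (length(keep) < n_pcs + 2) stop("matrix too sparse for PCA")
  sub <- m$values[keep, keep, drop = FALSE]
  d <- abs(row(sub) - col(sub))
  expd <- vapply(0:(nrow(sub) - 1), function(k) mean(sub[d == k]), 0)
  oe <- sub / expd[d + 1]
  oe[!is.finite(oe)] <- 0
  oe <- pmin(oe, oe_cap)
  cc <- suppressWarnings(stats::cor(oe))
  if (all(!is.finite(cc))) stop("matrix too sparse: correlation undefined")
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  expl <- ev / sum(ev)
  lapply(seq_len(n_pcs), function(p) {
    t0 <- eg$vectors[, p] * sqrt(ev[p])
    if (t0[which.max(abs(t0))] < 0) t0 <- -t0
    full <- rep(NA_real_, m$grid$n_bins)
    full[keep] <- t0
    score_track(full, m$grid, kind = paste0("pc", p),
                params = list(explained_var = expl[p]))
  })
}

#' Spearman correlation between two score tracks
#'
#' Rank correlation over bins non-missing in both tracks; requires at least
#' 10 shared bins.
#'
#' @param a,b [score_track()]s on the same grid.
#' @return Spearman rho.
#' @export
pc_correlation <- function(a, b) {
  stopifnot(inherits(a, "score_track"), inherits(b, "score_track"))
  if (!same_grid(a$grid, b$grid)) stop("tracks must share a grid")
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < 10) stop("fewer than 10 shared non-missing bins")
  stats::cor(a$values[ok], b$values[ok], method = "spearman")
}

#' 0-based bins where a track's sign switches
#'
#' Positions (index of the right-hand bin) at which consecutive non-missing
#' values change sign. Used to locate the superdomain seam on PC1 profiles.
#'
#' @param track A [score_track()] or numeric vector.
#' @return Integer vector of 0-based bin indices.
#' @export
sign_switch_bins <- function(track) {
  v <- if (inherits(track, "score_track")) track$values else track
  idx <- which(!is.na(v) & v != 0)
  if (length(idx) < 2) return(integer(0))
  s <- sign(v[idx])
  as.integer(idx[which(s[-1] != s[-length(s)]) + 1] - 1L)
}

#' Coverage score: mean contact spanning each bin
#'
#' The raw score of bin i is the mean count over all off-diagonal unmasked
#' cells (a, b) with a <= i <= b -- a V-shaped region of the map whose arms
#' extend to the matrix edges, so all interaction length scales contribute.
#' The track is normalized as log2(score / chromosomal mean), smoothed with
#' a five-window degree-two Savitzky-Golay filter (edge bins are assigned
#' linearly interpolated values), and finally standardized (`"zscore"`),
#' rescaled to \[0, 1\] (`"unit"`), or left as is (`"none"`). The global
#' minimum of the track marks the superdomain hinge on a bipartite
#' chromosome.
#'
#' @param m An iced [contact_matrix()].
#' @param edge_exclude_bp Exclude bins within this many bp of either
#'   chromosome end (0 disables).
#' @param rescale Final rescaling of the smoothed track.
#' @return A [score_track()] (`coverage_z`, `coverage_01`, or
#'   `coverage_log2`).
#' @export
coverage_score <- function(m, edge_exclude_bp = 0,
                           rescale = c("zscore", "unit", "none")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$grid$n_bins
  if (edge_exclude_bp > 0 && m$grid$chrom_length <= 2 * edge_exclude_bp)
    stop("chromosome shorter than twice the edge exclusion")
  keep <- unmasked_bins(m)
  v <- m$values[keep + 1L, keep + 1L, drop = FALSE]
  ut <- which(upper.tri(v), arr.ind = TRUE)
  a <- keep[ut[, 1]]; b <- keep[ut[, 2]]
  val <- v[ut]
  raw <- rep(NA_real_, n)
  for (i in keep) {
    sel <- a <= i & b >= i
    raw[i + 1L] <- if (any(sel)) mean(val[sel]) else NA
  }
  if (edge_exclude_bp > 0) {
    ex <- ceiling(edge_exclude_bp / m$grid$bin_size)
    raw[c(seq_len(ex), (n - ex + 1):n)] <- NA
  }
  lg <- log2(raw / mean(raw, na.rm = TRUE))
  lg[!is.finite(lg)] <- NA
  sm <- savgol_smooth(lg, window = 5, degree = 2)
  out <- switch(rescale,
                zscore = (sm - mean(sm, na.rm = TRUE)) / stats::sd(sm, na.rm = TRUE),
                unit = (sm - min(sm, na.rm = TRUE)) /
                  (max(sm, na.rm = TRUE) - min(sm, na.rm = TRUE)),
                none = sm)
  kind <- switch(rescale, zscore = "coverage_z", unit = "coverage_01",
                 none = "coverage_log2")
  score_track(out, m$grid, kind = kind,
              params = list(edge_exclude_bp = edge_exclude_bp,
                            rescale = rescale, raw = raw))
}

# Savitzky-Golay smoothing with NA bridging and linear interpolation for
# edge bins: interior NAs are linearly interpolated before filtering and
# restored afterwards; the half-window bins at each end are extrapolated
# from the nearest two smoothed values.
savgol_smooth <- function(x, window = 5, degree = 2) {
  n <- length(x)
  ok <- !is.na(x)
  if (sum(ok) < window) return(x)
  first <- which(ok)[1]; last <- tail(which(ok), 1)
  core <- first:last
  xi <- x[core]
  if (anyNA(xi))
    xi <- stats::approx(seq_along(xi)[!is.na(xi)], xi[!is.na(xi)],
                        xout = seq_along(xi))$y
  sm <- signal::sgolayfilt(xi, p = degree, n = window)
  hw <- (window - 1) %/% 2
  m <- length(sm)
  if (m > 2 * hw + 2) {
    for (e in seq_len(hw)) {   # linear extrapolation from nearest two
      sm[hw + 1 - e] <- sm[hw + 2 - e] - (sm[hw + 3 - e] - sm[hw + 2 - e])
      sm[m - hw + e] <- sm[m - hw + e - 1] +
        (sm[m - hw + e - 1] - sm[m - hw + e - 2])
    }
  }
  out <- rep(NA_real_, n)
  out[core] <- sm
  out[is.na(x)] <- NA
  out
}

#' Boundary region of minimal interaction
#'
#' On a \[0, 1\]-rescaled coverage track, the maximal contiguous run of bins
#' below `threshold` that contains the global minimum; empty when no bin
#' falls below the threshold.
#'
#' @param track A unit-rescaled coverage [score_track()].
#' @param threshold Coverage threshold (default 0.015).
#' @return Integer vector of 0-based bin indices (possibly empty).
#' @export
boundary_region <- function(track, threshold = 0.015) {
  v <- track$values
  below <- !is.na(v) & v < threshold
  if (!any(below)) return(integer(0))
  mn <- which.min(v)
  if (!below[mn]) return(integer(0))
  lo <- mn
  while (lo > 1 && below[lo - 1]) lo <- lo - 1
  hi <- mn
  while (hi < length(v) && below[hi + 1]) hi <- hi + 1
  as.integer((lo:hi) - 1L)
}

# window sizes in bins from bp options; presets match the 500 kb and 40 kb
# analyses (--is 3500001/520001, --ids 2000001/320001, --ss 1000001/160001)
insulation_params <- function(bin_size, is_bp = NULL, ids_bp = NULL,
                              ss_bp = NULL) {
  if (is.null(is_bp))
    is_bp <- if (bin_size == 5e5) 3500001 else if (bin_size == 4e4) 520001
  else is_bp
  if (is.null(ids_bp))
    ids_bp <- if (bin_size == 5e5) 2000001 else if (bin_size == 4e4) 320001
  if (is.null(ss_bp))
    ss_bp <- if (bin_size == 5e5) 1000001 else if (bin_size == 4e4) 160001
  if (is.null(is_bp) || is.null(ids_bp) || is.null(ss_bp))
    stop("no insulation presets for this bin size; give is_bp/ids_bp/ss_bp")
  list(is_bins = as.integer(round(is_bp / bin_size)),
       ids_bins = as.integer(round(ids_bp / bin_size)),
       ss_bins = as.integer(round(ss_bp / bin_size)))
}

#' Insulation score and delta profiles
#'
#' The insulation score of bin i is the mean contact within the
#' off-diagonal square \[i - is_bins, i - 1\] x \[i + 1, i + is_bins\],
#' log2-ratioed to its chromosomal mean; bins without a full square are
#' missing, and windows with under half their cells available (masking) are
#' missing too. The delta vector is the mean insulation over the
#' `ids_bins` bins to the left minus the mean over the `ids_bins` bins to
#' the right; boundaries appear as +/- zero crossings. By default the
#' insulation track is smoothed (moving mean of span `ss_bins`) before
#' differencing.
#'
#' @param m An iced [contact_matrix()].
#' @param is_bp,ids_bp,ss_bp Window sizes in bp; presets exist for 500 kb
#'   (3500001 / 2000001 / 1000001) and 40 kb (520001 / 320001 / 160001)
#'   bins.
#' @param smooth_first Smooth insulation before computing delta.
#' @return List with `insulation` and `delta` [score_track()]s.
#' @export
insulation_profile <- function(m, is_bp = NULL, ids_bp = NULL, ss_bp = NULL,
                               smooth_first = TRUE) {
  stopifnot(inherits(m, "contact_matrix"))
  pr <- insulation_params(m$grid$bin_size, is_bp, ids_bp, ss_bp)
  if (pr$is_bins < 2) stop("insulation window must span at least 2 bins")
  n <- m$grid$n_bins
  v <- m$values
  masked <- rep(FALSE, n); masked[m$mask + 1L] <- TRUE
  ins <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (masked[i]) next
    li <- (i - pr$is_bins):(i - 1)
    ri <- (i + 1):(i + pr$is_bins)
    if (li[1] < 1 || ri[pr$is_bins] > n) next
    cells <- v[li, ri, drop = FALSE]
    avail <- outer(!masked[li], !masked[ri], "&")
    if (mean(avail) < 0.5) next
    # masked rows/columns remove the square's nearest-diagonal (largest)
    # cells preferentially, so a plain mean over available cells dips at
    # mask edges; average within distance classes instead, weighted by the
    # full square's distance composition
    dcl <- outer(li, ri, function(a, b) abs(a - b))
    num <- den <- 0
    for (k in unique(as.vector(dcl))) {
      sel <- dcl == k
      nav <- sel & avail
      if (!any(nav)) next
      num <- num + sum(sel) * mean(cells[nav])
      den <- den + sum(sel)
    }
    ins[i] <- num / den
  }
  lg <- log2(ins / mean(ins, na.rm = TRUE))
  lg[!is.finite(lg)] <- NA
  base <- if (smooth_first) running_mean(lg, pr$ss_bins) else lg
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    li <- (i - pr$ids_bins):(i - 1)
    ri <- (i + 1):(i + pr$ids_bins)
    if (li[1] < 1 || ri[pr$ids_bins] > n) next
    lv <- base[li]; rv <- base[ri]
    if (mean(!is.na(lv)) < 0.5 || mean(!is.na(rv)) < 0.5) next
    delta[i] <- mean(lv, na.rm = TRUE) - mean(rv, na.rm = TRUE)
  }
  out_ins <- if (smooth_first) base else lg
  list(insulation = score_track(out_ins, m$grid, kind = "insulation",
                                params = pr),
       delta = score_track(delta, m$grid, kind = "delta", params = pr))
}

# centred moving mean with half-width hw, NA-tolerant
running_mean <- function(x, hw) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - hw):min(n, i + hw)
    if (all(is.na(x[w]))) NA_real_ else mean(x[w], na.rm = TRUE)
  }, 0)
}

#' Call TAD boundaries and domains from insulation profiles
#'
#' Candidate boundaries are the bins where the delta vector crosses zero
#' from positive to negative. Boundary strength is the difference between
#' the delta local maximum to the left and local minimum to the right of
#' the boundary bin (search limited to `bmoe` bins). Candidates with
#' strength at or below the noise threshold `nt` are dropped; candidates
#' within `bmoe` bins of a stronger one are merged into it. TADs tile the
#' span between consecutive surviving boundaries; `mbs`/`mts` are minimum
#' boundary and TAD strength filters (default 0 keeps everything).
#'
#' @param insulation,delta [score_track()]s from [insulation_profile()].
#' @param nt Noise threshold on boundary strength.
#' @param bmoe Boundary margin of error, bins.
#' @param mbs,mts Minimum boundary / TAD strength.
#' @return A [tad_set()].
#' @export
call_boundaries_tads <- function(insulation, delta, nt = 0.01, bmoe = 3,
                                 mbs = 0, mts = 0) {
  dv <- delta$values
  n <- length(dv)
  cand <- integer(0)
  for (i in 2:n) {
    if (!is.na(dv[i - 1]) && !is.na(dv[i]) && dv[i - 1] > 0 && dv[i] <= 0)
      cand <- c(cand, i)   # 1-based bin where delta turns non-positive
  }
  if (!length(cand))
    return(tad_set(integer(0), numeric(0),
                   matrix(integer(0), 0, 2,
                          dimnames = list(NULL, c("start", "end"))),
                   insulation$grid))
  strength <- vapply(cand, function(i) {
    lw <- dv[max(1, i - 1 - bmoe):(i - 1)]
    rw <- dv[i:min(n, i + bmoe)]
    max(lw, na.rm = TRUE) - min(rw, na.rm = TRUE)
  }, 0)
  keep <- strength > max(nt, mbs)
  cand <- cand[keep]; strength <- strength[keep]
  if (length(cand) > 1) {   # merge near candidates, keeping the stronger
    ord <- order(-strength)
    taken <- logical(length(cand))
    chosen <- integer(0)
    for (o in ord) {
      if (taken[o]) next
      chosen <- c(chosen, o)
      taken[abs(cand - cand[o]) <= bmoe] <- TRUE
    }
    cand <- cand[sort(chosen)]; strength <- strength[sort(chosen)]
  }
  b0 <- as.integer(cand - 1L)   # 0-based boundary bins
  valid <- which(!is.na(insulation$values)) - 1L
  lo <- if (length(valid)) min(valid) else 0L
  hi <- if (length(valid)) max(valid) + 1L else n
  edges <- c(lo, b0, hi)
  tads <- cbind(start = edges[-length(edges)], end = edges[-1])
  tads <- tads[tads[, 2] > tads[, 1], , drop = FALSE]
  tad_set(b0, strength, tads, insulation$grid)
}

#' Per-bin partition labels from a TAD set
#'
#' Bins between consecutive boundaries share a label; used to compare TAD
#' calls as partitions.
#'
#' @param ts A [tad_set()].
#' @return Integer label per bin (0-based bin order).
#' @export
partition_from_tads <- function(ts) {
  idx <- seq_len(ts$grid$n_bins) - 1L
  findInterval(idx, ts$boundaries) + 1L
}

#' Adjusted Rand index between two TAD partitions
#'
#' Converts TAD sets to per-bin partition labels over the shared bins and
#' applies the standard pair-counting adjusted Rand formula; 1 for
#' identical partitions, approximately 0 for independent ones.
#'
#' @param a,b [tad_set()]s on the same grid, or integer label vectors of
#'   equal length.
#' @return ARI in \[-1, 1\].
#' @export
tad_similarity <- function(a, b) {
  la <- if (inherits(a, "tad_set")) partition_from_tads(a) else a
  lb <- if (inherits(b, "tad_set")) partition_from_tads(b) else b
  if (!length(la) || !length(lb) || length(la) != length(lb))
    stop("partitions must be non-empty and of equal length")
  adjusted_rand <- function(x, y) {
    ct <- table(x, y)
    comb2 <- function(v) sum(v * (v - 1) / 2)
    sij <- comb2(as.vector(ct))
    sa <- comb2(rowSums(ct)); sb <- comb2(colSums(ct))
    np <- length(x) * (length(x) - 1) / 2
    expected <- sa * sb / np
    denom <- (sa + sb) / 2 - expected
    if (denom == 0) return(1)
    (sij - expected) / denom
  }
  adjusted_rand(la, lb)
}

#' Hierarchical clustering of score tracks
#'
#' Pairwise distances between standardized tracks -- Euclidean or
#' 1 - Pearson correlation -- computed over bins non-missing in both,
#' followed by average-linkage hierarchical clustering.
#'
#' @param tracks Named list of [score_track()]s on a shared grid.
#' @param metric `"euclidean"` or `"one_minus_r"`.
#' @return List with `dist` (a `dist`) and `hclust`.
#' @export
compare_tracks <- function(tracks, metric = c("euclidean", "one_minus_r")) {
  metric <- match.arg(metric)
  if (length(tracks) < 2) stop("need at least 2 tracks")
  k <- length(tracks)
  dm <- matrix(0, k, k,
               dimnames = list(names(tracks), names(tracks)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- tracks[[i]]$values; y <- tracks[[j]]$values
      ok <- !is.na(x) & !is.na(y)
      d <- if (metric == "euclidean") sqrt(sum((x[ok] - y[ok])^2))
      else 1 - stats::cor(x[ok], y[ok])
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dd <- stats::as.dist(dm)
  list(dist = dd, hclust = stats::hclust(dd, method = "average"))
}
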