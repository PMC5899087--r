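#' Symmetric binned contact matrix for one chromosome and allele
#'
#' Container for an intrachromosomal Hi-C contact map: a symmetric matrix of
#' counts (or transformed values), the [bin_grid()] it is binned on, the set of
#' masked (filtered-out) bins, and a processing `stage` tag. Stages follow
#' `raw -> filtered -> iced -> {quantile -> pearson | oe -> pearson}`.
#'
#' @param values Symmetric numeric matrix, `n_bins x n_bins`.
#' @param grid A [bin_grid()].
#' @param mask Integer vector of 0-based masked bin indices.
#' @param stage Processing stage tag.
#' @param meta Optional named list of provenance fields (sample, allele, ...).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, grid, mask = integer(0),
                           stage = c("raw", "filtered", "iced", "quantile",
                                     "oe", "pearson"),
                           meta = list()) {
  stage <- match.arg(stage)
  stopifnot(inherits(grid, "bin_grid"), is.matrix(values))
  if (nrow(values) != grid$n_bins || ncol(values) != grid$n_bins)
    stop("values must be n_bins x n_bins for the supplied grid")
  sym_err <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(sym_err) && sym_err > 1e-9)
    stop("contact matrix must be symmetric (max |A - t(A)| = ", sym_err, ")")
  structure(
    list(values = values, grid = grid,
         mask = sort(unique(as.integer(mask))), stage = stage, meta = meta),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s, %d bins @ %s bp, stage=%s, %d masked\n",
              x$grid$chrom, x$grid$n_bins,
              format(x$grid$bin_size, big.mark = ","), x$stage,
              length(x$mask)))
  invisible(x)
}

#' @export
plot.contact_matrix <- function(x, main = NULL, ...) {
  v <- x$values
  v[v < 0] <- 0
  image(log1p(v), axes = FALSE, useRaster = TRUE,
        main = main %||% sprintf("%s (%s)", x$grid$chrom, x$stage), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unmasked (0-based) bin indices
unmasked_bins <- function(m) setdiff(seq_len(m$grid$n_bins) - 1L, m$mask)

# replace values keeping grid/mask, advancing stage
cm_update <- function(m, values, stage, mask = m$mask) {
  contact_matrix(values, m$grid, mask = mask, stage = stage, meta = m$meta)
}

#' Per-bin score track
#'
#' A per-bin numeric profile on a [bin_grid()] (principal-component score,
#' coverage score, insulation, d-score density, ...), with the parameter set
#' used to compute it kept as provenance.
#'
#' @param values Numeric vector of length `n_bins`; `NA` marks missing bins.
#' @param grid A [bin_grid()].
#' @param kind Track kind label, e.g. `"coverage_z"`, `"insulation"`, `"pc1"`.
#' @param params Named list of parameters used.
#' @export
score_track <- function(values, grid, kind = "score", params = list()) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(values) != grid$n_bins)
    stop("track length must equal bin count")
  structure(list(values = as.numeric(values), grid = grid, kind = kind,
                 params = params),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<score_track> %s on %s (%d bins, %d missing); range [%.3g, %.3g]\n",
              x$kind, x$grid$chrom, x$grid$n_bins, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
plot.score_track <- function(x, ...) {
  plot((seq_along(x$values) - 1) * x$grid$bin_size / 1e6, x$values,
       type = "l", xlab = sprintf("%s position (Mb)", x$grid$chrom),
       ylab = x$kind, ...)
  invisible(x)
}

#' Set of TAD boundaries and the domains between them
#'
#' @param boundaries Integer vector of 0-based boundary bin indices,
#'   strictly increasing.
#' @param strength Numeric vector of boundary strengths (> 0), same length.
#' @param tads Two-column matrix of half-open bin intervals `[start, end)`.
#' @param grid A [bin_grid()].
#' @export
tad_set <- function(boundaries, strength, tads, grid) {
  stopifnot(length(boundaries) == length(strength))
  if (is.unsorted(boundaries, strictly = TRUE) && length(boundaries) > 1)
    stop("boundaries must be strictly increasing")
  if (length(strength) && any(strength <= 0))
    stop("boundary strength must be > 0")
  structure(list(boundaries = as.integer(boundaries),
                 strength = as.numeric(strength),
                 tads = tads, grid = grid),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("<tad_set> %d boundaries, %d TADs on %s\n",
              length(x$boundaries), nrow(x$tads), x$grid$chrom))
  invisible(x)
}
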