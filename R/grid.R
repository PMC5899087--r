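#' Binning grid for one chromosome
#'
#' A `bin_grid` maps genomic coordinates to fixed-width, non-overlapping bins
#' and back. Positions are 1-based (as in `.pairs` records); bins are 0-based
#' half-open intervals, so position `p` falls in bin `floor((p - 1) / bin_size)`.
#'
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome name.
#' @return An object of class `bin_grid` with fields `chrom`, `chrom_length`,
#'   `bin_size`, `n_bins`.
#' @examples
#' g <- bin_grid(1e8, 5e5)
#' g$n_bins
#' coord_to_bin(g, c(1, 499999, 500001))
#' @export
bin_grid <- function(chrom_length, bin_size, chrom = "chrX") {
  stopifnot(length(chrom_length) == 1, length(bin_size) == 1)
  if (!is.finite(chrom_length) || chrom_length < 1)
    stop("chrom_length must be a positive number of bp")
  if (!is.finite(bin_size) || bin_size < 1)
    stop("bin_size must be a positive number of bp")
  structure(
    list(chrom = chrom,
         chrom_length = as.numeric(chrom_length),
         bin_size = as.numeric(bin_size),
         n_bins = as.integer(ceiling(chrom_length / bin_size))),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %s: %s bp in %d bins of %s bp\n",
              x$chrom, format(x$chrom_length, big.mark = ","),
              x$n_bins, format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' Map 1-based genomic positions to 0-based bin indices
#'
#' @param grid A [bin_grid()].
#' @param pos Vector of 1-based positions.
#' @return Integer vector of 0-based bin indices.
#' @export
coord_to_bin <- function(grid, pos) {
  stopifnot(inherits(grid, "bin_grid"))
  bad <- which(pos < 1 | pos > grid$chrom_length)
  if (length(bad))
    stop(sprintf("position %s outside %s [1, %s] (record %d)",
                 format(pos[bad[1]], scientific = FALSE), grid$chrom,
                 format(grid$chrom_length, scientific = FALSE), bad[1]))
  as.integer(floor((pos - 1) / grid$bin_size))
}

#' 1-based start coordinate of a 0-based bin
#' @param grid A [bin_grid()].
#' @param bin 0-based bin indices.
#' @export
bin_to_start <- function(grid, bin) {
  stopifnot(inherits(grid, "bin_grid"), all(bin >= 0), all(bin < grid$n_bins))
  bin * grid$bin_size + 1
}

same_grid <- function(a, b) {
  identical(a$chrom, b$chrom) && a$chrom_length == b$chrom_length &&
    a$bin_size == b$bin_size
}
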