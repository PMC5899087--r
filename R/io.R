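#' Write read pairs in `.pairs` dialect
#'
#' Tab-separated columns `readID chrom1 pos1 chrom2 pos2 strand1 strand2`
#' (1-based positions) plus optional `allele1 allele2` tags, preceded by a
#' minimal header. Any truth side channel is written to a separate TSV by
#' [write_truth_tsv()], never embedded here.
#'
#' @param pairs `.pairs` data frame.
#' @param path Output file.
#' @export
write_pairs_file <- function(pairs, path) {
  cols <- intersect(c("readID", "chrom1", "pos1", "chrom2", "pos2",
                      "strand1", "strand2", "allele1", "allele2"),
                    names(pairs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("## pairs format v1.0",
               paste0("#columns: ", paste(cols, collapse = " "))), con)
  utils::write.table(pairs[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a `.pairs` file written by [write_pairs_file()]
#' @param path Input file.
#' @return Data frame of pairs.
#' @export
read_pairs_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#columns:", lines, value = TRUE)
  cols <- strsplit(sub("^#columns: *", "", hdr[1]), " ")[[1]]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                          stringsAsFactors = FALSE)
  df
}

#' Write a contact matrix as sparse COO TSV
#'
#' Upper-triangle non-zero entries as `bin1 bin2 value` with 0-based bins.
#'
#' @param m A [contact_matrix()].
#' @param path Output file.
#' @export
write_coo <- function(m, path) {
  v <- m$values
  up <- which(upper.tri(v, diag = TRUE) & v != 0 & !is.na(v),
              arr.ind = TRUE)
  df <- data.frame(bin1 = up[, 1] - 1L, bin2 = up[, 2] - 1L,
                   count = v[up])
  utils::write.table(df[order(df$bin1, df$bin2), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a COO TSV into a contact matrix
#' @param path Input file.
#' @param grid The [bin_grid()] the matrix is binned on.
#' @param stage Stage tag for the result.
#' @export
read_coo <- function(path, grid, stage = "raw") {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("bin1", "bin2", "count"))
  v <- matrix(0, grid$n_bins, grid$n_bins)
  v[cbind(df$bin1 + 1L, df$bin2 + 1L)] <- df$count
  v[cbind(df$bin2 + 1L, df$bin1 + 1L)] <- df$count
  contact_matrix(v, grid, stage = stage)
}

#' Write a score track as bedGraph
#'
#' 0-based half-open intervals; missing bins are skipped.
#'
#' @param track A [score_track()].
#' @param path Output file.
#' @param name Track name for the header.
#' @export
write_bedgraph <- function(track, path, name = track$kind) {
  g <- track$grid
  keep <- which(!is.na(track$values))
  start <- (keep - 1) * g$bin_size
  end <- pmin(keep * g$bin_size, g$chrom_length)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(
    data.frame(g$chrom, format(start, scientific = FALSE, trim = TRUE),
               format(end, scientific = FALSE, trim = TRUE),
               track$values[keep]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Write TADs and boundaries as BED (0-based half-open)
#'
#' @param ts A [tad_set()].
#' @param path Output file.
#' @param what `"tads"` or `"boundaries"`.
#' @export
write_bed_tads <- function(ts, path, what = c("tads", "boundaries")) {
  what <- match.arg(what)
  g <- ts$grid
  if (what == "tads") {
    df <- data.frame(g$chrom, ts$tads[, "start"] * g$bin_size,
                     pmin(ts$tads[, "end"] * g$bin_size, g$chrom_length),
                     sprintf("tad%03d", seq_len(nrow(ts$tads))))
  } else {
    df <- data.frame(g$chrom, ts$boundaries * g$bin_size,
                     pmin((ts$boundaries + 1) * g$bin_size, g$chrom_length),
                     sprintf("boundary%03d", seq_along(ts$boundaries)),
                     ts$strength)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a simulation truth side channel as TSV
#'
#' Ground-truth fields are kept apart from the standard-format outputs so
#' that simulated files are indistinguishable from real ones.
#'
#' @param truth A [sim_truth()] or a data frame (e.g. per-pair alleles).
#' @param path Output file.
#' @export
write_truth_tsv <- function(truth, path) {
  if (inherits(truth, "sim_truth")) {
    flat <- lapply(unclass(truth), function(x)
      if (is.null(x)) "" else paste(x, collapse = ","))
    df <- data.frame(field = names(flat), value = unlist(flat))
  } else {
    df <- as.data.frame(truth)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write the allelic QC count tables as TSV
#'
#' Four per-chromosome tables (cis+trans ends, trans ends, cis pairs,
#' long-range cis pairs) with BL6/spretus counts and ratios, stacked with a
#' `table` column.
#'
#' @param tables Output of [tally_counts()].
#' @param path Output file.
#' @export
write_count_tables <- function(tables, path) {
  stacked <- do.call(rbind, lapply(names(tables), function(nm) {
    cbind(table = rep(nm, nrow(tables[[nm]])), tables[[nm]])
  }))
  utils::write.table(stacked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
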