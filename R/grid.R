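#' Fixed-width genomic bin grid
#'
#' Tiles every chromosome of a layout with contiguous half-open bins of
#' `bin_size` bp (default 20 kb, the resolution the LAD atlas is built at);
#' only the final bin of a chromosome may be shorter. Bins overlapping a
#' blacklist interval by at least 1 bp are masked and excluded from signal
#' scaling, normalization, HMM training and all downstream statistics.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (> 0); default 20000.
#' @param blacklist Optional [feature_set()] of regions to mask (e.g. the
#'   ENCODE blacklist).
#' @return A `bin_grid` with per-bin vectors `chrom`, `start`, `end`, logical
#'   `mask` (`TRUE` = masked) and `short` (`TRUE` for a trailing bin shorter
#'   than `bin_size`).
#' @export
#' @examples
#' gl <- genome_layout("chr1", 110000)
#' make_grid(gl, 20000)
make_grid <- function(layout, bin_size = 20000, blacklist = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  assert_that(is.numeric(bin_size) && bin_size > 0, "bin_size must be > 0")
  starts <- lapply(layout$chrom, function(cn) {
    seq(0, layout$length[[cn]] - 1, by = bin_size)
  })
  chrom <- rep(layout$chrom, lengths(starts))
  start <- unlist(starts, use.names = FALSE)
  end <- pmin(start + bin_size, layout$length[chrom])
  grid <- structure(list(layout = layout, bin_size = bin_size,
                         chrom = chrom, start = start, end = end,
                         mask = rep(FALSE, length(start)),
                         short = (end - start) < bin_size),
                    class = "bin_grid")
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hits <- GenomicRanges::findOverlaps(grid_granges(grid),
                                        as_granges(blacklist),
                                        minoverlap = 1L)
    grid$mask[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  grid
}

grid_granges <- function(grid) {
  GenomicRanges::GRanges(grid$chrom,
                         IRanges::IRanges(start = grid$start + 1,
                                          end = grid$end))
}

n_bins <- function(grid) length(grid$start)

same_grid <- function(a, b) {
  identical(a$bin_size, b$bin_size) && identical(a$chrom, b$chrom) &&
    identical(a$start, b$start) && identical(a$mask, b$mask)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", n_bins(x), " bins of ", x$bin_size, " bp over ",
      length(x$layout$chrom), " chromosomes (", sum(x$mask),
      " masked)\n", sep = "")
  invisible(x)
}

#' Real-valued per-bin track
#'
#' @param grid A [make_grid()] bin grid.
#' @param values Numeric vector, one value per bin; `NA` where masked or
#'   uncovered. Values at unmasked bins must be finite or `NA`.
#' @return A `binned_track`.
#' @export
binned_track <- function(grid, values) {
  stopifnot(inherits(grid, "bin_grid"))
  values <- as.numeric(values)
  assert_that(length(values) == n_bins(grid),
              "value vector length does not match grid")
  assert_that(all(is.finite(values) | is.na(values)),
              "track values must be finite or NA")
  values[grid$mask] <- NA_real_
  structure(list(grid = grid, values = values), class = "binned_track")
}

#' Nonnegative integer per-bin counts
#'
#' @param grid A [make_grid()] bin grid.
#' @param counts Nonnegative counts, one per bin; `NA` allowed at masked bins.
#' @return A `count_track`.
#' @export
count_track <- function(grid, counts) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- as.numeric(counts)
  assert_that(length(counts) == n_bins(grid),
              "count vector length does not match grid")
  ok <- is.na(counts) | (is.finite(counts) & counts >= 0)
  assert_that(all(ok), "counts must be nonnegative")
  structure(list(grid = grid, counts = counts), class = "count_track")
}

# Effective per-bin availability of a track: unmasked and carrying a value.
track_ok <- function(track) {
  !track$grid$mask & !is.na(track$values %||% track$counts)
}

#' Read a 4-column bedGraph onto a bin grid
#'
#' Intervals must be grid-aligned: each must start on a bin boundary and end
#' on a bin boundary or chromosome end. Intervals spanning several bins (as
#' produced when equal-valued neighbours are merged) are split, assigning the
#' same value to each covered bin. Uncovered bins are `NA` (masked in
#' practice); overlapping intervals and off-grid boundaries are errors rather
#' than being averaged, so grid mismatches surface instead of being smoothed
#' over.
#'
#' @param path bedGraph file path.
#' @param grid Target [make_grid()] grid.
#' @param chrom_alias Optional name map as in [read_bed_intervals()].
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, grid, chrom_alias = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  values <- rep(NA_real_, n_bins(grid))
  df <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#",
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric"), quote = ""),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(binned_track(grid, values))
  chrom <- df[[1]]
  if (!is.null(chrom_alias)) {
    hit <- chrom %in% names(chrom_alias)
    chrom[hit] <- chrom_alias[chrom[hit]]
  }
  known <- chrom %in% grid$layout$chrom
  if (any(!known)) {
    warning(sum(!known), " bedGraph record(s) on unknown chromosomes dropped",
            call. = FALSE)
    df <- df[known, , drop = FALSE]
    chrom <- chrom[known]
  }
  bs <- grid$bin_size
  clen <- grid$layout$length[chrom]
  start <- df[[2]]; end <- df[[3]]
  if (any(start >= end) || any(start < 0) || any(end > clen)) {
    stop("bedGraph interval out of range or start >= end", call. = FALSE)
  }
  if (any(start %% bs != 0) || any(end %% bs != 0 & end != clen)) {
    stop("bedGraph interval not aligned to the bin grid", call. = FALSE)
  }
  # first global bin index of each chromosome
  offset <- setNames(cumsum(c(0, head(tabulate(
    factor(grid$chrom, levels = grid$layout$chrom)), -1))),
    grid$layout$chrom)
  for (i in seq_len(nrow(df))) {
    bins <- offset[[chrom[i]]] + seq(start[i] %/% bs, (end[i] - 1) %/% bs) + 1
    if (any(!is.na(values[bins]))) {
      stop("overlapping bedGraph intervals at ", chrom[i], ":", start[i],
           call. = FALSE)
    }
    values[bins] <- df[[4]][i]
  }
  binned_track(grid, values)
}

#' Write a track as bedGraph
#'
#' One record per unmasked, non-missing bin in layout order; values are
#' written at full double precision so a write/read round trip is exact.
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  g <- track$grid
  keep <- !is.na(track$values)
  out <- sprintf("%s\t%s\t%s\t%.17g", g$chrom[keep],
                 format(g$start[keep], scientific = FALSE, trim = TRUE),
                 format(g$end[keep], scientific = FALSE, trim = TRUE),
                 track$values[keep])
  writeLines(out, path)
  invisible(path)
}
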