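#' Genome layout: ordered chromosomes and their lengths
#'
#' A `genome_layout` fixes the chromosome order used for every genome-wide
#' vector in the package (bins, tracks, state calls) and binds interval
#' inputs to a coordinate frame. All coordinates in the package are 0-based,
#' half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names (order is kept).
#' @param length Positive integer vector of chromosome lengths in bp.
#'
#' @return An object of class `genome_layout` with fields `chrom` and
#'   `length`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  assert_that(length(chrom) > 0, "layout must contain at least one chromosome")
  assert_that(!anyDuplicated(chrom), "duplicate chromosome names in layout")
  assert_that(all(is.finite(length) & length > 0),
              "chromosome lengths must be positive")
  assert_that(length(chrom) == base::length(length),
              "chrom and length differ in length")
  structure(list(chrom = chrom, length = setNames(length, chrom)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length. Chromosome
#' order in the file defines genome-wide bin order.
#'
#' @param path Path to a chrom.sizes text file.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "empty chrom.sizes file")
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, function(p) {
    length(p) != 2L || is.na(suppressWarnings(as.numeric(p[2])))
  }, logical(1)))
  if (length(bad)) {
    stop("malformed chrom.sizes line ", bad[1], ": '", lines[bad[1]], "'",
         call. = FALSE)
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome '", chrom[anyDuplicated(chrom)],
         "' in chrom.sizes", call. = FALSE)
  }
  genome_layout(chrom, as.numeric(vapply(parts, `[`, character(1), 2L)))
}

#' Write a chrom.sizes file
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  writeLines(paste(layout$chrom, format(layout$length, scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}
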