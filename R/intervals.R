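#' Feature sets: typed BED intervals
#'
#' A `feature_set` is a data frame of 0-based half-open intervals
#' (`chrom`, `start`, `end`, `name`, optional `strand`) optionally bound to a
#' [genome_layout()]. It carries transposable elements, replication-timing
#' domains, ATAC peaks, chromHMM states, compartments, blacklists and any
#' other interval annotation the atlas statistics consume.
#'
#' @param chrom,start,end,name,strand Interval columns; `name` defaults to
#'   `"."`, `strand` to `NA`.
#' @param layout Optional [genome_layout()] to validate against. Intervals on
#'   chromosomes absent from the layout are dropped with a warning; intervals
#'   exceeding chromosome length are an error.
#' @return A `feature_set` data frame.
#' @export
feature_set <- function(chrom, start, end, name = ".", strand = NA_character_,
                        layout = NULL) {
  chrom <- as.character(chrom)
  df <- data.frame(chrom = chrom, start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), length(chrom)),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  assert_that(all(df$start >= 0), "negative start coordinate")
  if (any(df$start >= df$end)) {
    stop("interval with start >= end (0-based half-open required)",
         call. = FALSE)
  }
  if (!is.null(layout)) {
    known <- df$chrom %in% layout$chrom
    if (any(!known)) {
      warning(sum(!known), " record(s) on chromosomes absent from layout ",
              "dropped", call. = FALSE)
      df <- df[known, , drop = FALSE]
    }
    assert_that(all(df$end <= layout$length[df$chrom]),
                "interval end exceeds chromosome length")
    df$chrom <- factor(df$chrom, levels = layout$chrom)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    df$chrom <- as.character(df$chrom)
  }
  rownames(df) <- NULL
  class(df) <- c("feature_set", "data.frame")
  attr(df, "layout") <- layout
  df
}

#' Read BED3/BED4/BED6 intervals
#'
#' @param path BED file path (uncompressed, tab-separated).
#' @param layout Optional [genome_layout()]; see [feature_set()].
#' @param chrom_alias Optional named character vector mapping file chromosome
#'   names to layout names (e.g. `c("1" = "chr1")`), applied before
#'   validation so chr-prefixed and bare names can be mixed.
#' @return A [feature_set()].
#' @export
read_bed_intervals <- function(path, layout = NULL, chrom_alias = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character", quote = "")
  assert_that(ncol(df) >= 3, "BED file needs at least 3 columns")
  chrom <- df[[1]]
  if (!is.null(chrom_alias)) {
    hit <- chrom %in% names(chrom_alias)
    chrom[hit] <- chrom_alias[chrom[hit]]
  }
  feature_set(chrom,
              as.numeric(df[[2]]), as.numeric(df[[3]]),
              name = if (ncol(df) >= 4) df[[4]] else ".",
              strand = if (ncol(df) >= 6) df[[6]] else NA_character_,
              layout = layout)
}

#' Write intervals (domains or features) as BED
#'
#' Records are emitted sorted by layout chromosome order (file order when no
#' layout is bound) then start, as 0-based half-open BED4.
#'
#' @param x A `feature_set` or `domain_set` data frame with columns `chrom`,
#'   `start`, `end` and a name column (`name` or `label`).
#' @param path Output path.
#' @param layout Optional [genome_layout()] defining sort order.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(x, path, layout = attr(x, "layout")) {
  nm <- if ("label" %in% names(x)) x$label else x$name %||% "."
  df <- data.frame(chrom = as.character(x$chrom), start = x$start,
                   end = x$end, name = nm)
  if (!is.null(layout)) {
    df <- df[order(match(df$chrom, layout$chrom), df$start), , drop = FALSE]
  } else {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
  }
  out <- sprintf("%s\t%s\t%s\t%s", df$chrom,
                 format(df$start, scientific = FALSE, trim = TRUE),
                 format(df$end, scientific = FALSE, trim = TRUE), df$name)
  writeLines(out, path)
  invisible(path)
}

as_granges <- function(x) {
  GenomicRanges::GRanges(as.character(x$chrom),
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Gene table with strand-aware TSS
#'
#' @param chrom,start,end,strand,gene_id Gene body intervals (0-based
#'   half-open) with strand in `{"+", "-"}` and unique ids.
#' @param layout Optional [genome_layout()].
#' @return A `gene_table` data frame with a `tss` column: `start` on the plus
#'   strand, `end - 1` on the minus strand.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand = "+",
                       layout = NULL) {
  strand <- rep_len(as.character(strand), length(gene_id))
  assert_that(all(strand %in% c("+", "-")), "gene strand must be '+' or '-'")
  assert_that(!anyDuplicated(gene_id), "duplicate gene ids")
  fs <- feature_set(chrom, start, end, name = as.character(gene_id),
                    strand = strand, layout = layout)
  df <- data.frame(gene_id = fs$name, chrom = fs$chrom, start = fs$start,
                   end = fs$end, strand = fs$strand,
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  class(df) <- c("gene_table", "data.frame")
  attr(df, "layout") <- layout
  df
}

#' Read genes from a BED6 file
#'
#' @inheritParams read_bed_intervals
#' @return A [gene_table()].
#' @export
read_gene_bed <- function(path, layout = NULL, chrom_alias = NULL) {
  fs <- read_bed_intervals(path, layout = layout, chrom_alias = chrom_alias)
  assert_that(!all(is.na(fs$strand)), "gene BED must carry a strand column")
  gene_table(fs$name, fs$chrom, fs$start, fs$end, fs$strand, layout = layout)
}

#' Read a TPM expression table
#'
#' Tab-separated, header row, first column gene ids, remaining columns one
#' per cell type.
#'
#' @param path TSV path.
#' @return An `expression_table`: numeric matrix, genes in rows, cell types
#'   in columns.
#' @export
read_expression_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "")
  assert_that(ncol(df) >= 2, "expression table needs gene ids plus >= 1 cell type")
  assert_that(!anyDuplicated(df[[1]]), "duplicate gene ids in expression table")
  assert_that(!anyDuplicated(names(df)[-1]),
              "duplicate cell-type columns in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression table contains negative or non-numeric TPM values",
         call. = FALSE)
  }
  class(m) <- c("expression_table", class(m))
  m
}

#' Write a TPM expression table
#'
#' @param tpm Matrix (genes x cell types) with rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), unclass(tpm),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sequence accessor over a FASTA file
#'
#' @param path FASTA path (plain text).
#' @return A function `f(chrom, start, end)` returning the 0-based half-open
#'   subsequence as a character string.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  function(chrom, start, end) {
    assert_that(chrom %in% names(seqs), paste0("unknown sequence ", chrom))
    len <- length(seqs[[chrom]])
    assert_that(start >= 0 && end <= len && start < end,
                "subsequence out of range")
    as.character(Biostrings::subseq(seqs[[chrom]], start + 1, end))
  }
}
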