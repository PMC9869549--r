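#' 2x2 bin-count contingency table for a state vs a feature
#'
#' Counts assigned bins split by (carrying `state_label`) x (overlapping the
#' feature set by at least `min_overlap` bp): `a` in-state and overlapping,
#' `b` in-state only, `c` overlapping only, `d` the remainder.
#'
#' @param calls Labeled [state_calls()].
#' @param feature A [feature_set()] on the same layout.
#' @param state_label Label of interest (e.g. `"T1-LAD"`).
#' @param min_overlap Minimum overlap in bp to count a bin as hit (default
#'   1).
#' @return Named integer vector `c(a, b, c, d)` with
#'   `a + b + c + d = number of assigned bins`.
#' @export
bin_overlap_table <- function(calls, feature, state_label, min_overlap = 1L) {
  stopifnot(inherits(calls, "state_calls"))
  lab <- call_labels(calls)
  assigned <- !is.na(lab)
  hit <- rep(FALSE, n_bins(calls$grid))
  if (nrow(feature) > 0) {
    ov <- GenomicRanges::findOverlaps(grid_granges(calls$grid),
                                      as_granges(feature),
                                      minoverlap = as.integer(min_overlap))
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  in_state <- assigned & lab == state_label
  c(a = sum(assigned & in_state & hit),
    b = sum(assigned & in_state & !hit),
    c = sum(assigned & !in_state & hit),
    d = sum(assigned & !in_state & !hit))
}

#' Odds ratio and Fisher exact test for a 2x2 table
#'
#' OR = (a d)/(b c), with Haldane 0.5 added to every cell iff any cell is
#' zero. The two-sided Fisher p-value sums, over all tables with the observed
#' margins, the hypergeometric probabilities no larger than that of the
#' observed table (point-probability rule, with the conventional 1e-7
#' relative slack against ties at machine precision).
#'
#' @param table Named or ordered vector `c(a, b, c, d)` of nonnegative
#'   counts.
#' @param feature,state Optional names echoed into the result.
#' @return An `enrichment_result`: `odds_ratio`, `corrected`, `p_value`,
#'   `table`.
#' @export
odds_ratio_fisher <- function(table, feature = NA_character_,
                              state = NA_character_) {
  stopifnot(length(table) == 4, all(table >= 0))
  a <- table[[1]]; b <- table[[2]]; c_ <- table[[3]]; d <- table[[4]]
  assert_that(sum(table) > 0, "all-zero contingency table")
  or <- haldane_or(a, b, c_, d)
  # hypergeometric over tables with margins fixed: x = a varies
  m <- a + b          # in-state bins
  n_ <- c_ + d        # out-of-state bins
  k <- a + c_         # feature-overlapping bins
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(odds_ratio = or$or, corrected = or$corrected, p_value = p,
                 table = c(a = a, b = b, c = c_, d = d),
                 feature = feature, state = state),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> OR ", signif(x$odds_ratio, 4),
      if (x$corrected) " (Haldane-corrected)", ", Fisher p ",
      format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Permutation z-score for state-feature association
#'
#' The null preserves the domain run-length structure: each permutation
#' applies an independent uniform circular rotation of the state-label
#' vector over the assigned bins within each chromosome. The z-score
#' compares the observed in-state-and-overlapping bin count `a` against the
#' rotation null.
#'
#' @inheritParams bin_overlap_table
#' @param n_perm Number of rotations (>= 100).
#' @param seed RNG seed.
#' @return List: `z` (`NA` with a warning when the null is degenerate),
#'   `a_obs`, `null_mean`, `null_sd`, `n_perm`.
#' @export
permutation_zscore <- function(calls, feature, state_label, n_perm = 1000,
                               seed = 1, min_overlap = 1L) {
  assert_that(n_perm >= 100, "need at least 100 permutations")
  lab <- call_labels(calls)
  hit <- rep(FALSE, n_bins(calls$grid))
  if (nrow(feature) > 0) {
    ov <- GenomicRanges::findOverlaps(grid_granges(calls$grid),
                                      as_granges(feature),
                                      minoverlap = as.integer(min_overlap))
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  assigned_idx <- split(which(!is.na(lab)),
                        calls$grid$chrom[!is.na(lab)])
  assigned_idx <- assigned_idx[lengths(assigned_idx) > 0]
  a_obs <- sum(lab == state_label & hit, na.rm = TRUE)
  a_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      tot <- 0L
      for (idx in assigned_idx) {
        r <- sample.int(length(idx), 1) - 1L
        rotated <- lab[idx][c(seq_len(length(idx))[-seq_len(r)],
                              seq_len(r))]
        tot <- tot + sum(rotated == state_label & hit[idx])
      }
      tot
    }, integer(1))
  })
  nsd <- sd(a_null)
  if (nsd == 0) {
    warning("degenerate permutation null (sd = 0); z reported as NA",
            call. = FALSE)
    z <- NA_real_
  } else {
    z <- (a_obs - mean(a_null)) / nsd
  }
  list(z = z, a_obs = a_obs, null_mean = mean(a_null), null_sd = nsd,
       n_perm = n_perm)
}

#' Fraction of one interval set's bases covered by another
#'
#' @param set_a,set_b Interval data frames (`chrom`, `start`, `end`), each
#'   non-overlapping within itself; `set_a` must be non-empty.
#' @return `sum(overlap bp) / sum(set_a bp)`.
#' @export
base_overlap_fraction <- function(set_a, set_b) {
  assert_that(nrow(set_a) > 0, "empty set_a")
  lv <- union(unique(as.character(set_a$chrom)),
              unique(as.character(set_b$chrom)))
  a <- GenomicRanges::reduce(GenomicRanges::GRanges(
    factor(set_a$chrom, lv), IRanges::IRanges(set_a$start + 1, set_a$end)))
  if (nrow(set_b) == 0) return(0)
  b <- GenomicRanges::reduce(GenomicRanges::GRanges(
    factor(set_b$chrom, lv), IRanges::IRanges(set_b$start + 1, set_b$end)))
  ov <- GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov))) /
    sum(as.numeric(GenomicRanges::width(a)))
}

#' Per-domain GC content by label
#'
#' GC = (#G + #C) / (#A + #C + #G + #T) per domain; ambiguous bases are
#' excluded from the denominator. T1-LADs are expected to show the lowest GC
#' (highest AT) content, then T2-LADs, then nonLADs.
#'
#' @param domains A `domain_set`.
#' @param fasta A [read_fasta()] accessor.
#' @return List: `per_domain` (domains with a `gc` column, `NA` for
#'   all-ambiguous sequence) and `by_label` (label, median GC, median AT).
#' @export
gc_content <- function(domains, fasta) {
  gc <- vapply(seq_len(nrow(domains)), function(i) {
    s <- fasta(domains$chrom[i], domains$start[i], domains$end[i])
    counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                          c("A", "C", "G", "T"))
    tot <- sum(counts)
    if (tot == 0) NA_real_ else (counts[["C"]] + counts[["G"]]) / tot
  }, numeric(1))
  per_domain <- cbind(as.data.frame(domains), gc = gc)
  by_label <- do.call(rbind, lapply(split(gc, domains$label), function(v) {
    data.frame(median_gc = median(v, na.rm = TRUE),
               median_at = 1 - median(v, na.rm = TRUE))
  }))
  by_label <- data.frame(label = rownames(by_label), by_label,
                         row.names = NULL)
  by_label <- by_label[order(match(by_label$label,
                                   label_rank_order(by_label$label))), ]
  list(per_domain = per_domain, by_label = by_label)
}

#' Benjamini-Hochberg adjustment over enrichment results
#'
#' @param results List of [odds_ratio_fisher()] results.
#' @return Data frame with OR, p and BH-adjusted p per result.
#' @export
adjust_enrichment <- function(results) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(feature = r$feature, state = r$state,
               odds_ratio = r$odds_ratio, p_value = r$p_value)
  }))
  df$p_adjusted <- stats::p.adjust(df$p_value, method = "BH")
  df
}
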