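#' Signal extraction scaling (SES) factor for input normalization
#'
#' Estimates the ChIP/input scaling factor from the background portion of the
#' genome. Unmasked bins are ranked by ascending ChIP count (ties broken by
#' ascending input count, then genomic order); cumulative ChIP and input
#' fractions P(i) and Q(i) are accumulated along this ranking, and the
#' background extent k is the rank maximizing Q(i) - P(i) (the point of
#' maximal divergence between the two cumulative curves, i.e. where signal
#' begins to dominate). The factor f = P(k)/Q(k) rescales depth-normalized
#' input so that it matches depth-normalized ChIP over the background bins:
#' f * sum(input_{1..k}) = sum(chip_{1..k}) after both tracks are normalized
#' to equal totals.
#'
#' @param chip,input [count_track()]s on the same grid with positive totals.
#' @return An `ses_result`: `factor` (applied to depth-normalized input),
#'   `k` (background rank), and the diagnostic curves `P` and `Q` along the
#'   ChIP ranking.
#' @export
ses_scale_factor <- function(chip, input) {
  stopifnot(inherits(chip, "count_track"), inherits(input, "count_track"))
  assert_that(same_grid(chip$grid, input$grid), "tracks on different grids")
  ok <- track_ok(chip) & track_ok(input)
  assert_that(sum(ok) >= 10, "fewer than 10 unmasked bins: SES unstable")
  c_ok <- chip$counts[ok]; i_ok <- input$counts[ok]
  assert_that(sum(c_ok) > 0 && sum(i_ok) > 0,
              "all-zero ChIP or input track")
  ord <- order(c_ok, i_ok, seq_along(c_ok))
  P <- cumsum(c_ok[ord]) / sum(c_ok)
  Q <- cumsum(i_ok[ord]) / sum(i_ok)
  k <- which.max(Q - P)
  structure(list(factor = P[k] / Q[k], k = k, P = P, Q = Q,
                 order = which(ok)[ord]),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat("<ses_result> factor ", signif(x$factor, 6), " at background rank ",
      x$k, "/", length(x$P), "\n", sep = "")
  invisible(x)
}

#' Per-bin log2(ChIP / scaled input) track
#'
#' Input counts are first depth-equalized to the ChIP total, then multiplied
#' by the SES factor; the value is `log2((chip + pc) / (f * input_eq + pc))`.
#'
#' @param chip,input [count_track()]s on the same grid.
#' @param ses An [ses_scale_factor()] result (or any list with `$factor`).
#' @param pseudocount Nonnegative pseudocount (default 1) keeping zero-count
#'   bins finite.
#' @return A [binned_track()] of log2 ratios; masked bins `NA`.
#' @export
log2_ratio_track <- function(chip, input, ses = list(factor = 1),
                             pseudocount = 1) {
  stopifnot(inherits(chip, "count_track"), inherits(input, "count_track"))
  assert_that(same_grid(chip$grid, input$grid), "tracks on different grids")
  assert_that(pseudocount >= 0, "negative pseudocount")
  ok <- track_ok(chip) & track_ok(input)
  depth <- sum(chip$counts[ok]) / sum(input$counts[ok])
  values <- rep(NA_real_, n_bins(chip$grid))
  values[ok] <- log2((chip$counts[ok] + pseudocount) /
                     (ses$factor * depth * input$counts[ok] + pseudocount))
  binned_track(chip$grid, values)
}

#' Quantile normalization across tracks
#'
#' Classic quantile normalization over the unmasked bins: each track's rank r
#' is replaced by the mean across tracks of the r-th order statistics, so all
#' tracks end up with identical value distributions. Applied between cell
#' types to damp batch effects. Masked bins are untouched.
#'
#' @param tracks List of >= 2 [binned_track()]s on identical grids with
#'   identical missing-value patterns.
#' @return List of normalized [binned_track()]s, same order.
#' @export
quantile_normalize <- function(tracks) {
  assert_that(length(tracks) >= 2, "need >= 2 tracks")
  g <- tracks[[1]]$grid
  ok <- !is.na(tracks[[1]]$values)
  for (t in tracks) {
    assert_that(same_grid(t$grid, g), "tracks on different grids")
    assert_that(identical(is.na(t$values), !ok),
                "tracks have mismatched masks")
  }
  m <- vapply(tracks, function(t) t$values[ok], numeric(sum(ok)))
  mq <- limma::normalizeQuantiles(m, ties = TRUE)
  lapply(seq_along(tracks), function(i) {
    v <- tracks[[i]]$values
    v[ok] <- mq[, i]
    binned_track(g, v)
  })
}

#' Merge replicate tracks by per-bin median
#'
#' @param tracks List of >= 1 [binned_track()]s on identical grids. A bin
#'   missing in any replicate is missing in the result.
#' @return A [binned_track()].
#' @export
merge_replicates_median <- function(tracks) {
  assert_that(length(tracks) >= 1, "need >= 1 track")
  g <- tracks[[1]]$grid
  for (t in tracks) assert_that(same_grid(t$grid, g),
                                "tracks on different grids")
  if (length(tracks) == 1L) return(tracks[[1]])
  m <- vapply(tracks, `[[`, numeric(n_bins(g)), "values")
  binned_track(g, apply(m, 1, function(r) {
    if (anyNA(r)) NA_real_ else median(r)
  }))
}

#' Classify bins as ChIP-enriched after total-count scaling
#'
#' ChIP counts are scaled so the ChIP total matches the input total; a bin is
#' enriched when its scaled ChIP count strictly exceeds its input count.
#'
#' @param chip,input [count_track()]s on the same grid with positive totals.
#' @return Logical vector, one per bin; `NA` at masked/missing bins.
#' @export
classify_enriched_bins <- function(chip, input) {
  stopifnot(inherits(chip, "count_track"), inherits(input, "count_track"))
  assert_that(same_grid(chip$grid, input$grid), "tracks on different grids")
  ok <- track_ok(chip) & track_ok(input)
  assert_that(sum(chip$counts[ok]) > 0 && sum(input$counts[ok]) > 0,
              "zero-total track")
  scale <- sum(input$counts[ok]) / sum(chip$counts[ok])
  enr <- rep(NA, n_bins(chip$grid))
  enr[ok] <- (chip$counts[ok] * scale) > input$counts[ok]
  enr
}

#' Fraction of fully enriched sliding windows per domain label
#'
#' For each domain label and window size w, slides a window of w consecutive
#' unmasked bins over every domain of that label and reports the fraction of
#' windows whose bins are all positive. A decreasing fraction with window
#' size indicates gaps in enrichment (as seen in T2-LADs relative to
#' T1-LADs).
#'
#' @param track A [binned_track()] of log2 ratios.
#' @param domains A `domain_set` (see [calls_to_domains()]).
#' @param window_sizes Integer vector of window sizes in bins (>= 1).
#' @return Data frame with `label`, `window_bins`, `n_windows`, `fraction`
#'   (NA when no domain of that label can host a window).
#' @export
windowed_enrichment_fraction <- function(track, domains,
                                         window_sizes = c(1, 2, 5, 10)) {
  assert_that(all(window_sizes >= 1), "window sizes must be >= 1")
  g <- track$grid
  labels <- sort(unique(domains$label))
  res <- expand.grid(label = labels, window_bins = sort(window_sizes),
                     stringsAsFactors = FALSE)
  res$n_windows <- 0L
  res$n_enriched <- 0L
  dom_gr <- as_granges(domains)
  hits <- GenomicRanges::findOverlaps(grid_granges(g), dom_gr,
                                      type = "within")
  for (d in seq_len(nrow(domains))) {
    bins <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == d]
    vals <- track$values[bins]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    pos <- cumsum(c(0, vals > 0))
    for (j in which(res$label == domains$label[d])) {
      w <- res$window_bins[j]
      nw <- length(vals) - w + 1
      if (nw < 1) next
      full <- (pos[(w + 1):(length(vals) + 1)] - pos[1:nw]) == w
      res$n_windows[j] <- res$n_windows[j] + nw
      res$n_enriched[j] <- res$n_enriched[j] + sum(full)
    }
  }
  res$fraction <- ifelse(res$n_windows > 0, res$n_enriched / res$n_windows,
                         NA_real_)
  res
}
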