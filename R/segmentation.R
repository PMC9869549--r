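#' Per-bin state calls
#'
#' @param grid A [make_grid()] grid.
#' @param states Integer vector of 0-based state indices, `NA` at
#'   masked/unassigned bins.
#' @param labels Optional character vector of length K mapping state index
#'   `k` to `labels[k + 1]` (e.g. `c("nonLAD", "T2-LAD", "T1-LAD")`).
#' @param cell_type Cell-type name carried into domains and atlas tables.
#' @return A `state_calls`.
#' @export
state_calls <- function(grid, states, labels = NULL, cell_type = "cell") {
  stopifnot(inherits(grid, "bin_grid"))
  states <- as.integer(states)
  assert_that(length(states) == n_bins(grid),
              "state vector length does not match grid")
  states[grid$mask] <- NA_integer_
  if (!is.null(labels)) {
    assert_that(!anyDuplicated(labels), "state labels must be unique")
    assert_that(all(is.na(states) | (states >= 0 &
                                     states < length(labels))),
                "state index outside label map")
  }
  structure(list(grid = grid, states = states, labels = labels,
                 cell_type = cell_type),
            class = "state_calls")
}

#' @export
print.state_calls <- function(x, ...) {
  tab <- table(call_labels(x))
  cat("<state_calls> '", x$cell_type, "': ", sep = "")
  cat(paste0(names(tab), "=", as.integer(tab)), sep = ", ")
  cat(" (", sum(is.na(x$states)), " unassigned)\n", sep = "")
  invisible(x)
}

# Per-bin label vector (NA where unassigned); generic state names when the
# calls are unlabeled.
call_labels <- function(calls) {
  lab <- calls$labels %||% paste0("state", seq_len(max(calls$states,
                                                       na.rm = TRUE) + 1) - 1)
  out <- rep(NA_character_, length(calls$states))
  ok <- !is.na(calls$states)
  out[ok] <- lab[calls$states[ok] + 1]
  out
}

#' Decode a signal track into per-bin state calls
#'
#' Applies a fitted model to the replicate-median, quantile-normalized track:
#' posterior (MAP per bin) decoding by default, Viterbi by flag. Masked bins
#' stay unassigned.
#'
#' @param model A fitted [gaussian_hmm()].
#' @param track A [binned_track()].
#' @param decoder `"map"` (posterior) or `"viterbi"`.
#' @param cell_type Name recorded on the calls.
#' @return A [state_calls()] (unlabeled; see [label_states()]).
#' @export
assign_states <- function(model, track, decoder = c("map", "viterbi"),
                          cell_type = "cell") {
  decoder <- match.arg(decoder)
  obs <- obs_sequences(track)
  states <- rep(NA_integer_, n_bins(track$grid))
  if (length(obs$values)) {
    dec <- if (decoder == "map") {
      posterior_decode(model, obs)$states
    } else {
      viterbi(model, obs)
    }
    for (i in seq_along(obs$bins)) states[obs$bins[[i]]] <- dec[[i]]
  }
  state_calls(track$grid, states, cell_type = cell_type)
}

#' Label states by descending median signal
#'
#' Computes the median track value over the bins of each state and assigns
#' domain-subtype labels in descending order: the state with the highest
#' median signal becomes `T1-<prefix>`, the second `T2-<prefix>`, the lowest
#' `non<prefix>` (three-state scheme; other K get rank labels
#' `R<rank>-<prefix>`). Used with LB1 signal for LADs and H3K9me2 signal for
#' KDDs.
#'
#' @param calls [state_calls()] from [assign_states()].
#' @param track The [binned_track()] the model was decoded on.
#' @param prefix Label scheme suffix, `"LAD"` (default) or `"KDD"`.
#' @return The calls with `labels` filled in.
#' @export
label_states <- function(calls, track, prefix = "LAD") {
  stopifnot(inherits(calls, "state_calls"))
  assert_that(same_grid(calls$grid, track$grid), "calls/track grid mismatch")
  states <- sort(unique(calls$states[!is.na(calls$states)]))
  K <- max(states) + 1L
  med <- vapply(seq_len(K) - 1L, function(k) {
    median(track$values[which(calls$states == k)], na.rm = TRUE)
  }, numeric(1))
  if (anyDuplicated(med[!is.na(med)])) {
    warning("tied state medians; breaking ties by state index",
            call. = FALSE)
  }
  rank_desc <- order(-med, seq_len(K))   # ties toward lower state index
  lab <- if (K == 3) {
    c(paste0("T1-", prefix), paste0("T2-", prefix), paste0("non", prefix))
  } else {
    paste0("R", seq_len(K), "-", prefix)
  }
  labels <- character(K)
  labels[rank_desc] <- lab
  calls$labels <- labels
  calls
}

#' Merge labeled calls into BED-ready domains
#'
#' Maximal runs of consecutive same-label bins become one interval; runs are
#' broken by chromosome ends and by masked bins (no bridging across
#' blacklist gaps).
#'
#' @param calls Labeled [state_calls()].
#' @return A `domain_set` data frame (`chrom`, `start`, `end`, `label`,
#'   `cell_type`), 0-based half-open, with the grid's layout attached.
#' @export
calls_to_domains <- function(calls) {
  stopifnot(inherits(calls, "state_calls"))
  assert_that(!is.null(calls$labels), "calls must be labeled first")
  g <- calls$grid
  lab <- call_labels(calls)
  key <- paste(g$chrom, lab)       # NA label yields "chrom NA": breaks runs
  new_run <- c(TRUE, key[-1] != head(key, -1))
  run_id <- cumsum(new_run)
  keep <- !is.na(lab)
  idx <- split(seq_along(lab)[keep], run_id[keep])
  df <- data.frame(
    chrom = vapply(idx, function(i) g$chrom[i[1]], character(1)),
    start = vapply(idx, function(i) g$start[i[1]], numeric(1)),
    end = vapply(idx, function(i) g$end[i[length(i)]], numeric(1)),
    label = vapply(idx, function(i) lab[i[1]], character(1)),
    cell_type = calls$cell_type, row.names = NULL)
  class(df) <- c("domain_set", "data.frame")
  attr(df, "layout") <- g$layout
  df
}

#' Project domains back onto per-bin calls
#'
#' Inverse of [calls_to_domains()] for bins fully contained in a domain; used
#' to load deposited domain BEDs onto a grid and in round-trip checks.
#'
#' @param domains A `domain_set` (or [feature_set()] with a name column).
#' @param grid Target [make_grid()] grid.
#' @param labels Label map (state index order); defaults to the T1/T2/non
#'   ordering of the labels present.
#' @param cell_type Cell-type name for the calls.
#' @return A labeled [state_calls()].
#' @export
domains_to_calls <- function(domains, grid, labels = NULL,
                             cell_type = domains$cell_type[1] %||% "cell") {
  lab_col <- if ("label" %in% names(domains)) domains$label else domains$name
  labels <- labels %||% label_rank_order(unique(lab_col))
  hits <- GenomicRanges::findOverlaps(grid_granges(grid), as_granges(domains),
                                      type = "within")
  states <- rep(NA_integer_, n_bins(grid))
  states[S4Vectors::queryHits(hits)] <-
    match(lab_col[S4Vectors::subjectHits(hits)], labels) - 1L
  state_calls(grid, states, labels = labels, cell_type = cell_type)
}

# Canonical label ordering: T1 first, then T2, then non*, then the rest
# alphabetically.
label_rank_order <- function(labels) {
  rank <- ifelse(grepl("^T1", labels), 1,
          ifelse(grepl("^T2", labels), 2,
          ifelse(grepl("^non", labels), 3, 4)))
  labels[order(rank, labels)]
}

#' Domain size and coverage summaries
#'
#' Per cell type and label: domain count, median and mean length, total bp,
#' fraction of the genome and fraction of the assigned (unmasked) genome.
#' When several cell types are present, the attribute `across_cell_types`
#' summarizes each label by the median of per-cell-type median sizes and the
#' mean genome fraction (the "median across cell types" convention).
#'
#' @param domains A `domain_set`.
#' @param grid The [make_grid()] grid the calls were made on.
#' @return Data frame of per-(cell type, label) summaries.
#' @export
domain_stats <- function(domains, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  genome_bp <- sum(grid$layout$length)
  assigned_bp <- sum((grid$end - grid$start)[!grid$mask])
  len <- domains$end - domains$start
  grp <- split(seq_len(nrow(domains)),
               list(cell_type = domains$cell_type, label = domains$label),
               drop = TRUE)
  res <- do.call(rbind, lapply(names(grp), function(gn) {
    i <- grp[[gn]]
    data.frame(cell_type = domains$cell_type[i[1]],
               label = domains$label[i[1]], n = length(i),
               median_bp = median(len[i]), mean_bp = mean(len[i]),
               total_bp = sum(len[i]),
               frac_genome = sum(len[i]) / genome_bp,
               frac_assigned = sum(len[i]) / assigned_bp)
  }))
  rownames(res) <- NULL
  res <- res[order(match(res$label, label_rank_order(unique(res$label))),
                   res$cell_type), ]
  across <- do.call(rbind, lapply(split(res, res$label), function(d) {
    data.frame(label = d$label[1],
               median_of_medians_bp = median(d$median_bp),
               pooled_median_bp = median(
                 len[domains$label == d$label[1]]),
               mean_frac_genome = mean(d$frac_genome),
               mean_frac_assigned = mean(d$frac_assigned))
  }))
  rownames(across) <- NULL
  attr(res, "across_cell_types") <- across
  res
}

#' Mean signal around oriented domain boundaries
#'
#' Finds every adjacency where a `pair[1]` domain directly abuts a `pair[2]`
#' domain, orients each so the `pair[1]` side lies at negative offsets
#' (right-to-left adjacencies are mirrored), and averages the track per
#' offset over all boundaries. Offsets are bin centers relative to the
#' boundary, so the profile is symmetric about 0.
#'
#' @param track A [binned_track()] of signal.
#' @param domains A `domain_set`.
#' @param pair Character pair `c(labelLow, labelHigh)`, e.g.
#'   `c("nonLAD", "T2-LAD")`.
#' @param flank_bp Flank on each side in bp; must be a multiple of the bin
#'   size (default 1e5, i.e. 100 kb).
#' @return Data frame `offset_bp`, `mean_signal`, `n_bins` with attributes
#'   `n_boundaries` and `pair`; zero rows of NA mean signal when no adjacency
#'   exists.
#' @export
boundary_profile <- function(track, domains, pair, flank_bp = 1e5) {
  g <- track$grid
  bs <- g$bin_size
  assert_that(flank_bp %% bs == 0, "flank must be a multiple of bin size")
  w <- flank_bp %/% bs
  d <- domains[order(match(domains$chrom, g$layout$chrom), domains$start), ]
  same_chrom <- d$chrom[-1] == head(d$chrom, -1)
  abut <- same_chrom & (d$start[-1] == head(d$end, -1))
  fwd <- abut & head(d$label, -1) == pair[1] & d$label[-1] == pair[2]
  rev <- abut & head(d$label, -1) == pair[2] & d$label[-1] == pair[1]
  boundaries <- data.frame(
    chrom = d$chrom[c(which(fwd), which(rev)) + 1],
    pos = d$start[c(which(fwd), which(rev)) + 1],
    orient = rep(c(1, -1), c(sum(fwd), sum(rev))))
  offsets <- c(-(w:1), 1:w) * bs - c(-rep(bs / 2, w), rep(bs / 2, w))
  first_bin <- setNames(cumsum(c(0, head(tabulate(
    factor(g$chrom, levels = g$layout$chrom)), -1))), g$layout$chrom)
  sums <- counts <- numeric(2 * w)
  for (b in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[b]
    bin0 <- boundaries$pos[b] %/% bs            # chromosome-local right bin
    rel <- c(-(w:1), 0:(w - 1))                 # bins left then right
    # mirrored adjacency: the bin centered at +x fills the -x offset slot
    if (boundaries$orient[b] < 0) rel <- -rel - 1
    bins <- first_bin[[ch]] + bin0 + rel + 1
    nchrom <- sum(g$chrom == ch)
    valid <- bin0 + rel >= 0 & bin0 + rel < nchrom
    v <- rep(NA_real_, 2 * w)
    v[valid] <- track$values[bins[valid]]
    okv <- !is.na(v)
    sums[okv] <- sums[okv] + v[okv]
    counts[okv] <- counts[okv] + 1
  }
  res <- data.frame(offset_bp = offsets,
                    mean_signal = ifelse(counts > 0, sums / counts, NA_real_),
                    n_bins = counts)
  attr(res, "n_boundaries") <- nrow(boundaries)
  attr(res, "pair") <- pair
  res
}

#' Labeled transition-matrix report
#'
#' Reorders the fitted transition matrix into T1, T2, non order (descending
#' signal rank) and optionally log2-transforms it for display; zero entries
#' become `-Inf` under the transform.
#'
#' @param model A fitted [gaussian_hmm()].
#' @param labels Label map from [label_states()] calls (state index order).
#' @param log2 Apply elementwise log2.
#' @return Labeled K x K matrix, rows summing to 1 when untransformed.
#' @export
transition_report <- function(model, labels, log2 = FALSE) {
  stopifnot(inherits(model, "gaussian_hmm"))
  assert_that(length(labels) == model$K, "label map does not match K")
  ord <- match(label_rank_order(labels), labels)
  A <- model$A[ord, ord, drop = FALSE]
  dimnames(A) <- list(labels[ord], labels[ord])
  if (log2) base::log2(A) else A
}
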