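#' Atlas of state calls across cell types on one grid
#'
#' @param calls List of labeled [state_calls()], one per cell type, on
#'   identical grids and label schemes.
#' @return An `atlas_calls`: `grid`, per-bin label matrix (bins x cell
#'   types), and `assigned` — the logical mask of bins assigned in every cell
#'   type, the denominator of all invariance statistics ("assigned genome").
#' @export
build_atlas <- function(calls) {
  assert_that(length(calls) >= 2, "atlas needs >= 2 cell types")
  g <- calls[[1]]$grid
  scheme <- label_rank_order(calls[[1]]$labels)
  labmat <- vapply(calls, function(cl) {
    assert_that(same_grid(cl$grid, g), "calls on different grids")
    assert_that(identical(label_rank_order(cl$labels), scheme),
                "calls use different label schemes")
    call_labels(cl)
  }, character(n_bins(g)))
  colnames(labmat) <- vapply(calls, `[[`, character(1), "cell_type")
  assert_that(!anyDuplicated(colnames(labmat)), "duplicate cell-type names")
  assigned <- rowSums(is.na(labmat)) == 0
  if (!any(assigned)) warning("no bin assigned in all cell types",
                              call. = FALSE)
  structure(list(grid = g, labels = labmat, scheme = scheme,
                 assigned = assigned),
            class = "atlas_calls")
}

#' @export
print.atlas_calls <- function(x, ...) {
  cat("<atlas_calls> ", ncol(x$labels), " cell types, ",
      sum(x$assigned), "/", n_bins(x$grid), " bins assigned\n", sep = "")
  invisible(x)
}

# Bin-width vector of the atlas grid, for bp-weighted fractions.
atlas_cell_types <- function(atlas) colnames(atlas$labels)

#' Invariance fraction of a cell-type subset
#'
#' Fraction of the assigned genome (bins assigned in every subset member)
#' holding the same state across the subset. Modes: `"T1"` / `"T2"` — the
#' same single subtype in every member; `"combined"` — the union of the T1-
#' and T2-invariant bins (disjoint events, so it equals the sum);
#' `"genome"` — any identical label, including the non state.
#'
#' @param atlas An [build_atlas()] atlas.
#' @param subset Character vector of >= 2 cell-type names (default: all).
#' @param mode One of `"T1"`, `"T2"`, `"combined"`, `"genome"`.
#' @return Fraction in `[0, 1]`.
#' @export
invariance_fraction <- function(atlas, subset = atlas_cell_types(atlas),
                                mode = c("combined", "T1", "T2", "genome")) {
  mode <- match.arg(mode)
  assert_that(length(subset) >= 2, "subset must contain >= 2 cell types")
  assert_that(all(subset %in% atlas_cell_types(atlas)),
              "unknown cell type in subset")
  m <- atlas$labels[, subset, drop = FALSE]
  ok <- rowSums(is.na(m)) == 0
  same <- ok & rowSums(m == m[, 1]) == ncol(m)
  denom <- sum(ok)
  if (denom == 0) return(NA_real_)
  # combined = T1 + T2 exactly (disjoint events), so compute it as the sum
  # of the per-subtype fractions rather than re-counting the union
  if (mode == "combined") {
    return(invariance_fraction(atlas, subset, "T1") +
             invariance_fraction(atlas, subset, "T2"))
  }
  hit <- switch(mode,
    T1 = same & m[, 1] == label_of(atlas, "T1"),
    T2 = same & m[, 1] == label_of(atlas, "T2"),
    genome = same)
  sum(hit) / denom
}

label_of <- function(atlas, rank) {
  hit <- grep(paste0("^", rank), atlas$scheme, value = TRUE)
  assert_that(length(hit) == 1, paste0("no unique ", rank, " label"))
  hit
}

#' Invariance as a function of the number of cell types compared
#'
#' For each subset size k, evaluates [invariance_fraction()] over all
#' `choose(n, k)` subsets when that count is at most `exhaustive_threshold`,
#' otherwise over `n_samples` distinct subsets drawn without replacement
#' under `seed`.
#'
#' @inheritParams invariance_fraction
#' @param k_range Subset sizes (within 2..number of cell types).
#' @param modes Invariance modes to evaluate.
#' @param n_samples Subsets sampled per k when not exhaustive.
#' @param exhaustive_threshold Enumerate exhaustively up to this many
#'   subsets (default 500).
#' @param seed Sampling seed.
#' @return Data frame `k`, `mode`, `mean`, `sd`, `n_subsets`, `exhaustive`.
#' @export
invariance_curve <- function(atlas, k_range = 2:length(atlas_cell_types(atlas)),
                             modes = c("T1", "T2", "combined", "genome"),
                             n_samples = 100, exhaustive_threshold = 500,
                             seed = 1) {
  cts <- atlas_cell_types(atlas)
  assert_that(all(k_range >= 2 & k_range <= length(cts)),
              "k range outside [2, n cell types]")
  rows <- list()
  for (k in sort(k_range)) {
    n_total <- choose(length(cts), k)
    if (n_total <= exhaustive_threshold) {
      subsets <- combn(cts, k, simplify = FALSE)
      exhaustive <- TRUE
    } else {
      subsets <- with_seed(derive_seed(seed, k), {
        seen <- character(0)
        out <- list()
        while (length(out) < n_samples) {
          s <- sort(sample(cts, k))
          key <- paste(s, collapse = "|")
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1]] <- s
          }
        }
        out
      })
      exhaustive <- FALSE
    }
    for (mode in modes) {
      f <- vapply(subsets, function(s) {
        invariance_fraction(atlas, s, mode)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        k = k, mode = mode, mean = mean(f),
        sd = if (length(f) > 1) sd(f) else NA_real_,
        n_subsets = length(f), exhaustive = exhaustive)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise T1 vs T2 invariance comparison
#'
#' For every cell-type pair, counts the bins labeled T1 (resp. T2) in the
#' first member that retain the same label in the second. Reports the
#' invariant fraction of the assigned genome per subtype, a 2x2 odds ratio
#' (subtype x invariant) with Haldane 0.5 correction when a zero cell
#' occurs, and, across pairs, a paired two-sided t-test of the T1 vs T2
#' fractions.
#'
#' @param atlas An [build_atlas()] atlas.
#' @return List with `pairs` (per-pair table: fractions of assigned genome,
#'   conditional retention rates, odds ratio) and `t_test`
#'   (`stats::t.test` result or `NULL` when degenerate).
#' @export
pairwise_invariance_comparison <- function(atlas) {
  cts <- atlas_cell_types(atlas)
  t1 <- label_of(atlas, "T1"); t2 <- label_of(atlas, "T2")
  prs <- combn(cts, 2, simplify = FALSE)
  rows <- lapply(prs, function(p) {
    m <- atlas$labels[, p, drop = FALSE]
    ok <- rowSums(is.na(m)) == 0
    denom <- sum(ok)
    is_t1 <- ok & m[, 1] == t1
    is_t2 <- ok & m[, 1] == t2
    if (!any(is_t1) || !any(is_t2)) {
      warning("pair ", p[1], "/", p[2], " lacks T1 or T2 bins; skipped",
              call. = FALSE)
      return(NULL)
    }
    a <- sum(is_t1 & m[, 2] == t1)   # T1 bins staying T1
    b <- sum(is_t1) - a
    c_ <- sum(is_t2 & m[, 2] == t2)  # T2 bins staying T2
    d <- sum(is_t2) - c_
    or <- haldane_or(a, b, c_, d)
    data.frame(cell_a = p[1], cell_b = p[2],
               frac_T1 = a / denom, frac_T2 = c_ / denom,
               retention_T1 = a / (a + b), retention_T2 = c_ / (c_ + d),
               odds_ratio = or$or, corrected = or$corrected)
  })
  pairs <- do.call(rbind, rows)
  tt <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 2 &&
      sd(pairs$frac_T1 - pairs$frac_T2) > 0) {
    tt <- t.test(pairs$frac_T1, pairs$frac_T2, paired = TRUE)
  }
  list(pairs = pairs, t_test = tt)
}

haldane_or <- function(a, b, c_, d) {
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(or = (a * d) / (b * c_), corrected = corrected)
}

#' Percentile of a focal subset's invariance among size-matched subsets
#'
#' Evaluates [invariance_fraction()] for every subset of the same size and
#' reports the focal subset's percentile rank: the fraction of subsets with
#' strictly smaller invariance, times 100. Used to ask whether
#' developmentally related cell types (e.g. the four differentiated mesoderm
#' types) are more invariant than random backgrounds.
#'
#' @inheritParams invariance_fraction
#' @param focal_subset Character vector of cell types.
#' @return List: `percentile`, `focal_fraction`, `distribution` (all subset
#'   fractions), `n_subsets`.
#' @export
subset_percentile <- function(atlas, focal_subset, mode = "genome") {
  cts <- atlas_cell_types(atlas)
  assert_that(all(focal_subset %in% cts), "unknown focal cell type")
  k <- length(focal_subset)
  subsets <- combn(cts, k, simplify = FALSE)
  f <- vapply(subsets, function(s) invariance_fraction(atlas, s, mode),
              numeric(1))
  focal <- invariance_fraction(atlas, focal_subset, mode)
  list(percentile = 100 * sum(f < focal) / length(f),
       focal_fraction = focal, distribution = f, n_subsets = length(f))
}

#' Assign each gene a domain state per cell type
#'
#' Rule `"majority"`: the label whose assigned bins overlap the gene body by
#' the most bp, ties broken by the TSS bin's label; rule `"tss"`: the label
#' of the bin containing the TSS. Genes overlapping no assigned bin are
#' unassigned (`NA`).
#'
#' @param calls Labeled [state_calls()] (one cell type) or a list of them.
#' @param genes A [gene_table()].
#' @param rule `"majority"` (default) or `"tss"`.
#' @return A `gene_state_assignment` data frame: `gene_id` plus one label
#'   column per cell type; attribute `rule`.
#' @export
assign_gene_states <- function(calls, genes, rule = c("majority", "tss")) {
  rule <- match.arg(rule)
  if (inherits(calls, "state_calls")) calls <- list(calls)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  for (cl in calls) {
    lab <- call_labels(cl)
    g <- cl$grid
    tss_bin <- bin_at(g, genes$chrom, genes$tss)
    tss_lab <- ifelse(is.na(tss_bin), NA_character_, lab[tss_bin])
    if (rule == "tss") {
      out[[cl$cell_type]] <- tss_lab
      next
    }
    hits <- GenomicRanges::findOverlaps(gene_gr, grid_granges(g))
    ov <- GenomicRanges::pintersect(
      gene_gr[S4Vectors::queryHits(hits)],
      grid_granges(g)[S4Vectors::subjectHits(hits)])
    dfh <- data.frame(gene = S4Vectors::queryHits(hits),
                      label = lab[S4Vectors::subjectHits(hits)],
                      bp = GenomicRanges::width(ov))
    dfh <- dfh[!is.na(dfh$label), , drop = FALSE]
    assigned <- rep(NA_character_, nrow(genes))
    if (nrow(dfh)) {
      agg <- stats::aggregate(bp ~ gene + label, dfh, sum)
      for (gi in unique(agg$gene)) {
        sub <- agg[agg$gene == gi, ]
        best <- sub$label[sub$bp == max(sub$bp)]
        assigned[gi] <- if (length(best) == 1) {
          best
        } else if (!is.na(tss_lab[gi]) && tss_lab[gi] %in% best) {
          tss_lab[gi]
        } else {
          label_rank_order(best)[1]
        }
      }
    }
    out[[cl$cell_type]] <- assigned
  }
  attr(out, "rule") <- rule
  class(out) <- c("gene_state_assignment", "data.frame")
  out
}

# Global bin index containing position pos (bp, 0-based) on chrom; NA when
# the bin is masked or the chromosome unknown.
bin_at <- function(grid, chrom, pos) {
  first_bin <- setNames(cumsum(c(0, head(tabulate(
    factor(grid$chrom, levels = grid$layout$chrom)), -1))),
    grid$layout$chrom)
  idx <- first_bin[chrom] + pos %/% grid$bin_size + 1
  idx[is.na(first_bin[chrom]) | pos < 0 |
        pos >= grid$layout$length[chrom]] <- NA
  as.integer(idx)
}

#' Gene flows between domain states of two cell types
#'
#' @param assignment An [assign_gene_states()] table covering both cell
#'   types.
#' @param cell_a,cell_b Cell-type column names (`a` = rows, `b` = columns).
#' @return List: `flows` (K x K count matrix in T1, T2, non order),
#'   `n_unassigned` (genes lacking a state in either cell type).
#' @export
gene_state_transitions <- function(assignment, cell_a, cell_b) {
  assert_that(all(c(cell_a, cell_b) %in% names(assignment)),
              "cell type missing from assignment")
  a <- assignment[[cell_a]]; b <- assignment[[cell_b]]
  ok <- !is.na(a) & !is.na(b)
  labs <- label_rank_order(unique(c(a[ok], b[ok])))
  flows <- table(factor(a[ok], levels = labs), factor(b[ok], levels = labs))
  flows <- unclass(as.matrix(flows))
  names(dimnames(flows)) <- c(cell_a, cell_b)
  list(flows = flows, n_unassigned = sum(!ok))
}

#' Proportion of genes expressed per domain state
#'
#' Per cell type and label, the fraction of assigned genes with
#' TPM strictly above `threshold_tpm` (default 5), plus the mean and sd of
#' that proportion across cell types.
#'
#' @param assignment An [assign_gene_states()] table.
#' @param expression An [read_expression_table()] matrix (genes x cell
#'   types).
#' @param threshold_tpm Expression call threshold (>= 0).
#' @return List: `per_cell_type` (cell_type, label, n_genes, proportion) and
#'   `summary` (label, mean, sd across cell types).
#' @export
proportion_expressed <- function(assignment, expression, threshold_tpm = 5) {
  assert_that(threshold_tpm >= 0, "threshold must be >= 0")
  cts <- intersect(names(assignment)[-1], colnames(expression))
  assert_that(length(cts) > 0, "no shared cell types")
  genes <- intersect(assignment$gene_id, rownames(expression))
  rows <- list()
  for (ct in cts) {
    lab <- assignment[[ct]][match(genes, assignment$gene_id)]
    expr <- expression[genes, ct] > threshold_tpm
    for (l in label_rank_order(unique(lab[!is.na(lab)]))) {
      sel <- !is.na(lab) & lab == l
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, label = l, n_genes = sum(sel),
        proportion = if (any(sel)) mean(expr[sel]) else NA_real_)
    }
  }
  per_ct <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_ct, per_ct$label), function(d) {
    data.frame(label = d$label[1], mean = mean(d$proportion, na.rm = TRUE),
               sd = sd(d$proportion))
  }))
  rownames(summ) <- NULL
  list(per_cell_type = per_ct, summary = summ)
}

#' Expression fold change grouped by domain-state transition
#'
#' Per gene, log2((TPM_target + pc) / (TPM_ref + pc)); genes are grouped by
#' their (reference state -> target state) transition and a one-way ANOVA
#' tests whether mean fold change differs across transition groups (genes
#' moving into higher-contact states are expected to go down, and vice
#' versa).
#'
#' @param assignment An [assign_gene_states()] table.
#' @param expression Genes x cell types TPM matrix.
#' @param reference_cell_type,target_cell_type Column names present in both
#'   tables.
#' @param pseudocount_tpm Pseudocount (default 1).
#' @return List: `groups` (transition, n, mean_lfc, sd_lfc), `anova`
#'   (data frame with F and p, or `NULL` with a warning when fewer than two
#'   non-empty groups), `lfc` (per-gene values with transitions).
#' @export
expression_fold_change_by_transition <- function(assignment, expression,
                                                 reference_cell_type,
                                                 target_cell_type,
                                                 pseudocount_tpm = 1) {
  assert_that(all(c(reference_cell_type, target_cell_type) %in%
                    names(assignment)), "cell type missing from assignment")
  assert_that(all(c(reference_cell_type, target_cell_type) %in%
                    colnames(expression)), "cell type missing from expression")
  genes <- intersect(assignment$gene_id, rownames(expression))
  ref <- assignment[[reference_cell_type]][match(genes, assignment$gene_id)]
  tgt <- assignment[[target_cell_type]][match(genes, assignment$gene_id)]
  ok <- !is.na(ref) & !is.na(tgt)
  lfc <- log2((expression[genes, target_cell_type] + pseudocount_tpm) /
              (expression[genes, reference_cell_type] + pseudocount_tpm))
  df <- data.frame(gene_id = genes[ok],
                   transition = paste0(ref[ok], "->", tgt[ok]),
                   lfc = lfc[ok])
  groups <- do.call(rbind, lapply(split(df, df$transition), function(d) {
    data.frame(transition = d$transition[1], n = nrow(d),
               mean_lfc = mean(d$lfc), sd_lfc = sd(d$lfc))
  }))
  rownames(groups) <- NULL
  aov_res <- NULL
  if (length(unique(df$transition)) >= 2) {
    fit <- anova(aov(lfc ~ transition, data = df))
    aov_res <- data.frame(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
                          df_between = fit$Df[1], df_within = fit$Df[2])
  } else {
    warning("fewer than 2 non-empty transition groups; ANOVA skipped",
            call. = FALSE)
  }
  list(groups = groups, anova = aov_res, lfc = df)
}
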