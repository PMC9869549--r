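# 20-bin, 3-cell-type toy atlas with hand-placed labels.
toy_atlas <- function() {
  grid <- toy_grid(c(chr1 = 4e5), bin = 2e4)  # 20 bins
  L <- c("T1-LAD", "T2-LAD", "nonLAD")
  a <- rep(L, c(8, 6, 6))
  b <- a; b[9:10] <- "T1-LAD"        # two T2 bins gain T1 in b
  c_ <- a; c_[1:2] <- "T2-LAD"; c_[15] <- "T2-LAD"
  list(grid = grid,
       calls = list(toy_calls(grid, a, cell_type = "ctA"),
                    toy_calls(grid, b, cell_type = "ctB"),
                    toy_calls(grid, c_, cell_type = "ctC")),
       labels = list(a = a, b = b, c = c_))
}

test_that("invariance fractions equal bin-by-bin brute force on a toy atlas", {
  ta <- toy_atlas()
  atlas <- build_atlas(ta$calls)
  lab <- ta$labels
  brute <- function(members, want) {
    same <- Reduce(`&`, lapply(members[-1], function(m) m == members[[1]]))
    mean(same & members[[1]] %in% want)
  }
  for (subset in list(c("ctA", "ctB"), c("ctA", "ctC"),
                      c("ctA", "ctB", "ctC"))) {
    members <- lab[match(subset, c("ctA", "ctB", "ctC"))]
    expect_equal(invariance_fraction(atlas, subset, "T1"),
                 brute(members, "T1-LAD"))
    expect_equal(invariance_fraction(atlas, subset, "T2"),
                 brute(members, "T2-LAD"))
    expect_equal(invariance_fraction(atlas, subset, "combined"),
                 brute(members, c("T1-LAD", "T2-LAD")))
    expect_equal(invariance_fraction(atlas, subset, "genome"),
                 brute(members, c("T1-LAD", "T2-LAD", "nonLAD")))
  }
  # identical members are fully invariant
  atlas2 <- build_atlas(list(ta$calls[[1]],
                             toy_calls(ta$grid, lab$a, cell_type = "dup")))
  expect_equal(invariance_fraction(atlas2, mode = "genome"), 1.0)
})

test_that("combined invariance is exactly T1 + T2 and genome-wide dominates", {
  cfg <- sim_config(chrom_lengths = c(chrS1 = 1e8), n_cell_types = 4)
  truth <- simulate_atlas(cfg, seed = 5)
  atlas <- build_atlas(truth$calls)
  cts <- colnames(atlas$labels)
  for (subset in list(cts[1:2], cts[c(1, 3)], cts, cts[2:4])) {
    t1 <- invariance_fraction(atlas, subset, "T1")
    t2 <- invariance_fraction(atlas, subset, "T2")
    comb <- invariance_fraction(atlas, subset, "combined")
    expect_identical(comb, t1 + t2)
    expect_gte(invariance_fraction(atlas, subset, "genome"), comb)
  }
})

test_that("invariance curves are monotone non-increasing under enumeration", {
  cfg <- sim_config(chrom_lengths = c(chrS1 = 6e7), n_cell_types = 5)
  truth <- simulate_atlas(cfg, seed = 23)
  atlas <- build_atlas(truth$calls)
  curve <- invariance_curve(atlas, k_range = 2:5, seed = 1)
  expect_true(all(curve$exhaustive))
  for (m in unique(curve$mode)) {
    expect_true(all(diff(curve$mean[curve$mode == m]) <= 1e-12))
  }
})

test_that("simulated atlas invariance matches the closed-form expectation", {
  cfg <- sim_config()   # 2e4 bins, 3 cell types, switch prob 0.2
  truth <- simulate_atlas(cfg, seed = 41)
  atlas <- build_atlas(truth$calls)
  # Monte-Carlo error scale: runs move as blocks, so use the run count
  n_runs <- nrow(calls_to_domains(truth$calls[[1]]))
  for (mode in c("T1", "T2", "combined", "genome")) {
    obs <- invariance_fraction(atlas, c("ct1", "ct2"), mode)
    exp_ <- expected_invariance(truth, 1:2, mode)
    se <- sqrt(exp_ * (1 - exp_) / n_runs)
    expect_lt(abs(obs - exp_), 5 * se + 0.01)
  }
  # non-adjacent pair composes the kernel
  obs13 <- invariance_fraction(atlas, c("ct1", "ct3"), "genome")
  exp13 <- expected_invariance(truth, c(1, 3), "genome")
  expect_lt(abs(obs13 - exp13), 0.05)
  # zero switching: every cell type identical
  cfg0 <- sim_config(chrom_lengths = c(chrS1 = 2e7), switch_prob = 0)
  truth0 <- simulate_atlas(cfg0, seed = 2)
  expect_equal(invariance_fraction(build_atlas(truth0$calls),
                                   mode = "genome"), 1.0)
  expect_equal(expected_invariance(truth0, 1:3, "genome"), 1.0)
})

test_that("pairwise comparison reproduces hand-computed odds ratios", {
  ta <- toy_atlas()
  atlas <- build_atlas(ta$calls)
  res <- pairwise_invariance_comparison(atlas)
  expect_equal(nrow(res$pairs), 3)
  ab <- res$pairs[res$pairs$cell_a == "ctA" & res$pairs$cell_b == "ctB", ]
  # hand tally: a holds 8 T1 bins, all still T1 in b; 6 T2 bins, 2 lost
  expect_equal(ab$frac_T1, 8 / 20)
  expect_equal(ab$frac_T2, 4 / 20)
  # zero cell (no T1 lost): Haldane correction applies
  expect_true(ab$corrected)
  expect_equal(ab$odds_ratio, (8.5 * 2.5) / (0.5 * 4.5))
  expect_s3_class(res$t_test, "htest")

  # identical cell types: fractions are the label shares, degenerate t-test
  atlas2 <- build_atlas(list(ta$calls[[1]],
                             toy_calls(ta$grid, ta$labels$a,
                                       cell_type = "dup")))
  res2 <- pairwise_invariance_comparison(atlas2)
  expect_equal(res2$pairs$retention_T1, 1)
  expect_equal(res2$pairs$retention_T2, 1)
  expect_null(res2$t_test)
})

test_that("subset percentile ranks a focal subset against size-matched ones", {
  cfg <- sim_config(chrom_lengths = c(chrS1 = 6e7), n_cell_types = 6,
                    switch_prob = 0.3)
  truth <- simulate_atlas(cfg, seed = 9)
  atlas <- build_atlas(truth$calls)
  cts <- colnames(atlas$labels)
  # adjacent cell types diverge least, so an adjacent run should rank high
  res <- subset_percentile(atlas, cts[1:2], mode = "genome")
  expect_equal(res$n_subsets, choose(6, 2))
  expect_equal(res$percentile,
               100 * sum(res$distribution < res$focal_fraction) /
                 res$n_subsets)
  # the maximal subset ranks at 100 * (C - 1) / C (no ties in practice)
  imax <- which.max(res$distribution)
  focal_best <- combn(cts, 2, simplify = FALSE)[[imax]]
  res_best <- subset_percentile(atlas, focal_best, mode = "genome")
  expect_equal(res_best$percentile, 100 * (res$n_subsets - 1) / res$n_subsets)
})

test_that("gene states follow majority bp overlap with TSS tie-break", {
  grid <- toy_grid(c(chr1 = 1e5), bin = 2e4)
  calls <- toy_calls(grid, c("T1-LAD", "T1-LAD", "T1-LAD", "nonLAD",
                             "nonLAD"), cell_type = "ctA")
  genes <- gene_table(c("inside", "majority", "tie"),
                      rep("chr1", 3),
                      c(10000, 36000, 50000),
                      c(16000, 76000, 70000),   # 60% T1 / 40% non; 10k/10k tie
                      strand = c("+", "+", "-"))
  asn <- assign_gene_states(calls, genes, rule = "majority")
  expect_equal(asn$ctA[asn$gene_id == "inside"], "T1-LAD")
  expect_equal(asn$ctA[asn$gene_id == "majority"], "T1-LAD")
  # tie: 50-59999 covers 10k T1 + 10k non; TSS at 69999 sits in nonLAD
  expect_equal(asn$ctA[asn$gene_id == "tie"], "nonLAD")

  tss <- assign_gene_states(calls, genes, rule = "tss")
  expect_equal(tss$ctA, c("T1-LAD", "T1-LAD", "nonLAD"))

  # genes planted inside single domains are recovered perfectly
  cfg <- sim_config(chrom_lengths = c(chrS1 = 6e7), n_genes = 300)
  truth <- simulate_atlas(cfg, seed = 17)
  ge <- simulate_genes_expression(truth, cfg, seed = 17)
  for (rule in c("majority", "tss")) {
    asn2 <- assign_gene_states(truth$calls, ge$genes, rule = rule)
    for (ct in colnames(ge$true_states)) {
      expect_identical(asn2[[ct]], unname(ge$true_states[, ct]))
    }
  }
})

test_that("gene transition flows count hand-enumerable fixtures", {
  asn <- data.frame(gene_id = paste0("g", 1:6),
                    esc = c("T1-LAD", "T1-LAD", "T2-LAD", "T2-LAD",
                            "nonLAD", "nonLAD"),
                    cm = c("T1-LAD", "T2-LAD", "T2-LAD", "nonLAD",
                           "nonLAD", "T2-LAD"))
  tr <- gene_state_transitions(asn, "esc", "cm")
  expect_equal(tr$flows["T1-LAD", "T2-LAD"], 2 - 1)
  expect_equal(tr$flows["T1-LAD", "T1-LAD"], 1)
  expect_equal(tr$flows["T2-LAD", "nonLAD"], 1)
  expect_equal(tr$flows["T1-LAD", "nonLAD"], 0)
  expect_equal(sum(tr$flows), 6)
  expect_equal(tr$n_unassigned, 0)

  # identical assignments give a diagonal matrix
  asn2 <- asn; asn2$cm <- asn2$esc
  tr2 <- gene_state_transitions(asn2, "esc", "cm")
  expect_true(all(tr2$flows[upper.tri(tr2$flows)] == 0))
  expect_true(all(tr2$flows[lower.tri(tr2$flows)] == 0))

  # generator constraint: no direct T1 <-> non switches between adjacent
  # cell types when forbidden
  cfg <- sim_config(chrom_lengths = c(chrS1 = 1e8), n_genes = 800)
  truth <- simulate_atlas(cfg, seed = 29)
  ge <- simulate_genes_expression(truth, cfg, seed = 29)
  asn3 <- assign_gene_states(truth$calls, ge$genes)
  tr3 <- gene_state_transitions(asn3, "ct1", "ct2")
  expect_equal(tr3$flows["T1-LAD", "nonLAD"], 0)
  expect_equal(tr3$flows["nonLAD", "T1-LAD"], 0)
})

test_that("expressed-gene proportions recover the generator's probabilities", {
  cfg <- sim_config(chrom_lengths = c(chrS1 = 2e8, chrS2 = 2e8),
                    n_genes = 2000)
  truth <- simulate_atlas(cfg, seed = 37)
  ge <- simulate_genes_expression(truth, cfg, seed = 37)
  asn <- assign_gene_states(truth$calls, ge$genes)
  pe <- proportion_expressed(asn, ge$tpm, threshold_tpm = 5)
  want <- setNames(cfg$p_expressed, c("T1-LAD", "T2-LAD", "nonLAD"))
  for (l in names(want)) {
    got <- pe$summary$mean[pe$summary$label == l]
    n_l <- min(pe$per_cell_type$n_genes[pe$per_cell_type$label == l])
    expect_lt(abs(got - want[[l]]),
              4 * sqrt(want[[l]] * (1 - want[[l]]) / n_l) + 0.01)
  }
  # degenerate thresholds
  pe0 <- proportion_expressed(asn, ge$tpm, threshold_tpm = 0)
  zero_tpm <- ge$tpm; zero_tpm[] <- 0
  pez <- proportion_expressed(asn, zero_tpm, threshold_tpm = 5)
  expect_true(all(pez$per_cell_type$proportion == 0))
})

test_that("fold changes group by transition and ANOVA detects planted shifts", {
  # hand-computed 6-gene fixture
  asn <- data.frame(gene_id = paste0("g", 1:6),
                    esc = c("T1-LAD", "T1-LAD", "T2-LAD", "T2-LAD",
                            "nonLAD", "nonLAD"),
                    cm = c("T1-LAD", "T1-LAD", "T2-LAD", "nonLAD",
                           "nonLAD", "nonLAD"))
  tpm <- matrix(c(1, 3, 7, 15, 31, 63,
                  3, 7, 15, 31, 63, 127), ncol = 2,
                dimnames = list(paste0("g", 1:6), c("esc", "cm")))
  # (identical fold changes within groups make the ANOVA fit exactly,
  # which R flags; the group means are the point here)
  fc <- suppressWarnings(
    expression_fold_change_by_transition(asn, tpm, "esc", "cm"))
  expect_equal(fc$groups$mean_lfc[fc$groups$transition == "T1-LAD->T1-LAD"],
               1)  # (1+1) -> (3+1) etc: log2(2) every gene
  expect_equal(fc$groups$n[fc$groups$transition == "T2-LAD->nonLAD"], 1)
  # equal expression between the two columns: all fold changes exactly 0
  same <- suppressWarnings(
    expression_fold_change_by_transition(asn, tpm[, c(1, 1), drop = FALSE],
                                         "esc", "esc"))
  expect_true(all(same$groups$mean_lfc == 0))
  # planted two-group shift is detected with overwhelming power
  set.seed(6)
  n <- 100
  asn2 <- data.frame(gene_id = paste0("h", 1:(2 * n)),
                     a = rep(c("T1-LAD", "nonLAD"), each = n),
                     b = rep(c("nonLAD", "T1-LAD"), each = n))
  base <- rlnorm(2 * n, log(20), 0.1)
  shift <- rep(c(1, -1), each = n) + rnorm(2 * n, 0, 0.1)  # +-1 log2 units
  tpm2 <- cbind(a = base, b = pmax((base + 1) * 2^shift - 1, 0))
  rownames(tpm2) <- asn2$gene_id
  fc2 <- expression_fold_change_by_transition(asn2, tpm2, "a", "b")
  expect_lt(fc2$anova$p, 1e-6)
  expect_equal(sort(fc2$groups$mean_lfc), c(-1, 1), tolerance = 0.05)
})
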