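#' Simulation configuration
#'
#' Defaults describe the regime the pipeline is built for: a 3-state hidden
#' segmentation with strongly self-adherent states (self-transition 0.98,
#' giving multi-hundred-kb domains at 20-kb bins), Gaussian log2-ratio
#' emissions ordered T1 > T2 > non with substantial T2 overlap with both
#' neighbours, two replicates, Poisson ChIP/input counts, a small blacklist,
#' a multi-cell-type atlas derived by run-level state switching between
#' adjacent ranks, and genes whose expression probability rises as lamina
#' contact falls.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width (bp).
#' @param mu,sigma Emission means/sds per state, T1, T2, non order.
#' @param A 3x3 transition matrix (row-stochastic); default self 0.98 with
#'   off-diagonal mass favouring the adjacent rank.
#' @param n_replicates,replicate_noise_sd Replicate signal model.
#' @param count_depth Mean input reads per bin.
#' @param count_multipliers Per-state ChIP rate multipliers.
#' @param blacklist_fraction Fraction of bins masked.
#' @param n_cell_types Cell types in the atlas.
#' @param switch_prob Probability that a domain run changes state between
#'   consecutive cell types.
#' @param forbid_T1_non Disallow direct T1 <-> non switches (switching moves
#'   through the adjacent rank, as LAD transitions do).
#' @param n_genes,gene_length Gene placement.
#' @param gene_state_weights Relative placement weight per state.
#' @param p_expressed P(expressed | state), T1, T2, non order.
#' @param tpm_expressed_meanlog,tpm_expressed_sdlog,tpm_silent_meanlog,tpm_silent_sdlog
#'   Log-normal TPM parameters for expressed/silent genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chrS1 = 1e8, chrS2 = 1e8,
                                         chrS3 = 1e8, chrS4 = 1e8),
                       bin_size = 20000,
                       mu = c(0.7, 0.2, -0.5),
                       sigma = c(0.3, 0.3, 0.35),
                       A = matrix(c(0.980, 0.015, 0.005,
                                    0.010, 0.980, 0.010,
                                    0.005, 0.015, 0.980),
                                  3, 3, byrow = TRUE),
                       n_replicates = 2, replicate_noise_sd = 0.1,
                       count_depth = 50,
                       count_multipliers = c(2.0, 1.4, 0.6),
                       blacklist_fraction = 0.02,
                       n_cell_types = 3, switch_prob = 0.2,
                       forbid_T1_non = TRUE,
                       n_genes = 2000, gene_length = 5000,
                       gene_state_weights = c(1, 1, 1),
                       p_expressed = c(0.1, 0.4, 0.7),
                       tpm_expressed_meanlog = log(100),
                       tpm_expressed_sdlog = 0.8,
                       tpm_silent_meanlog = log(0.05),
                       tpm_silent_sdlog = 0.8) {
  K <- length(mu)
  assert_that(K == 3 && length(sigma) == K, "simulator is three-state")
  assert_that(all(abs(rowSums(A) - 1) < 1e-9) && all(A >= 0),
              "A rows must sum to 1")
  assert_that(all(sigma > 0), "sigma must be positive")
  assert_that(switch_prob >= 0 && switch_prob <= 1 &&
                blacklist_fraction >= 0 && blacklist_fraction < 1 &&
                all(p_expressed >= 0 & p_expressed <= 1),
              "probabilities must lie in [0, 1]")
  cfg <- list(chrom_lengths = chrom_lengths, bin_size = bin_size, K = K,
              mu = mu, sigma = sigma, A = A,
              n_replicates = n_replicates,
              replicate_noise_sd = replicate_noise_sd,
              count_depth = count_depth,
              count_multipliers = count_multipliers,
              blacklist_fraction = blacklist_fraction,
              n_cell_types = n_cell_types, switch_prob = switch_prob,
              forbid_T1_non = forbid_T1_non, n_genes = n_genes,
              gene_length = gene_length,
              gene_state_weights = gene_state_weights,
              p_expressed = p_expressed,
              tpm_expressed_meanlog = tpm_expressed_meanlog,
              tpm_expressed_sdlog = tpm_expressed_sdlog,
              tpm_silent_meanlog = tpm_silent_meanlog,
              tpm_silent_sdlog = tpm_silent_sdlog,
              truth_labels = c("T1-LAD", "T2-LAD", "nonLAD"))
  class(cfg) <- "sim_config"
  cfg
}

# Stationary distribution of a row-stochastic matrix.
stationary_dist <- function(A) {
  e <- eigen(t(A))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Run-level switching kernel between consecutive cell types (bin-marginal).
switch_kernel <- function(cfg) {
  s <- cfg$switch_prob
  if (cfg$forbid_T1_non) {
    matrix(c(1 - s, s, 0,
             s / 2, 1 - s, s / 2,
             0, s, 1 - s), 3, 3, byrow = TRUE)
  } else {
    matrix(c(1 - s, s / 2, s / 2,
             s / 2, 1 - s, s / 2,
             s / 2, s / 2, 1 - s), 3, 3, byrow = TRUE)
  }
}

# Grid with a seeded random blacklist covering the configured bin fraction.
sim_grid <- function(cfg, seed) {
  layout <- genome_layout(names(cfg$chrom_lengths), cfg$chrom_lengths)
  grid <- make_grid(layout, cfg$bin_size)
  n_mask <- round(cfg$blacklist_fraction * n_bins(grid))
  blacklist <- NULL
  if (n_mask > 0) {
    pick <- with_seed(derive_seed(seed, 1),
                      sort(sample.int(n_bins(grid), n_mask)))
    grid$mask[pick] <- TRUE
    blacklist <- feature_set(grid$chrom[pick], grid$start[pick],
                             grid$end[pick], name = "blacklist",
                             layout = layout)
  }
  list(grid = grid, blacklist = blacklist)
}

#' Simulate a ground-truth state sequence for one cell type
#'
#' Per chromosome, samples a Markov chain over the unmasked bins from the
#' stationary distribution of `A` and `A` itself; masked bins stay
#' unassigned.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param grid Optional pre-built grid (from an atlas simulation); built
#'   fresh (with its blacklist) when omitted.
#' @return A labeled [state_calls()] (cell type `"ct1"`).
#' @export
simulate_states <- function(config, seed = 1, grid = NULL) {
  if (is.null(grid)) grid <- sim_grid(config, seed)$grid
  pi0 <- stationary_dist(config$A)
  states <- rep(NA_integer_, n_bins(grid))
  with_seed(derive_seed(seed, 2), {
    for (ch in grid$layout$chrom) {
      idx <- which(grid$chrom == ch & !grid$mask)
      if (!length(idx)) next
      s <- integer(length(idx))
      s[1] <- sample.int(config$K, 1, prob = pi0)
      for (t in seq_along(idx)[-1]) {
        s[t] <- sample.int(config$K, 1, prob = config$A[s[t - 1], ])
      }
      states[idx] <- s - 1L
    }
  })
  state_calls(grid, states, labels = config$truth_labels,
              cell_type = "ct1")
}

#' Simulate replicate signal tracks from a truth segmentation
#'
#' Per replicate and unmasked bin: `N(mu_state, sigma_state^2)` plus
#' independent replicate noise `N(0, replicate_noise_sd^2)`.
#'
#' @param truth A [simulate_states()] result.
#' @param config The [sim_config()].
#' @param seed Master seed.
#' @return List of [binned_track()]s, one per replicate.
#' @export
simulate_signal <- function(truth, config, seed = 1) {
  st <- truth$states
  ok <- !is.na(st)
  with_seed(derive_seed(seed, 3), {
    lapply(seq_len(config$n_replicates), function(r) {
      v <- rep(NA_real_, length(st))
      v[ok] <- rnorm(sum(ok), mean = config$mu[st[ok] + 1],
                     sd = config$sigma[st[ok] + 1]) +
        rnorm(sum(ok), sd = config$replicate_noise_sd)
      binned_track(truth$grid, v)
    })
  })
}

#' Simulate Poisson ChIP and input count tracks
#'
#' Input counts are Poisson(depth); ChIP counts Poisson(depth x per-state
#' multiplier), exercising the SES scaling and enrichment classifiers.
#'
#' @inheritParams simulate_signal
#' @return List with `chip` and `input` [count_track()]s.
#' @export
simulate_counts <- function(truth, config, seed = 1) {
  st <- truth$states
  ok <- !is.na(st)
  with_seed(derive_seed(seed, 4), {
    input <- chip <- rep(NA_real_, length(st))
    input[ok] <- rpois(sum(ok), config$count_depth)
    chip[ok] <- rpois(sum(ok),
                      config$count_depth *
                        config$count_multipliers[st[ok] + 1])
    list(chip = count_track(truth$grid, chip),
         input = count_track(truth$grid, input))
  })
}

#' Simulate a multi-cell-type atlas with known shared structure
#'
#' Cell type 1 is a fresh Markov segmentation; each later cell type copies
#' the previous one and switches each maximal same-state run, with
#' probability `switch_prob`, to an adjacent-rank state (T1 <-> T2,
#' T2 <-> non; direct T1 <-> non switches are forbidden when configured, so
#' gene transitions between the extreme states must pass through T2). The
#' bin-level label kernel between consecutive cell types is recorded so
#' expected invariance fractions are available in closed form
#' ([expected_invariance()]).
#'
#' @param config A [sim_config()].
#' @param seed Master seed; all sub-streams derive from it.
#' @return A `synthetic_truth`: `grid`, `blacklist`, `calls` (list of true
#'   labeled [state_calls()]), `kernel`, `marginals` (per-cell-type state
#'   distributions), `config`, `seed`.
#' @export
simulate_atlas <- function(config, seed = 1) {
  assert_that(config$n_cell_types >= 2, "atlas needs >= 2 cell types")
  gb <- sim_grid(config, seed)
  calls <- vector("list", config$n_cell_types)
  calls[[1]] <- simulate_states(config, seed, grid = gb$grid)
  S <- switch_kernel(config)
  for (ct in seq_len(config$n_cell_types)[-1]) {
    prev <- calls[[ct - 1]]$states
    nxt <- prev
    with_seed(derive_seed(seed, 100 + ct), {
      for (ch in gb$grid$layout$chrom) {
        idx <- which(gb$grid$chrom == ch & !is.na(prev))
        if (!length(idx)) next
        s <- prev[idx]
        run_id <- cumsum(c(TRUE, s[-1] != head(s, -1)))
        for (run in split(seq_along(s), run_id)) {
          from <- s[run[1]] + 1L
          probs <- S[from, ]
          draw <- sample.int(3, 1, prob = probs)
          nxt[idx[run]] <- draw - 1L
        }
      }
    })
    calls[[ct]] <- state_calls(gb$grid, nxt, labels = config$truth_labels,
                               cell_type = paste0("ct", ct))
  }
  pi0 <- stationary_dist(config$A)
  marginals <- matrix(NA_real_, config$n_cell_types, 3,
                      dimnames = list(paste0("ct", seq_len(config$n_cell_types)),
                                      config$truth_labels))
  m <- pi0
  for (ct in seq_len(config$n_cell_types)) {
    marginals[ct, ] <- m
    m <- as.numeric(m %*% S)
  }
  structure(list(grid = gb$grid, blacklist = gb$blacklist, calls = calls,
                 kernel = S, marginals = marginals, config = config,
                 seed = seed),
            class = "synthetic_truth")
}

#' Closed-form expected invariance of a simulated atlas
#'
#' Bin labels evolve across cell types as a Markov chain with the run-switch
#' kernel S, so the probability that a bin holds label l in every member of
#' a subset {i1 < i2 < ...} is `m_{i1}(l) * prod_j S^(i_{j+1} - i_j)[l, l]`.
#'
#' @param truth A [simulate_atlas()] truth object.
#' @param subset Integer cell-type indices (default: all).
#' @param mode As in [invariance_fraction()].
#' @return Expected fraction.
#' @export
expected_invariance <- function(truth, subset = seq_along(truth$calls),
                                mode = c("combined", "T1", "T2", "genome")) {
  mode <- match.arg(mode)
  subset <- sort(as.integer(subset))
  assert_that(length(subset) >= 2, "subset must contain >= 2 cell types")
  S <- truth$kernel
  per_label <- truth$marginals[subset[1], ]
  for (j in seq_along(subset)[-1]) {
    Sg <- matpow(S, subset[j] - subset[j - 1])
    per_label <- per_label * diag(Sg)
  }
  switch(mode,
         T1 = per_label[[1]], T2 = per_label[[2]],
         combined = per_label[[1]] + per_label[[2]],
         genome = sum(per_label))
}

matpow <- function(M, n) {
  out <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% M
    M <- M %*% M
    n <- n %/% 2
  }
  out
}

#' Simulate genes and a TPM expression table over an atlas
#'
#' Genes are placed wholly inside single unmasked bins of the first cell
#' type (so their domain state is unambiguous in every cell type), sampled
#' with per-state placement weights. Per cell type, a gene is expressed with
#' probability `p_expressed[state in that cell type]`; TPM is log-normal
#' with the expressed or silent parameters accordingly.
#'
#' @param truth A [simulate_atlas()] truth.
#' @param config The [sim_config()].
#' @param seed Master seed.
#' @return List: `genes` ([gene_table()]), `tpm` (genes x cell types
#'   matrix), `true_states` (genes x cell types label matrix).
#' @export
simulate_genes_expression <- function(truth, config, seed = 1) {
  g <- truth$grid
  assert_that(config$gene_length <= config$bin_size,
              "gene length must fit inside one bin")
  st1 <- truth$calls[[1]]$states
  placeable <- which(!is.na(st1) & (g$end - g$start) >= config$gene_length)
  assert_that(config$n_genes <= length(placeable),
              "more genes requested than placeable bins")
  with_seed(derive_seed(seed, 5), {
    w <- config$gene_state_weights[st1[placeable] + 1]
    bins <- sample(placeable, config$n_genes, prob = w)
    offset <- floor(runif(config$n_genes) *
                      (g$end[bins] - g$start[bins] - config$gene_length + 1))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    genes <- gene_table(sprintf("gene%05d", seq_len(config$n_genes)),
                        g$chrom[bins], g$start[bins] + offset,
                        g$start[bins] + offset + config$gene_length,
                        strand = strand, layout = g$layout)
    ord <- match(genes$gene_id, sprintf("gene%05d", seq_len(config$n_genes)))
    bins <- bins[ord]
    cts <- vapply(truth$calls, `[[`, character(1), "cell_type")
    true_states <- vapply(truth$calls, function(cl) {
      call_labels(cl)[bins]
    }, character(config$n_genes))
    dimnames(true_states) <- list(genes$gene_id, cts)
    tpm <- matrix(NA_real_, config$n_genes, length(cts),
                  dimnames = list(genes$gene_id, cts))
    for (j in seq_along(cts)) {
      state <- truth$calls[[j]]$states[bins] + 1L
      expressed <- rbinom(config$n_genes, 1, config$p_expressed[state]) == 1
      tpm[, j] <- ifelse(
        expressed,
        rlnorm(config$n_genes, config$tpm_expressed_meanlog,
               config$tpm_expressed_sdlog),
        rlnorm(config$n_genes, config$tpm_silent_meanlog,
               config$tpm_silent_sdlog))
    }
    class(tpm) <- c("expression_table", class(tpm))
    list(genes = genes, tpm = tpm, true_states = true_states)
  })
}
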