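#' Fit, decode and label a domain segmentation from one signal track
#'
#' Convenience wrapper over the core steps for a single cell type: fit a
#' K-state Gaussian HMM to the (replicate-median, normalized) track by
#' Baum-Welch, decode per-bin states, and label them by descending median
#' signal.
#'
#' @param track A [binned_track()] of log2-ratio signal.
#' @param K Number of states (default 3).
#' @param prefix Label scheme, `"LAD"` or `"KDD"`.
#' @param decoder `"map"` or `"viterbi"`.
#' @param cell_type Name recorded on the calls.
#' @param seed Seed for the k-means initialization.
#' @param ... Passed to [fit_baum_welch()].
#' @return List: `model` ([gaussian_hmm()]), `calls` (labeled
#'   [state_calls()]), `domains` (`domain_set`).
#' @export
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chrS1 = 4e7), n_genes = 10)
#' truth <- simulate_states(cfg, seed = 7)
#' track <- merge_replicates_median(simulate_signal(truth, cfg, seed = 7))
#' fit <- call_domains(track, K = 3, cell_type = "demo", seed = 7)
#' head(fit$domains)
call_domains <- function(track, K = 3, prefix = "LAD",
                         decoder = c("map", "viterbi"), cell_type = "cell",
                         seed = 1, ...) {
  model <- fit_baum_welch(track, K = K, seed = seed, ...)
  calls <- assign_states(model, track, decoder = match.arg(decoder),
                         cell_type = cell_type)
  calls <- label_states(calls, track, prefix = prefix)
  list(model = model, calls = calls, domains = calls_to_domains(calls))
}
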