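# Independent brute-force oracles used to validate the implementations.

# Enumerate all K^T state paths of a Gaussian HMM over one sequence and
# return exact log-likelihood, per-position posteriors and the best path.
enumerate_hmm <- function(x, pi, A, mu, sigma) {
  T_ <- length(x); K <- length(mu)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(pi[s[1]]) + dnorm(x[1], mu[s[1]], sigma[s[1]], log = TRUE)
    for (t in seq_len(T_)[-1]) {
      lp <- lp + log(A[s[t - 1], s[t]]) +
        dnorm(x[t], mu[s[t]], sigma[s[t]], log = TRUE)
    }
    lp
  })
  total <- max(logp) + log(sum(exp(logp - max(logp))))
  post <- sapply(seq_len(T_), function(t) {
    sapply(seq_len(K), function(k) {
      sel <- paths[, t] == k
      exp(max(logp[sel]) + log(sum(exp(logp[sel] - max(logp[sel])))) - total)
    })
  })                                    # K x T
  best <- paths[which.max(logp), ] - 1L # ties: expand.grid varies state 1
  list(loglik = total, posterior = t(post), viterbi_logp = max(logp),
       best_path = as.integer(best))
}

# Exhaustive SES scan: best background rank and factor by trying all ranks.
ses_brute <- function(chip, input) {
  ord <- order(chip, input, seq_along(chip))
  P <- cumsum(chip[ord]) / sum(chip)
  Q <- cumsum(input[ord]) / sum(input)
  best <- 1; bestv <- Q[1] - P[1]
  for (i in seq_along(P)) {
    if (Q[i] - P[i] > bestv) { best <- i; bestv <- Q[i] - P[i] }
  }
  list(k = best, factor = P[best] / Q[best])
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
fisher_brute <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  xs <- max(0, k - n_):min(k, m)
  probs <- vapply(xs, function(x) {
    choose(m, x) * choose(n_, k - x) / choose(m + n_, k)
  }, numeric(1))
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Per-bp overlap fraction by scanning single bases.
overlap_brute <- function(set_a, set_b) {
  bp_a <- unlist(lapply(seq_len(nrow(set_a)), function(i) {
    paste0(set_a$chrom[i], ":", seq(set_a$start[i], set_a$end[i] - 1))
  }))
  bp_b <- unlist(lapply(seq_len(nrow(set_b)), function(i) {
    paste0(set_b$chrom[i], ":", seq(set_b$start[i], set_b$end[i] - 1))
  }))
  mean(bp_a %in% bp_b)
}

# Small deterministic grid/track builders for fixtures.
toy_grid <- function(lengths = c(chrA = 2e5, chrB = 1e5), bin = 2e4,
                     blacklist = NULL) {
  make_grid(genome_layout(names(lengths), lengths), bin, blacklist)
}

toy_calls <- function(grid, labels_per_bin,
                      scheme = c("T1-LAD", "T2-LAD", "nonLAD"),
                      cell_type = "toy") {
  states <- match(labels_per_bin, scheme) - 1L
  state_calls(grid, states, labels = scheme, cell_type = cell_type)
}
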