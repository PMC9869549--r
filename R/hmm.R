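#' K-state hidden Markov model with Gaussian emissions
#'
#' The segmentation engine: initial state probabilities `pi`, transition
#' matrix `A` (rows sum to 1), and per-state Gaussian emission parameters
#' `mu`, `sigma`. Fitted models additionally carry the training
#' log-likelihood, the iteration count and a convergence flag.
#'
#' @param pi Initial state probabilities (length K, sums to 1).
#' @param A K x K transition matrix, row-stochastic.
#' @param mu,sigma Emission means and standard deviations (`sigma > 0`).
#' @param logLik,n_iter,converged Optional training metadata.
#' @return A `gaussian_hmm`.
#' @export
gaussian_hmm <- function(pi, A, mu, sigma, logLik = NA_real_,
                         n_iter = NA_integer_, converged = NA) {
  K <- length(mu)
  A <- matrix(as.numeric(A), K, K)
  assert_that(length(pi) == K && length(sigma) == K,
              "pi, mu, sigma must share length K")
  assert_that(all(sigma > 0), "sigma must be positive")
  assert_that(abs(sum(pi) - 1) < 1e-9, "pi must sum to 1")
  assert_that(all(abs(rowSums(A) - 1) < 1e-9), "A rows must sum to 1")
  assert_that(all(pi >= 0) && all(A >= 0), "negative probabilities")
  structure(list(K = K, pi = as.numeric(pi), A = A, mu = as.numeric(mu),
                 sigma = as.numeric(sigma), logLik = logLik,
                 n_iter = n_iter, converged = converged),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat("<gaussian_hmm> K =", x$K, "\n  mu:   ", signif(x$mu, 4),
      "\n  sigma:", signif(x$sigma, 4), "\n  diag(A):",
      signif(diag(x$A), 4), "\n")
  if (!is.na(x$logLik)) {
    cat("  logLik", format(x$logLik), "after", x$n_iter, "iterations",
        if (isTRUE(x$converged)) "(converged)" else "(not converged)", "\n")
  }
  invisible(x)
}

# Number of free parameters: (K-1) for pi, K(K-1) for A, 2K for emissions.
hmm_n_params <- function(K) K^2 + 2 * K - 1

#' Observation sequences from a binned track
#'
#' Splits a track into maximal runs of consecutive non-missing bins within
#' each chromosome. Each run is one HMM observation sequence (sequences
#' restart from `pi`, so no information flows across blacklist gaps or
#' chromosome ends).
#'
#' @param track A [binned_track()].
#' @return An `obs_sequences`: list with `values` (list of numeric vectors)
#'   and `bins` (list of global bin index vectors).
#' @export
obs_sequences <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  ok <- !is.na(track$values)
  run_id <- cumsum(c(TRUE, track$grid$chrom[-1] != head(track$grid$chrom, -1) |
                             ok[-1] != head(ok, -1)))
  keep <- split(seq_along(ok), run_id)
  keep <- keep[vapply(keep, function(i) ok[i[1]], logical(1))]
  structure(list(values = lapply(keep, function(i) track$values[i]),
                 bins = unname(keep)),
            class = "obs_sequences")
}

as_obs <- function(x) {
  if (inherits(x, "obs_sequences")) return(x$values)
  if (inherits(x, "binned_track")) return(obs_sequences(x)$values)
  if (is.numeric(x)) return(list(x))
  stopifnot(is.list(x), all(vapply(x, is.numeric, logical(1))))
  x
}

#' k-means initialization of emission parameters
#'
#' Clusters the pooled 1-D observations with k-means (k-means++ seeding,
#' fixed seed); emission means and standard deviations come from the
#' clusters, while `pi` and `A` start uniform. States are ordered by
#' ascending mean so identical seeds give identical initializations.
#'
#' @param values Numeric vector of observations (>= K distinct finite
#'   values).
#' @param K Number of states (>= 2).
#' @param seed Integer seed for the k-means++ draw.
#' @param sigma_min Lower floor on emission standard deviations.
#' @return A [gaussian_hmm()] with uniform `pi` and `A`.
#' @export
kmeans_init <- function(values, K, seed = 1, sigma_min = 1e-3) {
  assert_that(K >= 2, "K must be >= 2")
  values <- values[is.finite(values)]
  assert_that(length(unique(values)) >= K,
              "need at least K distinct finite values")
  # 10 seeded k-means++ draws, keeping the best within-cluster sum of
  # squares: single draws occasionally seed two centers in one cluster and
  # Lloyd iterations cannot escape that local optimum
  km <- with_seed(seed, {
    best <- NULL
    for (attempt in 1:10) {
      centers <- kmeanspp_centers(values, K)
      fit <- suppressWarnings(
        kmeans(values, centers = matrix(centers, ncol = 1), iter.max = 100))
      if (all(fit$size > 0) && length(unique(fit$cluster)) == K &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
    best
  })
  assert_that(!is.null(km),
              "k-means produced an empty cluster in all 10 attempts")
  mu <- as.numeric(km$centers)
  sig <- vapply(seq_len(K), function(k) {
    v <- values[km$cluster == k]
    if (length(v) > 1) sd(v) else 0
  }, numeric(1))
  ord <- order(mu)
  gaussian_hmm(pi = rep(1 / K, K), A = matrix(1 / K, K, K),
               mu = mu[ord], sigma = pmax(sig[ord], sigma_min))
}

# k-means++ seeding over 1-D data: first center uniform, then each next
# center drawn with probability proportional to squared distance to the
# nearest chosen center.
kmeanspp_centers <- function(values, K) {
  centers <- numeric(K)
  centers[1] <- values[sample.int(length(values), 1)]
  d2 <- (values - centers[1])^2
  for (k in seq_len(K - 1) + 1) {
    if (all(d2 == 0)) {
      centers[k] <- values[sample.int(length(values), 1)]
    } else {
      centers[k] <- values[sample.int(length(values), 1, prob = d2)]
    }
    d2 <- pmin(d2, (values - centers[k])^2)
  }
  # kmeans() requires distinct centers; jitter exact duplicates minimally
  while (anyDuplicated(centers)) {
    i <- anyDuplicated(centers)
    centers[i] <- centers[i] + stats::runif(1, -1e-8, 1e-8)
  }
  centers
}

#' Total log-likelihood of sequences under a model
#'
#' Forward algorithm in log space; independent sequences each start from
#' `pi` and their log-likelihoods add.
#'
#' @param model A [gaussian_hmm()].
#' @param sequences A [binned_track()], [obs_sequences()], numeric vector or
#'   list of numeric vectors.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, sequences) {
  stopifnot(inherits(model, "gaussian_hmm"))
  assert_that(all(model$sigma > 0), "sigma must be positive")
  seqs <- as_obs(sequences)
  assert_that(length(seqs) > 0 && all(lengths(seqs) > 0),
              "empty observation sequences")
  sum(vapply(seqs, .hmm_forward_cpp, numeric(1), logpi = log(model$pi),
             logA = log(model$A), mu = model$mu, sigma = model$sigma))
}

#' Fit a Gaussian HMM by Baum-Welch (EM)
#'
#' Starting from a k-means initialization (or a supplied model), iterates
#' forward-backward E-steps and closed-form M-steps until the relative
#' log-likelihood improvement falls below `tol` or `max_iter` is reached.
#' Emission standard deviations are floored at `sigma_min` to prevent
#' variance collapse on near-constant segments.
#'
#' @inheritParams log_likelihood
#' @param K Number of states.
#' @param init Optional [gaussian_hmm()] to start from (overrides `K`).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param seed Seed for the k-means initialization.
#' @param sigma_min Emission sd floor (default 1e-3).
#' @return A fitted [gaussian_hmm()] with `logLik`, `n_iter`, `converged`,
#'   and attribute `logLik_trace` (per-iteration log-likelihoods).
#' @export
fit_baum_welch <- function(sequences, K = 3, init = NULL, tol = 1e-6,
                           max_iter = 1000, seed = 1, sigma_min = 1e-3) {
  seqs <- as_obs(sequences)
  n <- sum(lengths(seqs))
  assert_that(n >= 10 * K, "need at least 10*K observations")
  model <- init %||% kmeans_init(unlist(seqs, use.names = FALSE), K,
                                 seed = seed, sigma_min = sigma_min)
  K <- model$K
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    logpi <- log(model$pi); logA <- log(model$A)
    ll <- 0
    g1 <- numeric(K)
    xi <- matrix(0, K, K)
    wsum <- numeric(K); wx <- numeric(K); wx2 <- numeric(K)
    for (s in seqs) {
      e <- .hmm_estep_cpp(s, logpi, logA, model$mu, model$sigma)
      ll <- ll + e$loglik
      g1 <- g1 + e$gamma[1, ]
      xi <- xi + e$xi
      wsum <- wsum + colSums(e$gamma)
      wx <- wx + as.numeric(crossprod(e$gamma, s))
      wx2 <- wx2 + as.numeric(crossprod(e$gamma, s^2))
    }
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood at EM iteration ", iter, call. = FALSE)
    }
    trace <- c(trace, ll)
    mu <- wx / wsum
    sigma <- pmax(sqrt(pmax(wx2 / wsum - mu^2, 0)), sigma_min)
    pi_new <- g1 / sum(g1)
    A_new <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    # guard rows with no expected transitions (possible for unvisited states)
    empty <- rowSums(xi) == 0
    if (any(empty)) A_new[empty, ] <- 1 / K
    model <- gaussian_hmm(pi_new, A_new, mu, sigma)
    if (is.finite(ll_prev) &&
        (ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  model$logLik <- log_likelihood(model, seqs)
  model$n_iter <- iter
  model$converged <- converged
  attr(model, "logLik_trace") <- trace
  model
}

#' Posterior (MAP per bin) decoding
#'
#' Per observation, the state maximizing the marginal posterior given the
#' whole sequence; ties break toward the lower state index.
#'
#' @inheritParams log_likelihood
#' @return List with `states` (list of integer vectors, 0-based) and
#'   `posterior` (list of T x K matrices).
#' @export
posterior_decode <- function(model, sequences) {
  stopifnot(inherits(model, "gaussian_hmm"))
  seqs <- as_obs(sequences)
  logpi <- log(model$pi); logA <- log(model$A)
  post <- lapply(seqs, function(s) {
    .hmm_estep_cpp(s, logpi, logA, model$mu, model$sigma)$gamma
  })
  states <- lapply(post, function(g) max.col(g, ties.method = "first") - 1L)
  list(states = states, posterior = post)
}

#' Viterbi decoding
#'
#' Jointly most probable state path per sequence; ties break toward the lower
#' state index.
#'
#' @inheritParams log_likelihood
#' @return List of integer state vectors (0-based).
#' @export
viterbi <- function(model, sequences) {
  stopifnot(inherits(model, "gaussian_hmm"))
  seqs <- as_obs(sequences)
  lapply(seqs, function(s) {
    as.integer(.hmm_viterbi_cpp(s, log(model$pi), log(model$A), model$mu,
                                model$sigma))
  })
}

#' Model selection over a range of state counts
#'
#' Fits each K with several seeded restarts keeping the best log-likelihood,
#' and reports AIC = 2p - 2 logL and BIC = p ln(n) - 2 logL with
#' p = K^2 + 2K - 1 free parameters. The default choice is the BIC argmin;
#' the per-K improvement deltas are reported so the "simplest adequate
#' model" elbow rule can be applied by inspection.
#'
#' @inheritParams log_likelihood
#' @param K_range Integer vector of state counts within 2..8.
#' @param restarts Seeded initializations per K (best kept).
#' @param seed Base seed; restart r of state count K uses a sub-seed derived
#'   from it.
#' @param ... Passed to [fit_baum_welch()].
#' @return List with `table` (data frame: K, logLik, p, AIC, BIC, dAIC,
#'   dBIC relative to the previous K), `chosen_K` (BIC argmin) and `models`.
#' @export
model_selection <- function(sequences, K_range = 2:5, restarts = 3,
                            seed = 1, ...) {
  assert_that(length(K_range) > 0, "empty K range")
  assert_that(all(K_range >= 2 & K_range <= 8), "K range must lie in [2, 8]")
  seqs <- as_obs(sequences)
  n <- sum(lengths(seqs))
  fits <- lapply(K_range, function(K) {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- fit_baum_welch(seqs, K = K,
                            seed = derive_seed(seed, K * 100 + r), ...)
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    best
  })
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  p <- hmm_n_params(K_range)
  tab <- data.frame(K = K_range, logLik = ll, p = p,
                    AIC = 2 * p - 2 * ll, BIC = p * log(n) - 2 * ll)
  tab$dAIC <- c(NA, diff(tab$AIC))
  tab$dBIC <- c(NA, diff(tab$BIC))
  if (any(diff(ll) < -1e-6)) {
    warning("log-likelihood decreased with larger K (local optimum); ",
            "consider more restarts", call. = FALSE)
  }
  list(table = tab, chosen_K = K_range[which.min(tab$BIC)],
       models = setNames(fits, paste0("K", K_range)), n = n)
}
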