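# Downstream statistics: hierarchical odds-ratio enrichment, expected PUF
# counts, bootstrap quantile-quantile comparisons.

#' Per-term PUF/PKF count table
#'
#' Tallies, per term, the number of PUFs carrying the predicted term and
#' the number of PKFs carrying the known annotation (protein-level: a
#' protein counts once per term), restricted to terms with at least
#' `min_obs` observations in both groups.  Term depth is attached for the
#' hierarchical model's depth adjustment.
#'
#' @param predicted_store closed [AnnotationStore-class] of PUF predictions.
#' @param known_store closed [AnnotationStore-class] of PKF annotations.
#' @param graph an [OntologyGraph-class].
#' @param min_obs inclusive minimum count in each group (default 4; the
#'   binary-feature variant conventionally uses 6).
#' @return data.frame: term, k_puf, n_puf, k_pkf, n_pkf, depth.
#' @export
buildTermCounts <- function(predicted_store, known_store, graph,
                            min_obs = 4) {
  stopifnot(min_obs >= 1)
  pa <- unique(predicted_store@assignments[, c("protein_id", "term_id")])
  ka <- unique(known_store@assignments[, c("protein_id", "term_id")])
  if (!nrow(pa) || !nrow(ka)) stop("empty annotation store")
  n_puf <- length(unique(pa$protein_id))
  n_pkf <- length(unique(ka$protein_id))
  k_puf <- table(pa$term_id)
  k_pkf <- table(ka$term_id)
  terms <- intersect(names(k_puf)[k_puf >= min_obs],
                     names(k_pkf)[k_pkf >= min_obs])
  data.frame(term = terms,
             k_puf = as.integer(k_puf[terms]), n_puf = n_puf,
             k_pkf = as.integer(k_pkf[terms]), n_pkf = n_pkf,
             depth = as.integer(termDepth(graph)[terms]),
             row.names = NULL)
}

#' Count table for binary sequence features
#'
#' The enrichment machinery is generic over count tables; this builds one
#' from a binary protein x feature matrix and the two protein groups, with
#' a constant depth so the hierarchy collapses to a single pooled level.
#'
#' @param feature_matrix binary protein x feature matrix with dimnames.
#' @param puf_ids,pkf_ids protein id vectors (rows of the matrix).
#' @param min_obs inclusive minimum count in each group (default 6).
#' @return data.frame shaped like [buildTermCounts()] output.
#' @export
buildBinaryCounts <- function(feature_matrix, puf_ids, pkf_ids, min_obs = 6) {
  mp <- feature_matrix[intersect(puf_ids, rownames(feature_matrix)), ,
                       drop = FALSE]
  mk <- feature_matrix[intersect(pkf_ids, rownames(feature_matrix)), ,
                       drop = FALSE]
  k_puf <- colSums(mp); k_pkf <- colSums(mk)
  keep <- k_puf >= min_obs & k_pkf >= min_obs
  nk <- sum(keep)
  data.frame(term = colnames(feature_matrix)[keep],
             k_puf = as.integer(k_puf[keep]), n_puf = rep(nrow(mp), nk),
             k_pkf = as.integer(k_pkf[keep]), n_pkf = rep(nrow(mk), nk),
             depth = rep(1L, nk), row.names = NULL)
}

# split-half potential scale reduction factor on an iterations x chains
# matrix of draws
splitRhat <- function(draws) {
  n <- nrow(draws) %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c)
    cbind(draws[seq_len(n), c], draws[n + seq_len(n), c])))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

mcmcSummary <- function(samp, transform = identity, rhat_limit = 1.05) {
  # samp: coda mcmc.list; one row per monitored parameter
  mat <- do.call(rbind, lapply(samp, as.matrix))   # pooled draws
  params <- colnames(mat)
  ess <- coda::effectiveSize(samp)
  out <- do.call(rbind, lapply(params, function(p) {
    draws <- transform(mat[, p])
    per_chain <- sapply(samp, function(ch) as.matrix(ch)[, p])
    data.frame(param = p,
               median = median(draws),
               q10 = unname(quantile(draws, 0.1)),
               q90 = unname(quantile(draws, 0.9)),
               ess = unname(ess[p]),
               rhat = splitRhat(per_chain))
  }))
  converged <- all(is.finite(out$rhat)) && all(out$rhat <= rhat_limit)
  if (!converged)
    warning("MCMC convergence suspect: max split-Rhat = ",
            round(max(out$rhat, na.rm = TRUE), 3))
  attr(out, "converged") <- converged
  stopifnot(all(out$q10 <= out$median & out$median <= out$q90))
  out
}

enrichmentModelString <- "model {
  for (t in 1:T) {
    k_pkf[t] ~ dbin(p_pkf[t], n_pkf)
    k_puf[t] ~ dbin(p_puf[t], n_puf)
    logit(p_pkf[t]) <- alpha[t]
    logit(p_puf[t]) <- alpha[t] + beta[t]
    alpha[t] ~ dnorm(0, 0.25)
    beta[t] ~ dnorm(mu_d[depth_idx[t]], tau_beta)
  }
  for (d in 1:D) { mu_d[d] ~ dnorm(mu0, tau_mu) }
  mu0 ~ dnorm(0, 0.25)
  sigma_beta ~ dt(0, 1, 3) T(0,)
  tau_beta <- pow(sigma_beta, -2)
  sigma_mu ~ dt(0, 1, 3) T(0,)
  tau_mu <- pow(sigma_mu, -2)
}"

#' Hierarchical Bayesian odds-ratio enrichment of terms in PUFs vs PKFs
#'
#' Per-term binomial counts in the two groups with a logit-linear group
#' effect: `logit(p_pkf) = alpha_t`, `logit(p_puf) = alpha_t + beta_t`.
#' The log odds ratios `beta_t` are partially pooled within term-depth
#' levels, `beta_t ~ N(mu_d(t), sigma)`, and the depth-level means are
#' pooled again, `mu_d ~ N(mu0, tau)`, with weakly informative priors
#' (N(0, sd 2) on alpha and mu0, half-t(3) on the scales).  Posterior via
#' MCMC (JAGS); the reported odds ratio is `exp(beta_t)`.
#'
#' @param counts data.frame from [buildTermCounts()].
#' @param n_iter post-adaptation iterations per chain (default 2000).
#' @param n_chains number of chains (default 2).
#' @param n_adapt adaptation iterations (default 500).
#' @param seed integer seed.
#' @param rhat_limit convergence flag limit on split-Rhat (default 1.05).
#' @return data.frame (one row per term): term, median, q10, q90 of the
#'   odds ratio, ess, rhat; attribute `converged`.
#' @export
fitEnrichmentModel <- function(counts, n_iter = 2000, n_chains = 2,
                               n_adapt = 500, seed = 1L,
                               rhat_limit = 1.05) {
  stopifnot(nrow(counts) > 0)
  depth_levels <- sort(unique(counts$depth))
  dat <- list(T = nrow(counts), D = length(depth_levels),
              k_puf = counts$k_puf, n_puf = counts$n_puf[1],
              k_pkf = counts$k_pkf, n_pkf = counts$n_pkf[1],
              depth_idx = match(counts$depth, depth_levels))
  inits <- lapply(seq_len(n_chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + i))
  mod <- rjags::jags.model(textConnection(enrichmentModelString), data = dat,
                           inits = inits, n.chains = n_chains,
                           n.adapt = n_adapt, quiet = TRUE)
  samp <- rjags::coda.samples(mod, "beta", n.iter = n_iter,
                              progress.bar = "none")
  out <- mcmcSummary(samp, transform = exp, rhat_limit = rhat_limit)
  out$param <- NULL
  cbind(term = counts$term, out)
}

expectedCountModelString <- "model {
  for (t in 1:T) {
    p[t] ~ dbeta(k_pkf[t] + 1, n_pkf - k_pkf[t] + 1)
    k_puf[t] ~ dbin(p[t], n_puf)
  }
}"

#' Expected number of PUFs per term under PKF-frequency priors
#'
#' Takes the term frequency among PKFs as a Beta prior (`Beta(k_pkf + 1,
#' n_pkf - k_pkf + 1)`), updates it with the binomial term frequency among
#' PUF predictions, and reports `total_pufs * p_t` from the posterior
#' draws: the number of PUFs expected to carry each term if PUF
#' annotations were as complete as PKF annotations.  Conjugate, so the
#' closed-form posterior `Beta(k_pkf + k_puf + 1, n_pkf - k_pkf + n_puf -
#' k_puf + 1)` is an exact oracle for the MCMC.
#'
#' @param counts data.frame from [buildTermCounts()].
#' @param total_pufs total number of PUFs to scale to (must be >= n_puf).
#' @inheritParams fitEnrichmentModel
#' @return data.frame: term, median, q10, q90 of the expected count, ess,
#'   rhat; attribute `converged`.
#' @export
fitExpectedCountModel <- function(counts, total_pufs, n_iter = 2000,
                                  n_chains = 2, n_adapt = 500, seed = 1L,
                                  rhat_limit = 1.05) {
  stopifnot(nrow(counts) > 0, total_pufs >= counts$n_puf[1])
  dat <- list(T = nrow(counts), k_puf = counts$k_puf,
              n_puf = counts$n_puf[1], k_pkf = counts$k_pkf,
              n_pkf = counts$n_pkf[1])
  inits <- lapply(seq_len(n_chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + i))
  mod <- rjags::jags.model(textConnection(expectedCountModelString),
                           data = dat, inits = inits, n.chains = n_chains,
                           n.adapt = n_adapt, quiet = TRUE)
  samp <- rjags::coda.samples(mod, "p", n.iter = n_iter,
                              progress.bar = "none")
  out <- mcmcSummary(samp, transform = function(p) total_pufs * p,
                     rhat_limit = rhat_limit)
  out$param <- NULL
  cbind(term = counts$term, out)
}

#' Bootstrap quantile-quantile comparison of two property distributions
#'
#' Resamples both groups with replacement `n_boot` times, computes the QQ
#' curve on a fixed grid of 99 equally spaced quantiles each time, and
#' forms a pointwise band.  The verdict is "excluded" when the identity
#' line y = x lies outside the band at every grid point (the two
#' distributions differ everywhere on the quantile grid), "not_excluded"
#' otherwise, and "indeterminate" for degenerate constant samples.
#'
#' @param values_puf,values_pkf numeric samples (e.g. protein lengths).
#' @param n_boot bootstrap resamples (default 500).
#' @param band_level pointwise band level (default 0.95).
#' @param seed integer seed.
#' @param n_grid number of quantile grid points (default 99).
#' @return list: `qq` (data.frame prob, q_pkf, q_puf: the observed curve),
#'   `band` (data.frame prob, lo, hi of the bootstrap PUF-minus-PKF
#'   quantile difference), `verdict`, `median_puf`, `median_pkf`.
#' @export
bootstrapQQ <- function(values_puf, values_pkf, n_boot = 500,
                        band_level = 0.95, seed = 1L, n_grid = 99) {
  stopifnot(length(values_puf) > 0, length(values_pkf) > 0, n_boot >= 100)
  probs <- seq_len(n_grid) / (n_grid + 1)
  obs <- data.frame(prob = probs,
                    q_pkf = unname(quantile(values_pkf, probs)),
                    q_puf = unname(quantile(values_puf, probs)))
  if (stats::sd(values_puf) == 0 || stats::sd(values_pkf) == 0)
    return(list(qq = obs, band = NULL, verdict = "indeterminate",
                median_puf = median(values_puf),
                median_pkf = median(values_pkf)))
  set.seed(seed)
  diffs <- replicate(n_boot, {
    bp <- sample(values_puf, replace = TRUE)
    bk <- sample(values_pkf, replace = TRUE)
    unname(quantile(bp, probs) - quantile(bk, probs))
  })
  a <- (1 - band_level) / 2
  lo <- apply(diffs, 1, quantile, probs = a)
  hi <- apply(diffs, 1, quantile, probs = 1 - a)
  excluded <- all(lo > 0 | hi < 0)
  list(qq = obs, band = data.frame(prob = probs, lo = lo, hi = hi),
       verdict = if (excluded) "excluded" else "not_excluded",
       median_puf = median(values_puf), median_pkf = median(values_pkf))
}
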