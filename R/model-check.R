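# Posterior predictive model checking and PCA pre-evaluation of the
# scenario-prior combinations.

#' Posterior predictive model check
#'
#' Draws parameter vectors from the adjusted posterior (with its importance
#' weights), simulates a dataset from each, and locates every observed
#' summary statistic inside its posterior predictive distribution. The
#' two-sided tail probability per statistic is
#' `2 * min(P(sim <= obs), P(sim >= obs))`; significance uses a Bonferroni
#' threshold `alpha / n_statistics`.
#'
#' @param posterior An `abc_posterior` (see [estimate_posteriors()]).
#' @param observed Observed summary statistics.
#' @param n_loci,sample_sizes Simulation design for the predictive
#'   datasets (use the observed dataset's design).
#' @param n_ppc Number of posterior predictive simulations.
#' @param alpha Family-wise significance level.
#' @param motif_length Repeat motif length.
#' @return An `abc_model_check` tibble: `statistic`, `observed`,
#'   `pred_median`, `p_value`, `significant`; attribute `n_significant`.
#' @export
model_check <- function(posterior, observed, n_loci, sample_sizes,
                        n_ppc = 500, alpha = 0.05, motif_length = 2) {
  stopifnot(inherits(posterior, "abc_posterior"))
  if (n_ppc < 100) {
    rlang::warn("n_ppc < 100 gives coarse tail probabilities")
  }
  sn <- stat_names(length(sample_sizes))
  obs <- observed_as_vector(observed, sn)
  sam <- posterior$samples
  w <- sam$weight
  if (sum(w) == 0) w <- rep(1, length(w))
  # per-parameter adjustment can break the joint ordering constraints
  # (db < t1, t1 < t2); such draws have zero prior support and are excluded
  valid <- rep(TRUE, nrow(sam))
  if ("db" %in% names(sam)) valid <- valid & sam$db < sam$t1
  if ("t2" %in% names(sam)) valid <- valid & sam$t1 < sam$t2
  if (!any(valid)) {
    rlang::abort("no posterior draw satisfies the ordering constraints")
  }
  w_valid <- w * valid
  if (sum(w_valid) == 0) w_valid <- as.numeric(valid)
  idx <- sample(nrow(sam), n_ppc, replace = TRUE, prob = w_valid)

  sims <- matrix(NA_real_, nrow = n_ppc, ncol = length(sn),
                 dimnames = list(NULL, sn))
  cols <- as.list(sam)
  ss <- as.integer(sample_sizes)
  for (k in seq_len(n_ppc)) {
    d <- lapply(cols, `[`, idx[k])
    m <- epoch_matrices_fast(posterior$scenario, d)
    sim <- cpp_sim_dataset(
      m$epochs, m$merges, ss, as.integer(n_loci),
      d$mu_mic, d$p_mic, d$sni_mic, 20L
    )
    sims[k, ] <- cpp_summary_stats(sim$repeat_count, sim$indel_offset, ss,
                                   as.integer(motif_length))
  }

  p <- vapply(seq_along(sn), function(j) {
    s <- sims[, j]
    s <- s[is.finite(s)]
    if (length(s) == 0 || !is.finite(obs[j])) return(NA_real_)
    lo <- mean(s <= obs[j])
    hi <- mean(s >= obs[j])
    min(1, 2 * min(lo, hi))
  }, numeric(1))

  out <- tibble::tibble(
    statistic = sn,
    observed = as.numeric(obs),
    pred_median = apply(sims, 2, median, na.rm = TRUE),
    p_value = p,
    significant = !is.na(p) & p < alpha / length(sn)
  )
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "alpha") <- alpha
  attr(out, "n_ppc") <- n_ppc
  class(out) <- c("abc_model_check", class(out))
  out
}

#' PCA pre-evaluation of scenarios against the observed data
#'
#' Projects a uniform subsample of the reference table and the observed
#' statistic vector onto the first principal components of the standardized
#' statistics. If the observed point falls inside the cloud of simulated
#' points, the scenario-prior combinations can plausibly generate data like
#' the observed.
#'
#' @param table An `abc_reftable`.
#' @param observed Observed summary statistics.
#' @param n_points Size of the uniform subsample to project.
#' @return An `abc_pca`: list with `scores` (tibble `scenario`, `PC1`,
#'   `PC2`), `observed` (tibble `PC1`, `PC2`), `var_explained` and the
#'   `prcomp` fit.
#' @export
pca_preevaluation <- function(table, observed, n_points = 10000) {
  stopifnot(nrow(table) >= 2)
  sn <- attr(table, "stat_names")
  obs <- observed_as_vector(observed, sn)
  keep <- sn[apply(table[, sn], 2, function(x) stats::sd(x) > 0)]
  idx <- if (nrow(table) > n_points) {
    sample(nrow(table), n_points)
  } else {
    seq_len(nrow(table))
  }
  S <- as.matrix(table[idx, keep])
  fit <- prcomp(S, center = TRUE, scale. = TRUE)
  proj <- predict(fit, newdata = rbind(obs[keep]))
  structure(
    list(
      scores = tibble::tibble(
        scenario = table$scenario[idx],
        PC1 = fit$x[, 1],
        PC2 = if (ncol(fit$x) > 1) fit$x[, 2] else 0
      ),
      observed = tibble::tibble(PC1 = proj[1, 1],
                                PC2 = if (ncol(proj) > 1) proj[1, 2] else 0),
      var_explained = fit$sdev^2 / sum(fit$sdev^2),
      prcomp = fit
    ),
    class = "abc_pca"
  )
}
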