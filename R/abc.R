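# The ABC engine: rejection step, scenario choice by weighted multinomial
# logistic regression, and logit-transformed local-linear parameter
# adjustment (Beaumont-style), with posterior summaries in generations and
# years.

# observed statistics as a named vector in reference-table stat order
observed_as_vector <- function(observed, sn) {
  if (is.data.frame(observed)) {
    observed <- setNames(observed$value, observed$statistic)
  }
  miss <- setdiff(sn, names(observed))
  if (length(miss) > 0) {
    rlang::abort(paste0("observed statistics missing: ",
                        paste(miss, collapse = ", ")))
  }
  observed[sn]
}

epanechnikov <- function(d, bw) {
  w <- 1 - (d / bw)^2
  w[w < 0] <- 0
  w
}

#' Rejection step: retain the simulations closest to the observed data
#'
#' Statistics are standardized by the reference table's median and MAD
#' (robust scaling); the retained set is the `ceiling(fraction * n)` rows
#' with smallest Euclidean distance to the observed vector. A statistic
#' with zero MAD carries no information about the distance and is dropped
#' with a warning.
#'
#' @param table An `abc_reftable`.
#' @param observed Observed summary statistics: the tibble from
#'   [summary_vector()] or a named numeric vector.
#' @param fraction Fraction of rows to retain (the full analysis used 0.01).
#' @return The retained rows with an extra `distance` column; attributes
#'   `bandwidth` (largest retained distance), `scale_center`, `scale_mad`,
#'   `stats_used` and `n_total`.
#' @export
select_closest <- function(table, observed, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  sn <- attr(table, "stat_names")
  obs <- observed_as_vector(observed, sn)
  S <- as.matrix(table[, sn])
  med <- apply(S, 2, median)
  scl <- apply(S, 2, mad)
  drop <- scl == 0 | !is.finite(scl)
  if (any(drop)) {
    rlang::warn(paste0("dropping zero-MAD statistics from the distance: ",
                       paste(sn[drop], collapse = ", ")))
  }
  use <- sn[!drop]
  Z <- sweep(sweep(S[, use, drop = FALSE], 2, med[use]), 2, scl[use], "/")
  zobs <- (obs[use] - med[use]) / scl[use]
  d <- sqrt(rowSums(sweep(Z, 2, zobs)^2))
  n_keep <- ceiling(fraction * nrow(table))
  keep <- order(d)[seq_len(n_keep)]
  out <- table[keep, ]
  out$distance <- d[keep]
  out <- as_reftable(out, table)
  attr(out, "bandwidth") <- max(d[keep])
  attr(out, "scale_center") <- med[use]
  attr(out, "scale_mad") <- scl[use]
  attr(out, "stats_used") <- use
  attr(out, "observed_z") <- zobs
  attr(out, "n_total") <- nrow(table)
  out
}

# standardized statistic offsets from the observed point, for the retained
# set produced by select_closest
retained_offsets <- function(retained) {
  use <- attr(retained, "stats_used")
  med <- attr(retained, "scale_center")
  scl <- attr(retained, "scale_mad")
  zobs <- attr(retained, "observed_z")
  Z <- sweep(sweep(as.matrix(retained[, use]), 2, med), 2, scl, "/")
  sweep(Z, 2, zobs)
}

#' Scenario choice: direct and logistic posterior probabilities
#'
#' The direct estimate is the scenario composition of the retained set. The
#' logistic estimate fits a weighted multinomial logistic regression of the
#' scenario indicator on the standardized statistic offsets from the
#' observed point (Epanechnikov weights on the rejection distances,
#' bandwidth = largest retained distance) and evaluates it at offset zero,
#' i.e. at the observed data. Optional confidence intervals come from a
#' nonparametric bootstrap of the retained set.
#'
#' @param table An `abc_reftable` containing at least two scenarios.
#' @param observed Observed summary statistics.
#' @param fraction Fraction of rows to retain.
#' @param n_boot Bootstrap resamples for the logistic CI (0 = no CI).
#' @return An `abc_model_choice`: tibble `scenario`, `n_retained`,
#'   `prob_direct`, `prob_logistic` (+ `ci_low`/`ci_high` when
#'   bootstrapped). Attribute `fallback` is `TRUE` when complete separation
#'   forced the logistic estimate back to the direct one.
#' @export
model_choice <- function(table, observed, fraction = 0.01, n_boot = 0) {
  if (length(unique(table$scenario)) < 2) {
    rlang::abort("model choice needs at least two scenarios in the table")
  }
  retained <- select_closest(table, observed, fraction)
  scens <- sort(unique(table$scenario))
  present <- sort(unique(retained$scenario))
  absent <- setdiff(scens, present)
  if (length(absent) > 0) {
    rlang::warn(paste0("scenario(s) absent from the retained set: ",
                       paste(absent, collapse = ", ")))
  }
  X <- retained_offsets(retained)
  w <- epanechnikov(retained$distance, attr(retained, "bandwidth"))

  direct <- as.vector(table(factor(retained$scenario, levels = scens))) /
    nrow(retained)

  fit_probs <- function(X, y, w) {
    # multinomial logistic at offset 0; w = kernel weights
    if (length(unique(y)) < 2) {
      p <- as.numeric(scens %in% y)
      return(p / sum(p))
    }
    dat <- data.frame(y = factor(y, levels = present), X)
    fit <- nnet::multinom(y ~ ., data = dat, weights = w, trace = FALSE,
                          maxit = 200, MaxNWts = 5000)
    p0 <- predict(fit, newdata = as.data.frame(t(rep(0, ncol(X)))) |>
                    setNames(colnames(X)), type = "probs")
    if (length(p0) == 1) { # two classes: probability of the second level
      p0 <- c(1 - p0, p0)
    }
    p0 <- as.numeric(p0)
    full <- numeric(length(scens))
    full[match(present, scens)] <- p0
    full
  }

  logistic <- tryCatch(fit_probs(X, retained$scenario, w),
                       error = function(e) NULL)
  fallback <- FALSE
  if (is.null(logistic) || any(!is.finite(logistic))) {
    rlang::warn("logistic fit failed (separation?); using direct estimate")
    logistic <- direct
    fallback <- TRUE
  }

  out <- tibble::tibble(
    scenario = scens,
    n_retained = as.vector(table(factor(retained$scenario, levels = scens))),
    prob_direct = direct,
    prob_logistic = logistic
  )
  if (n_boot > 0) {
    bp <- matrix(NA_real_, nrow = n_boot, ncol = length(scens))
    for (b in seq_len(n_boot)) {
      idx <- sample(nrow(retained), replace = TRUE)
      bp[b, ] <- tryCatch(
        fit_probs(X[idx, , drop = FALSE], retained$scenario[idx], w[idx]),
        error = function(e) rep(NA_real_, length(scens))
      )
    }
    out$ci_low <- apply(bp, 2, quantile, 0.025, na.rm = TRUE)
    out$ci_high <- apply(bp, 2, quantile, 0.975, na.rm = TRUE)
  }
  attr(out, "fallback") <- fallback
  attr(out, "fraction") <- fraction
  class(out) <- c("abc_model_choice", class(out))
  out
}

# logit transform of x onto (lo, hi), clamped away from the boundaries
logit_bounded <- function(x, lo, hi, eps = 1e-8) {
  u <- (x - lo) / (hi - lo)
  u <- pmin(pmax(u, eps), 1 - eps)
  log(u / (1 - u))
}

inv_logit_bounded <- function(y, lo, hi) {
  lo + (hi - lo) / (1 + exp(-y))
}

#' Posterior parameter estimation by local-linear regression adjustment
#'
#' Each parameter of the target scenario is logit-transformed onto its
#' prior interval (so adjusted values can never leave the prior support),
#' regressed linearly on the standardized statistic offsets of the retained
#' set with Epanechnikov weights, residual-corrected to offset zero (the
#' observed data) and back-transformed. Summaries are weighted median and
#' 5%/95% quantiles, in generations and (for time parameters) years.
#'
#' @param table An `abc_reftable`.
#' @param observed Observed summary statistics.
#' @param priors Prior tibble used to build the table.
#' @param scenario Scenario whose rows to use; default the only scenario in
#'   `table` (supply one when the table mixes scenarios).
#' @param fraction Fraction of that scenario's rows to retain.
#' @param generation_time Years per generation for the years conversion.
#' @param zero_slopes Force all regression slopes to zero (pure rejection;
#'   mainly for calibration checks).
#' @return An `abc_posterior`: list with `samples` (adjusted draws +
#'   `weight`, `distance`), `summary` (per parameter: `median`, `q050`,
#'   `q950`, and `median_years`, `q050_years`, `q950_years` for the time
#'   parameters), `scenario`, `ridge_fallback` flag.
#' @export
estimate_posteriors <- function(table, observed, priors = default_priors(),
                                scenario = NULL, fraction = 0.01,
                                generation_time = 3, zero_slopes = FALSE) {
  if (is.null(scenario)) {
    scenario <- unique(table$scenario)
    if (length(scenario) != 1) {
      rlang::abort("table mixes scenarios: supply `scenario`")
    }
  }
  sub <- as_reftable(table[table$scenario == scenario, ], table)
  if (nrow(sub) == 0) rlang::abort("no rows for the requested scenario")
  retained <- select_closest(sub, observed, fraction)
  X <- retained_offsets(retained)
  w <- epanechnikov(retained$distance, attr(retained, "bandwidth"))
  if (all(w == 0)) w <- rep(1, length(w)) # degenerate: all at the boundary

  pars <- required_parameters(scenario)
  pars <- setdiff(pars, character(0))
  pr <- priors[match(pars, priors$name), ]
  ridge_fallback <- FALSE

  samples <- tibble::tibble(.rows = nrow(retained))
  for (i in seq_along(pars)) {
    nm <- pars[i]
    x <- retained[[nm]]
    lo <- pr$low[i]; hi <- pr$high[i]
    if (hi <= lo) { # point prior: nothing to adjust
      samples[[nm]] <- x
      next
    }
    y <- logit_bounded(x, lo, hi)
    if (zero_slopes || all(abs(y - y[1]) < 1e-12)) {
      ystar <- y
    } else {
      Xd <- cbind(1, X)
      fit <- tryCatch(stats::lm.wfit(Xd, y, w), error = function(e) NULL)
      beta <- if (!is.null(fit)) fit$coefficients else NULL
      if (is.null(beta) || any(is.na(beta))) {
        # ridge fallback on a singular design
        ridge_fallback <- TRUE
        lam <- 1e-6 * nrow(Xd)
        A <- crossprod(Xd * w, Xd) + diag(lam, ncol(Xd))
        beta <- solve(A, crossprod(Xd * w, y))
      }
      slopes <- beta[-1]
      ystar <- y - as.vector(X %*% slopes)
    }
    samples[[nm]] <- inv_logit_bounded(ystar, lo, hi)
  }
  samples$weight <- w
  samples$distance <- retained$distance

  time_pars <- intersect(pars, c("t1", "t2", "db"))
  summ <- purrr::map_dfr(pars, function(nm) {
    q <- weighted_quantile(samples[[nm]], w, c(0.5, 0.05, 0.95))
    row <- tibble::tibble(parameter = nm, median = q[1], q050 = q[2],
                          q950 = q[3])
    if (nm %in% time_pars) {
      row$median_years <- convert_to_years(q[1], generation_time)
      row$q050_years <- convert_to_years(q[2], generation_time)
      row$q950_years <- convert_to_years(q[3], generation_time)
    } else {
      row$median_years <- NA_real_
      row$q050_years <- NA_real_
      row$q950_years <- NA_real_
    }
    row
  })

  structure(
    list(samples = samples, summary = summ, scenario = scenario,
         priors = pr, fraction = fraction,
         generation_time = generation_time,
         ridge_fallback = ridge_fallback,
         n_retained = nrow(retained)),
    class = "abc_posterior"
  )
}

# weighted quantiles of a sample (type-4-style interpolation on the
# cumulative weights)
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w))
  if (sum(w) == 0) w <- rep(1, length(w))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  sapply(probs, function(p) {
    i <- which(cw >= p)[1]
    x[i]
  })
}

#' Convert times from generations to years
#'
#' @param generations Time(s) in generations.
#' @param generation_time Years per generation (3 for wolves).
#' @return Time(s) in years.
#' @examples
#' convert_to_years(6830) # 20490
#' @export
convert_to_years <- function(generations, generation_time = 3) {
  stopifnot(generation_time > 0)
  generations * generation_time
}

#' Bottleneck severity ratio
#'
#' `R = Nb / N`: the pre-bottleneck effective size over the current
#' (post-bottleneck) one; values above 1 mean the population declined.
#'
#' @param nb Pre-bottleneck effective size.
#' @param n Current effective size.
#' @param digits Decimals to round to (reported to 1 decimal).
#' @return `R`, rounded.
#' @examples
#' bottleneck_ratio(6400, 3380) # 1.9
#' @export
bottleneck_ratio <- function(nb, n, digits = 1) {
  if (any(n <= 0)) rlang::abort("current size must be > 0")
  round(nb / n, digits)
}

#' @export
tidy.abc_posterior <- function(x, ...) x$summary

#' @export
glance.abc_posterior <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n_retained = x$n_retained,
    fraction = x$fraction,
    generation_time = x$generation_time,
    ridge_fallback = x$ridge_fallback
  )
}

#' @export
tidy.abc_model_choice <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.abc_model_choice <- function(x, ...) {
  best <- x$scenario[which.max(x$prob_logistic)]
  tibble::tibble(
    best_scenario = best,
    prob_best = max(x$prob_logistic),
    fraction = attr(x, "fraction"),
    fallback = isTRUE(attr(x, "fallback"))
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC posterior for scenario", x$scenario, "(", x$n_retained,
      "retained draws )\n")
  print(x$summary)
  invisible(x)
}
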