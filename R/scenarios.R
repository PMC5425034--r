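#' Competing demographic scenarios for three diverging wolf populations
#'
#' Four scenarios describe how three extant populations (pop1 = Italian
#' Peninsula, pop2 = Iberian Peninsula, pop3 = Dinaric regions) descend from
#' a single ancestral population: the three either split simultaneously
#' (scenarios 1 and 2) or sequentially (scenarios 3 and 4), and each
#' descendant population either passed through a bottleneck (scenarios 2
#' and 4) or did not (scenarios 1 and 3).
#'
#' @param ids Scenario ids to return, a subset of `1:4`.
#' @return A tibble with one row per scenario: `scenario`, `split_mode`
#'   (`"simultaneous"` or `"sequential"`), `bottleneck` (logical) and a
#'   human-readable `label`.
#' @examples
#' wolf_scenarios()
#' @export
wolf_scenarios <- function(ids = 1:4) {
  stopifnot(all(ids %in% 1:4))
  tibble::tibble(
    scenario   = 1:4,
    split_mode = c("simultaneous", "simultaneous", "sequential", "sequential"),
    bottleneck = c(FALSE, TRUE, FALSE, TRUE),
    label = c(
      "simultaneous split, no bottleneck",
      "simultaneous split, bottleneck",
      "sequential split, no bottleneck",
      "sequential split, bottleneck"
    )
  )[ids, ]
}

#' Default uniform priors for the demographic and mutation parameters
#'
#' Bounds are chosen to contain the posterior 90% intervals reported for the
#' southern-European wolf analysis; every bound can be overridden through the
#' `overrides` argument or a configuration file (see [read_abc_config()]).
#'
#' Parameters: `N1`,`N2`,`N3` current (post-bottleneck) diploid effective
#' sizes; `N1b`,`N2b`,`N3b` pre-bottleneck sizes; `Nanc` ancestral size;
#' `t1` divergence time and `t2` second (older) split time, in generations;
#' `db` time at which sizes changed from `Nib` to `Ni` (the reduced phase
#' lasting until the present), in generations; `mu_mic` mean microsatellite
#' mutation rate per locus per generation; `p_mic` geometric step parameter
#' of the generalized stepwise model; `sni_mic` single-nucleotide indel rate.
#'
#' @param overrides Optional named list of `c(low, high)` pairs replacing the
#'   default bounds, e.g. `list(t1 = c(500, 5000))`.
#' @return A tibble with columns `name`, `low`, `high`, `kind` (`"uniform"`).
#' @examples
#' default_priors(overrides = list(t1 = c(500, 5000)))
#' @export
default_priors <- function(overrides = NULL) {
  pr <- tibble::tribble(
    ~name,      ~low,   ~high,
    "N1",        100,    10000,
    "N2",        100,    10000,
    "N3",        100,    10000,
    "N1b",       100,    30000,
    "N2b",       100,    30000,
    "N3b",       100,    30000,
    "Nanc",      100,    10000,
    "t1",        100,    10000,
    "t2",        100,    10000,
    "db",        100,    10000,
    "mu_mic",    1e-4,   1e-3,
    "p_mic",     0.1,    0.3,
    "sni_mic",   1e-8,   1e-5
  )
  pr$kind <- "uniform"
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% pr$name) {
        rlang::abort(paste0("unknown prior parameter '", nm, "'"))
      }
      v <- overrides[[nm]]
      stopifnot(length(v) == 2)
      pr$low[pr$name == nm] <- v[1]
      pr$high[pr$name == nm] <- v[2]
    }
  }
  if (any(pr$low > pr$high)) {
    rlang::abort("prior bounds must satisfy low <= high")
  }
  pr
}

#' Parameters required by a scenario
#'
#' @param scenario Scenario id in `1:4`.
#' @return Character vector of parameter names drawn for that scenario.
#' @export
required_parameters <- function(scenario) {
  sc <- wolf_scenarios(scenario)
  par <- c("N1", "N2", "N3", "Nanc", "t1", "mu_mic", "p_mic", "sni_mic")
  if (sc$bottleneck) par <- c(par, "N1b", "N2b", "N3b", "db")
  if (sc$split_mode == "sequential") par <- c(par, "t2")
  par
}

#' Draw parameter vectors from the priors under a scenario's constraints
#'
#' Each parameter is uniform on its prior interval. Ordering constraints
#' (`db < t1`, and `t1 < t2` for sequential scenarios) are enforced by
#' jointly resampling the constrained pair until it satisfies the ordering,
#' i.e. the joint draw is uniform on the constrained region.
#'
#' @param scenario Scenario id in `1:4`.
#' @param priors Prior tibble as returned by [default_priors()].
#' @param n Number of draws.
#' @return A tibble with `n` rows; columns `scenario` plus one column per
#'   parameter of the scenario (parameters a scenario does not use are
#'   absent).
#' @examples
#' sample_parameters(2, n = 3)
#' @export
sample_parameters <- function(scenario, priors = default_priors(), n = 1) {
  stopifnot(length(scenario) == 1, scenario %in% 1:4, n >= 1)
  need <- required_parameters(scenario)
  missing <- setdiff(need, priors$name)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing prior for: ", paste(missing, collapse = ", ")))
  }
  pr <- priors[match(need, priors$name), ]

  draw1 <- function(nm, n) {
    i <- match(nm, pr$name)
    runif(n, pr$low[i], pr$high[i])
  }
  out <- lapply(need, draw1, n = n)
  names(out) <- need
  out <- tibble::as_tibble(out)

  # ordering constraints, enforced jointly: resample every offending pair
  # until all orderings hold simultaneously (scenario 4 couples db < t1
  # with t1 < t2 through the shared t1)
  pairs <- list()
  if ("db" %in% need) pairs <- c(pairs, list(c("db", "t1")))
  if ("t2" %in% need) pairs <- c(pairs, list(c("t1", "t2")))
  for (pp in pairs) {
    i <- match(pp[1], pr$name); j <- match(pp[2], pr$name)
    if (pr$low[i] >= pr$high[j]) {
      rlang::abort(paste0(
        "infeasible constraint: ", pp[1], " must be < ", pp[2],
        " but low(", pp[1], ") >= high(", pp[2], ")"
      ))
    }
  }
  if (length(pairs) > 0) {
    repeat {
      bad <- rep(FALSE, n)
      for (pp in pairs) bad <- bad | out[[pp[1]]] >= out[[pp[2]]]
      if (!any(bad)) break
      idx <- which(bad)
      for (nm in unique(unlist(pairs))) {
        i <- match(nm, pr$name)
        out[[nm]][idx] <- runif(length(idx), pr$low[i], pr$high[i])
      }
    }
  }

  dplyr::bind_cols(tibble::tibble(scenario = rep(scenario, n)), out)
}

#' Translate a scenario and one parameter draw into an executable epoch plan
#'
#' The epoch plan is the piecewise-constant demography handed to the
#' coalescent simulator: per-population size epochs tiling time from the
#' present (0) backwards, plus merge events at which all lineages of a
#' source population move into an ancestor.
#'
#' Layouts: under a bottleneck scenario, population *i* has size `Ni` on
#' `[0, db)` and `Nib` on `[db, t_split)`; without a bottleneck, size `Ni`
#' throughout `[0, t_split)`. Simultaneous scenarios merge all three
#' populations at `t1` into an ancestor of size `Nanc`; sequential scenarios
#' merge pop2 and pop3 at `t1` into an intermediate ancestor (size `Nanc`)
#' that merges with pop1 at `t2` into the root ancestor (size `Nanc`).
#'
#' @param scenario Scenario id in `1:4`.
#' @param draw A one-row parameter tibble from [sample_parameters()] (or any
#'   named list with the scenario's parameters).
#' @return An object of class `epoch_plan`: a list with tibbles `epochs`
#'   (`pop`, `start`, `end`, `size`) and `merges` (`time`, `source`,
#'   `dest`), and `n_sampled = 3`.
#' @examples
#' d <- sample_parameters(2, n = 1)
#' build_epochs(2, d)
#' @export
build_epochs <- function(scenario, draw) {
  stopifnot(length(scenario) == 1, scenario %in% 1:4)
  draw <- as.list(draw)
  need <- required_parameters(scenario)
  for (nm in need) {
    if (is.null(draw[[nm]]) || !is.finite(draw[[nm]])) {
      rlang::abort(paste0("draw is missing parameter '", nm, "'"))
    }
  }
  sc <- wolf_scenarios(scenario)
  g <- function(nm) as.numeric(draw[[nm]])
  if (any(c(g("N1"), g("N2"), g("N3"), g("Nanc")) < 1)) {
    rlang::abort("population sizes must be >= 1")
  }
  if (sc$bottleneck && g("db") >= g("t1")) {
    rlang::abort("draw violates db < t1")
  }
  if (sc$split_mode == "sequential" && g("t1") >= g("t2")) {
    rlang::abort("draw violates t1 < t2")
  }

  # split time of each sampled population
  t_split <- if (sc$split_mode == "simultaneous") {
    rep(g("t1"), 3)
  } else {
    c(g("t2"), g("t1"), g("t1"))
  }

  ep <- list()
  for (i in 1:3) {
    Ni <- g(paste0("N", i))
    if (sc$bottleneck) {
      Nib <- g(paste0("N", i, "b"))
      ep[[i]] <- tibble::tibble(
        pop = i, start = c(0, g("db")), end = c(g("db"), t_split[i]),
        size = c(Ni, Nib)
      )
    } else {
      ep[[i]] <- tibble::tibble(pop = i, start = 0, end = t_split[i],
                                size = Ni)
    }
  }

  if (sc$split_mode == "simultaneous") {
    merges <- tibble::tibble(time = g("t1"), source = 1:3, dest = 4L)
    ep[[4]] <- tibble::tibble(pop = 4, start = g("t1"), end = Inf,
                              size = g("Nanc"))
  } else {
    merges <- tibble::tibble(
      time = c(g("t1"), g("t1"), g("t2"), g("t2")),
      source = c(2L, 3L, 1L, 4L),
      dest = c(4L, 4L, 5L, 5L)
    )
    ep[[4]] <- tibble::tibble(pop = 4, start = g("t1"), end = g("t2"),
                              size = g("Nanc"))
    ep[[5]] <- tibble::tibble(pop = 5, start = g("t2"), end = Inf,
                              size = g("Nanc"))
  }

  plan <- structure(
    list(
      epochs = dplyr::bind_rows(ep),
      merges = merges,
      n_sampled = 3L,
      scenario = scenario
    ),
    class = "epoch_plan"
  )
  validate_epoch_plan(plan)
  plan
}

# Fast path used in the reference-table / posterior-predictive loops:
# identical layouts to build_epochs() but plain matrices, no validation
# (draws are valid by construction there). Columns: epochs (pop, start,
# end, size); merges (time, source, dest).
epoch_matrices_fast <- function(scenario, d) {
  if (scenario == 1) {
    list(
      epochs = cbind(c(1, 2, 3, 4), c(0, 0, 0, d$t1),
                     c(d$t1, d$t1, d$t1, Inf),
                     c(d$N1, d$N2, d$N3, d$Nanc)),
      merges = cbind(rep(d$t1, 3), 1:3, rep(4, 3))
    )
  } else if (scenario == 2) {
    list(
      epochs = cbind(c(1, 1, 2, 2, 3, 3, 4),
                     c(0, d$db, 0, d$db, 0, d$db, d$t1),
                     c(d$db, d$t1, d$db, d$t1, d$db, d$t1, Inf),
                     c(d$N1, d$N1b, d$N2, d$N2b, d$N3, d$N3b, d$Nanc)),
      merges = cbind(rep(d$t1, 3), 1:3, rep(4, 3))
    )
  } else if (scenario == 3) {
    list(
      epochs = cbind(c(1, 2, 3, 4, 5),
                     c(0, 0, 0, d$t1, d$t2),
                     c(d$t2, d$t1, d$t1, d$t2, Inf),
                     c(d$N1, d$N2, d$N3, d$Nanc, d$Nanc)),
      merges = cbind(c(d$t1, d$t1, d$t2, d$t2), c(2, 3, 1, 4),
                     c(4, 4, 5, 5))
    )
  } else {
    list(
      epochs = cbind(c(1, 1, 2, 2, 3, 3, 4, 5),
                     c(0, d$db, 0, d$db, 0, d$db, d$t1, d$t2),
                     c(d$db, d$t2, d$db, d$t1, d$db, d$t1, d$t2, Inf),
                     c(d$N1, d$N1b, d$N2, d$N2b, d$N3, d$N3b, d$Nanc,
                       d$Nanc)),
      merges = cbind(c(d$t1, d$t1, d$t2, d$t2), c(2, 3, 1, 4),
                     c(4, 4, 5, 5))
    )
  }
}

#' Validate an epoch plan
#'
#' Checks that each population's epochs tile its lifetime without gaps or
#' overlaps, that sampled populations exist from the present (time 0), that
#' every population except the final ancestor ends at its merge time, and
#' that exactly one population persists to infinity.
#'
#' @param plan An `epoch_plan`.
#' @return `plan`, invisibly; aborts with a message on violation.
#' @export
validate_epoch_plan <- function(plan) {
  stopifnot(inherits(plan, "epoch_plan"))
  ep <- plan$epochs
  mg <- plan$merges
  pops <- sort(unique(ep$pop))
  final <- ep$pop[is.infinite(ep$end)]
  if (length(final) != 1) {
    rlang::abort("exactly one population must persist to infinity")
  }
  for (p in pops) {
    e <- ep[ep$pop == p, ]
    e <- e[order(e$start), ]
    if (any(e$size < 1)) rlang::abort("epoch sizes must be >= 1")
    if (any(e$start >= e$end)) rlang::abort("epochs must have start < end")
    if (nrow(e) > 1 && any(abs(e$end[-nrow(e)] - e$start[-1]) > 1e-9)) {
      rlang::abort(paste0("gap/overlap in epochs of population ", p))
    }
    birth <- if (p <= plan$n_sampled) 0 else mg$time[match(p, mg$dest)]
    if (abs(e$start[1] - birth) > 1e-9) {
      rlang::abort(paste0("population ", p,
                          " epochs do not start at its origin time"))
    }
    if (p != final) {
      death <- mg$time[match(p, mg$source)]
      if (is.na(death)) {
        rlang::abort(paste0("population ", p, " never merges"))
      }
      if (abs(e$end[nrow(e)] - death) > 1e-9) {
        rlang::abort(paste0("population ", p,
                            " epochs do not end at its merge time"))
      }
    }
  }
  invisible(plan)
}

#' Serialize / restore scenario + prior configuration
#'
#' The configuration is a YAML file with a `scenarios` block (ids to
#' compare), a `priors` block (one `low`/`high` pair per parameter) and any
#' run settings (`n_per_scenario`, `fraction`, `n_loci`, `sample_sizes`,
#' `generation_time`, `seed`).
#'
#' @param path File path.
#' @param config For writing: a named list.
#' @return `read_abc_config()` returns a list with elements `scenarios`,
#'   `priors` (a prior tibble) and any further settings.
#' @export
read_abc_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  if (!is.null(raw$priors)) {
    out$priors <- default_priors(overrides = lapply(raw$priors, unlist))
  } else {
    out$priors <- default_priors()
  }
  if (is.null(out$scenarios)) out$scenarios <- 1:4
  out$scenarios <- as.integer(unlist(out$scenarios))
  out
}

#' @rdname read_abc_config
#' @export
write_abc_config <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$priors) && is.data.frame(cfg$priors)) {
    pr <- cfg$priors
    cfg$priors <- setNames(
      lapply(seq_len(nrow(pr)), function(i) c(pr$low[i], pr$high[i])),
      pr$name
    )
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
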