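# Prior-predictive reference table: rows of (scenario, parameter draw,
# summary statistics), ABC's working dataset.

#' Build an ABC reference table
#'
#' For every row: draw a parameter vector from the priors under the
#' scenario's constraints, simulate a multilocus microsatellite dataset
#' under the structured coalescent, and compute the summary-statistic
#' vector. The full analysis used millions of rows per scenario; the
#' default here is a scaled-down table suitable for method validation, and
#' the count is a plain argument.
#'
#' @param scenarios Scenario ids to simulate (default all four).
#' @param priors Prior tibble, see [default_priors()].
#' @param n_per_scenario Simulations per scenario.
#' @param n_loci Loci per simulated dataset.
#' @param sample_sizes Diploid sample sizes per population.
#' @param motif_length Repeat motif length in nucleotides.
#' @param progress Print a progress line per scenario.
#' @return An `abc_reftable`: a tibble with columns `scenario`, the union of
#'   parameter columns (NA where a scenario does not use a parameter) and
#'   the 21 statistic columns. Attributes: `stat_names`, `param_names`,
#'   `n_loci`, `sample_sizes`, `motif_length`.
#' @examples
#' tab <- build_reference_table(1:2, n_per_scenario = 20, n_loci = 5,
#'                              sample_sizes = c(8, 8, 8))
#' dplyr::count(tab, scenario)
#' @export
build_reference_table <- function(scenarios = 1:4,
                                  priors = default_priors(),
                                  n_per_scenario = 1000,
                                  n_loci = 20,
                                  sample_sizes = c(39, 20, 40),
                                  motif_length = 2,
                                  progress = FALSE) {
  stopifnot(n_per_scenario >= 1)
  P <- length(sample_sizes)
  sn <- stat_names(P)
  all_pars <- unique(unlist(lapply(scenarios, required_parameters)))
  blocks <- list()
  for (sc in scenarios) {
    draws <- sample_parameters(sc, priors, n = n_per_scenario)
    stats <- matrix(NA_real_, nrow = n_per_scenario, ncol = length(sn),
                    dimnames = list(NULL, sn))
    cols <- as.list(draws) # plain vectors: cheap per-row access
    ss <- as.integer(sample_sizes)
    for (i in seq_len(n_per_scenario)) {
      d <- lapply(cols, `[`, i)
      ok <- tryCatch({
        m <- epoch_matrices_fast(sc, d)
        sim <- cpp_sim_dataset(
          m$epochs, m$merges, ss, as.integer(n_loci),
          d$mu_mic, d$p_mic, d$sni_mic, 20L
        )
        stats[i, ] <- cpp_summary_stats(
          sim$repeat_count, sim$indel_offset, ss,
          as.integer(motif_length)
        )
        TRUE
      }, error = function(e) e)
      if (!isTRUE(ok)) {
        rlang::abort(paste0("simulation failed at scenario ", sc, " row ",
                            i, ": ", conditionMessage(ok)))
      }
    }
    for (nm in setdiff(all_pars, names(draws))) draws[[nm]] <- NA_real_
    blocks[[as.character(sc)]] <- dplyr::bind_cols(
      draws[, c("scenario", all_pars)], tibble::as_tibble(stats)
    )
    if (progress) {
      message("scenario ", sc, ": ", n_per_scenario, " simulations done")
    }
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "stat_names") <- sn
  attr(out, "param_names") <- all_pars
  attr(out, "n_loci") <- n_loci
  attr(out, "sample_sizes") <- sample_sizes
  attr(out, "motif_length") <- motif_length
  class(out) <- c("abc_reftable", class(out))
  out
}

# restore reftable attributes after a dplyr verb stripped the class
as_reftable <- function(x, template) {
  for (a in c("stat_names", "param_names", "n_loci", "sample_sizes",
              "motif_length")) {
    attr(x, a) <- attr(template, a)
  }
  if (!inherits(x, "abc_reftable")) {
    class(x) <- c("abc_reftable", class(x))
  }
  x
}

#' Write / read a reference table as CSV
#'
#' The header row carries the column names (`scenario`, parameter symbols,
#' statistic names); attributes are stored in a sidecar JSON with the same
#' path plus `.meta.json`.
#'
#' @param table An `abc_reftable`.
#' @param path CSV path.
#' @export
write_reference_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(
    stat_names = attr(table, "stat_names"),
    param_names = attr(table, "param_names"),
    n_loci = attr(table, "n_loci"),
    sample_sizes = attr(table, "sample_sizes"),
    motif_length = attr(table, "motif_length")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "stat_names") <- meta$stat_names
    attr(out, "param_names") <- meta$param_names
    attr(out, "n_loci") <- meta$n_loci
    attr(out, "sample_sizes") <- meta$sample_sizes
    attr(out, "motif_length") <- meta$motif_length
  } else {
    attr(out, "stat_names") <- grep("^P[0-9]", names(out), value = TRUE)
    attr(out, "param_names") <- setdiff(names(out),
                                        c("scenario",
                                          attr(out, "stat_names")))
  }
  class(out) <- c("abc_reftable", class(out))
  out
}
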