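# Pseudo-observed datasets and mtDNA fixtures with known truth, so every
# stage of the pipeline can be validated without any external download.

#' Posterior point estimates for the southern-European wolf analysis
#'
#' The median posterior parameter vector for the best-supported scenario
#' (simultaneous split with bottlenecks) of the Italian (pop1), Iberian
#' (pop2) and Dinaric (pop3) wolf populations: current and pre-bottleneck
#' effective sizes, divergence time `t1` and bottleneck time `db` in
#' generations, and the microsatellite mutation parameters. Useful as the
#' canonical "true" parameter set for recovery experiments.
#'
#' @return A one-row parameter tibble usable wherever a draw is expected.
#' @examples
#' wolf_posterior_medians()
#' @export
wolf_posterior_medians <- function() {
  tibble::tibble(
    scenario = 2L,
    N1 = 3380, N2 = 3240, N3 = 5480,
    N1b = 6400, N2b = 14400, N3b = 16500,
    Nanc = 3270,
    t1 = 6830, db = 5010,
    mu_mic = 1.72e-4, p_mic = 0.104, sni_mic = 2.67e-6
  )
}

#' Generate a pseudo-observed microsatellite dataset with known truth
#'
#' Simulates a dataset under the structured coalescent at a known parameter
#' vector and returns (or writes) it together with a truth record, enabling
#' scenario-recovery and parameter-coverage experiments.
#'
#' @param scenario True scenario id.
#' @param params True parameter draw (default: the wolf posterior medians).
#' @param n_loci Number of loci (the study design used 39).
#' @param sample_sizes Diploid sample sizes (study design: 39, 20, 40).
#' @param dir If non-NULL, write `pseudo_observed.gen` (Genepop) and
#'   `truth.json` into this directory.
#' @param motif_length Repeat motif length.
#' @return A list with `data` (a `microsat_tbl`) and `truth` (list of
#'   scenario, parameters and design).
#' @examples
#' po <- make_pseudo_observed(n_loci = 5, sample_sizes = c(6, 6, 6))
#' po$truth$scenario
#' @export
make_pseudo_observed <- function(scenario = 2,
                                 params = wolf_posterior_medians(),
                                 n_loci = 39,
                                 sample_sizes = c(39, 20, 40),
                                 dir = NULL,
                                 motif_length = 2) {
  data <- simulate_dataset(scenario, params, n_loci, sample_sizes,
                           motif_length = motif_length)
  truth <- list(
    scenario = scenario,
    params = as.list(params[setdiff(names(params), "scenario")]),
    n_loci = n_loci,
    sample_sizes = sample_sizes,
    motif_length = motif_length
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genepop(data, file.path(dir, "pseudo_observed.gen"),
                  title = "synthetic pseudo-observed microsatellite dataset")
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(data = data, truth = truth)
}

#' Generate a synthetic multi-fragment mtDNA alignment
#'
#' Builds aligned sequence fragments whose concatenation carries exactly the
#' requested haplotype structure: `length(haplotype_counts)` haplotypes at
#' the given counts, distinguished by `n_variants` variant columns placed at
#' seeded random positions (each variant column separates one non-reference
#' haplotype from the reference; variants are assigned round-robin, so
#' `n_variants >= length(haplotype_counts) - 1` is required). The background
#' sequence is uniform random; composition does not affect any statistic
#' computed here.
#'
#' @param haplotype_counts Integer counts per haplotype (sum = sample size).
#' @param region_lengths Named or unnamed fragment lengths in bp; the wolf
#'   study design is `c(CR = 498, ATP6 = 588, COIII = 231, ND4 = 847)`
#'   (2164 bp concatenated).
#' @param n_variants Total number of variant columns across the
#'   concatenated alignment.
#' @param allow_monomorphic Permit `n_variants = 0` with a single haplotype
#'   instead of erroring.
#' @return A tibble `sample_id`, `region`, `sequence` (one row per sample
#'   per region) with attribute `truth` (haplotype assignment and variant
#'   positions).
#' @examples
#' fr <- make_mtdna_fixture(c(34, 5), region_lengths = 498, n_variants = 1)
#' collapse_haplotypes(concatenate_regions(fr))
#' @export
make_mtdna_fixture <- function(haplotype_counts,
                               region_lengths = c(CR = 498, ATP6 = 588,
                                                  COIII = 231, ND4 = 847),
                               n_variants = length(haplotype_counts) - 1,
                               allow_monomorphic = FALSE) {
  k <- length(haplotype_counts)
  n <- sum(haplotype_counts)
  if (n < 2) rlang::abort("need at least 2 sequences in total")
  total_len <- sum(region_lengths)
  if (n_variants > total_len) {
    rlang::abort("more variant columns than alignment columns")
  }
  if (n_variants < 1 && !(k == 1 && allow_monomorphic)) {
    rlang::abort("need n_variants >= 1 (or allow_monomorphic with one haplotype)")
  }
  if (k > 1 && n_variants < k - 1) {
    rlang::abort("need at least one variant column per non-reference haplotype")
  }
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, total_len, replace = TRUE)
  hap <- matrix(rep(backbone, k), nrow = k, byrow = TRUE)
  pos <- if (n_variants > 0) sample(total_len, n_variants) else integer(0)
  target <- if (k > 1) rep(2:k, length.out = n_variants) else integer(0)
  for (v in seq_along(pos)) {
    ref <- hap[1, pos[v]]
    hap[target[v], pos[v]] <- sample(setdiff(bases, ref), 1)
  }

  if (is.null(names(region_lengths))) {
    names(region_lengths) <- paste0("R", seq_along(region_lengths))
  }
  starts <- cumsum(c(1, utils::head(region_lengths, -1)))
  assignment <- rep(seq_len(k), times = haplotype_counts)
  ids <- sprintf("S%03d", seq_len(n))
  rows <- list()
  for (r in seq_along(region_lengths)) {
    span <- starts[r]:(starts[r] + region_lengths[r] - 1)
    rows[[r]] <- tibble::tibble(
      sample_id = ids,
      region = names(region_lengths)[r],
      sequence = vapply(assignment, function(h) {
        paste(hap[h, span], collapse = "")
      }, character(1))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(
    haplotype = assignment,
    variant_positions = sort(pos),
    region_lengths = region_lengths
  )
  out
}
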