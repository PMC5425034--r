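# Coalescent simulation of multilocus microsatellite data under an epoch
# plan. The numerical core lives in src/coalescent.cpp; these wrappers
# convert between the tidy representations and the core's matrices, and all
# randomness flows through R's RNG so set.seed() governs every simulation.

# epoch plan -> plain matrices for the C++ core
plan_matrices <- function(plan) {
  stopifnot(inherits(plan, "epoch_plan"))
  ep <- plan$epochs
  list(
    epochs = cbind(ep$pop, ep$start, ep$end, ep$size),
    merges = if (nrow(plan$merges) > 0) {
      cbind(plan$merges$time, plan$merges$source, plan$merges$dest)
    } else {
      matrix(numeric(0), ncol = 3)
    }
  )
}

#' Simulate a structured-coalescent genealogy
#'
#' Generates one genealogy for `2 * sum(sample_sizes)` gene copies under a
#' piecewise-constant demography. Within a population of diploid effective
#' size *N*, *k* lineages coalesce at total rate *k(k-1)/(4N)* per
#' generation; waiting times are exponential and epoch boundaries/merge
#' events truncate them exactly (memorylessness).
#'
#' @param plan An [epoch_plan][build_epochs].
#' @param sample_sizes Integer vector of diploid sample sizes, one per
#'   sampled population.
#' @return A tibble with one row per node: `node` (1-based id, tips first in
#'   population-major order, the two copies of an individual adjacent),
#'   `parent` (`NA` for the root), `time` (generations before present; 0 at
#'   the tips), `pop` (population in which the node lives/coalesced) and
#'   `is_tip`.
#' @examples
#' plan <- build_epochs(1, sample_parameters(1, n = 1))
#' g <- simulate_genealogy(plan, c(5, 5, 5))
#' max(g$time) # TMRCA in generations
#' @export
simulate_genealogy <- function(plan, sample_sizes) {
  stopifnot(all(sample_sizes >= 1))
  m <- plan_matrices(plan)
  g <- cpp_sim_genealogy(m$epochs, m$merges, as.integer(sample_sizes))
  n <- length(g$parent)
  tibble::tibble(
    node = seq_len(n),
    parent = ifelse(g$parent < 0, NA_integer_, g$parent + 1L),
    time = g$time,
    pop = g$pop,
    is_tip = seq_len(n) <= g$n_tips
  )
}

#' Generalized stepwise mutation on a genealogy
#'
#' Drops microsatellite mutations on every branch: counts are
#' Poisson(`mu` * branch length); each mutation shifts the repeat count by
#' +/- *k* with fair sign and geometric step size P(k) = (1-p) p^(k-1)
#' (mean 1/(1-p); `p = 0` is the strict stepwise model).
#'
#' @param genealogy Tibble from [simulate_genealogy()].
#' @param mu Mutation rate per locus per generation.
#' @param p Geometric step parameter, in `[0, 1)`.
#' @param root_repeat Repeat count of the ancestral allele.
#' @return A tibble with one row per tip: `node`, `pop`, `repeat_count`,
#'   `indel_offset` (0; see [apply_sni()]).
#' @export
mutate_gsm <- function(genealogy, mu, p, root_repeat = 20) {
  stopifnot(mu >= 0, p >= 0, p < 1)
  n_tips <- sum(genealogy$is_tip)
  st <- cpp_mutate(
    ifelse(is.na(genealogy$parent), -1L, genealogy$parent - 1L),
    genealogy$time, n_tips, mu, p, 0, as.integer(root_repeat)
  )
  tibble::tibble(
    node = seq_len(n_tips),
    pop = genealogy$pop[seq_len(n_tips)],
    repeat_count = st$repeat_count,
    indel_offset = st$indel_offset
  )
}

#' Single-nucleotide indel overlay
#'
#' Adds flanking-sequence indel events on the same genealogy: counts per
#' branch are Poisson(`sni` * branch length), each shifting the indel offset
#' by +/- 1 nucleotide. Two gene copies carry the same allele only if both
#' the repeat count and the indel offset match.
#'
#' @param genealogy Tibble from [simulate_genealogy()].
#' @param sni Indel rate per locus per generation.
#' @param states Tip states from [mutate_gsm()].
#' @return `states` with `indel_offset` replaced by the simulated offsets.
#' @export
apply_sni <- function(genealogy, sni, states) {
  stopifnot(sni >= 0)
  n_tips <- sum(genealogy$is_tip)
  st <- cpp_mutate(
    ifelse(is.na(genealogy$parent), -1L, genealogy$parent - 1L),
    genealogy$time, n_tips, 0, 0, sni, 0L
  )
  states$indel_offset <- states$indel_offset + st$indel_offset
  states
}

#' Simulate a multilocus microsatellite dataset
#'
#' One fresh genealogy per locus (loci unlinked), generalized stepwise
#' mutation plus the single-nucleotide-indel overlay on each. This is the
#' generative model behind every reference-table row.
#'
#' @param scenario Scenario id in `1:4`.
#' @param draw One-row parameter tibble (see [sample_parameters()]).
#' @param n_loci Number of independent loci.
#' @param sample_sizes Diploid sample sizes per population.
#' @param motif_length Repeat-motif length in nucleotides (allele size =
#'   `motif_length * repeat_count + indel_offset`).
#' @param root_repeat Ancestral repeat count (statistics are
#'   translation-invariant, so the value is inert).
#' @return A `microsat_tbl`: a tibble with columns `population` (factor),
#'   `individual`, `locus`, `gene_copy` (1 or 2), `repeat_count`,
#'   `indel_offset`, with `motif_length` carried as an attribute.
#' @examples
#' d <- sample_parameters(2, n = 1)
#' ms <- simulate_dataset(2, d, n_loci = 5, sample_sizes = c(10, 8, 12))
#' dplyr::count(ms, population)
#' @export
simulate_dataset <- function(scenario, draw, n_loci, sample_sizes,
                             motif_length = 2, root_repeat = 20) {
  stopifnot(n_loci >= 1)
  plan <- build_epochs(scenario, draw)
  d <- as.list(draw)
  m <- plan_matrices(plan)
  sim <- cpp_sim_dataset(
    m$epochs, m$merges, as.integer(sample_sizes), as.integer(n_loci),
    as.numeric(d$mu_mic), as.numeric(d$p_mic), as.numeric(d$sni_mic),
    as.integer(root_repeat)
  )
  microsat_from_matrices(sim$repeat_count, sim$indel_offset, sample_sizes,
                         motif_length = motif_length)
}

# Build the tidy microsat_tbl from gene-copy x locus matrices (population-
# major row order, copies of an individual adjacent).
microsat_from_matrices <- function(repm, offm, sample_sizes,
                                   pop_labels = NULL,
                                   locus_labels = NULL,
                                   motif_length = 2) {
  P <- length(sample_sizes)
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(P))
  L <- ncol(repm)
  if (is.null(locus_labels)) locus_labels <- paste0("L", seq_len(L))
  pop <- rep(pop_labels, times = 2 * sample_sizes)
  ind <- unlist(lapply(seq_len(P), function(p) {
    rep(paste0(pop_labels[p], "_", seq_len(sample_sizes[p])), each = 2)
  }))
  copy <- rep(rep(1:2, length.out = 2 * sum(sample_sizes)))
  out <- tibble::tibble(
    population = factor(rep(pop, times = L), levels = pop_labels),
    individual = rep(ind, times = L),
    locus = rep(locus_labels, each = nrow(repm)),
    gene_copy = rep(copy, times = L),
    repeat_count = as.vector(repm),
    indel_offset = as.vector(offm)
  )
  attr(out, "motif_length") <- motif_length
  attr(out, "pop_levels") <- pop_labels
  class(out) <- c("microsat_tbl", class(out))
  out
}

# Inverse of microsat_from_matrices: tidy table -> matrices + sizes.
# Row order: population level order, individual, gene copy.
microsat_to_matrices <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("population", "individual", "locus", "gene_copy",
            "repeat_count", "indel_offset")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("microsat table lacks columns: ",
                        paste(missing, collapse = ", ")))
  }
  pop <- if (is.factor(data$population)) data$population else
    factor(data$population)
  loci <- unique(data$locus)
  # locus outermost so each locus forms one matrix column; within a locus,
  # populations contiguous and the two copies of an individual adjacent
  ord <- order(match(data$locus, loci), as.integer(pop), data$individual,
               data$gene_copy)
  d <- data[ord, ]
  pop <- pop[ord]
  L <- length(loci)
  n_rows <- nrow(d) / L
  if (n_rows != round(n_rows)) {
    rlang::abort("unbalanced microsat table: loci x gene copies do not tile")
  }
  repm <- matrix(d$repeat_count, nrow = n_rows, ncol = L)
  offm <- matrix(d$indel_offset, nrow = n_rows, ncol = L)
  first_block <- seq_len(n_rows)
  sizes <- as.vector(table(pop[first_block])[levels(pop)]) / 2
  list(
    repeat_count = repm, indel_offset = offm,
    sample_sizes = as.integer(sizes),
    pop_labels = levels(pop), locus_labels = loci,
    motif_length = attr(data, "motif_length") %||% 2
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
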