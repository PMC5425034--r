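# Microsatellite summary statistics: the descriptive per-population
# diversity report and the ABC summary-statistic vector.

# Names of the ABC statistics for P populations, in the fixed order used
# everywhere: per population (nal, div, var), then per pair (nal, div, fst,
# das) over pairs (1,2), (1,3), ..., (P-1,P).
stat_names <- function(P = 3) {
  one <- unlist(lapply(seq_len(P), function(p) {
    paste0("P", p, "_", c("nal", "div", "var"))
  }))
  two <- character(0)
  for (a in seq_len(P - 1)) for (b in (a + 1):P) {
    two <- c(two, paste0("P", a, "P", b, "_", c("nal", "div", "fst", "das")))
  }
  c(one, two)
}

#' Per-population microsatellite diversity report
#'
#' Computes, per population and averaged over loci: observed (`ao`) and
#' effective (`ae` = 1 / sum p^2) allele numbers, observed heterozygosity
#' (`ho`, the fraction of heterozygous individuals), unbiased expected
#' heterozygosity (`he`, with the 2n/(2n-1) small-sample correction) and the
#' inbreeding coefficient `f`.
#'
#' @param data A `microsat_tbl`.
#' @param f_method `"ratio_of_means"` computes `f = 1 - mean(ho)/mean(he)`
#'   from the locus-averaged heterozygosities; `"mean_of_ratios"` averages
#'   per-locus `1 - ho/he` over polymorphic loci.
#' @return A tibble with one row per population: `population`, `n`
#'   (individuals), `ao`, `ae`, `ho`, `he`, `f`. `f` is `NA` when `he`
#'   is 0 overall (monomorphic population).
#' @examples
#' d <- sample_parameters(1, n = 1)
#' ms <- simulate_dataset(1, d, n_loci = 10, sample_sizes = c(10, 10, 10))
#' diversity_report(ms)
#' @export
diversity_report <- function(data, f_method = c("ratio_of_means",
                                                "mean_of_ratios")) {
  f_method <- match.arg(f_method)
  stopifnot(nrow(data) > 0)
  key <- allele_id(data)
  per_locus <- data %>%
    dplyr::mutate(.allele = key) %>%
    dplyr::group_by(.data$population, .data$locus) %>%
    dplyr::summarise(
      n = dplyr::n() / 2,
      ao = dplyr::n_distinct(.data$.allele),
      ae = {
        p <- table(.data$.allele) / dplyr::n()
        1 / sum(p^2)
      },
      he = {
        nc <- dplyr::n()
        p <- table(.data$.allele) / nc
        if (nc > 1) nc / (nc - 1) * (1 - sum(p^2)) else 0
      },
      ho = {
        a <- .data$.allele[order(.data$individual, .data$gene_copy)]
        mean(a[seq(1, length(a), 2)] != a[seq(2, length(a), 2)])
      },
      .groups = "drop"
    )
  per_locus %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(
      n = .data$n[1],
      ao = mean(.data$ao),
      ae = mean(.data$ae),
      ho = mean(.data$ho),
      he = mean(.data$he),
      f = if (mean(.data$he) == 0) {
        NA_real_
      } else if (f_method == "ratio_of_means") {
        1 - mean(.data$ho) / mean(.data$he)
      } else {
        poly <- .data$he > 0
        mean(1 - .data$ho[poly] / .data$he[poly])
      },
      .groups = "drop"
    )
}

# allele identity key: repeat count and indel offset must both match
allele_id <- function(data) {
  paste(data$repeat_count, data$indel_offset, sep = "/")
}

#' One-sample ABC statistics for a single population
#'
#' Mean (over loci) number of alleles, mean genetic diversity (unbiased
#' expected heterozygosity) and mean allele-size variance, with allele sizes
#' in nucleotides (`motif_length * repeat_count + indel_offset`).
#'
#' @param data A `microsat_tbl` containing exactly one population (or the
#'   population to use selected beforehand).
#' @return A tibble with columns `statistic` (`nal`, `div`, `var`) and
#'   `value`.
#' @export
one_sample_stats <- function(data) {
  stopifnot(length(unique(data$population)) == 1)
  data$population <- factor(as.character(data$population))
  m <- microsat_to_matrices(data)
  v <- cpp_summary_stats(m$repeat_count, m$indel_offset, m$sample_sizes,
                         as.integer(m$motif_length))
  tibble::tibble(statistic = c("nal", "div", "var"), value = v[1:3])
}

#' Two-sample ABC statistics for a pair of populations
#'
#' Pooled mean number of alleles, pooled mean genetic diversity,
#' Weir-Cockerham theta (Fst; ratio of summed variance components over loci
#' and alleles) and the shared-allele distance DAS = 1 minus the mean
#' proportion of alleles shared between inter-population individual pairs.
#'
#' @param data A `microsat_tbl`.
#' @param pops Length-2 vector naming the two populations to compare.
#' @return A tibble with columns `statistic` (`nal`, `div`, `fst`, `das`)
#'   and `value`. `fst` is `NA` when both populations are monomorphic for
#'   the same allele at every locus.
#' @export
pairwise_stats <- function(data, pops = levels(factor(data$population))[1:2]) {
  stopifnot(length(pops) == 2)
  sub <- data[as.character(data$population) %in% as.character(pops), ]
  sub$population <- factor(as.character(sub$population),
                           levels = as.character(pops))
  attr(sub, "motif_length") <- attr(data, "motif_length") %||% 2
  m <- microsat_to_matrices(sub)
  v <- cpp_summary_stats(m$repeat_count, m$indel_offset, m$sample_sizes,
                         as.integer(m$motif_length))
  if (!is.na(v[9]) && (v[9] < -1 || v[9] > 1)) {
    rlang::warn("Weir-Cockerham theta outside [-1, 1]; check input")
  }
  tibble::tibble(statistic = c("nal", "div", "fst", "das"), value = v[7:10])
}

#' The full ABC summary-statistic vector
#'
#' Concatenates, in a fixed documented order, the one-sample statistics of
#' every population and the two-sample statistics of every population pair:
#' for P populations the vector has length `3P + 4 P(P-1)/2` (21 for P = 3).
#' Names follow `P<i>_<stat>` and `P<i>P<j>_<stat>`.
#'
#' @param data A `microsat_tbl`.
#' @return A tibble with columns `statistic` and `value`, in vector order.
#' @examples
#' d <- sample_parameters(1, n = 1)
#' ms <- simulate_dataset(1, d, n_loci = 5, sample_sizes = c(6, 6, 6))
#' summary_vector(ms)
#' @export
summary_vector <- function(data) {
  m <- microsat_to_matrices(data)
  v <- cpp_summary_stats(m$repeat_count, m$indel_offset, m$sample_sizes,
                         as.integer(m$motif_length))
  tibble::tibble(statistic = stat_names(length(m$sample_sizes)), value = v)
}

# fast path used by the reference-table builder: matrices in, named vector out
summary_vector_matrices <- function(repm, offm, sample_sizes,
                                    motif_length = 2) {
  v <- cpp_summary_stats(repm, offm, as.integer(sample_sizes),
                         as.integer(motif_length))
  names(v) <- stat_names(length(sample_sizes))
  v
}

#' Permutation test for Hardy-Weinberg proportions per locus
#'
#' Shuffles gene copies among the individuals of a population to build the
#' null distribution of observed heterozygosity and reports a two-sided
#' p-value per locus, with a Bonferroni significance flag.
#'
#' @param data A `microsat_tbl`.
#' @param n_perm Number of permutations.
#' @param alpha Family-wise significance level before Bonferroni division.
#' @return A tibble: `population`, `locus`, `ho`, `p_value`, `significant`.
#' @export
hwe_test <- function(data, n_perm = 500, alpha = 0.05) {
  key <- allele_id(data)
  d <- data %>% dplyr::mutate(.allele = key)
  res <- d %>%
    dplyr::group_by(.data$population, .data$locus) %>%
    dplyr::summarise(
      ho = {
        a <- .data$.allele[order(.data$individual, .data$gene_copy)]
        mean(a[seq(1, length(a), 2)] != a[seq(2, length(a), 2)])
      },
      p_value = {
        a <- .data$.allele[order(.data$individual, .data$gene_copy)]
        obs <- mean(a[seq(1, length(a), 2)] != a[seq(2, length(a), 2)])
        null <- replicate(n_perm, {
          s <- sample(a)
          mean(s[seq(1, length(s), 2)] != s[seq(2, length(s), 2)])
        })
        lo <- (sum(null <= obs) + 1) / (n_perm + 1)
        hi <- (sum(null >= obs) + 1) / (n_perm + 1)
        min(1, 2 * min(lo, hi))
      },
      .groups = "drop"
    )
  n_tests <- nrow(res)
  res$significant <- res$p_value < alpha / n_tests
  res
}
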