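# Independently coded brute-force oracles for the summary statistics.
# These deliberately use naive enumeration (loops over gene copies,
# individuals and sequence pairs) so they share no code path with the
# package's implementations.

# Unbiased expected heterozygosity as the exact probability that two gene
# copies drawn without replacement differ, enumerated over all pairs.
oracle_he <- function(alleles) {
  n <- length(alleles)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diff <- diff + (alleles[i] != alleles[j])
  }
  diff / choose(n, 2)
}

# Weir & Cockerham (1984) theta for r populations, transcribed directly
# from the published variance-component formulas with explicit loops over
# loci and alleles. genotype list: per population, a (2n x L) matrix of
# allele labels with the two rows of an individual adjacent.
oracle_theta <- function(pop_mats) {
  r <- length(pop_mats)
  L <- ncol(pop_mats[[1]])
  num <- 0; den <- 0
  for (l in 1:L) {
    allele_set <- unique(unlist(lapply(pop_mats, function(m) m[, l])))
    n_i <- vapply(pop_mats, function(m) nrow(m) / 2, numeric(1))
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in allele_set) {
      p_i <- vapply(pop_mats, function(m) mean(m[, l] == al), numeric(1))
      h_i <- vapply(pop_mats, function(m) {
        n <- nrow(m) / 2
        het <- 0
        for (k in 1:n) {
          g <- m[c(2 * k - 1, 2 * k), l]
          if (g[1] != g[2] && al %in% g) het <- het + 1
        }
        het / n
      }, numeric(1))
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# Nucleotide diversity as the mean pairwise difference over every one of
# the choose(n, 2) sequence pairs after expanding haplotype counts.
oracle_pi <- function(seqs, counts, L, count_gaps = FALSE) {
  all_seqs <- rep(seqs, times = counts)
  n <- length(all_seqs)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(all_seqs[i], "")[[1]]
    b <- strsplit(all_seqs[j], "")[[1]]
    both <- a != "-" & b != "-"
    d <- sum(a[both] != b[both])
    if (count_gaps) d <- d + sum(xor(a == "-", b == "-"))
    tot <- tot + d
  }
  tot / choose(n, 2) / L
}

# Shared-allele distance by explicit enumeration of inter-population
# individual pairs: per pair and locus, the number of alleles the two
# genotypes share (multiset intersection), divided by 2.
oracle_das <- function(mat_a, mat_b) {
  na <- nrow(mat_a) / 2; nb <- nrow(mat_b) / 2
  L <- ncol(mat_a)
  tot <- 0; cnt <- 0
  for (i in 1:na) for (j in 1:nb) for (l in 1:L) {
    ga <- mat_a[c(2 * i - 1, 2 * i), l]
    gb <- mat_b[c(2 * j - 1, 2 * j), l]
    shared <- 0
    used <- c(FALSE, FALSE)
    for (x in ga) {
      hit <- which(!used & gb == x)
      if (length(hit) > 0) { shared <- shared + 1; used[hit[1]] <- TRUE }
    }
    tot <- tot + shared / 2
    cnt <- cnt + 1
  }
  1 - tot / cnt
}

# microsat_tbl -> per-population matrices of composite allele labels
pop_allele_mats <- function(data) {
  m <- msatabc:::microsat_to_matrices(data)
  lab <- matrix(paste(m$repeat_count, m$indel_offset, sep = "/"),
                nrow = nrow(m$repeat_count))
  row0 <- c(0, cumsum(2 * m$sample_sizes))
  lapply(seq_along(m$sample_sizes), function(p) {
    lab[(row0[p] + 1):row0[p + 1], , drop = FALSE]
  })
}

# small random microsat table for property tests
random_microsat <- function(n_ind = c(4, 5), n_loci = 3, n_alleles = 4,
                            sni = TRUE) {
  P <- length(n_ind)
  rows <- 2 * sum(n_ind)
  repm <- matrix(sample(10:(9 + n_alleles), rows * n_loci, replace = TRUE),
                 nrow = rows)
  offm <- if (sni) {
    matrix(sample(c(0L, 0L, 0L, 1L, -1L), rows * n_loci, replace = TRUE),
           nrow = rows)
  } else {
    matrix(0L, nrow = rows, ncol = n_loci)
  }
  msatabc:::microsat_from_matrices(repm, offm, n_ind)
}
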