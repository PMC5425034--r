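# mtDNA haplotype statistics: multi-fragment concatenation, indel-aware
# haplotype collapsing, haplotype (H) and nucleotide (pi) diversity, and
# FASTA input/output.

#' Concatenate per-region alignments into a multi-fragment alignment
#'
#' @param fragments A tibble with columns `sample_id`, `region`, `sequence`
#'   (aligned, equal length within a region; gaps `-` allowed), e.g. from
#'   [make_mtdna_fixture()] or [read_fasta()] calls bound together.
#' @return A tibble `sample_id`, `sequence` with the concatenated sequence;
#'   per-region lengths are kept in the `region_lengths` attribute (region
#'   boundaries are `cumsum` of these).
#' @examples
#' fr <- make_mtdna_fixture(c(3, 2), region_lengths = c(CR = 40, ND4 = 60),
#'                          n_variants = 1)
#' nchar(concatenate_regions(fr)$sequence[1])
#' @export
concatenate_regions <- function(fragments) {
  stopifnot(all(c("sample_id", "region", "sequence") %in% names(fragments)))
  regions <- unique(fragments$region)
  lens <- integer(0)
  wide <- NULL
  for (r in regions) {
    fr <- fragments[fragments$region == r, ]
    if (length(unique(nchar(fr$sequence))) != 1) {
      rlang::abort(paste0("region ", r, " is not aligned (unequal lengths)"))
    }
    lens[r] <- nchar(fr$sequence[1])
    fr <- fr[, c("sample_id", "sequence")]
    names(fr)[2] <- r
    wide <- if (is.null(wide)) fr else {
      miss <- c(setdiff(wide$sample_id, fr$sample_id),
                setdiff(fr$sample_id, wide$sample_id))
      if (length(miss) > 0) {
        rlang::abort(paste0("samples missing from some region: ",
                            paste(unique(miss), collapse = ", ")))
      }
      dplyr::left_join(wide, fr, by = "sample_id")
    }
  }
  out <- tibble::tibble(
    sample_id = wide$sample_id,
    sequence = do.call(paste0, wide[regions])
  )
  attr(out, "region_lengths") <- lens
  out
}

#' Collapse aligned sequences into haplotypes (indel-aware)
#'
#' Two sequences belong to the same haplotype only if they are identical at
#' every alignment column, gap characters included; an indel therefore
#' separates haplotypes. Ambiguity codes are treated as plain mismatching
#' states (strict comparison).
#'
#' @param alignment A tibble with `sample_id` and `sequence` (equal-length
#'   aligned sequences), optionally a `population` column.
#' @return A `haplotype_tbl`: `haplotype` (`H1`, `H2`, ... by decreasing
#'   count), `sequence`, `count`, and if populations were given one
#'   count column per population.
#' @export
collapse_haplotypes <- function(alignment) {
  stopifnot(all(c("sample_id", "sequence") %in% names(alignment)))
  seqs <- toupper(alignment$sequence)
  if (length(unique(nchar(seqs))) != 1) {
    rlang::abort("sequences are not aligned (unequal lengths)")
  }
  fac <- factor(seqs, levels = unique(seqs))
  cnt <- as.vector(table(fac))
  ord <- order(-cnt)
  out <- tibble::tibble(
    haplotype = paste0("H", seq_along(ord)),
    sequence = levels(fac)[ord],
    count = cnt[ord]
  )
  if ("population" %in% names(alignment)) {
    tab <- table(fac, alignment$population)
    for (p in colnames(tab)) out[[p]] <- as.vector(tab[ord, p])
  }
  class(out) <- c("haplotype_tbl", class(out))
  out
}

#' Haplotype diversity
#'
#' Unbiased gene diversity of a haplotype frequency distribution:
#' `H = n/(n-1) * (1 - sum(p_i^2))`, the small-sample-corrected probability
#' that two randomly drawn sequences carry different haplotypes.
#'
#' @param counts Integer haplotype counts, or a `haplotype_tbl` (its
#'   `count` column is used).
#' @return `H` as a single number.
#' @examples
#' haplotype_diversity(c(34, 5)) # 0.229 to 3 decimals
#' @export
haplotype_diversity <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) rlang::abort("haplotype diversity needs n >= 2 sequences")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity
#'
#' Unbiased mean pairwise nucleotide difference per site:
#' `pi = n/(n-1) * sum_{i<j} 2 p_i p_j d_ij / L`. By default `d_ij` counts
#' only columns where both sequences carry a base (gap-containing columns
#' distinguish haplotypes but are excluded from the difference count) and
#' `L` is the alignment length; set `count_gaps = TRUE` to count
#' base-vs-gap columns as differences.
#'
#' @param haplotypes A `haplotype_tbl` (from [collapse_haplotypes()]), or a
#'   character vector of aligned haplotype sequences.
#' @param counts Haplotype counts (ignored when `haplotypes` is a
#'   `haplotype_tbl`).
#' @param length Alignment length `L`; defaults to the sequence length.
#' @param count_gaps Count base-vs-gap columns in `d_ij`.
#' @return `pi` as a single number.
#' @examples
#' fr <- make_mtdna_fixture(c(34, 5), region_lengths = 498, n_variants = 1)
#' nucleotide_diversity(collapse_haplotypes(concatenate_regions(fr)))
#' @export
nucleotide_diversity <- function(haplotypes, counts = NULL, length = NULL,
                                 count_gaps = FALSE) {
  if (is.data.frame(haplotypes)) {
    counts <- haplotypes$count
    seqs <- haplotypes$sequence
  } else {
    seqs <- haplotypes
  }
  stopifnot(length(seqs) == length(counts))
  keep <- counts > 0
  seqs <- toupper(seqs[keep]); counts <- counts[keep]
  n <- sum(counts)
  if (n < 2) rlang::abort("nucleotide diversity needs n >= 2 sequences")
  L <- length %||% nchar(seqs[1])
  k <- base::length(seqs)
  if (k == 1) return(0)
  mats <- strsplit(seqs, "")
  d <- function(a, b) {
    both <- mats[[a]] != "-" & mats[[b]] != "-"
    diffs <- sum(mats[[a]][both] != mats[[b]][both])
    if (count_gaps) diffs <- diffs + sum(xor(mats[[a]] == "-",
                                             mats[[b]] == "-"))
    diffs
  }
  p <- counts / n
  tot <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    tot <- tot + 2 * p[i] * p[j] * d(i, j)
  }
  n / (n - 1) * tot / L
}

#' Read / write FASTA alignments
#'
#' Thin wrappers around Biostrings returning and accepting tidy tibbles.
#'
#' @param path FASTA file path.
#' @param region Optional region label attached to every record.
#' @return `read_fasta()` returns a tibble `sample_id`, `sequence` (plus
#'   `region` if given).
#' @export
read_fasta <- function(path, region = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("Biostrings is required for FASTA input/output")
  }
  x <- Biostrings::readBStringSet(path)
  out <- tibble::tibble(sample_id = names(x),
                        sequence = unname(as.character(x)))
  if (!is.null(region)) out$region <- region
  out
}

#' @rdname read_fasta
#' @param alignment Tibble with `sample_id` and `sequence`.
#' @export
write_fasta <- function(alignment, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("Biostrings is required for FASTA input/output")
  }
  x <- Biostrings::BStringSet(setNames(alignment$sequence,
                                       alignment$sample_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
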