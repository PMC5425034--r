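# Genepop input/output for microsatellite tables.
#
# Allele encoding: each allele is written as a 3-digit code equal to its
# size in nucleotides plus a constant of 100, with
# size = motif_length * repeat_count + indel_offset. Decoding recovers
# repeat_count = size %/% motif_length and indel_offset = size %% motif
# length, which is exact for ladder alleles (offset 0) and preserves
# identity-by-size for off-ladder alleles. Code 000 denotes missing.

GENEPOP_CONST <- 100L

encode_allele <- function(repeat_count, indel_offset, motif_length = 2) {
  code <- motif_length * repeat_count + indel_offset + GENEPOP_CONST
  if (any(code < 1 | code > 999)) {
    rlang::abort("allele size out of the 3-digit Genepop range")
  }
  sprintf("%03d", code)
}

decode_allele <- function(code, motif_length = 2) {
  size <- as.integer(code) - GENEPOP_CONST
  list(repeat_count = size %/% motif_length,
       indel_offset = size %% motif_length)
}

#' Write a microsatellite table in Genepop format
#'
#' @param data A `microsat_tbl` (see [simulate_dataset()]).
#' @param path Output file path.
#' @param title Title line written as the first record.
#' @return `path`, invisibly.
#' @seealso [read_genepop()] for the inverse; the allele encoding (3-digit
#'   code = allele size in nucleotides + 100) is exactly invertible for
#'   ladder alleles and identity-preserving otherwise.
#' @export
write_genepop <- function(data, path, title = "msatabc dataset") {
  m <- microsat_to_matrices(data)
  lines <- c(title, m$locus_labels)
  P <- length(m$pop_labels)
  row0 <- c(0, cumsum(2 * m$sample_sizes))
  for (p in seq_len(P)) {
    lines <- c(lines, "POP")
    for (i in seq_len(m$sample_sizes[p])) {
      r1 <- row0[p] + 2 * i - 1
      g <- paste0(
        encode_allele(m$repeat_count[r1, ], m$indel_offset[r1, ],
                      m$motif_length),
        encode_allele(m$repeat_count[r1 + 1, ], m$indel_offset[r1 + 1, ],
                      m$motif_length)
      )
      lines <- c(lines,
                 paste0(m$pop_labels[p], "_", i, " ,  ",
                        paste(g, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Genepop file into a microsatellite table
#'
#' Accepts the standard dialect: a title line, locus names (one per line or
#' comma-separated on one line), then `POP` blocks of
#' `id , 6-digit genotypes`. Populations are labelled `pop1`, `pop2`, ... in
#' file order.
#'
#' @param path Genepop file path.
#' @param motif_length Motif length used by the allele encoding.
#' @return A `microsat_tbl`.
#' @export
read_genepop <- function(path, motif_length = 2) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) {
    rlang::abort("not a Genepop file: need a title, locus names and POP")
  }
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)

  pops <- cumsum(is_pop)
  rows_rep <- list(); rows_off <- list(); sizes <- integer(0); inds <- list()
  for (p in seq_len(max(pops))) {
    sel <- which(pops == p & !is_pop)
    sel <- sel[sel > first_pop - 1]
    ids <- character(0); repm <- NULL; offm <- NULL
    for (ln in lines[sel]) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2) {
        rlang::abort(paste0("malformed Genepop record: ", ln))
      }
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "[[:space:]]+")[[1]]
      if (length(codes) != L) {
        rlang::abort(paste0("individual ", id, " has ", length(codes),
                            " genotypes for ", L, " loci"))
      }
      a1 <- decode_allele(substr(codes, 1, 3), motif_length)
      a2 <- decode_allele(substr(codes, 4, 6), motif_length)
      ids <- c(ids, id)
      repm <- rbind(repm, a1$repeat_count, a2$repeat_count)
      offm <- rbind(offm, a1$indel_offset, a2$indel_offset)
    }
    sizes <- c(sizes, length(ids))
    rows_rep[[p]] <- repm
    rows_off[[p]] <- offm
    inds[[p]] <- ids
  }
  microsat_from_matrices(
    do.call(rbind, rows_rep), do.call(rbind, rows_off), sizes,
    pop_labels = paste0("pop", seq_along(sizes)),
    locus_labels = loci, motif_length = motif_length
  )
}
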