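#' Locate zero-mismatch primer sites on both strands of a genome
#'
#' `+`-strand hits are occurrences of the primer's expanded concrete set;
#' `-`-strand hits are occurrences of its reverse complement's expanded
#' set. Both are reported in forward-strand coordinates (1-based,
#' inclusive) and sorted by start. Overlapping occurrences are all
#' reported.
#'
#' @param genome one-row genome record (needs `accession`, `sequence`) or
#'   a plain nucleotide string.
#' @param primer_sequence IUPAC primer sequence, 5'->3'.
#' @param primer_id identifier stored in the result.
#' @return `data.frame` with columns `accession`, `primer_id`, `strand`,
#'   `start`, `end`.
#' @export
find_primer_sites <- function(genome, primer_sequence, primer_id = NA_character_) {
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1L)
    seq <- genome$sequence
    acc <- genome$accession
  } else {
    seq <- genome
    acc <- NA_character_
  }
  w <- nchar(primer_sequence)
  fwd <- find_matches(seq, primer_sequence)
  rev <- find_matches(seq, reverse_complement(primer_sequence))
  n_hits <- length(fwd) + length(rev)
  out <- data.frame(
    accession = rep(acc, n_hits),
    primer_id = rep(primer_id, n_hits),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    start = c(fwd, rev),
    stringsAsFactors = FALSE
  )
  out$end <- out$start + w - 1L
  out[order(out$start, out$strand), , drop = FALSE]
}

.empty_amplicons <- function() {
  out <- data.frame(species_id = integer(), pair_id = character(),
                    accession = character(), start = integer(),
                    end = integer(), strand = character(),
                    reported_length = integer(), sequence = character(),
                    stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS) out[[r]] <- character()
  out
}

.subseq_rc <- function(sequence, start, end, strand) {
  s <- substr(sequence, start, end)
  if (strand == "-") reverse_complement(s) else s
}

#' Extract in-silico amplicons of one primer pair from one genome
#'
#' An amplicon is emitted for every combination of a forward-primer site
#' and a downstream reverse-primer site (the reverse complement of the
#' reverse primer) on the same strand whose reported length -- the
#' distance from the first base of the forward site to the last base of
#' the reverse site -- lies strictly between `min_len` and `max_len`
#' nucleotides. Both genome strands are scanned; minus-strand amplicons
#' are reverse-complemented so every emitted sequence reads
#' forward-primer-first, and their `start`/`end` remain forward-strand
#' coordinates of the inclusive span. The extracted sequence is the full
#' inclusive span, i.e. `reported_length + 1` bases including both primer
#' sites.
#'
#' @param genome one-row genome record from [read_genomes()].
#' @param pair one catalog row (needs `pair_id`, `f_seq`, `r_seq`).
#' @param min_len,max_len strict bounds on the reported length
#'   (defaults 100 and 2300).
#' @return Amplicon `data.frame` (no variant numbering yet).
#' @export
extract_amplicons <- function(genome, pair, min_len = 100L, max_len = 2300L) {
  stopifnot(is.data.frame(genome), nrow(genome) == 1L)
  pair <- as.list(pair)
  f_hits <- find_primer_sites(genome, pair$f_seq, "F")
  r_hits <- find_primer_sites(genome, pair$r_seq, "R")

  res <- list()
  add <- function(start, end, strand) {
    data.frame(species_id = genome$species_id %||% NA_integer_,
               pair_id = pair$pair_id, accession = genome$accession,
               start = start, end = end, strand = strand,
               reported_length = end - start,
               sequence = .subseq_rc(genome$sequence, start, end, strand),
               genome[intersect(TAXONOMY_RANKS, names(genome))],
               stringsAsFactors = FALSE, row.names = NULL)
  }

  # plus strand: forward site (+) upstream of the reverse primer's rc site (-)
  fs <- f_hits[f_hits$strand == "+", ]
  rs <- r_hits[r_hits$strand == "-", ]
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    len <- rs$end[j] - fs$start[i]
    if (len > min_len && len < max_len) {
      res[[length(res) + 1L]] <- add(fs$start[i], rs$end[j], "+")
    }
  }
  # minus strand: forward primer matched the reverse complement, so its
  # site is a (-) hit ending at the minus-strand 5' side; the reverse
  # primer itself matches the forward strand (+)
  fs <- f_hits[f_hits$strand == "-", ]
  rs <- r_hits[r_hits$strand == "+", ]
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    len <- fs$end[i] - rs$start[j]
    if (len > min_len && len < max_len) {
      res[[length(res) + 1L]] <- add(rs$start[j], fs$end[i], "-")
    }
  }
  if (!length(res)) return(.empty_amplicons())
  out <- do.call(rbind, res)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Collapse amplicons to unique per-species sequence variants
#'
#' Amplicons from all strains/records of a species are pooled; identical
#' sequences within a species collapse to one record, and distinct
#' sequences (>= 1 nucleotide difference) receive variant numbers
#' `V1, V2, ...` in order of first appearance (by accession, then
#' forward-strand coordinate). Identical sequences in *different* species
#' are not collapsed.
#'
#' @param amplicons raw amplicon `data.frame` from [extract_amplicons()]
#'   (one primer pair, any number of genomes).
#' @return Amplicon `data.frame` with a `variant_id` column, one row per
#'   (species, variant).
#' @export
collapse_species_variants <- function(amplicons) {
  if (nrow(amplicons) == 0L) {
    out <- amplicons
    out$variant_id <- integer()
    return(out)
  }
  if (length(unique(amplicons$pair_id)) != 1L) {
    stop("amplicons must all belong to one primer pair", call. = FALSE)
  }
  ord <- order(amplicons$species_id, amplicons$accession,
               amplicons$start, amplicons$end)
  amplicons <- amplicons[ord, , drop = FALSE]
  keep <- !duplicated(paste(amplicons$species_id, amplicons$sequence,
                            sep = "\r"))
  out <- amplicons[keep, , drop = FALSE]
  out$variant_id <- as.integer(stats::ave(seq_len(nrow(out)),
                                          out$species_id, FUN = seq_along))
  rownames(out) <- NULL
  out[, c("species_id", "variant_id",
          setdiff(names(out), c("species_id", "variant_id")))]
}

#' Extract and collapse amplicons for a set of genomes
#'
#' Convenience wrapper: runs [extract_amplicons()] over every genome row
#' and [collapse_species_variants()] on the pooled result.
#'
#' @inheritParams extract_amplicons
#' @param genomes genome `data.frame` (QC-passed).
#' @return Variant-numbered amplicon `data.frame`.
#' @export
extract_all <- function(genomes, pair, min_len = 100L, max_len = 2300L) {
  parts <- lapply(seq_len(nrow(genomes)), function(i) {
    extract_amplicons(genomes[i, , drop = FALSE], pair, min_len, max_len)
  })
  collapse_species_variants(do.call(rbind, c(parts, list(.empty_amplicons()))))
}
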