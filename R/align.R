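#' Alignment scoring constants
#'
#' Defaults mirror the megablast defaults: match reward +1, mismatch
#' penalty -2, and a simple linear gap cost of -2 per gapped base (no
#' separate opening cost).
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch penalty.
#' @param gap negative per-base gap cost.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, gap = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  if (!(match > 0L && mismatch < 0L && gap < 0L)) {
    stop("need match > 0, mismatch < 0, gap < 0", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "align_scoring")
}

.check_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  toupper(x)
}

#' Exact semiglobal alignment of a query against a subject
#'
#' Optimal-score alignment of the *full* query against any contiguous
#' region of the subject (free end gaps on the subject only), computed by
#' exact dynamic programming, so query coverage is 100% by construction.
#' Percent identity follows the BLAST `pident` definition: identical
#' columns over total alignment columns, gap columns included in the
#' denominator. Ambiguity codes count as mismatches to everything. Ties
#' in score are broken deterministically: fewer gap columns first, then
#' leftmost subject start.
#'
#' @param query,subject nucleotide strings (uppercased internally).
#' @param scoring an [align_scoring()] object.
#' @return List with `score`, `identities`, `alignment_columns`,
#'   `gap_columns`, `pident`, `qcovs` (always 100), `subject_start`,
#'   `subject_end`, `aligned_query`, `aligned_subject`.
#' @examples
#' semiglobal_align("ACGT", "TTACGTTT")$pident  # 100
#' @export
semiglobal_align <- function(query, subject, scoring = align_scoring()) {
  query <- .check_seq(query, "query")
  subject <- .check_seq(subject, "subject")
  .semiglobal_align_cpp(query, subject, scoring$match, scoring$mismatch,
                        scoring$gap)
}

#' All-vs-all alignment of the amplicons of one primer pair
#'
#' Every ordered (query, subject) combination, including self-alignments,
#' is aligned with [semiglobal_align()]; self and same-species results are
#' discarded later by [filter_asi97()], mirroring the post-alignment
#' discard rules of the screening protocol.
#'
#' @param amplicons variant-numbered amplicon `data.frame` (one primer
#'   pair) from [collapse_species_variants()].
#' @param scoring an [align_scoring()] object.
#' @return `data.frame` with one row per ordered pair: `pair_id`,
#'   `query_id`, `subject_id`, `species_q`, `species_s`, `pident`,
#'   `alignment_columns`, `identities`, `qcovs`, `score`.
#' @export
all_vs_all <- function(amplicons, scoring = align_scoring()) {
  n <- nrow(amplicons)
  if (n < 1L) stop("need at least one amplicon", call. = FALSE)
  ids <- paste0("SP", amplicons$species_id, ".V", amplicons$variant_id)
  idx <- expand.grid(q = seq_len(n), s = seq_len(n))
  res <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    q <- idx$q[k]; s <- idx$s[k]
    al <- semiglobal_align(amplicons$sequence[q], amplicons$sequence[s],
                           scoring)
    res[[k]] <- data.frame(
      pair_id = amplicons$pair_id[q],
      query_id = ids[q], subject_id = ids[s],
      species_q = amplicons$species_id[q],
      species_s = amplicons$species_id[s],
      pident = al$pident, alignment_columns = al$alignment_columns,
      identities = al$identities, qcovs = al$qcovs, score = al$score,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

#' Filter alignments to similarity relations between distinct species
#'
#' Keeps alignments with 100% query coverage and percent identity at or
#' above `threshold` (inclusive, with a 1e-9 floating-point guard), then
#' discards self-alignments (same SPn.Vn), alignments within one species
#' (same SPn) and symmetric duplicates. When several alignments remain
#' for an unordered species pair (multiple variants), one representative
#' is chosen uniformly at random under `rng_seed`; the *set* of species
#' pairs retained does not depend on the seed, only the representative
#' alignment does.
#'
#' @param results `data.frame` from [all_vs_all()] (one primer pair).
#' @param threshold percent-identity threshold (default 97).
#' @param rng_seed seed for the random representative; `NULL` uses the
#'   current RNG state.
#' @return `data.frame` with one row per unordered species pair:
#'   `pair_id`, `species_a`, `species_b` (canonical `a < b`), `pident`,
#'   `alignment_columns`, `identities`, `query_id`, `subject_id`, sorted
#'   by (`species_a`, `species_b`).
#' @export
filter_asi97 <- function(results, threshold = 97, rng_seed = NULL) {
  keep <- results$qcovs == 100 &
    results$pident >= threshold - 1e-9 &
    results$query_id != results$subject_id &
    results$species_q != results$species_s
  r <- results[keep, , drop = FALSE]
  empty <- data.frame(pair_id = character(), species_a = character(),
                      species_b = character(), pident = numeric(),
                      alignment_columns = integer(), identities = integer(),
                      query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(r) == 0L) return(empty)

  vkey <- ifelse(r$query_id < r$subject_id,
                 paste(r$query_id, r$subject_id, sep = "\r"),
                 paste(r$subject_id, r$query_id, sep = "\r"))
  r <- r[!duplicated(vkey), , drop = FALSE]

  a <- pmin(r$species_q, r$species_s)
  b <- pmax(r$species_q, r$species_s)
  skey <- paste(a, b, sep = "\r")
  groups <- split(seq_len(nrow(r)), skey)
  pick_one <- function() {
    vapply(groups, function(ii) {
      if (length(ii) == 1L) ii else ii[sample.int(length(ii), 1L)]
    }, integer(1L))
  }
  chosen <- if (is.null(rng_seed)) pick_one() else with_seed(rng_seed, pick_one())

  out <- data.frame(
    pair_id = r$pair_id[chosen],
    species_a = paste0("SP", a[chosen]),
    species_b = paste0("SP", b[chosen]),
    pident = r$pident[chosen],
    alignment_columns = r$alignment_columns[chosen],
    identities = r$identities[chosen],
    query_id = r$query_id[chosen],
    subject_id = r$subject_id[chosen],
    stringsAsFactors = FALSE
  )
  out <- out[order(a[chosen], b[chosen]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write similarity relations as a BLAST outfmt-6-like TSV
#'
#' Columns: `pair_id`, `species_a`, `species_b`, `pident`,
#' `alignment_columns` (BLAST `length`), `identities` (BLAST `nident`),
#' `query_id` (`qseqid`), `subject_id` (`sseqid`).
#'
#' @param relations `data.frame` from [filter_asi97()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_relations_tsv <- function(relations, path) {
  write.table(relations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
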