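#' IUPAC nucleotide ambiguity codes
#'
#' Named list mapping each of the 15 IUPAC nucleotide codes to the set of
#' concrete bases it denotes (e.g. `R` = A/G, `N` = A/C/G/T).
#'
#' @format A named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.iupac_letters <- names(IUPAC_CODES)

# Split a sequence into single characters, validating against the IUPAC
# alphabet; errors name the first offending position.
.iupac_chars <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .iupac_letters)
  if (length(bad)) {
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  chars
}

#' Number of concrete sequences denoted by a degenerate sequence
#'
#' @param sequence IUPAC nucleotide string.
#' @return Integer: the product of the per-position code-set sizes.
#' @export
degenerate_cardinality <- function(sequence) {
  chars <- .iupac_chars(sequence)
  prod(vapply(IUPAC_CODES[chars], length, integer(1L)))
}

#' Expand a degenerate sequence into all concrete realizations
#'
#' Each IUPAC code denotes a set of bases; the expansion is the Cartesian
#' product over positions, so the result has [degenerate_cardinality()]
#' elements, all plain A/C/G/T strings.
#'
#' @param sequence IUPAC nucleotide string.
#' @param max_cardinality guard against combinatorial blow-up.
#' @return Character vector of concrete sequences.
#' @examples
#' expand_degenerate("AY")  # "AC" "AT"
#' @export
expand_degenerate <- function(sequence, max_cardinality = 2^20) {
  chars <- .iupac_chars(sequence)
  card <- prod(vapply(IUPAC_CODES[chars], length, integer(1L)))
  if (card > max_cardinality) {
    stop("degenerate cardinality ", card, " exceeds max_cardinality",
         call. = FALSE)
  }
  grid <- expand.grid(rev(unname(IUPAC_CODES[chars])),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}

.COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN"
.COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented as sets (R<->Y, K<->M, B<->V, D<->H;
#' S, W and N are self-complementary), so the operation is an involution.
#'
#' @param sequence IUPAC nucleotide string.
#' @return The reverse-complemented IUPAC string.
#' @examples
#' reverse_complement("TTACCGCGGCKGCTG")  # "CAGCMGCCGCGGTAA"
#' @export
reverse_complement <- function(sequence) {
  chars <- .iupac_chars(sequence)
  comp <- chartr(.COMPLEMENT_FROM, .COMPLEMENT_TO, paste(chars, collapse = ""))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Classify a mean amplicon length into the S/M/L category
#'
#' Short: 100-300 bps; medium: 301-600 bps; long: >600 bps. Lengths below
#' 100 fall outside the catalog's domain and raise an error.
#'
#' @param mean_amplicon_length positive integer length in base pairs.
#' @return `"S"`, `"M"` or `"L"`.
#' @export
classify_length_category <- function(mean_amplicon_length) {
  l <- mean_amplicon_length
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l <= 0) {
    stop("mean_amplicon_length must be a single positive number", call. = FALSE)
  }
  if (l < 100) stop("amplicon length ", l, " is below the catalog domain (>= 100)",
                    call. = FALSE)
  if (l <= 300) "S" else if (l <= 600) "M" else "L"
}

# Zero-mismatch matching rule: a genome base g matches primer code p when
# g is a concrete base contained in baseset(p); a genome ambiguity code
# matches only the identical primer code. Encoded as a regex character
# class per position (base set plus the literal code for degenerate codes).
.primer_regex <- function(primer_sequence) {
  chars <- .iupac_chars(primer_sequence, "primer")
  classes <- vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (length(bases) == 1L) ch else
      paste0("[", paste(c(bases, ch), collapse = ""), "]")
  }, character(1L))
  paste(classes, collapse = "")
}

#' Scan a nucleotide string for zero-mismatch occurrences of a degenerate primer
#'
#' All occurrences are reported, including overlapping ones (the scan
#' advances one position at a time). Matching is strict: each genome
#' position must be a concrete base belonging to the primer code's base
#' set (or, for genome-side ambiguity codes, the identical code).
#'
#' @param subject nucleotide string to scan (uppercased internally).
#' @param primer_sequence IUPAC primer sequence, 5'->3'.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
find_matches <- function(subject, primer_sequence) {
  if (!is.character(subject) || length(subject) != 1L || is.na(subject)) {
    stop("subject must be a single string", call. = FALSE)
  }
  subject <- toupper(subject)
  if (nchar(subject) < nchar(primer_sequence)) return(integer(0))
  rx <- paste0("(?=", .primer_regex(primer_sequence), ")")
  hits <- gregexpr(rx, subject, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}
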