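# Independent oracles: deliberately brute-force / closed-form, sharing no
# code with the package implementation.

# IUPAC base sets, restated literally for independence from IUPAC_CODES
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# recursive expansion of a degenerate sequence
oracle_expand <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- ""
  for (ch in chars) {
    out <- as.vector(outer(out, ORACLE_IUPAC[[ch]], paste0))
  }
  sort(out)
}

# brute-force zero-mismatch site scan: try every expansion at every offset
oracle_find_sites <- function(genome, primer) {
  w <- nchar(primer)
  n <- nchar(genome)
  if (n < w) return(integer(0))
  hits <- integer(0)
  expansions <- oracle_expand(primer)
  for (start in seq_len(n - w + 1L)) {
    if (substr(genome, start, start + w - 1L) %in% expansions) {
      hits <- c(hits, start)
    }
  }
  hits
}

# Exhaustive semiglobal alignment: enumerate every monotone alignment of
# the full query against every contiguous subject region, then apply the
# contract's tie-break (max score, then fewest gap columns). Returns the
# optimum's score, gap count, identities and column count (which are
# determined by score+gaps for linear scoring).
oracle_semiglobal <- function(query, subject, match = 1, mismatch = -2,
                              gap = -2) {
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  best <- NULL
  consider <- function(score, gaps, ident, cols) {
    if (is.null(best) || score > best$score ||
        (score == best$score && gaps < best$gaps)) {
      best <<- list(score = score, gaps = gaps, identities = ident,
                    columns = cols)
    }
  }
  recurse <- function(i, t, score, gaps, ident, cols) {
    if (i > length(q) && !nchar(t)) {
      consider(score, gaps, ident, cols)
      return(invisible())
    }
    if (i <= length(q) && nchar(t)) {
      hit <- q[i] == substr(t, 1L, 1L)
      recurse(i + 1L, substr(t, 2L, nchar(t)),
              score + if (hit) match else mismatch,
              gaps, ident + hit, cols + 1L)
    }
    if (i <= length(q)) {
      recurse(i + 1L, t, score + gap, gaps + 1L, ident, cols + 1L)
    }
    if (nchar(t)) {
      recurse(i, substr(t, 2L, nchar(t)), score + gap, gaps + 1L, ident,
              cols + 1L)
    }
  }
  n <- nchar(subject)
  for (a in seq_len(n + 1L)) {
    for (b in seq(a - 1L, n)) {
      t <- if (b < a) "" else substr(subject, a, b)
      recurse(1L, t, 0, 0L, 0L, 0L)
    }
  }
  best$pident <- 100 * best$identities / best$columns
  best
}

# Biostrings reference for the same semiglobal problem (global in the
# pattern, local in the subject; linear gap cost)
oracle_biostrings_score <- function(query, subject, match = 1, mismatch = -2,
                                    gap = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(pattern = query, subject = subject,
                                      type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = gap)
  Biostrings::score(al)
}

# substitution-only closed form for percent identity
oracle_pident_closed_form <- function(L, m) 100 * (L - m) / L

# mutate a sequence at m distinct positions (always to a different base)
mutate_positions <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
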