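#' Path to the packaged primer-pair catalog
#'
#' The packaged catalog holds 39 primer pairs targeting the 16S rRNA gene
#' of oral bacteria and archaea: 33 pairs selected for high in-silico
#' species coverage plus the 6 pairs most used in the oral-microbiome
#' literature, with their 5'->3' sequences, reference
#' positions on the *E. coli* 16S rRNA gene, amplicon-length categories
#' (S/M/L), target domains and variable regions.
#'
#' @return Filesystem path to the TSV fixture.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "primer_catalog.tsv", package = "ampliscreen",
              mustWork = TRUE)
}

.parse_pos <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("U", "-", "–", "", "NA")] <- NA_character_
  suppressWarnings(as.integer(x))
}

#' Load and validate a primer-pair catalog
#'
#' Reads a TSV with one row per primer pair (columns `pair_id`,
#' `provenance`, `length_category`, `target_domain`, `f_id`, `f_seq`,
#' `f_first`, `f_last`, `r_id`, `r_seq`, `r_first`, `r_last`,
#' `length_bps`, `region`). Undefined reference positions are encoded as
#' `U` (or `-`) and parsed to `NA`. Rows whose primer sequences contain a
#' non-IUPAC character are rejected with a row-identifying warning;
#' duplicated `pair_id`s are a hard error. Where both the forward first
#' position and the reverse last position are defined, the catalog length
#' must equal `r_last - f_first`.
#'
#' @param path TSV path; defaults to the packaged catalog.
#' @return A `data.frame` of validated pairs (class `primer_catalog`).
#' @export
load_primer_catalog <- function(path = default_catalog_path()) {
  cat <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("pair_id", "provenance", "length_category", "target_domain",
                "f_id", "f_seq", "f_first", "f_last",
                "r_id", "r_seq", "r_first", "r_last", "length_bps", "region")
  missing <- setdiff(required, names(cat))
  if (length(missing)) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cat$pair_id)) {
    stop("duplicate pair_id in catalog: ",
         paste(unique(cat$pair_id[duplicated(cat$pair_id)]), collapse = ", "),
         call. = FALSE)
  }

  cat$f_seq <- toupper(trimws(cat$f_seq))
  cat$r_seq <- toupper(trimws(cat$r_seq))
  ok <- rep(TRUE, nrow(cat))
  for (i in seq_len(nrow(cat))) {
    bad <- c(
      tryCatch({ .iupac_chars(cat$f_seq[i], "forward primer"); NULL },
               error = function(e) conditionMessage(e)),
      tryCatch({ .iupac_chars(cat$r_seq[i], "reverse primer"); NULL },
               error = function(e) conditionMessage(e))
    )
    if (length(bad)) {
      warning("rejecting catalog row '", cat$pair_id[i], "': ",
              paste(bad, collapse = "; "), call. = FALSE)
      ok[i] <- FALSE
    }
  }
  cat <- cat[ok, , drop = FALSE]

  for (col in c("f_first", "f_last", "r_first", "r_last", "length_bps")) {
    cat[[col]] <- .parse_pos(cat[[col]])
  }
  nc <- nchar(cat$f_seq)
  if (any(nc < 10 | nc > 30)) {
    stop("forward primer length outside 10-30 nt for: ",
         paste(cat$pair_id[nc < 10 | nc > 30], collapse = ", "), call. = FALSE)
  }
  nc <- nchar(cat$r_seq)
  if (any(nc < 10 | nc > 30)) {
    stop("reverse primer length outside 10-30 nt for: ",
         paste(cat$pair_id[nc < 10 | nc > 30], collapse = ", "), call. = FALSE)
  }

  half_def <- xor(is.na(cat$f_first), is.na(cat$f_last)) |
    xor(is.na(cat$r_first), is.na(cat$r_last))
  if (any(half_def)) {
    stop("reference positions must be both defined or both undefined for: ",
         paste(cat$pair_id[half_def], collapse = ", "), call. = FALSE)
  }
  rev_order <- (!is.na(cat$f_first) & cat$f_first > cat$f_last) |
    (!is.na(cat$r_first) & cat$r_first > cat$r_last)
  if (any(rev_order)) {
    stop("reference first position exceeds last for: ",
         paste(cat$pair_id[rev_order], collapse = ", "), call. = FALSE)
  }

  defined <- !is.na(cat$length_bps) & !is.na(cat$f_first) & !is.na(cat$r_last)
  mismatch <- defined & (cat$length_bps != cat$r_last - cat$f_first)
  if (any(mismatch)) {
    stop("catalog length inconsistent with r_last - f_first for: ",
         paste(cat$pair_id[mismatch], collapse = ", "), call. = FALSE)
  }
  bad_cat <- !cat$length_category %in% c("S", "M", "L")
  if (any(bad_cat)) {
    stop("unknown length_category for: ",
         paste(cat$pair_id[bad_cat], collapse = ", "), call. = FALSE)
  }
  chk <- !is.na(cat$length_bps)
  want <- vapply(cat$length_bps[chk], classify_length_category, character(1L))
  if (any(want != cat$length_category[chk])) {
    stop("length_category inconsistent with length_bps for: ",
         paste(cat$pair_id[chk][want != cat$length_category[chk]],
               collapse = ", "), call. = FALSE)
  }
  bad_dom <- !cat$target_domain %in% c("bacteria", "archaea", "both")
  if (any(bad_dom)) {
    stop("unknown target_domain for: ",
         paste(cat$pair_id[bad_dom], collapse = ", "), call. = FALSE)
  }

  class(cat) <- c("primer_catalog", "data.frame")
  cat
}

#' Subset a catalog to the pairs evaluated against one domain
#'
#' A pair is evaluated against a domain when its `target_domain` is that
#' domain or `"both"`.
#'
#' @param catalog a `primer_catalog` data.frame.
#' @param domain `"bacteria"` or `"archaea"`.
#' @return The matching catalog rows.
#' @export
pairs_for_domain <- function(catalog, domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  catalog[catalog$target_domain %in% c(domain, "both"), , drop = FALSE]
}
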