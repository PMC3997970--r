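#' DNA sequence primitives
#'
#' Vectorised helpers for the uppercase ACGT alphabet used throughout the
#' package. Lowercase input is folded to uppercase; any other character is an
#' error that names the first offending position. `N` is accepted only where
#' an operation explicitly supports wildcards (see [count_pattern()]).
#'
#' @param x character vector of DNA sequences.
#' @param allow_n should the wildcard `N` be permitted?
#' @return For `dna_validate()`, the validated uppercase sequences (invisibly
#'   usable as input to the other helpers). `dna_complement()` and
#'   `dna_revcomp()` return character vectors of the same length.
#' @examples
#' dna_complement("TCCTCAGTC") # "AGGAGTCAG", the same-orientation complement
#' dna_revcomp("TCCTCAGTC")    # "GACTGAGGA"
#' @name dna
NULL

#' @rdname dna
#' @export
dna_validate <- function(x, allow_n = FALSE) {
  if (!is.character(x)) {
    abort("DNA input must be a character vector.")
  }
  x <- toupper(x)
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  bad <- stringi::stri_locate_first_regex(
    x,
    paste0("[^", paste(alphabet, collapse = ""), "]")
  )[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "invalid character '%s' at position %d of sequence %d (alphabet %s)",
      substr(x[i], bad[i], bad[i]), bad[i], i,
      paste(alphabet, collapse = "")
    ))
  }
  x
}

#' @rdname dna
#' @export
dna_complement <- function(x, allow_n = FALSE) {
  x <- dna_validate(x, allow_n = allow_n)
  chartr("ACGTN", "TGCAN", x)
}

#' @rdname dna
#' @export
dna_revcomp <- function(x, allow_n = FALSE) {
  stringi::stri_reverse(dna_complement(x, allow_n = allow_n))
}

#' The 64 DNA triplets in canonical series order
#'
#' All 4^3 = 64 triplets, ordered as four 16-triplet series starting with A,
#' C, G and T (lexicographic within each series). This fixed order is the
#' reference enumeration used by fixture files, rank codes and reports.
#'
#' @return A character vector of length 64, `"AAA"` first and `"TTT"` last.
#' @examples
#' head(triplets())
#' @export
triplets <- function() {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3)
}

#' Classify triplets by G+C content
#'
#' A triplet is GC-rich when at least 2 of its 3 bases are G or C (majority
#' rule), AT-rich otherwise; it is homogeneous (a "GC-triplet" or
#' "AT-triplet") when all three bases fall on one side.
#'
#' @param x character vector of 3-base sequences (no wildcards).
#' @return A tibble with columns `triplet`, `gc_count` (0-3), `richness`
#'   (`"GC-rich"` or `"AT-rich"`) and `homogeneous` (logical).
#' @examples
#' classify_triplets(c("CGG", "TAA", "TTG"))
#' @export
classify_triplets <- function(x) {
  x <- dna_validate(x)
  if (any(nchar(x) != 3L)) {
    abort("all sequences must be exactly 3 bases long")
  }
  gc <- stringi::stri_count_regex(x, "[GC]")
  tibble(
    triplet = x,
    gc_count = gc,
    richness = ifelse(gc >= 2L, "GC-rich", "AT-rich"),
    homogeneous = gc %in% c(0L, 3L)
  )
}
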