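#' Genome containers and FASTA input/output
#'
#' Genomes are held as [Biostrings::DNAStringSet] objects (one entry per
#' record); plain named character vectors are accepted everywhere and
#' coerced. `read_genome()` / `write_genome()` wrap the Biostrings FASTA
#' readers and writers (60-column wrap on output; gzip input supported).
#'
#' @param x a `DNAStringSet` or a (named) character vector of sequences.
#' @param path FASTA file path.
#' @param genome a genome as accepted by `as_genome()`.
#' @return `as_genome()` and `read_genome()` return a `DNAStringSet`;
#'   `write_genome()` returns `path` invisibly.
#' @examples
#' g <- as_genome(c(chr1 = "ACGTACGT"))
#' @name genome-io
NULL

#' @rdname genome-io
#' @export
as_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    return(x)
  }
  if (is.character(x)) {
    if (is.null(names(x))) {
      names(x) <- paste0("seq", seq_along(x))
    }
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  abort("genome must be a DNAStringSet or a character vector")
}

#' @rdname genome-io
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname genome-io
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 60L)
  invisible(path)
}

empty_occurrences <- function() {
  tibble(
    record = character(), start = integer(), end = integer(),
    strand = character()
  )
}

# greedy left-to-right removal of overlapping starts (starts sorted, 0-based)
drop_overlaps <- function(starts, width) {
  keep <- logical(length(starts))
  last_end <- -1L
  for (i in seq_along(starts)) {
    if (starts[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- starts[i] + width
    }
  }
  starts[keep]
}

# 0-based starts of matches of `pattern` in one subject sequence.
# wildcard = TRUE treats N in the pattern as any base; genome characters
# outside ACGT never match outside unconstrained (N) pattern positions.
match_starts <- function(pattern, subject, wildcard = FALSE) {
  if (nchar(pattern) == 0L || nchar(pattern) > length(subject)) {
    return(integer())
  }
  m <- Biostrings::matchPattern(
    pattern, subject,
    fixed = if (wildcard) FALSE else TRUE
  )
  starts <- BiocGenerics::start(m) - 1L
  if (wildcard && length(starts)) {
    fixed_pos <- which(strsplit(pattern, "")[[1]] != "N")
    if (length(fixed_pos)) {
      windows <- as.character(Biostrings::extractAt(
        subject, IRanges::IRanges(starts + 1L, width = nchar(pattern))
      ))
      ok <- vapply(windows, function(w) {
        all(strsplit(w, "")[[1]][fixed_pos] ==
              strsplit(pattern, "")[[1]][fixed_pos])
      }, logical(1))
      starts <- starts[ok]
    }
  }
  starts
}

#' Exact occurrence counting of a k-mer in a genome
#'
#' Finds every exact match of `kmer`, by default including overlapping
#' matches, with 0-based half-open coordinates (BED convention). In
#' `strand = "both"` mode the reverse complement of the query is also
#' matched on the forward sequence and reported with strand `"-"` at its
#' forward-strand coordinates; a palindromic query therefore yields one hit
#' per strand at the same position. Record boundaries are never crossed and
#' `N` characters in the genome never match.
#'
#' @inheritParams genome-io
#' @param kmer query sequence (ACGT, no wildcards; see [count_pattern()] for
#'   wildcards).
#' @param strand `"forward"` or `"both"`.
#' @param overlapping count overlapping matches (default) or apply a greedy
#'   left-to-right non-overlapping filter per record and strand.
#' @return A tibble with columns `record`, `start`, `end`, `strand`, one row
#'   per occurrence, sorted by record and position; total count is
#'   `nrow()`. The query and modes are attached as attributes.
#' @examples
#' count_exact(c(g = "GGGGG"), "GG")          # 4 overlapping matches
#' count_exact(c(g = "GAATTC"), "GAATTC", strand = "both")
#' @export
count_exact <- function(genome, kmer, strand = c("forward", "both"),
                        overlapping = TRUE) {
  strand <- match.arg(strand)
  genome <- as_genome(genome)
  if (length(kmer) != 1L || is.na(kmer)) {
    abort("kmer must be a single sequence")
  }
  kmer <- dna_validate(kmer)
  hits <- empty_occurrences()
  if (nchar(kmer) > 0L) {
    queries <- c("+" = kmer)
    if (strand == "both") {
      queries <- c(queries, "-" = dna_revcomp(kmer))
    }
    k <- nchar(kmer)
    hits <- purrr::map_dfr(seq_along(genome), function(i) {
      purrr::map_dfr(names(queries), function(s) {
        starts <- match_starts(queries[[s]], genome[[i]])
        if (!overlapping) starts <- drop_overlaps(starts, k)
        tibble(
          record = names(genome)[i], start = starts,
          end = starts + k, strand = s
        )
      })
    })
    hits <- arrange(hits, .data$record, .data$start, .data$strand)
  }
  structure(hits, query = kmer, strand_mode = strand,
            overlapping = overlapping)
}

#' Occurrence counts for every instantiation of a degenerate pattern
#'
#' Counts, in a single pass over the genome, the occurrences of each concrete
#' instantiation of a pattern containing `N` wildcards — e.g. `GGGNNNGGG`
#' yields one row per central triplet, 64 in all, including zero counts.
#'
#' @inheritParams count_exact
#' @param pattern query over A, C, G, T and N.
#' @param max_wildcards refuse patterns with more than this many `N`
#'   positions (the result has 4^N rows); raise it explicitly to override.
#' @return A tibble with one row per instantiation: `instantiation` (the
#'   concrete k-mer), `fill` (the letters at the `N` positions; e.g. the
#'   central triplet for `GGGNNNGGG`) and `count`. Rows are in lexicographic
#'   `fill` order, so a `GGGNNNGGG` scan lines up with [triplets()].
#' @examples
#' count_pattern(c(g = "GGGAAAGGGTTGGGACAGGG"), "GGGNNNGGG")
#' @export
count_pattern <- function(genome, pattern, strand = c("forward", "both"),
                          overlapping = TRUE, max_wildcards = 6) {
  strand <- match.arg(strand)
  genome <- as_genome(genome)
  pattern <- dna_validate(pattern, allow_n = TRUE)
  chars <- strsplit(pattern, "")[[1]]
  n_pos <- which(chars == "N")
  if (length(n_pos) > max_wildcards) {
    abort(sprintf(
      "pattern has %d N positions (4^%d = %s instantiations); raise max_wildcards to proceed",
      length(n_pos), length(n_pos),
      format(4^length(n_pos), big.mark = ",")
    ))
  }
  fills <- if (length(n_pos)) {
    apply(
      expand.grid(rep(list(c("A", "C", "G", "T")), length(n_pos)))[
        , rev(seq_along(n_pos)), drop = FALSE],
      1, paste, collapse = ""
    )
  } else {
    ""
  }
  fills <- sort(fills)
  k <- nchar(pattern)
  observed <- character()
  for (i in seq_along(genome)) {
    subj <- genome[[i]]
    for (s in if (strand == "both") c("+", "-") else "+") {
      pat <- if (s == "+") pattern else dna_revcomp(pattern, allow_n = TRUE)
      starts <- match_starts(pat, subj, wildcard = length(n_pos) > 0)
      if (!overlapping) starts <- drop_overlaps(starts, k)
      if (length(starts)) {
        windows <- as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(starts + 1L, width = k)
        ))
        if (s == "-") windows <- dna_revcomp(windows, allow_n = TRUE)
        # conservative: windows containing non-ACGT bases never count
        windows <- windows[!stringi::stri_detect_regex(windows, "[^ACGT]")]
        observed <- c(observed, windows)
      }
    }
  }
  fill_of <- function(w) {
    if (!length(n_pos)) return("")
    vapply(strsplit(w, ""), function(cs) paste(cs[n_pos], collapse = ""),
           character(1))
  }
  tallied <- table(factor(fill_of(observed), levels = fills))
  out <- tibble(
    instantiation = vapply(fills, function(f) {
      cs <- chars
      cs[n_pos] <- strsplit(f, "")[[1]]
      paste(cs, collapse = "")
    }, character(1), USE.NAMES = FALSE),
    fill = fills,
    count = as.integer(tallied)
  )
  structure(out, pattern = pattern, strand_mode = strand,
            overlapping = overlapping)
}

#' Paired ZFN half-site (dimer) search
#'
#' Finds composite target sites of a zinc finger nuclease pair: a left
#' half-site, an unconstrained spacer of `spacer_min` to `spacer_max` bases
#' (where cleavage occurs), and a right half-site. Under the
#' `"as_written"` convention the right half-site is the literal sequence on
#' the same strand as the left; under `"opposite_strand"` it is the binding
#' site of the second monomer read on the complementary strand, so its
#' reverse complement is matched. Both genomic strands are always searched;
#' coordinates are forward-strand 0-based half-open.
#'
#' @inheritParams count_exact
#' @param left,right the two half-site sequences (e.g. 9-mers for
#'   three-finger domains).
#' @param spacer_min,spacer_max allowed spacer lengths in bases (use the same
#'   value for a fixed spacer).
#' @param convention how `right` is oriented (see Details).
#' @return A tibble of hits: `record`, `start`, `end`, `strand`,
#'   `spacer_length`, `composite` (the matched sequence in query
#'   orientation).
#' @examples
#' g <- c(hbb = "TTTTGGCAGACTTGTGGAGAGGAGTCAGTTTT")
#' find_dimer_sites(g, "GGCAGACTT", "AGGAGTCAG", 6, 6)
#' @export
find_dimer_sites <- function(genome, left, right,
                             spacer_min = 6, spacer_max = spacer_min,
                             convention = c("as_written", "opposite_strand")) {
  convention <- match.arg(convention)
  genome <- as_genome(genome)
  left <- dna_validate(left)
  right <- dna_validate(right)
  if (spacer_min < 0 || spacer_max < spacer_min) {
    abort("need 0 <= spacer_min <= spacer_max")
  }
  right_lit <- switch(convention,
    as_written = right,
    opposite_strand = dna_revcomp(right)
  )
  hits <- purrr::map_dfr(seq(spacer_min, spacer_max), function(s) {
    composite <- paste0(left, strrep("N", s), right_lit)
    k <- nchar(composite)
    purrr::map_dfr(seq_along(genome), function(i) {
      subj <- genome[[i]]
      purrr::map_dfr(c("+", "-"), function(st) {
        pat <- if (st == "+") composite else dna_revcomp(composite, allow_n = TRUE)
        starts <- match_starts(pat, subj, wildcard = s > 0)
        if (!length(starts)) return(NULL)
        windows <- as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(starts + 1L, width = k)
        ))
        if (st == "-") windows <- dna_revcomp(windows, allow_n = TRUE)
        tibble(
          record = names(genome)[i], start = starts, end = starts + k,
          strand = st, spacer_length = s, composite = windows
        )
      })
    })
  })
  if (nrow(hits) == 0) {
    hits <- mutate(empty_occurrences(), spacer_length = integer(),
                   composite = character())
  }
  arrange(hits, .data$record, .data$start, .data$spacer_length, .data$strand)
}

#' Expected occurrences of a k-mer under an i.i.d. background
#'
#' Closed-form expectation `(L - k + 1) * prod(p[base_i])` for the number of
#' (overlapping) exact matches of a k-mer in an i.i.d. random sequence of
#' length `L`, clamped to 0 when the sequence is shorter than the k-mer.
#' Useful to contextualise observed genome occurrence counts.
#'
#' @param kmer query sequence.
#' @param genome_length sequence length `L` in bases.
#' @param base_probabilities named numeric vector of A/C/G/T probabilities,
#'   summing to 1.
#' @return A single non-negative number.
#' @examples
#' expected_occurrences("GGGCGGGGG", 3e9)
#' @export
expected_occurrences <- function(kmer, genome_length,
                                 base_probabilities = c(A = 0.25, C = 0.25,
                                                        G = 0.25, T = 0.25)) {
  kmer <- dna_validate(kmer)
  p <- base_probabilities[c("A", "C", "G", "T")]
  if (any(is.na(p)) || any(p < 0)) {
    abort("base_probabilities must be named non-negative values for A, C, G, T")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("base_probabilities must sum to 1")
  }
  k <- nchar(kmer)
  if (genome_length < k) {
    return(0)
  }
  (genome_length - k + 1) * prod(p[strsplit(kmer, "")[[1]]])
}

#' Off-target landscape of a code over a genome
#'
#' Reproduces, for any genome, the published report schema: for each of the
#' 64 triplets the occurrence count of `flank + triplet + flank`
#' (`GGGNNNGGG` with the default flank) joined with the triplet's rank in an
#' RSR code. When `x` is an assay table that already carries an
#' `occurrences` column (e.g. [sp1_assay_counts()]), scanning is skipped and
#' the tabulated counts are used as-is.
#'
#' @param x a genome ([as_genome()]-coercible) or an assay table with an
#'   `occurrences` column.
#' @param code an `rsr_code` (or coercible); optional when `x` carries
#'   counts but no ranking is wanted.
#' @param flank sequence added on both sides of the triplet (may be `""`).
#' @inheritParams count_exact
#' @return A 64-row tibble: `triplet`, `rank`, `site`, `occurrences` (and
#'   `p32_count` when `x` provides it), sorted by rank.
#' @examples
#' offtarget_landscape(sp1_assay_counts(), published_code("SP1"))
#' @export
offtarget_landscape <- function(x, code = NULL, flank = "GGG",
                                strand = c("forward", "both"),
                                overlapping = TRUE) {
  strand <- match.arg(strand)
  if (is.data.frame(x) && "occurrences" %in% names(x)) {
    validate_assay_records(x)
    out <- as_tibble(x)[intersect(c("triplet", "p32_count", "occurrences"),
                                  names(x))]
    out <- mutate(out, site = paste0(flank, .data$triplet, flank))
  } else {
    if (nchar(flank)) dna_validate(flank)
    counts <- count_pattern(
      as_genome(x), paste0(flank, "NNN", flank),
      strand = strand, overlapping = overlapping
    )
    out <- tibble(
      triplet = counts$fill,
      site = counts$instantiation,
      occurrences = counts$count
    )
  }
  if (!is.null(code)) {
    ranking <- as_ranking(code)
    out <- mutate(out,
                  rank = ranking$rank[match(.data$triplet, ranking$triplet)])
    out <- arrange(out, .data$rank)
  }
  select(out, any_of(c("triplet", "rank", "site", "p32_count", "occurrences")))
}

#' Write occurrence positions as BED6
#'
#' @param occurrences a tibble from [count_exact()] or [find_dimer_sites()].
#' @param path output file.
#' @param name feature name column value (defaults to the query attribute
#'   when present).
#' @return `path`, invisibly.
#' @export
write_bed <- function(occurrences, path, name = NULL) {
  name <- name %||% attr(occurrences, "query") %||% "site"
  bed <- tibble(
    chrom = occurrences$record,
    start = occurrences$start,
    end = occurrences$end,
    name = name,
    score = 0L,
    strand = occurrences$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
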