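#' The EMSA probe cassette and probe construction
#'
#' The band-shift probes are built from a fixed 58-base double-stranded
#' oligonucleotide cassette whose central `NNN` slot (0-based positions
#' 27-29) is replaced by the triplet under test; the slot sits between two
#' GGG anchors, so every probe carries `GGG<triplet>GGG` at positions 24-32
#' — the same 9-mer whose genomic occurrences the off-target landscape
#' counts.
#'
#' @param triplet the 3-base sequence to place in the slot (no wildcards).
#' @return `probe_cassette()` returns a list with elements `template`,
#'   `slot_start` (0-based), `slot_end` (exclusive). `generate_probe()`
#'   returns the 58-base probe sequence (vectorised over `triplet`);
#'   `generate_probe_set()` a 64-row tibble with columns `triplet` and
#'   `probe`, in canonical [triplets()] order.
#' @examples
#' generate_probe("CGG")
#' substr(generate_probe("AAA"), 25, 33) # "GGGAAAGGG"
#' @name probes
NULL

.cassette_template <- "GTCGGATCCTGTCTGAGGTGAGTTGGGNNNGGGCTTGTCTTCCGACGTCGAATTCGCG"

#' @rdname probes
#' @export
probe_cassette <- function() {
  list(
    template = .cassette_template,
    slot_start = 27L,
    slot_end = 30L
  )
}

#' @rdname probes
#' @export
generate_probe <- function(triplet) {
  triplet <- dna_validate(triplet)
  if (any(nchar(triplet) != 3L)) {
    abort("the cassette slot takes exactly 3 bases")
  }
  vapply(
    triplet,
    function(t) sub("NNN", t, .cassette_template, fixed = TRUE),
    character(1),
    USE.NAMES = FALSE
  )
}

#' @rdname probes
#' @export
generate_probe_set <- function() {
  tibble(triplet = triplets(), probe = generate_probe(triplets()))
}

#' Simulate an EMSA count table with known ground-truth ranks
#'
#' Generates a 64-row Phosphor Imager count table whose true preference
#' order is a given RSR code. Mean counts decay geometrically with rank
#' (`count_scale * decay^(rank - 1)`), loosely matching the published
#' range of roughly 4570 down to single digits over 64 ranks; means that
#' fall below `detection_limit` are set to 0, mimicking undetectable band
#' shifts. Noise is multiplicative lognormal (`sigma` on the log scale)
#' followed by Poisson sampling of the signal. With `sigma = 0`,
#' `poisson = FALSE` and `detection_limit = 0` the table is noiseless and
#' [compute_rsr_code()] recovers the true code exactly.
#'
#' @param code the ground-truth `rsr_code` (or coercible).
#' @param count_scale mean count at rank 1 (arbitrary Phosphor Imager
#'   units).
#' @param decay geometric decay ratio per rank, in (0, 1).
#' @param sigma standard deviation of the lognormal noise factor (log
#'   scale); 0 disables it.
#' @param detection_limit means below this value become 0 (undetectable).
#' @param poisson apply Poisson sampling to the (noisy) mean signal.
#' @param seed optional integer seed for reproducibility.
#' @return A tibble with columns `triplet` and `p32_count`, one row per
#'   triplet in canonical [triplets()] order, ready for
#'   [compute_rsr_code()].
#' @examples
#' truth <- published_code("SP1")
#' sim <- simulate_emsa_counts(truth, seed = 1)
#' glance(compare_rank_codes(compute_rsr_code(sim), truth))
#' @export
simulate_emsa_counts <- function(code, count_scale = 4570, decay = 0.90,
                                 sigma = 0.3, detection_limit = 8,
                                 poisson = TRUE, seed = NULL) {
  ranking <- as_ranking(code)
  if (!is.numeric(count_scale) || count_scale <= 0) {
    abort("count_scale must be positive")
  }
  if (!is.numeric(decay) || decay <= 0 || decay > 1) {
    abort("decay must give non-increasing means: need 0 < decay <= 1")
  }
  if (sigma < 0 || detection_limit < 0) {
    abort("sigma and detection_limit must be non-negative")
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  means <- count_scale * decay^(ranking$rank - 1)
  means[means < detection_limit] <- 0
  signal <- means * exp(rnorm(length(means), 0, sigma))
  counts <- if (poisson) rpois(length(signal), signal) else signal
  out <- tibble(triplet = ranking$triplet, p32_count = counts)
  arrange(out, match(.data$triplet, triplets()))
}

#' Simulate a genome with exactly planted motif occurrences
#'
#' Draws an i.i.d. random sequence with the requested base composition and
#' plants each motif a given number of times at random non-overlapping
#' positions. With `scrub = TRUE` (default) any spurious, chance occurrence
#' of a planted motif on the forward strand is removed by resampling one of
#' its bases outside the planted windows, so that the forward-strand exact
#' count of each motif equals its planted copy number by construction.
#'
#' @param length genome length in bases.
#' @param base_probabilities named A/C/G/T probabilities, summing to 1.
#' @param planted motifs to plant: a named integer vector
#'   (`c(GGGCGGGGG = 3)`) or a data frame with columns `motif` and `copies`.
#' @param scrub remove chance occurrences of the planted motifs.
#' @param seed optional integer seed.
#' @param record_name FASTA record name of the single simulated sequence.
#' @param max_attempts placement/scrub retry budget before giving up.
#' @return A [Biostrings::DNAStringSet] with one record; the planted
#'   positions are recorded in `attr(, "planted")` (a tibble with columns
#'   `motif` and `start`, 0-based).
#' @examples
#' g <- simulate_genome(2000, planted = c(GGCAGACTT = 2), seed = 7)
#' nrow(count_exact(g, "GGCAGACTT")) # exactly 2
#' @export
simulate_genome <- function(length,
                            base_probabilities = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                            planted = NULL, scrub = TRUE, seed = NULL,
                            record_name = "chr_syn", max_attempts = 1000) {
  p <- base_probabilities[c("A", "C", "G", "T")]
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("base_probabilities must be named A/C/G/T values summing to 1")
  }
  if (length < 0) {
    abort("length must be >= 0")
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  if (length == 0) {
    return(structure(Biostrings::DNAStringSet(character(0)),
                     planted = tibble(motif = character(), start = integer())))
  }

  plant_tab <- plant_table(planted)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)

  # place each copy at a random start, rejecting overlaps with earlier copies
  placed <- tibble(motif = character(), start = integer(), end = integer())
  for (i in seq_len(nrow(plant_tab))) {
    motif <- plant_tab$motif[i]
    k <- nchar(motif)
    if (k > length) {
      abort(sprintf("motif %s is longer than the genome", motif))
    }
    for (copy in seq_len(plant_tab$copies[i])) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- sample.int(length - k + 1L, 1L) - 1L
        if (!any(s < placed$end & s + k > placed$start)) {
          placed <- bind_rows(placed,
                              tibble(motif = motif, start = s, end = s + k))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not place copy %d of %s without overlap after %d attempts",
          copy, motif, max_attempts
        ))
      }
    }
  }
  for (i in seq_len(nrow(placed))) {
    bases[(placed$start[i] + 1L):placed$end[i]] <-
      strsplit(placed$motif[i], "")[[1]]
  }

  if (scrub && nrow(placed)) {
    bases <- scrub_spurious(bases, placed, p, max_attempts)
  }

  genome <- Biostrings::DNAStringSet(
    setNames(paste(bases, collapse = ""), record_name)
  )
  structure(genome, planted = placed[c("motif", "start")])
}

plant_table <- function(planted) {
  if (is.null(planted)) {
    return(tibble(motif = character(), copies = integer()))
  }
  tab <- if (is.data.frame(planted)) {
    tibble(motif = planted$motif, copies = as.integer(planted$copies))
  } else {
    tibble(motif = names(planted), copies = as.integer(planted))
  }
  tab$motif <- dna_validate(tab$motif)
  if (any(tab$copies < 0) || any(!nzchar(tab$motif))) {
    abort("planted motifs must be non-empty with copies >= 0")
  }
  tab[tab$copies > 0, ]
}

# resample single bases until no planted motif occurs outside its planted
# windows (forward strand); positions inside any planted window are protected
scrub_spurious <- function(bases, placed, p, max_attempts) {
  protected <- logical(length(bases))
  for (i in seq_len(nrow(placed))) {
    protected[(placed$start[i] + 1L):placed$end[i]] <- TRUE
  }
  seq_string <- function() paste(bases, collapse = "")
  for (round in seq_len(max_attempts)) {
    dirty <- FALSE
    text <- seq_string()
    for (motif in unique(placed$motif)) {
      starts <- stringi::stri_locate_all_fixed(
        text, motif, overlap = TRUE
      )[[1]][, "start"] - 1L
      starts <- starts[!is.na(starts)]
      spurious <- setdiff(starts, placed$start[placed$motif == motif])
      for (s in spurious) {
        window <- (s + 1L):(s + nchar(motif))
        free <- window[!protected[window]]
        if (!length(free)) {
          abort(sprintf(
            "cannot scrub occurrence of %s at %d: every base is inside a planted window",
            motif, s
          ))
        }
        pos <- free[sample.int(length(free), 1L)]
        bases[pos] <- sample(setdiff(c("A", "C", "G", "T"), bases[pos]), 1L)
        dirty <- TRUE
      }
    }
    if (!dirty) {
      return(bases)
    }
  }
  abort(sprintf("scrubbing did not converge after %d rounds", max_attempts))
}
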