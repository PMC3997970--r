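#' Rank-specific recognition codes
#'
#' An RSR code is a protein's complete rank-ordered listing of all 64 DNA
#' triplets, rank 1 = strongest complex formation. [compute_rsr_code()]
#' derives the code from an EMSA count table by sorting on `p32_count`
#' (descending); [rsr_code()] wraps an already-ranked triplet permutation
#' (e.g. a published mutant column for which no counts are available).
#'
#' Count ties are broken by `tie_policy`:
#' * `"stable"` (default) keeps the input-table row order, which reproduces
#'   the published SP1 column from the published count table;
#' * `"lexicographic"` orders tied triplets alphabetically.
#'
#' @param records data frame with columns `triplet` and `p32_count`, one row
#'   per triplet, all 64 present.
#' @param protein label for the protein the code belongs to.
#' @param tie_policy how to order triplets with equal counts.
#' @param ranking character vector: a permutation of [triplets()], strongest
#'   first.
#' @return An object of class `rsr_code`: a list with elements `protein` and
#'   `ranking` (a tibble with columns `rank`, `triplet` and, when derived
#'   from counts, `p32_count`). Use [tidy()] to get the ranking tibble and
#'   [glance()] for a one-row summary.
#' @examples
#' code <- compute_rsr_code(sp1_assay_counts(), protein = "SP1")
#' code
#' head(tidy(code))
#' @export
compute_rsr_code <- function(records, protein = "SP1",
                             tie_policy = c("stable", "lexicographic")) {
  tie_policy <- match.arg(tie_policy)
  validate_assay_records(records)
  ord <- switch(tie_policy,
    stable = order(-records$p32_count, seq_len(nrow(records))),
    lexicographic = order(-records$p32_count, records$triplet)
  )
  ranking <- tibble(
    rank = seq_len(nrow(records)),
    triplet = records$triplet[ord],
    p32_count = records$p32_count[ord]
  )
  new_rsr_code(protein, ranking)
}

#' @rdname compute_rsr_code
#' @export
rsr_code <- function(ranking, protein = "code") {
  ranking <- dna_validate(ranking)
  new_rsr_code(protein, tibble(rank = seq_along(ranking), triplet = ranking))
}

new_rsr_code <- function(protein, ranking) {
  dup <- ranking$triplet[duplicated(ranking$triplet)]
  missing <- setdiff(triplets(), ranking$triplet)
  if (length(dup) || length(missing)) {
    abort(sprintf(
      "ranking for %s is not a permutation of the 64 triplets (duplicated: %s; missing: %s)",
      protein, paste(unique(dup), collapse = ","),
      paste(missing, collapse = ",")
    ))
  }
  structure(list(protein = protein, ranking = ranking), class = "rsr_code")
}

#' Published RSR code for one protein
#'
#' Convenience accessor over [rank_codes()].
#'
#' @param protein one of `"SP1"`, `"CB1"`, `"MR14"`, `"MQ91"`, `"MQ135"`,
#'   `"MQ151"`.
#' @return An `rsr_code` object.
#' @examples
#' published_code("MQ91")
#' @export
published_code <- function(protein) {
  codes <- rank_codes()
  if (!protein %in% codes$protein) {
    abort(sprintf(
      "unknown protein '%s'; available: %s",
      protein, paste(unique(codes$protein), collapse = ", ")
    ))
  }
  col <- filter(codes, .data$protein == !!protein)
  rsr_code(col$triplet[order(col$rank)], protein = protein)
}

# coerce an rsr_code, permutation vector, or (rank, triplet) data frame
# to a ranking tibble
as_ranking <- function(x) {
  if (inherits(x, "rsr_code")) {
    return(x$ranking)
  }
  if (is.character(x)) {
    return(rsr_code(x)$ranking)
  }
  if (is.data.frame(x) && all(c("rank", "triplet") %in% names(x))) {
    return(arrange(as_tibble(x), .data$rank))
  }
  if (is.data.frame(x) && all(c("triplet", "p32_count") %in% names(x))) {
    return(compute_rsr_code(x)$ranking)
  }
  abort("cannot interpret input as an RSR code")
}

#' @export
print.rsr_code <- function(x, ...) {
  cat(sprintf("<rsr_code> %s: 64 triplets, rank 1 = %s, rank 64 = %s\n",
              x$protein, x$ranking$triplet[1], x$ranking$triplet[64]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rsr_code <- function(x, ...) {
  mutate(x$ranking, protein = x$protein, .before = 1)
}

#' @exportS3Method generics::glance
glance.rsr_code <- function(x, ...) {
  comp <- composition_summary(x, top_k = 26)
  tibble(
    protein = x$protein,
    n_triplets = nrow(x$ranking),
    strongest = x$ranking$triplet[1],
    weakest = x$ranking$triplet[64],
    gc_rich_top26 = comp$gc_rich
  )
}

#' Partition triplets by band-shift signal strength
#'
#' Splits a count table into `strong` (count at or above the threshold),
#' `weak` (detectable but below threshold) and `undetectable` (count 0)
#' groups. The default threshold of 500 with inclusive comparison reproduces
#' the published 26 / 35 / 3 split of the SP1 screen; note the published
#' strong group itself contains a triplet at exactly 500 (CGC), which is why
#' the comparison is inclusive by default.
#'
#' @inheritParams compute_rsr_code
#' @param threshold positive count threshold (same arbitrary units as
#'   `p32_count`).
#' @param inclusive should a count exactly at the threshold be `strong`?
#' @return The input tibble with an added factor column `group` (levels
#'   `strong`, `weak`, `undetectable`); group sizes via
#'   `dplyr::count(x, group)`.
#' @examples
#' dplyr::count(stability_grouping(sp1_assay_counts()), group)
#' @export
stability_grouping <- function(records, threshold = 500, inclusive = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("threshold must be a single positive number")
  }
  validate_assay_records(records)
  strong <- if (inclusive) records$p32_count >= threshold
            else records$p32_count > threshold
  mutate(
    as_tibble(records),
    group = factor(
      dplyr::case_when(
        .data$p32_count == 0 ~ "undetectable",
        strong ~ "strong",
        .default = "weak"
      ),
      levels = c("strong", "weak", "undetectable")
    )
  )
}

#' Base composition of the top-ranked triplets
#'
#' Counts, among the `top_k` strongest triplets of a code (or count table),
#' how many are GC-rich (majority G/C), how many of those are homogeneous
#' GC-triplets, and the AT-side equivalents. For the published SP1 screen
#' with `top_k = 26` this gives 18 GC-rich (6 GC-triplets) and 8 AT-rich
#' (3 AT-triplets).
#'
#' @param x an `rsr_code`, a triplet permutation, or a count table (ranked
#'   with the stable tie policy first).
#' @param top_k how many of the strongest triplets to summarise (1-64).
#' @return A one-row tibble with columns `top_k`, `gc_rich`, `gc_triplet`,
#'   `at_rich`, `at_triplet`.
#' @examples
#' composition_summary(sp1_assay_counts(), top_k = 26)
#' @export
composition_summary <- function(x, top_k = 26) {
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 1 || top_k > 64) {
    abort("top_k must be a single integer between 1 and 64")
  }
  ranking <- as_ranking(x)
  cls <- classify_triplets(ranking$triplet[seq_len(top_k)])
  tibble(
    top_k = as.integer(top_k),
    gc_rich = sum(cls$richness == "GC-rich"),
    gc_triplet = sum(cls$gc_count == 3L),
    at_rich = sum(cls$richness == "AT-rich"),
    at_triplet = sum(cls$gc_count == 0L)
  )
}

#' Compare two RSR codes
#'
#' Quantifies how strongly a mutation reorders binding preferences:
#' Spearman's rho and Kendall's tau on the two rank vectors, Spearman's
#' footrule (total absolute rank displacement), and the per-triplet signed
#' rank shift (`rank_b - rank_a`; positive = demoted in `b`).
#'
#' @param a,b `rsr_code` objects (or anything [rsr_code()]-coercible).
#' @return An object of class `rsr_comparison`. `tidy()` returns the 64-row
#'   per-triplet shift table; `glance()` returns a one-row tibble with
#'   `spearman_rho`, `kendall_tau` and `footrule`.
#' @examples
#' cmp <- compare_rank_codes(published_code("SP1"), published_code("MQ135"))
#' glance(cmp)
#' @export
compare_rank_codes <- function(a, b) {
  ra <- as_ranking(a)
  rb <- as_ranking(b)
  if (!setequal(ra$triplet, rb$triplet)) {
    abort("codes must rank the same triplet set")
  }
  shifts <- tibble(
    triplet = ra$triplet,
    rank_a = ra$rank,
    rank_b = rb$rank[match(ra$triplet, rb$triplet)]
  )
  shifts <- mutate(shifts, shift = .data$rank_b - .data$rank_a)
  structure(
    list(
      protein_a = if (inherits(a, "rsr_code")) a$protein else "a",
      protein_b = if (inherits(b, "rsr_code")) b$protein else "b",
      shifts = arrange(shifts, .data$rank_a),
      spearman_rho = cor(shifts$rank_a, shifts$rank_b, method = "spearman"),
      kendall_tau = cor(shifts$rank_a, shifts$rank_b, method = "kendall"),
      footrule = sum(abs(shifts$shift))
    ),
    class = "rsr_comparison"
  )
}

#' @export
print.rsr_comparison <- function(x, ...) {
  cat(sprintf(
    "<rsr_comparison> %s vs %s: rho %.3f, tau %.3f, footrule %d\n",
    x$protein_a, x$protein_b, x$spearman_rho, x$kendall_tau, x$footrule
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rsr_comparison <- function(x, ...) {
  mutate(x$shifts, protein_a = x$protein_a, protein_b = x$protein_b,
         .before = 1)
}

#' @exportS3Method generics::glance
glance.rsr_comparison <- function(x, ...) {
  tibble(
    protein_a = x$protein_a,
    protein_b = x$protein_b,
    spearman_rho = x$spearman_rho,
    kendall_tau = x$kendall_tau,
    footrule = x$footrule
  )
}

#' Rank of every triplet across a set of codes
#'
#' @param codes a list of `rsr_code` objects, or a long tibble with columns
#'   `protein`, `rank`, `triplet` (as returned by [rank_codes()]).
#' @return A 64-row tibble, one column of ranks per protein, rows in
#'   canonical [triplets()] order.
#' @examples
#' rank_shift_report(rank_codes())
#' @export
rank_shift_report <- function(codes) {
  long <- if (is.data.frame(codes)) {
    as_tibble(codes)
  } else {
    purrr::map_dfr(codes, function(code) {
      mutate(as_ranking(code)[c("rank", "triplet")],
             protein = if (inherits(code, "rsr_code")) code$protein else NA)
    })
  }
  if (length(unique(long$protein)) < 2) {
    abort("need at least two codes to report rank shifts")
  }
  wide <- tidyr::pivot_wider(
    long[c("protein", "rank", "triplet")],
    names_from = "protein", values_from = "rank"
  )
  arrange(wide, match(.data$triplet, triplets()))
}
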