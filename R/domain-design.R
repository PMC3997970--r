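#' Finger arrangements and the published design strategies
#'
#' Multi-finger domains are described by an ordered layout of finger labels,
#' written 5' to 3' along the binding site: `"321"` is the natural
#' three-finger SP1 domain, `"321321"` the tandem 2x3 six-finger design, and
#' so on. Each finger spans one 3-base subsite. `design_strategies()` lists
#' the five published layouts for sensitising the SP1 framework.
#'
#' @param layout a layout string such as `"321321"`, or an integer vector.
#' @return `parse_layout()` returns an integer vector of finger labels;
#'   `design_strategies()` a tibble with columns `strategy`, `layout`,
#'   `n_fingers`, `site_length`.
#' @examples
#' design_strategies()
#' @export
parse_layout <- function(layout) {
  if (is.character(layout) && length(layout) == 1) {
    layout <- as.integer(strsplit(layout, "")[[1]])
  }
  layout <- as.integer(layout)
  if (length(layout) < 1 || any(is.na(layout))) {
    abort("layout must be a non-empty string or vector of finger labels")
  }
  layout
}

#' @rdname parse_layout
#' @export
design_strategies <- function() {
  layouts <- c(
    "1 x 1st finger" = "321",
    "2 x 1st finger" = "3211",
    "2 x 3 design" = "321321",
    "3f + 4f design" = "3213211",
    "2 x 4f design" = "32113211"
  )
  tibble(
    strategy = names(layouts),
    layout = unname(layouts),
    n_fingers = unname(nchar(layouts)),
    site_length = 3L * unname(nchar(layouts))
  )
}

#' Build a composite binding site for a finger arrangement
#'
#' Concatenates one triplet per finger, in layout order, into the composite
#' site a multi-finger domain would bind; the site is `3 * n_fingers` bases
#' long. Overlap annotations from [annotate_overlap_loci()] are attached per
#' finger (metadata only; they do not change the site sequence or length).
#'
#' @inheritParams parse_layout
#' @param site_triplets character vector with one triplet per finger, in
#'   layout order.
#' @return A tibble with one row per finger (`finger`, `label`, `triplet`,
#'   `start`, `end` 0-based half-open within the site, `overlap`,
#'   `overlap_position`) carrying the full site as attributes `site` and
#'   `site_length`.
#' @examples
#' site <- build_composite_site("321", c("GGG", "GCG", "GGG"))
#' attr(site, "site")
#' @export
build_composite_site <- function(layout, site_triplets) {
  layout <- parse_layout(layout)
  site_triplets <- dna_validate(site_triplets)
  if (length(site_triplets) != length(layout)) {
    abort(sprintf(
      "layout has %d fingers but %d triplets were supplied",
      length(layout), length(site_triplets)
    ))
  }
  if (any(nchar(site_triplets) != 3L)) {
    abort("each finger subsite must be exactly 3 bases")
  }
  out <- annotate_overlap_loci(layout)
  out <- mutate(out,
    triplet = site_triplets,
    start = 3L * (row_number() - 1L),
    end = .data$start + 3L,
    .after = "label"
  )
  site <- paste(site_triplets, collapse = "")
  structure(out, site = site, site_length = nchar(site))
}

#' Annotate 4th-base overlap loci of an arrangement
#'
#' Fingers homologous to SP1 fingers 2 and 3 additionally contact the
#' complementary-strand base one position 3' of their own triplet — the
#' "4th base" of the adjacent subsite (the target-site overlap). Fingers
#' labelled 1 do not engage in overlap binding; their role is binding
#' initiation. The annotation marks, for each overlapping finger, the
#' 0-based site position of that converse-strand contact.
#'
#' @inheritParams parse_layout
#' @return A tibble with one row per finger: `finger` (index in layout),
#'   `label`, `overlap` (logical) and `overlap_position` (0-based position
#'   of the converse-strand contact, `NA` where there is none).
#' @examples
#' annotate_overlap_loci("321")  # fingers 3 and 2 overlap, finger 1 does not
#' @export
annotate_overlap_loci <- function(layout) {
  layout <- parse_layout(layout)
  idx <- seq_along(layout)
  overlap <- layout %in% c(2L, 3L)
  tibble(
    finger = idx,
    label = layout,
    overlap = overlap,
    overlap_position = ifelse(overlap, 3L * idx, NA_integer_)
  )
}

#' Enumerate candidate binding sites from per-finger codes
#'
#' For a domain of `n` fingers, each with its own RSR code, enumerates every
#' combination of the `rank_cutoff` strongest triplets per finger —
#' `rank_cutoff^n` candidate sites (262,144 for a three-finger domain at the
#' full cutoff of 64). Each candidate is scored by the sum of its per-finger
#' ranks (lower = preferred); the sum is the simplest monotone aggregate of
#' the ordinal per-finger preferences.
#'
#' @param codes a list with one `rsr_code` (or coercible) per finger, in
#'   layout order; a single code is recycled via `n_fingers`.
#' @param rank_cutoff integer in 1-64: per-finger rank cutoff `r`.
#' @param n_fingers number of fingers when `codes` is a single code.
#' @param max_sites refuse enumerations larger than this (the count is
#'   always available in closed form via `n_candidate_sites()`).
#' @return A tibble of `rank_cutoff^n` rows: per-finger rank columns
#'   (`rank_f1`, ...), `site` (the concatenated sequence) and `score`,
#'   sorted by score.
#' @examples
#' code <- published_code("SP1")
#' enumerate_candidate_sites(list(code, code), rank_cutoff = 2)
#' n_candidate_sites(3, 64) # 262144
#' @export
enumerate_candidate_sites <- function(codes, rank_cutoff = 64,
                                      n_fingers = NULL,
                                      max_sites = 2^22) {
  if (inherits(codes, "rsr_code") || is.character(codes)) {
    codes <- rep(list(codes), n_fingers %||% 3L)
  }
  rankings <- purrr::map(codes, as_ranking)
  n <- length(rankings)
  if (!is.numeric(rank_cutoff) || rank_cutoff < 1 || rank_cutoff > 64) {
    abort("rank_cutoff must be between 1 and 64")
  }
  total <- n_candidate_sites(n, rank_cutoff)
  if (total > max_sites) {
    abort(sprintf(
      "enumeration would produce %s sites; raise max_sites or use n_candidate_sites()",
      format(total, big.mark = ",")
    ))
  }
  grid <- expand.grid(
    rev(rep(list(seq_len(rank_cutoff)), n)),
    KEEP.OUT.ATTRS = FALSE
  )[, n:1, drop = FALSE]
  names(grid) <- paste0("rank_f", seq_len(n))
  parts <- purrr::map2(rankings, seq_len(n), function(rk, i) {
    rk$triplet[grid[[i]]]
  })
  out <- as_tibble(grid)
  out$site <- do.call(paste0, parts)
  out$score <- as.integer(Reduce(`+`, grid))
  arrange(out, .data$score)
}

#' @rdname enumerate_candidate_sites
#' @export
n_candidate_sites <- function(n_fingers, rank_cutoff = 64) {
  rank_cutoff^n_fingers
}
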