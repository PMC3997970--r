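#' Packaged assay and rank-code tables
#'
#' The package ships, as plain tab-separated fixtures, the published screen of
#' the SP1 second finger: Phosphor Imager (P32) band-shift counts for all 64
#' triplet probes together with the number of exact GGG<triplet>GGG matches in
#' the HuRef human genome assembly, the six rank-specific recognition codes
#' (SP1 wild type and five alpha-helix mutants), and the mutant helix
#' sequences. Loaders verify a recorded checksum and a set of content
#' invariants (column totals, the undetectable-triplet set, permutation
#' validity) on every read, so any corruption of the packaged data is caught
#' immediately.
#'
#' @return `sp1_assay_counts()`: a 64-row tibble with columns `triplet`,
#'   `p32_count` and `occurrences`, in the published descending-count order.
#'   `rank_codes()`: a 384-row long tibble with columns `protein`, `rank`,
#'   `triplet`. `mutant_helices()`: a 6-row tibble with columns `name`,
#'   `residues`, `substituted_positions`.
#' @examples
#' sp1_assay_counts()
#' dplyr::filter(rank_codes(), rank == 1)
#' @name fixtures
NULL

.fixture_md5 <- c(
  sp1_triplet_assay.tsv = "0784bb4ffe33b2cad5a331505c01f69c",
  rank_codes.tsv = "a2cfa4151ded3004f4f853dc352aab41",
  mutant_helices.tsv = "1cc5b2b3b91d39c8cd108e0c154e5b03"
)

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "rsrcode", mustWork = TRUE)
  observed <- unname(tools::md5sum(path))
  if (!identical(observed, unname(.fixture_md5[[name]]))) {
    abort(sprintf(
      "fixture integrity failure for %s: md5 %s, expected %s",
      name, observed, .fixture_md5[[name]]
    ))
  }
  path
}

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(
    path,
    comment = "#", col_types = col_types,
    progress = FALSE, lazy = FALSE
  )
}

#' @rdname fixtures
#' @export
sp1_assay_counts <- function() {
  tab <- read_assay_table(fixture_path("sp1_triplet_assay.tsv"))
  stopifnot(
    "packaged assay table must total 1,261,301 occurrences" =
      sum(tab$occurrences) == 1261301L,
    "undetectable triplets must be AAA, AAC, ACC" =
      setequal(tab$triplet[tab$p32_count == 0], c("AAA", "AAC", "ACC")),
    "CGG row must read 4570 / 16697" =
      tab$p32_count[tab$triplet == "CGG"] == 4570L &&
        tab$occurrences[tab$triplet == "CGG"] == 16697L
  )
  tab
}

#' @rdname fixtures
#' @export
rank_codes <- function() {
  wide <- read_tsv_quiet(
    fixture_path("rank_codes.tsv"),
    col_types = readr::cols(rank = readr::col_integer(),
                            .default = readr::col_character())
  )
  long <- tidyr::pivot_longer(
    wide, -"rank",
    names_to = "protein", values_to = "triplet"
  )
  long <- arrange(long, .data$protein, .data$rank)
  for (p in unique(long$protein)) {
    col <- long$triplet[long$protein == p]
    dup <- col[duplicated(col)]
    missing <- setdiff(triplets(), col)
    if (length(dup) || length(missing)) {
      abort(sprintf(
        "rank column %s is not a permutation of the 64 triplets (duplicated: %s; missing: %s)",
        p, paste(dup, collapse = ","), paste(missing, collapse = ",")
      ))
    }
  }
  select(long, "protein", "rank", "triplet")
}

#' @rdname fixtures
#' @export
mutant_helices <- function() {
  tab <- read_tsv_quiet(
    fixture_path("mutant_helices.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  stopifnot("each helix must be 9 residues" = all(nchar(tab$residues) == 9L))
  tab
}

#' Read and write triplet assay tables
#'
#' Plain tab-separated interchange format for EMSA count tables: header
#' columns `triplet`, `p32_count` and (optionally) `occurrences`; `#` lines
#' are comments. Row order is preserved on read and is significant: the
#' stable tie policy of [compute_rsr_code()] breaks count ties in table
#' order.
#'
#' @param path file path.
#' @param records a data frame with columns `triplet`, `p32_count` and
#'   optionally `occurrences`.
#' @return `read_assay_table()` returns a validated tibble (one row per
#'   triplet, all 64 present); `write_assay_table()` returns `path`
#'   invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' write_assay_table(sp1_assay_counts(), tmp)
#' identical(read_assay_table(tmp), sp1_assay_counts())
#' @export
read_assay_table <- function(path) {
  tab <- read_tsv_quiet(
    path,
    col_types = readr::cols(
      triplet = readr::col_character(),
      .default = readr::col_integer()
    )
  )
  if (!all(c("triplet", "p32_count") %in% names(tab))) {
    abort("assay table must have columns 'triplet' and 'p32_count'")
  }
  validate_assay_records(tab)
  tab
}

#' @rdname read_assay_table
#' @export
write_assay_table <- function(records, path) {
  validate_assay_records(records)
  keep <- intersect(c("triplet", "p32_count", "occurrences"), names(records))
  readr::write_tsv(records[keep], path, progress = FALSE)
  invisible(path)
}

validate_assay_records <- function(records) {
  records$triplet <- dna_validate(records$triplet)
  dup <- records$triplet[duplicated(records$triplet)]
  if (length(dup)) {
    abort(paste0("duplicate triplet(s): ", paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(triplets(), records$triplet)
  if (length(missing)) {
    abort(sprintf(
      "assay table must cover all 64 triplets; %d missing (e.g. %s)",
      length(missing), missing[1]
    ))
  }
  counts <- records$p32_count
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("p32_count must be non-negative and complete")
  }
  if ("occurrences" %in% names(records) &&
      (any(is.na(records$occurrences)) || any(records$occurrences < 0))) {
    abort("occurrences must be non-negative and complete")
  }
  invisible(records)
}
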