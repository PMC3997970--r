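#' Plot an RSR code's count decay
#'
#' Band-shift signal against rank, coloured by triplet G+C classification;
#' the y axis is log-scaled because the published counts decay roughly
#' geometrically (zero counts are dropped from the log plot).
#'
#' @param object an `rsr_code` with counts (from [compute_rsr_code()]).
#' @param ... ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rsr_code <- function(object, ...) {
  dat <- tidy(object)
  if (!"p32_count" %in% names(dat)) {
    abort("this code carries no counts; plot rank shifts instead")
  }
  dat <- left_join(dat, classify_triplets(dat$triplet), by = "triplet")
  ggplot(filter(dat, .data$p32_count > 0),
         aes(x = .data$rank, y = .data$p32_count,
             fill = .data$richness)) +
    geom_col() +
    scale_y_log10() +
    labs(
      x = "rank", y = "P32 count (arbitrary units, log scale)",
      fill = NULL,
      title = paste0(object$protein, " rank-specific recognition code")
    ) +
    theme_minimal()
}

#' Plot a pairwise rank comparison
#'
#' Rank-versus-rank scatter for two codes; points on the diagonal kept
#' their rank, points far from it were strongly re-ranked by the mutation.
#'
#' @param object an `rsr_comparison` from [compare_rank_codes()].
#' @param ... ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rsr_comparison <- function(object, ...) {
  ggplot(object$shifts, aes(x = .data$rank_a, y = .data$rank_b)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_abline(linetype = 2) +
    labs(
      x = paste0("rank in ", object$protein_a),
      y = paste0("rank in ", object$protein_b),
      title = sprintf("rho = %.2f, tau = %.2f, footrule = %d",
                      object$spearman_rho, object$kendall_tau,
                      object$footrule)
    ) +
    theme_minimal()
}

#' Bump chart of triplet ranks across proteins
#'
#' Traces how selected triplets move through the rank order across a set of
#' codes — the visual form of the rank-shift report.
#'
#' @param codes a long tibble as returned by [rank_codes()], or a list of
#'   `rsr_code` objects.
#' @param highlight triplets to label and colour; others are drawn in grey.
#' @return A ggplot object.
#' @examples
#' plot_rank_shift(rank_codes(), highlight = c("CGG", "GCG", "AAA"))
#' @export
plot_rank_shift <- function(codes, highlight = c("CGG", "GCG")) {
  wide <- rank_shift_report(codes)
  long <- tidyr::pivot_longer(wide, -"triplet",
                              names_to = "protein", values_to = "rank")
  long$protein <- factor(long$protein, levels = setdiff(names(wide), "triplet"))
  ggplot(long, aes(x = .data$protein, y = .data$rank,
                   group = .data$triplet)) +
    geom_line(colour = "grey80") +
    geom_line(
      data = filter(long, .data$triplet %in% highlight),
      aes(colour = .data$triplet), linewidth = 1
    ) +
    geom_point(
      data = filter(long, .data$triplet %in% highlight),
      aes(colour = .data$triplet)
    ) +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = "rank (1 = strongest)", colour = "triplet") +
    theme_minimal()
}
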