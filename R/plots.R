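#' Cumulative scaffold-length curve with the N50 point
#'
#' Scaffolds are ranked by length descending; the marked point is the scaffold
#' at which the cumulative length first reaches half the assembly size.
#'
#' @param assembly Assembly tibble (`id`, `seq`).
#' @return A ggplot object.
#' @export
plot_scaffold_lengths <- function(assembly) {
  check_assembly(assembly)
  st <- scaffold_stats(assembly)
  len <- sort(nchar(assembly$seq), decreasing = TRUE)
  d <- tibble(rank = seq_along(len), cumulative_bp = cumsum(as.numeric(len)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$cumulative_bp)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = st$assembly_size_bp / 2, linetype = 2) +
    ggplot2::geom_point(data = d[st$n50_rank, , drop = FALSE], colour = "red") +
    ggplot2::labs(x = "scaffold rank (length descending)",
                  y = "cumulative length (bp)",
                  title = sprintf("N50 rank %d, N50 length %s bp",
                                  st$n50_rank,
                                  format(st$n50_length_bp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Per-family RIP dominance against average family length
#'
#' @param families Per-family tibble from [classify_rip_mutations()] rows.
#' @param dominance_threshold Reference line (default 1, the RIP-typical
#'   boundary).
#' @return A ggplot object. Families with infinite dominance are drawn at the
#'   top of the finite range with an open symbol.
#' @export
plot_rip_dominance <- function(families, dominance_threshold = 1) {
  d <- mutate(families,
              infinite = !is.finite(.data$dominance),
              shown = ifelse(.data$infinite,
                             max(c(.data$dominance[is.finite(.data$dominance)], 2)) * 1.2,
                             .data$dominance))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg_length_bp, y = .data$shown,
                                  shape = .data$infinite)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = dominance_threshold, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "average family length (bp)",
                  y = "CpA<->TpA dominance") +
    ggplot2::theme_minimal()
}

#' Per-motif candidate-effector counts
#'
#' @param motif_counts Tibble from [candidate_summary()].
#' @return A ggplot bar chart, motifs in descending order of abundance.
#' @export
plot_motif_counts <- function(motif_counts) {
  d <- mutate(motif_counts,
              motif_name = stats::reorder(.data$motif_name, -.data$n_candidates))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$motif_name, y = .data$n_candidates)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "effector motif", y = "candidate proteins") +
    ggplot2::theme_minimal()
}

#' Length-weighted identity distribution of whole-genome alignment matches
#'
#' @param matches Tibble from [read_coords()].
#' @param threshold Identity threshold to mark (default 95).
#' @return A ggplot histogram weighted by aligned bases.
#' @export
plot_synteny_identity <- function(matches, threshold = 95) {
  ggplot2::ggplot(matches, ggplot2::aes(x = .data$pct_identity,
                                        weight = .data$length)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "percent identity", y = "aligned bases (bp)") +
    ggplot2::theme_minimal()
}
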