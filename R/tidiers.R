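#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy dinucleotide counts into a long tibble
#'
#' @param x A `dinuc_counts` object.
#' @param ... Unused.
#' @return Tibble with `dinucleotide`, `count`, `frequency`.
#' @method tidy dinuc_counts
#' @export
tidy.dinuc_counts <- function(x, ...) {
  np <- attr(x, "n_positions")
  tibble(dinucleotide = names(x), count = as.integer(x),
         frequency = if (np > 0) as.integer(x) / np else NA_real_)
}

#' One-row summary of dinucleotide counts (RIP indices)
#'
#' @param x A `dinuc_counts` object.
#' @param ... Unused.
#' @return The [rip_indices()] tibble.
#' @method glance dinuc_counts
#' @export
glance.dinuc_counts <- function(x, ...) rip_indices(x)

#' Tidy a deRIP consensus into per-position rows
#'
#' @param x A `derip_consensus` object.
#' @param ... Unused.
#' @return Tibble with `position` and `base` of the gapless model.
#' @method tidy derip_consensus
#' @export
tidy.derip_consensus <- function(x, ...) {
  tibble(position = seq_len(nchar(unclass(x))),
         base = strsplit(unclass(x), "", fixed = TRUE)[[1]])
}

#' One-row overview of an assembly summary
#'
#' @param x An `assembly_summary` tibble.
#' @param ... Unused.
#' @return The summary as a plain tibble.
#' @method glance assembly_summary
#' @export
glance.assembly_summary <- function(x, ...) as_tibble(unclass2(x))

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), c("assembly_summary", "rip_family_summary"))
  x
}

#' One-row pooled overview of per-family RIP summaries
#'
#' @param x A `rip_family_summary` tibble (one or more rows).
#' @param ... Passed to [genome_rip_summary()] (e.g. `dominance_threshold`).
#' @return The [genome_rip_summary()] tibble.
#' @method glance rip_family_summary
#' @export
glance.rip_family_summary <- function(x, ...) genome_rip_summary(x, ...)
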