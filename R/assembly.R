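#' Scaffold-level assembly statistics
#'
#' Computes scaffold count, assembly size, the N50 rank/length pair and GC
#' content for a genome assembly. Scaffolds are ranked by length descending
#' (ties broken by id ascending); the N50 length is the length of the first
#' scaffold at which the cumulative length reaches at least half the assembly
#' size, and the N50 rank is its 1-based rank. GC content is
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from both numerator
#' and denominator.
#'
#' @param assembly Tibble with columns `id`, `seq` (nucleotide scaffolds).
#' @return One-row tibble: `n_scaffolds`, `assembly_size_bp`, `n50_rank`,
#'   `n50_length_bp`, `gc_percent`.
#' @examples
#' asm <- tibble::tibble(id = paste0("s", 1:5),
#'                       seq = strrep("ACGT", c(5, 4, 3, 2, 1)))
#' scaffold_stats(asm)
#' @export
scaffold_stats <- function(assembly) {
  check_assembly(assembly)
  len <- nchar(assembly$seq)
  ord <- order(-len, assembly$id)
  len_sorted <- len[ord]
  total <- sum(as.numeric(len_sorted))
  cum <- cumsum(as.numeric(len_sorted))
  rank <- which(cum >= total / 2)[1L]
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(assembly$seq))
  acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  tibble(
    n_scaffolds = nrow(assembly),
    assembly_size_bp = total,
    n50_rank = rank,
    n50_length_bp = len_sorted[rank],
    gc_percent = 100 * (acgt[["G"]] + acgt[["C"]]) / sum(acgt)
  )
}

check_assembly <- function(assembly) {
  if (!is.data.frame(assembly) || !all(c("id", "seq") %in% names(assembly))) {
    stop("assembly must be a tibble with columns id, seq")
  }
  if (nrow(assembly) < 1L) stop("empty assembly")
  if (any(nchar(assembly$seq) == 0L)) {
    stop("zero-length scaffold(s): ",
         paste(assembly$id[nchar(assembly$seq) == 0L], collapse = ", "))
  }
  invisible(assembly)
}

#' Gene density in genes per megabase
#'
#' @param n_genes Number of protein-coding genes.
#' @param assembly_size_bp Assembly size in bp.
#' @return Genes per Mbp, rounded to one decimal.
#' @examples
#' gene_density(11415, 38.6e6)
#' @export
gene_density <- function(n_genes, assembly_size_bp) {
  if (assembly_size_bp <= 0) stop("assembly size must be positive")
  if (n_genes < 0) stop("negative gene count")
  round(n_genes / (assembly_size_bp / 1e6), 1)
}

#' Fraction of an assembly covered by repeat intervals
#'
#' Takes the union of the (possibly overlapping) intervals and reports the
#' covered fraction of the assembly as a percentage. Intervals are 0-based
#' half-open.
#'
#' @param assembly Assembly tibble (`id`, `seq`).
#' @param repeats Interval tibble (`scaffold`, `start`, `end`).
#' @return Percent of assembly bases covered, in \[0, 100\].
#' @export
masked_fraction <- function(assembly, repeats) {
  check_assembly(assembly)
  if (nrow(repeats) == 0L) return(0)
  check_intervals(repeats, assembly)
  covered <- sum(vapply(split(repeats, repeats$scaffold), function(d) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))))
  }, numeric(1)))
  100 * covered / sum(as.numeric(nchar(assembly$seq)))
}

check_intervals <- function(repeats, assembly) {
  lens <- setNames(nchar(assembly$seq), assembly$id)
  unknown <- setdiff(repeats$scaffold, assembly$id)
  if (length(unknown)) stop("interval scaffold(s) not in assembly: ",
                            paste(unique(unknown), collapse = ", "))
  over <- repeats$end > lens[repeats$scaffold]
  if (any(over)) {
    i <- which(over)[1L]
    stop("interval [", repeats$start[i], ",", repeats$end[i],
         ") extends beyond scaffold '", repeats$scaffold[i], "' (length ",
         lens[[repeats$scaffold[i]]], ")")
  }
  invisible(repeats)
}

#' Summarise whole-genome alignment identity
#'
#' Length-weighted summary of alignment matches: total aligned bases, mean
#' percent identity weighted by match length, and the fraction of aligned
#' bases in matches at or above an identity threshold.
#'
#' @param matches Tibble of alignment matches (from [read_coords()]).
#' @param threshold Identity threshold in percent (default 95).
#' @return One-row tibble: `aligned_bp`, `mean_identity`, `frac_ge_threshold`.
#' @export
synteny_identity_summary <- function(matches, threshold = 95) {
  if (nrow(matches) == 0L) stop("empty match list")
  w <- as.numeric(matches$length)
  tibble(
    aligned_bp = sum(w),
    mean_identity = sum(w * matches$pct_identity) / sum(w),
    frac_ge_threshold = sum(w[matches$pct_identity >= threshold]) / sum(w)
  )
}

#' Full assembly summary
#'
#' Combines [scaffold_stats()] with gene density and repeat coverage into a
#' genome report row mirroring the usual comparative-genomics summary table.
#'
#' @param assembly Assembly tibble.
#' @param n_genes Optional gene count (for gene density).
#' @param repeats Optional repeat interval tibble (for repeat percent).
#' @return One-row tibble of class `assembly_summary`.
#' @export
assembly_summary <- function(assembly, n_genes = NULL, repeats = NULL) {
  out <- scaffold_stats(assembly)
  out$gene_density_per_mbp <- if (is.null(n_genes)) NA_real_ else
    gene_density(n_genes, out$assembly_size_bp)
  out$repeat_percent <- if (is.null(repeats)) NA_real_ else
    masked_fraction(assembly, repeats)
  class(out) <- c("assembly_summary", class(out))
  out
}
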