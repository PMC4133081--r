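#' Overlapping dinucleotide counts
#'
#' Counts all overlapping adjacent base pairs (step 1, single given strand)
#' across one or more nucleotide sequences. Pairs are never counted across
#' sequence boundaries, and pairs containing N are skipped. Empty and
#' length-1 sequences contribute zero counts.
#'
#' @param seqs Character vector of nucleotide sequences (A,C,G,T,N).
#' @return Named integer vector of class `dinuc_counts` over the 16
#'   dinucleotides, with attribute `n_positions` (total counted pairs).
#' @examples
#' dinucleotide_counts("CACGTG")
#' @export
dinucleotide_counts <- function(seqs) {
  seqs <- seqs[nchar(seqs) >= 2L]
  if (length(seqs) == 0L) {
    counts <- setNames(integer(16L), dinuc_names())
  } else {
    freq <- Biostrings::dinucleotideFrequency(Biostrings::DNAStringSet(seqs))
    counts <- setNames(as.integer(colSums(freq)), colnames(freq))
  }
  structure(counts, n_positions = sum(counts), class = "dinuc_counts")
}

dinuc_names <- function() {
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
}

#' @export
print.dinuc_counts <- function(x, ...) {
  cat("dinucleotide counts over", attr(x, "n_positions"), "pairs\n")
  print(unclass(x))
  invisible(x)
}

#' RIP indices from dinucleotide counts
#'
#' The TpA/ApT index is the frequency of the RIP product dinucleotide TpA over
#' the non-RIP control ApT; both are reverse-complement palindromes, so a
#' single strand suffices. The combined CpA+TpG frequency tracks depletion of
#' the RIP target (CpA pooled with its reverse complement TpG).
#'
#' @param counts A `dinuc_counts` object (or named vector of the 16
#'   dinucleotide counts with attribute `n_positions`).
#' @return One-row tibble: `tpa_apt` (NA when the ApT count is zero),
#'   `tpa_apt_defined`, `cpa_tpg_freq`, `tpa_freq`, `n_positions`.
#' @export
rip_indices <- function(counts) {
  np <- attr(counts, "n_positions") %||% sum(counts)
  ta <- counts[["TA"]]; at <- counts[["AT"]]
  tibble(
    tpa_apt = if (at == 0L) NA_real_ else ta / at,
    tpa_apt_defined = at > 0L,
    cpa_tpg_freq = if (np == 0L) NA_real_ else (counts[["CA"]] + counts[["TG"]]) / np,
    tpa_freq = if (np == 0L) NA_real_ else ta / np,
    n_positions = np
  )
}

#' RIP indices partitioned into repetitive and non-repetitive genome fractions
#'
#' Pools dinucleotide counts across all repetitive segments (the union of the
#' repeat intervals) and separately across the non-repetitive complement.
#' Dinucleotides are never counted across segment boundaries.
#'
#' @param assembly Assembly tibble (`id`, `seq`).
#' @param repeats Interval tibble (`scaffold`, `start`, `end`), 0-based
#'   half-open.
#' @return Two-row tibble with a `partition` column (`"repetitive"`,
#'   `"non_repetitive"`) and the [rip_indices()] columns.
#' @export
partitioned_rip_indices <- function(assembly, repeats) {
  check_assembly(assembly)
  if (nrow(repeats) > 0L) check_intervals(repeats, assembly)
  seg <- genome_partition(assembly, repeats)
  bind_rows(
    mutate(rip_indices(dinucleotide_counts(seg$repetitive)), partition = "repetitive"),
    mutate(rip_indices(dinucleotide_counts(seg$non_repetitive)), partition = "non_repetitive")
  )[, c("partition", "tpa_apt", "tpa_apt_defined", "cpa_tpg_freq", "tpa_freq", "n_positions")]
}

# Split every scaffold into repeat-union segments and their complement.
genome_partition <- function(assembly, repeats) {
  rep_segs <- character()
  non_segs <- character()
  for (i in seq_len(nrow(assembly))) {
    sid <- assembly$id[i]
    s <- assembly$seq[i]
    len <- nchar(s)
    d <- repeats[repeats$scaffold == sid, , drop = FALSE]
    if (nrow(d) == 0L) {
      non_segs <- c(non_segs, s)
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    rep_segs <- c(rep_segs, substring(s, IRanges::start(ir), IRanges::end(ir)))
    comp <- IRanges::setdiff(IRanges::IRanges(1L, len), ir)
    if (length(comp)) {
      non_segs <- c(non_segs, substring(s, IRanges::start(comp), IRanges::end(comp)))
    }
  }
  list(repetitive = rep_segs, non_repetitive = non_segs)
}

#' deRIP consensus of a repeat-family alignment
#'
#' Reconstructs the putative pre-RIP ancestral sequence of a repeat family by
#' reverting RIP-consistent polymorphisms. Per alignment column:
#' \itemize{
#'   \item if the column contains both C and T and at least one row carries A
#'     at its next non-gap position (CpA to TpA evidence), emit C;
#'   \item if the column contains both G and A and at least one row carries T
#'     at its previous non-gap position (TpG to TpA evidence, the reverse
#'     complement context), emit G;
#'   \item otherwise emit the majority base (gaps excluded), ties broken in
#'     the fixed order C, G, T, A.
#' }
#' Columns whose majority character is the gap are dropped from the model.
#'
#' @param aln A `repeat_alignment` tibble (see [read_alignment()]).
#' @return The gapless consensus string, with attributes `aligned` (the
#'   column-aligned model, gap-filled at dropped columns) and `family_id`.
#' @export
derip_consensus <- function(aln) {
  mat <- alignment_matrix(aln)
  n <- nrow(mat); W <- ncol(mat)
  nxt <- next_nongap_char(mat)
  prv <- prev_nongap_char(mat)
  out <- character(W)
  for (j in seq_len(W)) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    if (2L * gaps > n || gaps == n) {
      out[j] <- "-"
      next
    }
    nz <- col != "-"
    if (any(col == "C") && any(col == "T") && any(nz & nxt[, j] == "A", na.rm = TRUE)) {
      out[j] <- "C"
    } else if (any(col == "G") && any(col == "A") && any(nz & prv[, j] == "T", na.rm = TRUE)) {
      out[j] <- "G"
    } else {
      out[j] <- majority_base(col[nz])
    }
  }
  structure(paste(out[out != "-"], collapse = ""),
            aligned = paste(out, collapse = ""),
            family_id = attr(aln, "family_id"),
            class = "derip_consensus")
}

#' @export
print.derip_consensus <- function(x, ...) {
  cat("deRIP consensus (", attr(x, "family_id") %||% "family", "), ",
      nchar(unclass(x)), " bp\n", sep = "")
  cat(unclass(x), "\n")
  invisible(x)
}

majority_base <- function(bases) {
  order_pref <- c("C", "G", "T", "A", "N")
  tab <- table(factor(bases, levels = order_pref))
  names(tab)[which.max(tab)]  # which.max takes the first maximum: C > G > T > A
}

alignment_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(mat) <- aln$id
  mat
}

# Per row: character at the next (previous) non-gap position, NA at the ends.
next_nongap_char <- function(mat) {
  per_row_matrix(mat, function(x) {
    ng <- which(x != "-")
    if (length(ng) == 0L) return(rep(NA_character_, length(x)))
    k <- findInterval(seq_along(x), ng) + 1L
    ifelse(k <= length(ng), x[ng[pmin(k, length(ng))]], NA_character_)
  })
}

prev_nongap_char <- function(mat) {
  per_row_matrix(mat, function(x) {
    ng <- which(x != "-")
    if (length(ng) == 0L) return(rep(NA_character_, length(x)))
    k <- findInterval(seq_along(x) - 1L, ng)
    ifelse(k >= 1L, x[ng[pmax(k, 1L)]], NA_character_)
  })
}

per_row_matrix <- function(mat, f) {
  res <- apply(mat, 1L, f)
  if (is.null(dim(res))) matrix(res, nrow = nrow(mat)) else t(res)
}

#' Classify RIP-like polymorphisms in a repeat-family alignment
#'
#' Compares every alignment row with a model (typically the deRIP consensus)
#' and tallies C-to-T transitions by the model's downstream context: a column
#' where the model has C and a row has T increments the CpY to TpY class,
#' where Y is the model's next non-gap base. Columns where the model has G and
#' a row has A are the reverse-complement case, classed via the model's
#' previous non-gap base X (X=T gives CpA/TpA, X=G gives CpC/TpC, X=C gives
#' CpG/TpG, X=A gives CpT/TpT). All other base substitutions count as
#' `other_mutations`; substitutions adjacent to model gaps with no flanking
#' base also fall into `other_mutations`. Indels are never counted.
#'
#' @param aln A `repeat_alignment` tibble.
#' @param model Model sequence: either a string aligned to the alignment
#'   columns (gaps allowed), or a [derip_consensus()] result (its aligned
#'   attribute is used). Defaults to the deRIP consensus of `aln`.
#' @return One-row tibble of class `rip_family_summary`: `family_id`,
#'   `n_rows`, `avg_length_bp`, the four class counts (`cpa_tpa`, `cpc_tpc`,
#'   `cpg_tpg`, `cpt_tpt`), `other_mutations`, `rip_like_total`, `dominance`,
#'   `dominance_flag`.
#' @export
classify_rip_mutations <- function(aln, model = NULL) {
  mat <- alignment_matrix(aln)
  W <- ncol(mat)
  if (is.null(model)) model <- derip_consensus(aln)
  mstr <- if (!is.null(attr(model, "aligned"))) attr(model, "aligned") else unclass(model)
  if (nchar(mstr) != W) {
    stop("model length (", nchar(mstr), ") does not match alignment width (", W, ")")
  }
  m <- strsplit(mstr, "", fixed = TRUE)[[1]]
  ng <- which(m != "-")
  if (length(ng) == 0L) stop("model contains no bases")
  k_next <- findInterval(seq_len(W), ng) + 1L
  m_next <- ifelse(k_next <= length(ng), m[ng[pmin(k_next, length(ng))]], NA_character_)
  k_prev <- findInterval(seq_len(W) - 1L, ng)
  m_prev <- ifelse(k_prev >= 1L, m[ng[pmax(k_prev, 1L)]], NA_character_)

  cls <- c(cpa_tpa = 0L, cpc_tpc = 0L, cpg_tpg = 0L, cpt_tpt = 0L)
  other <- 0L
  ct_class <- c(A = "cpa_tpa", C = "cpc_tpc", G = "cpg_tpg", T = "cpt_tpt")
  ga_class <- c(T = "cpa_tpa", G = "cpc_tpc", C = "cpg_tpg", A = "cpt_tpt")
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    sub <- m %in% c("A", "C", "G", "T") & row %in% c("A", "C", "G", "T") & row != m
    ct <- sub & m == "C" & row == "T"
    ga <- sub & m == "G" & row == "A"
    ct_ctx <- m_next[ct]
    ga_ctx <- m_prev[ga]
    for (b in names(ct_class)) cls[[ct_class[[b]]]] <- cls[[ct_class[[b]]]] +
        sum(ct_ctx == b, na.rm = TRUE)
    for (b in names(ga_class)) cls[[ga_class[[b]]]] <- cls[[ga_class[[b]]]] +
        sum(ga_ctx == b, na.rm = TRUE)
    # context-less or N-context RIP-type transitions, and all other substitutions
    other <- other + sum(is.na(ct_ctx) | ct_ctx == "N") +
      sum(is.na(ga_ctx) | ga_ctx == "N") + sum(sub & !ct & !ga)
  }
  dom <- rip_dominance(cls[["cpa_tpa"]], cls[["cpc_tpc"]], cls[["cpg_tpg"]], cls[["cpt_tpt"]])
  out <- tibble(
    family_id = attr(aln, "family_id") %||% "family",
    n_rows = nrow(mat),
    avg_length_bp = mean(nchar(gsub("-", "", aln$seq, fixed = TRUE))),
    cpa_tpa = cls[["cpa_tpa"]], cpc_tpc = cls[["cpc_tpc"]],
    cpg_tpg = cls[["cpg_tpg"]], cpt_tpt = cls[["cpt_tpt"]],
    other_mutations = other,
    rip_like_total = sum(cls),
    dominance = dom$dominance,
    dominance_flag = dom$flag
  )
  class(out) <- c("rip_family_summary", class(out))
  out
}

#' RIP dominance score
#'
#' Ratio of CpA/TpA-classed polymorphisms to the sum of the other three
#' CpN/TpN classes. A score of 1 or greater indicates RIP-typical CpA-context
#' dominance of C-to-T mutation.
#'
#' @param cpa_tpa,cpc_tpc,cpg_tpg,cpt_tpt Class counts.
#' @return List with `dominance` (ratio; `Inf` when only the CpA/TpA class is
#'   populated; 0 when all classes are empty) and `flag` (`"ok"`,
#'   `"infinite"`, or `"undefined"` for the 0/0 case).
#' @export
rip_dominance <- function(cpa_tpa, cpc_tpc, cpg_tpg, cpt_tpt) {
  den <- cpc_tpc + cpg_tpg + cpt_tpt
  if (den == 0) {
    if (cpa_tpa > 0) list(dominance = Inf, flag = "infinite")
    else list(dominance = 0, flag = "undefined")
  } else {
    list(dominance = cpa_tpa / den, flag = "ok")
  }
}

#' Genome-level RIP summary over repeat families
#'
#' Pools the per-family class counts (the overall dominance is computed from
#' pooled counts, not as a mean of per-family ratios), totals the RIP-like
#' mutations, and counts families at or above a dominance threshold.
#'
#' @param families Tibble of per-family summaries (rows from
#'   [classify_rip_mutations()], e.g. via [dplyr::bind_rows()]).
#' @param dominance_threshold Families with dominance at or above this value
#'   (infinite included) are counted; default 1.
#' @return One-row tibble: `n_families`, pooled class counts,
#'   `total_rip_like`, `overall_dominance`, `overall_flag`,
#'   `n_families_ge_threshold`.
#' @export
genome_rip_summary <- function(families, dominance_threshold = 1) {
  if (nrow(families) == 0L) stop("no repeat families supplied")
  pooled <- vapply(c("cpa_tpa", "cpc_tpc", "cpg_tpg", "cpt_tpt"),
                   function(k) sum(families[[k]]), numeric(1))
  dom <- rip_dominance(pooled[["cpa_tpa"]], pooled[["cpc_tpc"]],
                       pooled[["cpg_tpg"]], pooled[["cpt_tpt"]])
  tibble(
    n_families = nrow(families),
    cpa_tpa = pooled[["cpa_tpa"]], cpc_tpc = pooled[["cpc_tpc"]],
    cpg_tpg = pooled[["cpg_tpg"]], cpt_tpt = pooled[["cpt_tpt"]],
    total_rip_like = sum(families$rip_like_total),
    overall_dominance = dom$dominance,
    overall_flag = dom$flag,
    n_families_ge_threshold = sum(families$dominance >= dominance_threshold)
  )
}

#' Reverse complement of a nucleotide sequence
#' @param seq Character vector of sequences over A,C,G,T,N.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
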