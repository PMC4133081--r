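# Independent brute-force oracles used to cross-check the implementation.

random_dna_str <- function(n, with_n = FALSE) {
  paste(sample(c("A", "C", "G", "T", if (with_n) "N"), n, replace = TRUE),
        collapse = "")
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# dinucleotide counting by explicit position loop
oracle_dinuc <- function(seq) {
  counts <- setNames(rep(0L, 16L),
                     as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  for (s in seq) {
    x <- strsplit(s, "")[[1]]
    if (length(x) < 2) next
    for (i in seq_len(length(x) - 1L)) {
      p <- paste0(x[i], x[i + 1L])
      if (p %in% names(counts)) counts[[p]] <- counts[[p]] + 1L
    }
  }
  counts
}

# RIP mutation classification by explicit per-row, per-column scan
oracle_classify <- function(rows, model) {
  m <- strsplit(model, "")[[1]]
  cls <- c(cpa_tpa = 0L, cpc_tpc = 0L, cpg_tpg = 0L, cpt_tpt = 0L, other = 0L)
  next_base <- function(j) {
    if (j >= length(m)) return(NA_character_)
    for (k in (j + 1L):length(m)) if (m[k] != "-") return(m[k])
    NA_character_
  }
  prev_base <- function(j) {
    if (j <= 1L) return(NA_character_)
    for (k in (j - 1L):1L) if (m[k] != "-") return(m[k])
    NA_character_
  }
  ct_map <- c(A = "cpa_tpa", C = "cpc_tpc", G = "cpg_tpg", T = "cpt_tpt")
  ga_map <- c(T = "cpa_tpa", G = "cpc_tpc", C = "cpg_tpg", A = "cpt_tpt")
  for (row in rows) {
    r <- strsplit(row, "")[[1]]
    for (j in seq_along(m)) {
      if (!m[j] %in% c("A","C","G","T") || !r[j] %in% c("A","C","G","T")) next
      if (r[j] == m[j]) next
      if (m[j] == "C" && r[j] == "T") {
        b <- next_base(j)
        if (!is.na(b) && b %in% names(ct_map)) cls[[ct_map[[b]]]] <- cls[[ct_map[[b]]]] + 1L
        else cls[["other"]] <- cls[["other"]] + 1L
      } else if (m[j] == "G" && r[j] == "A") {
        b <- prev_base(j)
        if (!is.na(b) && b %in% names(ga_map)) cls[[ga_map[[b]]]] <- cls[[ga_map[[b]]]] + 1L
        else cls[["other"]] <- cls[["other"]] + 1L
      } else {
        cls[["other"]] <- cls[["other"]] + 1L
      }
    }
  }
  cls
}

# plain majority consensus (no RIP reversion), same tie order and gap dropping
oracle_majority_consensus <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  out <- apply(mat, 2L, function(col) {
    if (2L * sum(col == "-") > length(col) || all(col == "-")) return("-")
    nz <- col[col != "-"]
    tab <- table(factor(nz, levels = c("C", "G", "T", "A", "N")))
    names(tab)[which.max(tab)]
  })
  paste(out[out != "-"], collapse = "")
}

gc_frac <- function(s) {
  x <- strsplit(s, "")[[1]]
  sum(x %in% c("G", "C")) / max(1L, sum(x %in% c("A", "C", "G", "T")))
}

# independent residue-set encodings of the shipped motifs for the scan oracle
ORACLE_MOTIFS <- list(
  "[FWY]XC"  = list(c("Y","F","W"), "ANY", "C"),
  "[IL]XAR"  = list(c("L","I"), "ANY", "A", "R"),
  "RXLR"     = list("R", "ANY", "L", "R"),
  "CHXC"     = list("C", "H", "ANY", "C"),
  "KECXD"    = list("K", "E", "C", "ANY", "D"),
  "YXSL[KR]" = list("Y", "ANY", "S", "L", c("R","K"))
)

oracle_scan <- function(seq, elements) {
  x <- strsplit(seq, "")[[1]]
  L <- length(elements)
  hits <- integer()
  if (length(x) < L) return(hits)
  for (i in seq_len(length(x) - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      el <- elements[[k]]
      ch <- x[i + k - 1L]
      match_k <- if (identical(el, "ANY")) ch != "X" else ch %in% el
      if (!match_k) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# small fast simulation profile for round-trip tests
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_core_groups = 40L, n_divergent_per_species = 6L,
             n_expanded_per_species = 4L, n_repeat_families = 4L,
             copies_per_family = 6L, family_length_bp = 300L,
             genome_length_bp = 40000L, n_scaffolds = 4L,
             protein_length_range = c(60L, 250L), ...)
}

consensus_string <- function(x) {
  attributes(x) <- NULL
  x
}
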