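test_that("dinucleotide counts enumerate overlapping pairs and skip N", {
  dc <- dinucleotide_counts("CACGTG")
  expect_equal(unclass(dc)[c("CA", "AC", "CG", "GT", "TG")],
               c(CA = 1L, AC = 1L, CG = 1L, GT = 1L, TG = 1L))
  expect_equal(attr(dc, "n_positions"), 5L)

  ta <- dinucleotide_counts("TATATATA")
  expect_equal(ta[["TA"]], 4L)
  expect_equal(ta[["AT"]], 3L)

  expect_equal(attr(dinucleotide_counts("ANA"), "n_positions"), 0L)
  expect_equal(attr(dinucleotide_counts(c("", "A")), "n_positions"), 0L)
})

test_that("dinucleotide counts match a positional oracle on fuzzed sequences", {
  set.seed(23)
  for (rep in 1:20) {
    seqs <- vapply(sample(0:80, sample(1:4, 1)), random_dna_str, "", with_n = TRUE)
    got <- dinucleotide_counts(seqs)
    want <- oracle_dinuc(seqs)
    expect_equal(unclass(got)[names(want)], want, ignore_attr = TRUE)
    expect_equal(attr(got, "n_positions"), sum(want))
  }
})

test_that("RIP indices follow the TpA/ApT and CpA+TpG definitions", {
  idx <- rip_indices(dinucleotide_counts("TATATATA"))
  expect_equal(idx$tpa_apt, 4 / 3)
  expect_true(idx$tpa_apt_defined)

  gc <- rip_indices(dinucleotide_counts("GCGCGC"))
  expect_true(is.na(gc$tpa_apt))
  expect_false(gc$tpa_apt_defined)
})

test_that("TpA/ApT is invariant under reverse complement", {
  set.seed(41)
  for (rep in 1:15) {
    s <- random_dna_str(sample(20:400, 1))
    a <- rip_indices(dinucleotide_counts(s))
    b <- rip_indices(dinucleotide_counts(reverse_complement(s)))
    expect_equal(a$tpa_apt, b$tpa_apt)
  }
})

test_that("partitioned indices pool counts within segment boundaries only", {
  g <- tibble::tibble(id = "s1", seq = "TATAGCGC")
  p <- partitioned_rip_indices(g, tibble::tibble(scaffold = "s1", start = 0L, end = 4L))
  rep_row <- p[p$partition == "repetitive", ]
  non_row <- p[p$partition == "non_repetitive", ]
  expect_equal(rep_row$tpa_apt, 2)         # "TATA": TA 2, AT 1
  expect_false(non_row$tpa_apt_defined)    # "GCGC" has neither TA nor AT
  expect_equal(rep_row$n_positions + non_row$n_positions, 6L)  # boundary pair not counted

  empty <- partitioned_rip_indices(g, tibble::tibble(scaffold = character(),
                                                     start = integer(), end = integer()))
  expect_equal(empty$n_positions[empty$partition == "non_repetitive"], 7L)
  expect_equal(empty$n_positions[empty$partition == "repetitive"], 0L)
})

test_that("deRIP consensus reverts RIP-consistent polymorphisms", {
  expect_equal(consensus_string(derip_consensus(
    new_alignment(c("a", "b", "c"), c("CAA", "TAA", "CAA")))), "CAA")
  expect_equal(consensus_string(derip_consensus(
    new_alignment(c("a", "b"), c("TGA", "TAA")))), "TGA")
  expect_equal(consensus_string(derip_consensus(
    new_alignment(c("a", "b"), c("ACG", "ACG")))), "ACG")
  # gap-majority columns are dropped from the model
  gapped <- derip_consensus(new_alignment(c("a", "b", "c"), c("C-AA", "T-AA", "C-AA")))
  expect_equal(consensus_string(gapped), "CAA")
  expect_equal(attr(gapped, "aligned"), "C-AA")
})

test_that("deRIP consensus GC is never below the plain majority consensus GC", {
  set.seed(57)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    L <- sample(10:60, 1)
    rows <- vapply(seq_len(n), function(.) {
      s <- strsplit(random_dna_str(L), "")[[1]]
      s[sample(L, sample(0:3, 1))] <- "-"
      paste(s, collapse = "")
    }, "")
    rows <- rows[grepl("[ACGT]", rows)]
    if (length(rows) < 2) next
    aln <- new_alignment(paste0("r", seq_along(rows)), rows)
    expect_gte(gc_frac(consensus_string(derip_consensus(aln))),
               gc_frac(oracle_majority_consensus(rows)))
  }
})

test_that("RIP mutation classes follow model context on both strands", {
  s <- classify_rip_mutations(
    new_alignment(c("m", "r"), c("CAACGA", "TAACGA")), "CAACGA")
  expect_equal(s$cpa_tpa, 1L)
  expect_equal(s$cpc_tpc + s$cpg_tpg + s$cpt_tpt + s$other_mutations, 0L)

  s2 <- classify_rip_mutations(new_alignment(c("m", "r"), c("TGCA", "TACA")), "TGCA")
  expect_equal(s2$cpa_tpa, 1L)  # G->A preceded by T is the reverse-complement context

  s3 <- classify_rip_mutations(new_alignment(c("a", "b"), c("ACGT", "ACGT")), "ACGT")
  expect_equal(s3$rip_like_total + s3$other_mutations, 0L)

  # C->T at the model's end has no downstream context: counted as other
  s4 <- classify_rip_mutations(new_alignment(c("a", "b"), c("AC", "AT")), "AC")
  expect_equal(s4$other_mutations, 1L)
  expect_equal(s4$rip_like_total, 0L)

  expect_error(classify_rip_mutations(
    new_alignment(c("a", "b"), c("ACGT", "ACGT")), "ACG"), "length")
})

test_that("indels are never counted as mutations", {
  s <- classify_rip_mutations(new_alignment(c("a", "b"), c("C-AA", "CTAA")), "C-AA")
  expect_equal(s$rip_like_total + s$other_mutations, 0L)
})

test_that("dominance handles zero denominators with flags", {
  expect_equal(rip_dominance(4, 1, 1, 2)$dominance, 1)
  inf <- rip_dominance(2, 0, 0, 0)
  expect_equal(inf$dominance, Inf)
  expect_equal(inf$flag, "infinite")
  zero <- rip_dominance(0, 0, 0, 0)
  expect_equal(zero$dominance, 0)
  expect_equal(zero$flag, "undefined")
})

test_that("genome summary pools counts rather than averaging ratios", {
  fams <- dplyr::bind_rows(
    classify_rip_mutations(new_alignment(c("a", "b"), c("CAACAA", "TATAAA")), "CAACAA"),
    classify_rip_mutations(new_alignment(c("a", "b"), c("CCA", "CTA")), "CCA")
  )
  g <- genome_rip_summary(fams, dominance_threshold = 1)
  expect_equal(g$total_rip_like, sum(fams$rip_like_total))
  # pooled dominance equals ratio of summed counts
  expect_equal(g$overall_dominance,
               sum(fams$cpa_tpa) / sum(fams$cpc_tpc + fams$cpg_tpg + fams$cpt_tpt))
  # equal pooled counts across classes give 1/3
  eq <- tibble::tibble(cpa_tpa = c(1L, 1L), cpc_tpc = c(2L, 0L),
                       cpg_tpg = c(0L, 2L), cpt_tpt = c(1L, 1L),
                       rip_like_total = c(4L, 4L), dominance = c(0.5, 0.5))
  expect_equal(genome_rip_summary(eq)$overall_dominance, 1 / 3)
  two <- tibble::tibble(cpa_tpa = c(4L, 1L), cpc_tpc = c(1L, 1L),
                        cpg_tpg = c(1L, 0L), cpt_tpt = c(0L, 1L),
                        rip_like_total = c(6L, 3L), dominance = c(2, 0.5))
  expect_equal(genome_rip_summary(two)$n_families_ge_threshold, 1L)
  expect_error(genome_rip_summary(two[0, ]), "no repeat families")
})

test_that("classification against a true ancestor matches the brute-force oracle", {
  set.seed(77)
  for (rep in 1:40) {
    cfg <- sim_config(seed = 1000 + rep, rip_rate = runif(1, 0, 0.5),
                      bg_rate = runif(1, 0, 0.1),
                      copies_per_family = sample(2:10, 1),
                      family_length_bp = sample(10:50, 1))
    f <- generate_repeat_family(cfg, rep)
    got <- classify_rip_mutations(f$alignment, f$ancestor)
    want <- oracle_classify(f$alignment$seq, f$ancestor)
    expect_equal(c(got$cpa_tpa, got$cpc_tpc, got$cpg_tpg, got$cpt_tpt, got$other_mutations),
                 unname(want))
  }
})
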