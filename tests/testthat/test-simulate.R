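test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(99)
  a <- generate_repeat_family(cfg, 1)
  b <- generate_repeat_family(cfg, 1)
  expect_identical(a, b)
  pa <- generate_proteomes(cfg)
  pb <- generate_proteomes(cfg)
  expect_identical(pa, pb)
  expect_false(identical(a$alignment$seq,
                         generate_repeat_family(small_sim_config(100), 1)$alignment$seq))
})

test_that("zero mutation rates give copies identical to the ancestor", {
  cfg <- small_sim_config(3, rip_rate = 0, bg_rate = 0)
  f <- generate_repeat_family(cfg, 1)
  expect_true(all(f$alignment$seq == f$ancestor))
  s <- classify_rip_mutations(f$alignment, f$ancestor)
  expect_equal(s$rip_like_total + s$other_mutations, 0L)
})

test_that("generator bookkeeping matches the classified mutation counts", {
  cfg <- small_sim_config(17, rip_rate = 0.3, bg_rate = 0)
  f <- generate_repeat_family(cfg, 2)
  s <- classify_rip_mutations(f$alignment, f$ancestor)
  # with no background noise every recorded RIP event is a CpA/TpA-class hit
  expect_equal(s$cpa_tpa, f$truth$n_rip)
  expect_equal(s$cpc_tpc + s$cpg_tpg + s$cpt_tpt + s$other_mutations, 0L)
})

test_that("planted divergent, expanded and candidate sets are recovered exactly", {
  cfg <- small_sim_config(7)
  pr <- generate_proteomes(cfg)
  cls <- classify_groups(pr$ortholog_table)
  for (sp in c("sp1", "sp2", "sp3")) {
    div_groups <- cls$group_id[cls$label == paste0("divergent:", sp)]
    got_div <- sort(unlist(pr$ortholog_table[[sp]][pr$ortholog_table$group_id %in% div_groups]))
    expect_equal(got_div, sort(pr$truth$divergent[[sp]]))
    exp_groups <- sort(cls$group_id[cls$label == paste0("expanded:", sp)])
    expect_equal(exp_groups,
                 sort(pr$truth$expanded$group_id[pr$truth$expanded$species == sp]))
    hits <- scan_proteome(pr$proteomes[[sp]])
    pres <- motif_presence(hits, pr$proteomes[[sp]])
    cand <- classify_candidates(pr$proteomes[[sp]], pres, pr$secretion[[sp]])
    expect_equal(sort(cand$id[cand$candidate]), sort(pr$truth$candidates[[sp]]))
  }
})

test_that("secretion rows are consistent with the planted signal peptides", {
  cfg <- small_sim_config(21)
  pr <- generate_proteomes(cfg)
  for (sp in c("sp1", "sp2", "sp3")) {
    sec <- pr$secretion[[sp]]
    prot <- pr$proteomes[[sp]]
    sec_ids <- sec$id[sec$secreted]
    starts <- substr(prot$seq[match(sec_ids, prot$id)], 1, 1)
    expect_true(all(starts == "M"))
    expect_true(all(sec$cleavage_pos[sec$secreted] <
                      nchar(prot$seq[match(sec_ids, prot$id)])))
    expect_true(all(is.na(sec$cleavage_pos[!sec$secreted])))
  }
})

test_that("genome embedding hits the target repeat fraction with exact intervals", {
  cfg <- small_sim_config(5, repeat_fraction_target = 0.05)
  fams <- lapply(1:cfg$n_repeat_families, function(k) generate_repeat_family(cfg, k))
  gen <- generate_genome(cfg, fams)
  mf <- masked_fraction(gen$assembly, gen$repeats)
  expect_lt(abs(mf - 5), 1)
  # intervals exactly delimit embedded copies: bases inside differ from outside
  lens <- setNames(nchar(gen$assembly$seq), gen$assembly$id)
  expect_true(all(gen$repeats$end <= lens[gen$repeats$scaffold]))
  expect_true(all(gen$repeats$start >= 0))
  # embedded sequence matches a simulated family copy
  copies <- unlist(lapply(fams, function(f) f$alignment$seq))
  iv <- gen$repeats[1, ]
  embedded <- substr(gen$assembly$seq[gen$assembly$id == iv$scaffold],
                     iv$start + 1, iv$end)
  expect_true(embedded %in% copies)

  none <- generate_genome(cfg, list())
  expect_equal(nrow(none$repeats), 0L)
  expect_error(sim_config(repeat_fraction_target = 0.95), "unrealistic")
})

test_that("dataset bundles round-trip through their on-disk formats", {
  dir <- tempfile()
  bundle <- generate_dataset(small_sim_config(13), out_dir = dir)
  expect_true(file.exists(file.path(dir, "orthologs.tsv")))
  asm <- read_fasta(file.path(dir, "sp1_assembly.fasta"), "nucleotide")
  expect_equal(asm$seq, bundle$species$sp1$assembly$seq)
  tab <- read_ortholog_table(file.path(dir, "orthologs.tsv"))
  expect_equal(tab, bundle$ortholog_table)
  sec <- read_secretion_table(file.path(dir, "sp2_secretion.tsv"))
  expect_equal(sec$secreted, bundle$species$sp2$secretion$secreted)
  aln_files <- list.files(file.path(dir, "sp3_alignments"), full.names = TRUE)
  expect_equal(length(aln_files), bundle$config$n_repeat_families)
  aln <- read_alignment(aln_files[1])
  expect_equal(aln$seq, bundle$species$sp3$families[[1]]$alignment$seq)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
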