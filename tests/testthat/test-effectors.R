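test_that("motif compilation canonicalizes classes and rejects bad patterns", {
  m <- compile_motif("[YFW]XC")
  m2 <- compile_motif("[YWF]XC")
  expect_equal(m$name, m2$name)  # class members sorted: both spellings identical
  expect_equal(m$length, 3L)
  expect_error(compile_motif("[]XC"), "empty")
  expect_error(compile_motif("[YBZ]XC"), "illegal")
  expect_error(compile_motif("R1LR"), "illegal")
  expect_error(compile_motif("R"), "at least 2")
})

test_that("motif matching treats X as any residue but never matches sequence X", {
  m <- list(compile_motif("[YFW]XC"))
  expect_equal(scan_proteome(tibble::tibble(id = "p", seq = "YAC"), m)$position, 1L)
  expect_equal(nrow(scan_proteome(tibble::tibble(id = "p", seq = "YAG"), m)), 0L)
  expect_equal(scan_proteome(tibble::tibble(id = "p", seq = "MRSLRG"),
                             list(compile_motif("RXLR")))$position, 2L)
  # pattern X does not match the ambiguity letter X in the sequence
  expect_equal(nrow(scan_proteome(tibble::tibble(id = "p", seq = "YXC"), m)), 0L)
})

test_that("overlapping matches are all reported but presence is per protein", {
  m <- list(compile_motif("[YFW]XC"))
  prot <- tibble::tibble(id = "p", seq = "YYCCC")
  hits <- scan_proteome(prot, m)
  expect_equal(hits$position, c(1L, 2L))
  pres <- motif_presence(hits, prot, m)
  expect_equal(sum(pres[[compile_motif("[YFW]XC")$name]]), 1L)
  expect_equal(nrow(scan_proteome(prot, list())), 0L)
})

test_that("scanning agrees with a sliding-window oracle for every shipped motif", {
  set.seed(19)
  motifs <- default_motifs()
  names(ORACLE_MOTIFS) <- vapply(motifs, `[[`, "", "name")  # same shipped order
  prots <- tibble::tibble(id = sprintf("p%03d", 1:40),
                          seq = vapply(sample(5:100, 40, replace = TRUE),
                                       random_protein_str, ""))
  hits <- scan_proteome(prots, motifs)
  for (mp in motifs) {
    for (i in seq_len(nrow(prots))) {
      want <- oracle_scan(prots$seq[i], ORACLE_MOTIFS[[mp$name]])
      got <- hits$position[hits$motif_name == mp$name & hits$protein_id == prots$id[i]]
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(protein_mw("G"), 75.07)
  expect_equal(protein_mw("GG"), 132.12)
  expect_error(protein_mw("GXG"), "X")
  expect_gt(protein_mw("GXG", on_x = "average"), protein_mw("GG"))
  expect_error(protein_mw("GBG"), "unknown residue")
  # the 30 kDa low-MW boundary in candidate screens
  expect_lt(protein_mw(strrep("G", 100)) / 1000, 30)
})

test_that("isoelectric point brackets known residue behaviour", {
  expect_gt(protein_pi("G"), 5.5)
  expect_lt(protein_pi("G"), 6.5)
  expect_gt(protein_pi("KKKK"), 9)
  expect_lt(protein_pi("DDDD"), 4)
})

test_that("net charge decreases strictly in pH, so bisection has a unique root", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  counts <- setNames(rep(2, 7), c("K", "R", "H", "D", "E", "C", "Y"))
  grid <- seq(0.5, 13.5, by = 0.5)
  q <- vapply(grid, function(p) metcomp:::protein_net_charge(counts, p), numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("candidate classification applies all active criteria", {
  prot <- tibble::tibble(
    id = c("cand", "nosec", "long", "nomotif"),
    seq = c(random_protein_str(120), random_protein_str(120),
            random_protein_str(301), random_protein_str(90)))
  motifs <- list(compile_motif("[YFW]XC"))
  # plant a guaranteed motif instance in all but "nomotif"
  substr(prot$seq[1], 50, 52) <- "YAC"
  substr(prot$seq[2], 50, 52) <- "YAC"
  substr(prot$seq[3], 50, 52) <- "YAC"
  prot$seq[4] <- gsub("C", "G", prot$seq[4])
  sec <- tibble::tibble(id = c("cand", "long", "nomotif"),
                        secreted = c(TRUE, TRUE, TRUE),
                        cleavage_pos = NA_integer_, source = "")
  pres <- motif_presence(scan_proteome(prot, motifs), prot, motifs)

  cand <- classify_candidates(prot, pres, sec)
  expect_true(cand$candidate[cand$id == "cand"])
  expect_false(cand$candidate[cand$id == "nosec"])   # missing row: not secreted
  expect_true(cand$candidate[cand$id == "long"])     # no length cap by default

  capped <- classify_candidates(prot, pres, sec,
                                criteria = candidate_criteria(max_length_aa = 300))
  expect_false(capped$candidate[capped$id == "long"])  # 301 aa exceeds cap

  expect_error(candidate_criteria(FALSE, FALSE, NULL, FALSE), "at least one")
})

test_that("tightening criteria never adds candidates", {
  set.seed(61)
  prot <- tibble::tibble(id = sprintf("p%02d", 1:30),
                         seq = vapply(sample(50:400, 30, replace = TRUE),
                                      random_protein_str, ""))
  sec <- tibble::tibble(id = prot$id, secreted = runif(30) < 0.5,
                        cleavage_pos = NA_integer_, source = "")
  pres <- motif_presence(scan_proteome(prot), prot)
  base <- classify_candidates(prot, pres, sec)
  tighter <- classify_candidates(prot, pres, sec,
                                 criteria = candidate_criteria(max_length_aa = 200))
  tightest <- classify_candidates(prot, pres, sec, divergent_ids = prot$id[1:5],
                                  criteria = candidate_criteria(max_length_aa = 200,
                                                                require_divergent = TRUE))
  expect_true(all(tighter$id[tighter$candidate] %in% base$id[base$candidate]))
  expect_true(all(tightest$id[tightest$candidate] %in% tighter$id[tighter$candidate]))
})

test_that("candidate summary counts per motif in descending order", {
  motifs <- list(compile_motif("[YFW]XC"), compile_motif("RXLR"))
  prot <- tibble::tibble(id = c("a", "b"),
                         seq = c("MYACDDDDDDRSLRDDDD", "MYACDDDDDDDDDDDDDD"))
  sec <- tibble::tibble(id = c("a", "b"), secreted = TRUE,
                        cleavage_pos = NA_integer_, source = "")
  pres <- motif_presence(scan_proteome(prot, motifs), prot, motifs)
  cand <- classify_candidates(prot, pres, sec)
  cs <- candidate_summary(cand, pres)
  expect_equal(cs$n_candidates, c(2L, 1L))
  expect_equal(cs$motif_name[1], compile_motif("[YFW]XC")$name)
  none <- classify_candidates(prot, pres,
                              dplyr::mutate(sec, secreted = FALSE))
  expect_equal(nrow(candidate_summary(none, pres)), 0L)
})

test_that("motif registries load from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("'[YFW]XC': '[YFW]XC'", "RXLR: RXLR"), f)
  reg <- read_motif_registry(f)
  expect_equal(length(reg), 2L)
  expect_equal(reg[[2]]$name, "RXLR")
})
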