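#' Simulation configuration for the synthetic three-species dataset
#'
#' Defines a fully seeded toy three-species comparative dataset with known
#' ground truth: a shared proteome core with planted species-specific
#' (divergent) genes and expanded inparalog families, repeat families evolved
#' under a CpA-to-TpA-biased mutation process over a background transition
#' rate, genomes with embedded repeat copies and matching interval
#' annotations, and secretion tables consistent with planted
#' signal-peptide-like N-termini.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_core_groups Ortholog groups with one gene per species.
#' @param n_divergent_per_species Planted single-species (divergent) genes.
#' @param n_expanded_per_species Planted expanded groups per species.
#' @param expansion_size Members of the expanded species in each expanded
#'   group (the two other species get one each); must be at least 2.
#' @param n_repeat_families,copies_per_family,family_length_bp Repeat-family
#'   layout.
#' @param rip_rate Per-eligible-site probability of the RIP-like mutation
#'   (CpA's C to T; TpG's G to A), in \[0, 1\].
#' @param bg_rate Per-site background transition probability, in \[0, 1\].
#' @param genome_length_bp,n_scaffolds Genome layout.
#' @param repeat_fraction_target Fraction of the genome to cover with
#'   embedded repeat copies, in \[0, 0.9\].
#' @param motif_plant_rate Probability a protein receives one planted
#'   effector motif, in \[0, 1\].
#' @param secreted_fraction Probability a protein receives a synthetic signal
#'   peptide (and a positive secretion row), in \[0, 1\].
#' @param protein_length_range Length range (aa) of mature protein bodies.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_core_groups = 150L,
                       n_divergent_per_species = 12L,
                       n_expanded_per_species = 10L,
                       expansion_size = 3L,
                       n_repeat_families = 12L,
                       copies_per_family = 8L,
                       family_length_bp = 600L,
                       rip_rate = 0.2,
                       bg_rate = 0.01,
                       genome_length_bp = 200000L,
                       n_scaffolds = 8L,
                       repeat_fraction_target = 0.03,
                       motif_plant_rate = 0.3,
                       secreted_fraction = 0.25,
                       protein_length_range = c(80L, 500L)) {
  cfg <- list(seed = as.integer(seed), n_core_groups = n_core_groups,
              n_divergent_per_species = n_divergent_per_species,
              n_expanded_per_species = n_expanded_per_species,
              expansion_size = expansion_size,
              n_repeat_families = n_repeat_families,
              copies_per_family = copies_per_family,
              family_length_bp = family_length_bp,
              rip_rate = rip_rate, bg_rate = bg_rate,
              genome_length_bp = genome_length_bp, n_scaffolds = n_scaffolds,
              repeat_fraction_target = repeat_fraction_target,
              motif_plant_rate = motif_plant_rate,
              secreted_fraction = secreted_fraction,
              protein_length_range = protein_length_range)
  probs <- c(cfg$rip_rate, cfg$bg_rate, cfg$motif_plant_rate, cfg$secreted_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$repeat_fraction_target > 0.9) {
    stop("repeat_fraction_target > 0.9 is unrealistic packing")
  }
  if (cfg$expansion_size < 2L) stop("expansion_size must be >= 2")
  lens <- c(cfg$n_core_groups, cfg$family_length_bp, cfg$genome_length_bp,
            cfg$n_scaffolds, cfg$copies_per_family)
  if (any(lens <= 0)) stop("counts and lengths must be positive")
  structure(cfg, class = "sim_config")
}

# Independent deterministic RNG stream per generator stage, derived from the
# master seed. Kept below 2^31 - 1.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

SIM_SPECIES <- c("sp1", "sp2", "sp3")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate one repeat family under RIP-biased mutation
#'
#' Draws a uniform-random ancestor, then derives each copy by (i) mutating,
#' with probability `rip_rate` per eligible site, every CpA's C to T and every
#' TpG's G to A (eligibility read from the ancestor), then (ii) applying a
#' background transition (A/G, C/T) independently at every site with
#' probability `bg_rate`. No indels are introduced, so the copies form a
#' column-wise trivial alignment.
#'
#' @param cfg A [sim_config()].
#' @param family_index 1-based family number (also selects the RNG stream).
#' @return List with `family_id`, `ancestor` (string), `alignment` (a
#'   `repeat_alignment`), and `truth`: per-copy lists of RIP-mutated and
#'   background-mutated site indices plus total counts.
#' @export
generate_repeat_family <- function(cfg, family_index = 1L) {
  set.seed(stream_seed(cfg$seed, 1000L + family_index))
  L <- cfg$family_length_bp
  anc <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
  cpa_sites <- which(anc == "C" & c(anc[-1], "") == "A")
  tpg_sites <- which(anc == "G" & c("", anc[-L]) == "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  rip_sites <- vector("list", cfg$copies_per_family)
  bg_sites <- vector("list", cfg$copies_per_family)
  seqs <- character(cfg$copies_per_family)
  for (i in seq_len(cfg$copies_per_family)) {
    x <- anc
    hit_c <- cpa_sites[runif(length(cpa_sites)) < cfg$rip_rate]
    hit_g <- tpg_sites[runif(length(tpg_sites)) < cfg$rip_rate]
    x[hit_c] <- "T"
    x[hit_g] <- "A"
    bg <- which(runif(L) < cfg$bg_rate)
    x[bg] <- transition[x[bg]]
    rip_sites[[i]] <- sort(c(hit_c, hit_g))
    bg_sites[[i]] <- bg
    seqs[i] <- paste(x, collapse = "")
  }
  fam_id <- sprintf("fam%02d", family_index)
  list(
    family_id = fam_id,
    ancestor = paste(anc, collapse = ""),
    alignment = new_alignment(sprintf("%s_copy%02d", fam_id,
                                      seq_len(cfg$copies_per_family)),
                              seqs, family_id = fam_id),
    truth = list(rip_sites = rip_sites, bg_sites = bg_sites,
                 n_rip = sum(lengths(rip_sites)), n_bg = sum(lengths(bg_sites)))
  )
}

# Synthetic signal peptide: M + 2 charged + 10 hydrophobic + A-x-A cleavage
# site (x drawn from small polar residues so the prefix cannot complete an
# effector motif). Cleavage after residue 16.
SIGNAL_PEPTIDE_LEN <- 16L
random_signal_peptide <- function() {
  paste(c("M", sample(c("K", "R"), 2L, replace = TRUE),
          sample(c("A", "L", "I", "V", "F"), 10L, replace = TRUE),
          "A", sample(c("S", "T", "N", "Q", "G", "E", "D"), 1L), "A"),
        collapse = "")
}

random_protein <- function(range) {
  n <- sample(seq(range[1], range[2]), 1L)
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# Realize one concrete instance of a motif pattern: one member per position.
motif_instance <- function(mp) {
  chars <- strsplit(mp$regex, "", fixed = TRUE)[[1]]
  out <- character()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1L]
      out <- c(out, sample(chars[seq(i + 1L, close - 1L)], 1L))
      i <- close + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# Re-draw the first residue of any motif match outside the protected window
# until the sequence carries no unplanned motif matches.
scrub_motifs <- function(seq, motifs, protect_start = 0L, protect_end = 0L) {
  safe <- c("P", "G", "S", "T", "N", "Q", "D", "E")
  for (iter in seq_len(100L)) {
    changed <- FALSE
    for (mp in motifs) {
      pos <- gregexpr(paste0("(?=", mp$regex, ")"), seq, perl = TRUE)[[1]]
      if (pos[1L] == -1L) next
      for (p in as.integer(pos)) {
        if (p <= protect_end && (p + mp$length - 1L) >= protect_start) next
        substr(seq, p, p) <- sample(safe, 1L)
        changed <- TRUE
      }
    }
    if (!changed) return(seq)
  }
  seq
}

#' Simulate three proteomes with planted orthology and effector structure
#'
#' Core groups carry one gene per species; divergent genes appear in exactly
#' one species; expanded groups carry `expansion_size` inparalogs in one
#' species and one gene in each other. A fraction of proteins receive a
#' synthetic signal-peptide N-terminus with a matching positive secretion row;
#' effector motifs from the default registry are planted downstream of
#' residue 30 at rate `motif_plant_rate`. Background sequence is scrubbed of
#' chance motif matches, so the planted motif set is exactly the motif-positive
#' set and `secreted AND planted` is exactly the ground-truth candidate set.
#'
#' @param cfg A [sim_config()].
#' @return List with `proteomes` (named list of tibbles), `ortholog_table`,
#'   `secretion` (named list of secretion tibbles), and `truth` (divergent
#'   IDs, expanded group table, per-species candidate-effector ID sets,
#'   planted-motif table).
#' @export
generate_proteomes <- function(cfg) {
  set.seed(stream_seed(cfg$seed, 2L))
  motifs <- default_motifs()
  counter <- setNames(rep(0L, 3L), SIM_SPECIES)
  new_id <- function(sp) {
    counter[[sp]] <<- counter[[sp]] + 1L
    sprintf("%s_g%04d", sp, counter[[sp]])
  }
  genes <- list()   # id -> seq
  gene_sp <- character()
  g1 <- list(); g2 <- list(); g3 <- list()
  add_group <- function(members) {
    # members: named list species -> character vector of ids
    g1[[length(g1) + 1L]] <<- members[["sp1"]] %||% character()
    g2[[length(g2) + 1L]] <<- members[["sp2"]] %||% character()
    g3[[length(g3) + 1L]] <<- members[["sp3"]] %||% character()
  }
  mutate_variant <- function(seq) {
    aa <- strsplit(seq, "", fixed = TRUE)[[1]]
    k <- max(1L, round(length(aa) * 0.02))
    pos <- sample(seq_along(aa), k)
    aa[pos] <- sample(AA_LETTERS, k, replace = TRUE)
    paste(aa, collapse = "")
  }
  add_gene <- function(sp, seq) {
    id <- new_id(sp)
    genes[[id]] <<- seq
    gene_sp[id] <<- sp
    id
  }

  for (g in seq_len(cfg$n_core_groups)) {
    base <- random_protein(cfg$protein_length_range)
    add_group(setNames(lapply(SIM_SPECIES, function(sp)
      add_gene(sp, mutate_variant(base))), SIM_SPECIES))
  }
  expanded_truth <- tibble(group_id = character(), species = character())
  for (sp in SIM_SPECIES) {
    for (g in seq_len(cfg$n_expanded_per_species)) {
      base <- random_protein(cfg$protein_length_range)
      members <- lapply(SIM_SPECIES, function(s) {
        k <- if (s == sp) cfg$expansion_size else 1L
        vapply(seq_len(k), function(.) add_gene(s, mutate_variant(base)), "")
      })
      add_group(setNames(members, SIM_SPECIES))
      expanded_truth <- bind_rows(expanded_truth,
                                  tibble(group_id = sprintf("og%d", length(g1)),
                                         species = sp))
    }
  }
  divergent_truth <- setNames(vector("list", 3L), SIM_SPECIES)
  for (sp in SIM_SPECIES) {
    ids <- vapply(seq_len(cfg$n_divergent_per_species), function(.)
      add_gene(sp, random_protein(cfg$protein_length_range)), "")
    for (id in ids) add_group(setNames(list(id), sp))
    divergent_truth[[sp]] <- ids
  }
  table <- new_ortholog_table(g1, g2, g3, SIM_SPECIES)

  # secretion and motif planting
  ids <- names(genes)
  secreted <- runif(length(ids)) < cfg$secreted_fraction
  plant <- runif(length(ids)) < cfg$motif_plant_rate
  planted <- tibble(protein_id = character(), motif_name = character(),
                    position = integer())
  for (i in seq_along(ids)) {
    s <- genes[[ids[i]]]
    if (secreted[i]) s <- paste0(random_signal_peptide(), s)
    p_start <- 0L; p_end <- 0L
    if (plant[i]) {
      mp <- motifs[[sample(length(motifs), 1L)]]
      lo <- 31L
      hi <- nchar(s) - mp$length + 1L
      if (hi >= lo) {
        p_start <- sample(seq(lo, hi), 1L)
        p_end <- p_start + mp$length - 1L
        substr(s, p_start, p_end) <- motif_instance(mp)
        planted <- bind_rows(planted, tibble(protein_id = ids[i],
                                             motif_name = mp$name,
                                             position = p_start))
      } else {
        plant[i] <- FALSE
      }
    }
    genes[[ids[i]]] <- scrub_motifs(s, motifs, p_start, p_end)
  }

  proteomes <- lapply(SIM_SPECIES, function(sp) {
    sel <- ids[gene_sp[ids] == sp]
    tibble(id = sel, desc = "", seq = unlist(genes[sel], use.names = FALSE))
  })
  names(proteomes) <- SIM_SPECIES
  secretion <- lapply(SIM_SPECIES, function(sp) {
    sel <- gene_sp[ids] == sp
    is_sec <- secreted[sel]
    tibble(id = ids[sel], secreted = is_sec,
           cleavage_pos = ifelse(is_sec, SIGNAL_PEPTIDE_LEN, NA_integer_),
           source = "synthetic")
  })
  names(secretion) <- SIM_SPECIES
  candidates <- lapply(SIM_SPECIES, function(sp)
    ids[gene_sp[ids] == sp & secreted & plant])
  names(candidates) <- SIM_SPECIES

  list(proteomes = proteomes, ortholog_table = table, secretion = secretion,
       truth = list(divergent = divergent_truth, expanded = expanded_truth,
                    candidates = candidates, planted_motifs = planted))
}

#' Simulate a genome with embedded repeat copies
#'
#' Builds random-background scaffolds and embeds repeat-family copies at
#' non-overlapping positions until the target repeat fraction is approximated;
#' the returned interval set matches the embeddings exactly (0-based
#' half-open).
#'
#' @param cfg A [sim_config()].
#' @param families List of families from [generate_repeat_family()].
#' @return List with `assembly` (tibble `id`, `desc`, `seq`) and `repeats`
#'   (interval tibble), plus `embedded_bp`.
#' @export
generate_genome <- function(cfg, families) {
  set.seed(stream_seed(cfg$seed, 3L))
  n <- cfg$n_scaffolds
  w <- runif(n, 0.5, 1.5)
  lens <- pmax(1000L, as.integer(round(cfg$genome_length_bp * w / sum(w))))
  scaf <- vapply(lens, random_dna, "")
  ids <- sprintf("scaffold%02d", seq_len(n))
  intervals <- tibble(scaffold = character(), start = integer(), end = integer())
  target <- cfg$repeat_fraction_target * sum(lens)
  embedded <- 0L
  copies <- unlist(lapply(families, function(f) f$alignment$seq))
  if (length(copies)) {
    k <- 0L
    attempts <- 0L
    while (embedded < target && attempts < 10000L) {
      attempts <- attempts + 1L
      k <- k %% length(copies) + 1L
      cp <- copies[k]
      clen <- nchar(cp)
      si <- sample(n, 1L, prob = lens)
      if (lens[si] < clen + 2L) next
      start0 <- sample.int(lens[si] - clen, 1L) - 1L  # 0-based
      prior <- intervals[intervals$scaffold == ids[si], , drop = FALSE]
      if (nrow(prior) && any(start0 < prior$end & (start0 + clen) > prior$start)) next
      substr(scaf[si], start0 + 1L, start0 + clen) <- cp
      intervals <- bind_rows(intervals, tibble(scaffold = ids[si],
                                               start = start0,
                                               end = start0 + clen))
      embedded <- embedded + clen
    }
  }
  intervals <- arrange(intervals, .data$scaffold, .data$start)
  list(assembly = tibble(id = ids, desc = "", seq = scaf),
       repeats = intervals, embedded_bp = embedded)
}

#' Generate a complete synthetic three-species bundle
#'
#' Combines [generate_repeat_family()], [generate_proteomes()] and
#' [generate_genome()] into one bundle (each species gets its own repeat
#' families and genome), optionally writing all files in their standard
#' on-disk formats plus a ground-truth JSON.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, FASTA/BED/TSV files and
#'   `truth.json` are written there.
#' @return List with per-species entries (`assembly`, `repeats`, `families`,
#'   `proteome`, `secretion`, `mat_present`), the shared `ortholog_table`,
#'   `truth`, and `config`.
#' @export
generate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  prot <- generate_proteomes(cfg)
  # MAT complements mirror the archetypal three-isolate pattern: a full
  # homothallic complement, an incomplete MAT1-1, and MAT1-2 alone.
  mat <- list(sp1 = MAT_GENES,
              sp2 = c("MAT1-1-1", "MAT1-1-3"),
              sp3 = "MAT1-2")
  species <- lapply(seq_along(SIM_SPECIES), function(si) {
    sp <- SIM_SPECIES[si]
    sub <- cfg
    sub$seed <- stream_seed(cfg$seed, 7000L + si)
    fams <- lapply(seq_len(cfg$n_repeat_families), function(k)
      generate_repeat_family(sub, k))
    gen <- generate_genome(sub, fams)
    list(assembly = gen$assembly, repeats = gen$repeats,
         embedded_bp = gen$embedded_bp, families = fams,
         proteome = prot$proteomes[[sp]], secretion = prot$secretion[[sp]],
         mat_present = mat[[sp]])
  })
  names(species) <- SIM_SPECIES
  out <- list(species = species, ortholog_table = prot$ortholog_table,
              truth = prot$truth, config = cfg)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

write_dataset <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(bundle$species)) {
    d <- bundle$species[[sp]]
    write_fasta(d$assembly, file.path(out_dir, paste0(sp, "_assembly.fasta")))
    write_intervals(d$repeats, file.path(out_dir, paste0(sp, "_repeats.bed")))
    write_fasta(d$proteome, file.path(out_dir, paste0(sp, "_proteome.fasta")))
    write_secretion_table(d$secretion,
                          file.path(out_dir, paste0(sp, "_secretion.tsv")))
    adir <- file.path(out_dir, paste0(sp, "_alignments"))
    dir.create(adir, showWarnings = FALSE)
    for (f in d$families) {
      write_alignment(f$alignment, file.path(adir, paste0(f$family_id, ".fasta")))
    }
    writeLines(d$mat_present, file.path(out_dir, paste0(sp, "_mat.txt")))
  }
  write_ortholog_table(bundle$ortholog_table, file.path(out_dir, "orthologs.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(divergent = truth$divergent,
         expanded = truth$expanded,
         candidates = truth$candidates,
         planted_motifs = truth$planted_motifs),
    file.path(out_dir, "truth.json"))
  invisible(out_dir)
}
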