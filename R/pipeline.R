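#' Run the full comparative analysis and build a side-by-side report
#'
#' Orchestrates every analysis stage over a multi-species dataset — assembly
#' statistics, partitioned RIP indices, per-family RIP quantitation against
#' deRIP consensus models, orthology classification, candidate-effector
#' screening and MAT typing — and assembles a wide, one-column-per-species
#' comparative report. Stages whose inputs are missing are skipped with a
#' warning, not a failure.
#'
#' @param config Either a path to a YAML run configuration, a configuration
#'   list of file paths, or an in-memory bundle from [generate_dataset()].
#'   A path configuration holds `species` (a named list; each entry may give
#'   `assembly`, `proteome`, `repeats`, `alignments_dir`, `secretion`,
#'   `mat_present`, `n_genes`), `ortholog_table`, optional `motifs` (YAML
#'   registry), optional `coords`, and optional `thresholds`
#'   (`identity_threshold`, `dominance_threshold`, `max_candidate_length`).
#' @param out_dir Optional output directory for TSV sections and
#'   `report.json`.
#' @return A `metcomp_report`: list of tibbles (`assembly`, `rip_indices`,
#'   `rip_families`, `rip_genome`, `orthology`, `effectors`,
#'   `effector_motifs`, `mat`, `synteny`) plus `skipped`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- normalize_run_config(config)
  th <- cfg$thresholds
  skipped <- character()
  note_skip <- function(stage, sp, why) {
    msg <- paste0(stage, " [", sp, "]: skipped (", why, ")")
    warning(msg, call. = FALSE)
    skipped <<- c(skipped, msg)
  }

  species <- names(cfg$species)
  asm_rows <- list(); rip_idx <- list(); fam_tbl <- list(); rip_gen <- list()
  eff_cand <- list(); eff_motifs <- list(); mat_rows <- list()

  # orthology first: divergent sets feed the effector screen
  ortho <- NULL
  if (!is.null(cfg$ortholog_table)) {
    cls <- classify_groups(cfg$ortholog_table)
    ortho <- species_summary(cls, cfg$ortholog_table)
    divergent_ids <- lapply(ortholog_species(cfg$ortholog_table), function(s)
      unlist(cfg$ortholog_table[[s]][cls$label == paste0("divergent:", s)]))
    names(divergent_ids) <- ortholog_species(cfg$ortholog_table)
  } else {
    note_skip("orthology", "all", "no ortholog table")
    divergent_ids <- list()
  }

  motifs <- if (!is.null(cfg$motifs)) cfg$motifs else default_motifs()

  for (sp in species) {
    d <- cfg$species[[sp]]
    if (!is.null(d$assembly)) {
      n_genes <- d$n_genes %||% (if (!is.null(d$proteome)) nrow(d$proteome) else NULL)
      asm_rows[[sp]] <- mutate(
        assembly_summary(d$assembly, n_genes = n_genes, repeats = d$repeats),
        species = sp)
      if (!is.null(d$repeats)) {
        rip_idx[[sp]] <- mutate(partitioned_rip_indices(d$assembly, d$repeats),
                                species = sp)
      } else note_skip("rip-index", sp, "no repeat intervals")
    } else note_skip("assembly", sp, "no assembly")

    if (length(d$alignments)) {
      fams <- bind_rows(lapply(d$alignments, classify_rip_mutations))
      fam_tbl[[sp]] <- mutate(fams, species = sp)
      rip_gen[[sp]] <- mutate(
        genome_rip_summary(fams, th$dominance_threshold), species = sp)
    } else note_skip("rip-families", sp, "no repeat alignments")

    if (!is.null(d$proteome) && !is.null(d$secretion)) {
      hits <- scan_proteome(d$proteome, motifs)
      pres <- motif_presence(hits, d$proteome, motifs)
      crit <- candidate_criteria(max_length_aa = th$max_candidate_length)
      cand <- classify_candidates(d$proteome, pres, d$secretion,
                                  divergent_ids[[sp]], crit)
      eff_cand[[sp]] <- tibble(species = sp,
                               n_motif_positive = sum(cand$has_motif),
                               n_secreted = sum(cand$secreted),
                               n_candidates = sum(cand$candidate))
      eff_motifs[[sp]] <- mutate(candidate_summary(cand, pres), species = sp)
    } else note_skip("effectors", sp, "no proteome and/or secretion table")

    if (!is.null(d$mat_present)) {
      mat_rows[[sp]] <- mutate(classify_thallism(d$mat_present), species = sp)
    } else note_skip("mat", sp, "no MAT gene complement")
  }

  synteny <- NULL
  if (!is.null(cfg$coords)) {
    synteny <- synteny_identity_summary(cfg$coords, th$identity_threshold)
  }

  report <- structure(list(
    assembly = wide_by_species(bind_rows(asm_rows)),
    rip_indices = if (length(rip_idx)) bind_rows(rip_idx) else NULL,
    rip_families = if (length(fam_tbl)) bind_rows(fam_tbl) else NULL,
    rip_genome = if (length(rip_gen)) bind_rows(rip_gen) else NULL,
    orthology = ortho,
    effectors = if (length(eff_cand)) bind_rows(eff_cand) else NULL,
    effector_motifs = if (length(eff_motifs)) bind_rows(eff_motifs) else NULL,
    mat = if (length(mat_rows)) bind_rows(mat_rows) else NULL,
    synteny = synteny,
    skipped = skipped
  ), class = "metcomp_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# One row per metric, one column per species (comparative-table layout).
wide_by_species <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(NULL)
  long <- tidyr::pivot_longer(x, -"species", names_to = "feature",
                              values_to = "value")
  tidyr::pivot_wider(long, names_from = "species", values_from = "value")
}

normalize_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$species)) {
    stop("run config must be a list with a 'species' entry")
  }
  th <- config$thresholds %||% list()
  th$identity_threshold <- th$identity_threshold %||% 95
  th$dominance_threshold <- th$dominance_threshold %||% 1
  out <- list(thresholds = th)
  out$species <- lapply(config$species, function(d) {
    e <- list()
    e$assembly <- load_input(d$assembly, function(p) read_fasta(p, "nucleotide"))
    e$proteome <- load_input(d$proteome, function(p) read_fasta(p, "protein"))
    e$repeats <- load_input(d$repeats, read_intervals)
    e$secretion <- load_input(d$secretion, read_secretion_table)
    e$n_genes <- d$n_genes
    e$mat_present <- if (is.character(d$mat_present) && length(d$mat_present) == 1L &&
                         file.exists(d$mat_present)) readLines(d$mat_present)
      else d$mat_present
    e$alignments <- if (!is.null(d$alignments_dir)) {
      files <- sort(list.files(d$alignments_dir, pattern = "\\.(fa|fasta|aln)$",
                               full.names = TRUE))
      lapply(files, read_alignment)
    } else if (!is.null(d$families)) {
      lapply(d$families, function(f) f$alignment)  # in-memory bundle
    } else list()
    e
  })
  out$ortholog_table <- load_input(config$ortholog_table, read_ortholog_table)
  out$coords <- load_input(config$coords, read_coords)
  out$motifs <- if (is.character(config$motifs)) read_motif_registry(config$motifs)
    else config$motifs
  out
}

load_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("configured input not found: ", x)
    return(reader(x))
  }
  x
}

#' @export
print.metcomp_report <- function(x, ...) {
  cat("== comparative genome report ==\n")
  for (sec in c("assembly", "rip_genome", "orthology", "effectors", "mat")) {
    if (is.null(x[[sec]])) next
    cat("\n--", sec, "--\n")
    print(as.data.frame(x[[sec]]), digits = 4)
  }
  if (length(x$skipped)) cat("\nskipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flatten <- function(x) {
    for (cn in names(x)) {
      if (is.list(x[[cn]])) x[[cn]] <- vapply(x[[cn]], paste, "", collapse = ",")
    }
    x
  }
  for (sec in setdiff(names(report), "skipped")) {
    if (is.null(report[[sec]])) next
    readr::write_tsv(flatten(report[[sec]]), file.path(out_dir, paste0(sec, ".tsv")))
  }
  json <- lapply(report[setdiff(names(report), "skipped")], function(x)
    if (is.null(x)) NULL else as.data.frame(flatten(x)))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
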