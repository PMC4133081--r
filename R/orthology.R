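#' Classify three-species ortholog groups
#'
#' Labels every ortholog group by its per-species member counts:
#' \itemize{
#'   \item `divergent:<species>` — members in exactly one species (of any
#'     number); these genes have no orthologs in either comparator and are
#'     species-specific ("unique-by-orthology").
#'   \item `expanded:<species>` — present in all three species with strictly
#'     more members in one species than in each of the other two.
#'   \item `shared` — present in all three species with no strict single
#'     maximum.
#'   \item `ambiguous` — anything else (in practice, groups confined to
#'     exactly two species).
#' }
#'
#' @param table An `ortholog_table` tibble (see [read_ortholog_table()]).
#' @return Tibble with `group_id`, one `n_<species>` count column per species,
#'   and `label`.
#' @export
classify_groups <- function(table) {
  species <- ortholog_species(table)
  counts <- vapply(species, function(s) lengths(table[[s]]), integer(nrow(table)))
  counts <- matrix(counts, ncol = 3L, dimnames = list(NULL, species))
  label <- apply(counts, 1L, function(k) {
    pres <- sum(k > 0L)
    if (pres == 1L) return(paste0("divergent:", species[which(k > 0L)]))
    if (pres == 3L) {
      mx <- which(k == max(k))
      if (length(mx) == 1L) return(paste0("expanded:", species[mx]))
      return("shared")
    }
    "ambiguous"
  })
  out <- tibble(group_id = table$group_id)
  for (s in species) out[[paste0("n_", s)]] <- counts[, s]
  out$label <- label
  out
}

ortholog_species <- function(table) {
  species <- attr(table, "species")
  if (is.null(species)) species <- setdiff(names(table), "group_id")
  if (length(species) != 3L) stop("ortholog table must carry exactly 3 species")
  species
}

#' Per-species orthology summary
#'
#' Counts, for each species, the proteins in its divergent groups (proteins,
#' not groups), its expanded groups, and the expanded species' members of
#' those groups.
#'
#' @param classifications Output of [classify_groups()].
#' @param table The `ortholog_table` the classifications came from.
#' @return Tibble with one row per species: `species`,
#'   `n_divergent_proteins`, `n_divergent_groups`, `n_expanded_groups`,
#'   `n_expanded_proteins`.
#' @export
species_summary <- function(classifications, table) {
  species <- ortholog_species(table)
  stopifnot(identical(classifications$group_id, table$group_id))
  purrr::map_dfr(species, function(s) {
    div <- classifications$label == paste0("divergent:", s)
    exp <- classifications$label == paste0("expanded:", s)
    tibble(
      species = s,
      n_divergent_proteins = sum(lengths(table[[s]])[div]),
      n_divergent_groups = sum(div),
      n_expanded_groups = sum(exp),
      n_expanded_proteins = sum(lengths(table[[s]])[exp])
    )
  })
}

#' Add singleton groups for proteins absent from an ortholog table
#'
#' Ortholog inference output may omit proteins with no hits at all; given a
#' full per-species roster of protein IDs, every roster protein absent from
#' the table becomes a one-member (divergent) group.
#'
#' @param table An `ortholog_table` tibble.
#' @param rosters Named list (one entry per species) of character vectors of
#'   protein IDs.
#' @return The augmented `ortholog_table`.
#' @export
add_singleton_groups <- function(table, rosters) {
  species <- ortholog_species(table)
  if (!all(names(rosters) %in% species)) {
    stop("roster names must match the table's species: ",
         paste(species, collapse = ", "))
  }
  g <- lapply(species, function(s) table[[s]])
  names(g) <- species
  for (s in names(rosters)) {
    missing <- setdiff(rosters[[s]], unlist(g[[s]]))
    for (m in missing) {
      for (sp in species) {
        g[[sp]] <- c(g[[sp]], list(if (sp == s) m else character()))
      }
    }
  }
  new_ortholog_table(g[[species[1]]], g[[species[2]]], g[[species[3]]], species)
}
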