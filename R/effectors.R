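#' Compile an effector-motif pattern
#'
#' Parses a short amino-acid motif written with fixed residues, bracketed
#' residue classes and `X` for any residue (e.g. `"[YFW]XC"`, `"RXLR"`) into a
#' matcher over uppercase protein sequences. `X` in the pattern matches any of
#' the 20 standard residues; the ambiguity letter X in a sequence never
#' matches. Class members are canonicalized by sorting, so `"[YFW]XC"` and
#' `"[YWF]XC"` compile to the same pattern.
#'
#' @param spec Motif string.
#' @param name Motif name; defaults to the canonicalized spec.
#' @return A `motif_pattern` object (list with `name`, `spec`, `regex`,
#'   `length`).
#' @examples
#' compile_motif("[YFW]XC")
#' @export
compile_motif <- function(spec, name = NULL) {
  chars <- strsplit(spec, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(close)) stop("unclosed bracket in motif '", spec, "'")
      if (close == i + 1L) stop("empty residue class in motif '", spec, "'")
      members <- chars[(i + 1L):(close - 1L)]
      if (!all(members %in% AA_LETTERS)) {
        stop("illegal residue '", setdiff(members, AA_LETTERS)[1L],
             "' in motif '", spec, "'")
      }
      elements <- c(elements, list(sort(unique(members))))
      i <- close + 1L
    } else if (ch == "X") {
      elements <- c(elements, list(AA_LETTERS))
      i <- i + 1L
    } else {
      if (!ch %in% AA_LETTERS) stop("illegal residue '", ch, "' in motif '", spec, "'")
      elements <- c(elements, list(ch))
      i <- i + 1L
    }
  }
  if (length(elements) < 2L) stop("motif '", spec, "' needs at least 2 positions")
  canon <- vapply(elements, function(e) {
    if (length(e) == 20L) "X"
    else if (length(e) == 1L) e
    else paste0("[", paste(e, collapse = ""), "]")
  }, "")
  regex <- vapply(elements, function(e) {
    if (length(e) == 1L) e else paste0("[", paste(e, collapse = ""), "]")
  }, "")
  structure(list(name = name %||% paste(canon, collapse = ""),
                 spec = spec,
                 regex = paste(regex, collapse = ""),
                 length = length(elements)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif", x$name, "(", x$length, "positions )\n")
  invisible(x)
}

#' Default effector-motif registry
#'
#' The six fungal/oomycete pathogenicity-associated motifs reported among
#' candidate secreted effectors: `[YFW]XC`, `[LI]XAR`, `RXLR`, `CHXC`,
#' `KECXD` and `YXSL[RK]`. Larger registries can be loaded from YAML with
#' [read_motif_registry()].
#'
#' @return List of `motif_pattern` objects.
#' @export
default_motifs <- function() {
  specs <- c("[YFW]XC", "[LI]XAR", "RXLR", "CHXC", "KECXD", "YXSL[RK]")
  lapply(specs, compile_motif)
}

#' Read a motif registry from YAML
#'
#' The file maps motif names to pattern strings, e.g. `"[YFW]XC": "[YFW]XC"`.
#'
#' @param path Path to a YAML file.
#' @return List of `motif_pattern` objects.
#' @export
read_motif_registry <- function(path) {
  reg <- yaml::read_yaml(path)
  if (length(reg) == 0L) stop("empty motif registry: ", path)
  purrr::imap(reg, function(spec, name) compile_motif(spec, name = name))
}

#' Scan a proteome for motif matches
#'
#' Reports every (possibly overlapping) match start position of each motif in
#' each protein.
#'
#' @param proteins Tibble with columns `id`, `seq` (protein sequences).
#' @param motifs List of `motif_pattern` objects (default [default_motifs()]).
#' @return Tibble of hits: `protein_id`, `motif_name`, `position` (1-based).
#' @export
scan_proteome <- function(proteins, motifs = default_motifs()) {
  empty <- tibble(protein_id = character(), motif_name = character(),
                  position = integer())
  if (length(motifs) == 0L) return(empty)
  bind_rows(empty, purrr::map_dfr(motifs, function(mp) {
    look <- paste0("(?=", mp$regex, ")")  # lookahead so overlaps are reported
    hits <- gregexpr(look, proteins$seq, perl = TRUE)
    purrr::map_dfr(seq_along(hits), function(i) {
      pos <- hits[[i]]
      if (pos[1L] == -1L) return(NULL)
      tibble(protein_id = proteins$id[i], motif_name = mp$name,
             position = as.integer(pos))
    })
  }))
}

#' Per-protein motif presence matrix
#'
#' Collapses motif hits to one logical per protein and motif, covering every
#' scanned protein (including those with no hits).
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @param proteins The scanned proteome tibble.
#' @param motifs The motif list used for the scan.
#' @return Tibble with `protein_id`, one logical column per motif, and
#'   `any_motif`.
#' @export
motif_presence <- function(hits, proteins, motifs = default_motifs()) {
  out <- tibble(protein_id = proteins$id)
  for (mp in motifs) {
    out[[mp$name]] <- out$protein_id %in% hits$protein_id[hits$motif_name == mp$name]
  }
  out$any_motif <- out$protein_id %in% hits$protein_id
  out
}

# Average residue masses (Da); protein mass adds one water (18.0153 Da).
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153
X_AVG_MASS <- mean(AA_MASS)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, reported to two decimals.
#'
#' @param seq Character vector of protein sequences.
#' @param on_x How to treat the ambiguity residue X: `"error"` (default) or
#'   `"average"` (use the mean residue mass).
#' @return Molecular weight(s) in Daltons.
#' @examples
#' protein_mw("G")   # 75.07
#' @export
protein_mw <- function(seq, on_x = c("error", "average")) {
  on_x <- match.arg(on_x)
  vapply(seq, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    unknown <- setdiff(aa, c(names(AA_MASS), "X"))
    if (length(unknown)) stop("unknown residue '", unknown[1L], "'")
    nx <- sum(aa == "X")
    if (nx > 0L && on_x == "error") stop("ambiguous residue X in sequence")
    round(sum(AA_MASS[aa[aa != "X"]]) + nx * X_AVG_MASS + WATER_MASS, 2)
  }, numeric(1), USE.NAMES = FALSE)
}

# EMBOSS IEP pKa set
PKA <- list(nterm = 8.6, cterm = 3.6,
            positive = c(K = 10.8, R = 12.5, H = 6.5),
            negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

protein_net_charge <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - PKA$nterm)) +
    sum(counts[names(PKA$positive)] / (1 + 10^(pH - PKA$positive)))
  neg <- 1 / (1 + 10^(PKA$cterm - pH)) +
    sum(counts[names(PKA$negative)] / (1 + 10^(PKA$negative - pH)))
  pos - neg
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge (free N- and C-termini
#' plus D, E, C, Y, H, K, R side chains, EMBOSS pKa set) crosses zero, found
#' by bisection on \[0, 14\] to a tolerance of 0.01. Net charge is strictly
#' decreasing in pH, so the root is unique.
#'
#' @param seq Character vector of protein sequences (X is ignored: it carries
#'   no charge).
#' @param tol Bisection tolerance in pH units (default 0.01).
#' @return Isoelectric point(s) in pH units, to two decimals.
#' @export
protein_pi <- function(seq, tol = 0.01) {
  vapply(seq, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    unknown <- setdiff(aa, c(names(AA_MASS), "X"))
    if (length(unknown)) stop("unknown residue '", unknown[1L], "'")
    counts <- vapply(c(names(PKA$positive), names(PKA$negative)),
                     function(a) sum(aa == a), numeric(1))
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (protein_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
    }
    round((lo + hi) / 2, 2)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Candidate-effector selection criteria
#'
#' @param require_secreted Require a positive secretion prediction (default
#'   TRUE).
#' @param require_motif Require at least one effector-motif match (default
#'   TRUE).
#' @param max_length_aa Optional maximum precursor length in amino acids
#'   (e.g. 300 for the divergent-effector screen); proteins strictly longer
#'   are excluded. Default NULL (no cap).
#' @param require_divergent Require membership in the divergent
#'   (species-specific) gene set (default FALSE).
#' @return A `candidate_criteria` list.
#' @export
candidate_criteria <- function(require_secreted = TRUE, require_motif = TRUE,
                               max_length_aa = NULL, require_divergent = FALSE) {
  out <- list(require_secreted = require_secreted, require_motif = require_motif,
              max_length_aa = max_length_aa, require_divergent = require_divergent)
  if (!require_secreted && !require_motif && is.null(max_length_aa) &&
      !require_divergent) {
    stop("at least one criterion must be active")
  }
  structure(out, class = "candidate_criteria")
}

#' Classify candidate secreted effectors
#'
#' Joins a proteome to its motif-presence matrix, secretion predictions and
#' (optionally) divergent-gene membership, and flags proteins passing every
#' active criterion as candidates. Proteins with no secretion row are treated
#' as not secreted (a message reports how many).
#'
#' @param proteins Proteome tibble (`id`, `seq`).
#' @param presence Motif-presence tibble from [motif_presence()].
#' @param secretion Secretion tibble from [read_secretion_table()].
#' @param divergent_ids Optional character vector of divergent protein IDs.
#' @param criteria A [candidate_criteria()] list.
#' @return Tibble with one row per protein: `id`, `length_aa`, `secreted`,
#'   `has_motif`, `divergent`, per-criterion pass columns and `candidate`.
#' @export
classify_candidates <- function(proteins, presence, secretion,
                                divergent_ids = NULL,
                                criteria = candidate_criteria()) {
  out <- tibble(id = proteins$id, length_aa = nchar(proteins$seq))
  sec <- setNames(secretion$secreted, secretion$id)
  missing <- setdiff(out$id, secretion$id)
  if (criteria$require_secreted && length(missing)) {
    message(length(missing), " protein(s) missing from the secretion table; ",
            "treated as not secreted")
  }
  out$secreted <- !is.na(sec[out$id]) & sec[out$id]
  pres <- setNames(presence$any_motif, presence$protein_id)
  out$has_motif <- !is.na(pres[out$id]) & pres[out$id]
  out$divergent <- out$id %in% (divergent_ids %||% character())
  out$pass_secreted <- !criteria$require_secreted | out$secreted
  out$pass_motif <- !criteria$require_motif | out$has_motif
  out$pass_length <- if (is.null(criteria$max_length_aa)) TRUE else
    out$length_aa <= criteria$max_length_aa
  out$pass_divergent <- !criteria$require_divergent | out$divergent
  out$candidate <- out$pass_secreted & out$pass_motif & out$pass_length &
    out$pass_divergent
  out
}

#' Per-motif counts among candidate effectors
#'
#' A candidate matching k motifs contributes to k motif rows, so the counts
#' sum to at least the number of candidates.
#'
#' @param candidates Output of [classify_candidates()].
#' @param presence Motif-presence tibble from [motif_presence()].
#' @return Tibble `motif_name`, `n_candidates`, sorted descending.
#' @export
candidate_summary <- function(candidates, presence) {
  ids <- candidates$id[candidates$candidate]
  motif_cols <- setdiff(names(presence), c("protein_id", "any_motif"))
  sub <- presence[presence$protein_id %in% ids, , drop = FALSE]
  out <- tibble(
    motif_name = motif_cols,
    n_candidates = vapply(motif_cols, function(m) sum(sub[[m]]), integer(1),
                          USE.NAMES = FALSE)
  )
  out <- out[out$n_candidates > 0L, , drop = FALSE]
  arrange(out, desc(.data$n_candidates), .data$motif_name)
}
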