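#' Read sequences from a FASTA file
#'
#' Reads nucleotide or protein FASTA into a tibble, validating identifiers and
#' alphabet. Sequences are uppercased on read; soft-masking case is not
#' retained (masking is carried by interval sets, not letter case).
#'
#' @param path Path to a FASTA file.
#' @param mode `"nucleotide"` (alphabet A,C,G,T,N) or `"protein"` (the 20
#'   amino acids plus X).
#' @param on_illegal What to do with a letter outside the alphabet:
#'   `"error"` (default; reports the sequence and offset) or `"mask"`
#'   (replace with N or X).
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a scaffold", "ACGT"), tf)
#' read_fasta(tf, "nucleotide")
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein"),
                       on_illegal = c("error", "mask")) {
  mode <- match.arg(mode)
  on_illegal <- match.arg(on_illegal)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- toupper(as.character(set))
  if (any(!nzchar(seq))) stop("empty sequence(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  alph <- if (mode == "nucleotide") NT_LETTERS else AA_LETTERS_X
  seq <- validate_alphabet(seq, id, alph, on_illegal,
                           mask_char = if (mode == "nucleotide") "N" else "X")
  tibble(id = id, desc = desc, seq = unname(seq))
}


# Validate (or mask) letters outside `alph`; errors name sequence and offset.
validate_alphabet <- function(seq, id, alph, on_illegal, mask_char) {
  bad_rx <- paste0("[^", paste(alph, collapse = ""), "]")
  hit <- regexpr(bad_rx, seq)
  if (any(hit > 0L)) {
    if (on_illegal == "error") {
      i <- which(hit > 0L)[1L]
      stop("illegal character '", substr(seq[i], hit[i], hit[i]),
           "' in sequence '", id[i], "' at offset ", hit[i])
    }
    seq <- gsub(bad_rx, mask_char, seq)
  }
  seq
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  hdr <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a repeat-family multiple alignment
#'
#' Reads an aligned multi-FASTA (gap character `-`) into an alignment tibble.
#' All rows must be the same length and there must be at least two rows; each
#' row must contain at least one non-gap character.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param family_id Family label; defaults to the file name without extension.
#' @return A tibble of class `repeat_alignment` with columns `id`, `seq`, and
#'   attribute `family_id`.
#' @export
read_alignment <- function(path, family_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  id <- sub("\\s.*$", "", names(set))
  seq <- toupper(as.character(set))
  new_alignment(id, unname(seq),
                family_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a repeat-family alignment from sequences in memory
#'
#' @param id Character vector of row identifiers.
#' @param seq Equal-length gapped sequences over A,C,G,T,N,-.
#' @param family_id Family label.
#' @return A `repeat_alignment` tibble.
#' @export
new_alignment <- function(id, seq, family_id = "family") {
  if (length(seq) < 2L) stop("alignment needs >= 2 rows (got ", length(seq), ")")
  if (anyDuplicated(id)) stop("duplicate row id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  len <- nchar(seq)
  if (length(unique(len)) != 1L) {
    modal <- as.integer(names(sort(table(len), decreasing = TRUE))[1L])
    ragged <- id[len != modal]
    if (length(ragged) == 0L) ragged <- id
    stop("ragged alignment rows: ", paste(ragged, collapse = ", "))
  }
  seq <- validate_alphabet(seq, id, c(NT_LETTERS, "-"), "error", "N")
  if (any(!grepl("[ACGTN]", seq))) {
    stop("row(s) with no non-gap characters: ",
         paste(id[!grepl("[ACGTN]", seq)], collapse = ", "))
  }
  out <- tibble(id = id, seq = seq)
  attr(out, "family_id") <- family_id
  class(out) <- c("repeat_alignment", class(out))
  out
}

#' Write an alignment to aligned multi-FASTA
#' @param aln A `repeat_alignment` tibble.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) write_fasta(aln, path)

#' Read BED-like repeat intervals
#'
#' Three or more tab-separated columns: scaffold, start, end, with 0-based
#' half-open coordinates. Overlapping intervals are retained as given; the
#' union is taken where coverage arithmetic needs it. A strand column, if
#' present, is ignored.
#'
#' @param path Path to a BED-like TSV (no header).
#' @return A tibble with columns `scaffold`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(scaffold = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) stop("line ", which(ncols < 3L)[1L], ": fewer than 3 columns")
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("line ", which(is.na(start) | is.na(end))[1L], ": non-integer coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) stop("line ", bad[1L], ": start >= end (empty interval)")
  if (any(start < 0L)) stop("negative start coordinate")
  tibble(scaffold = vapply(parts, `[[`, "", 1L), start = start, end = end)
}

#' Write intervals as BED-like TSV
#' @param x Tibble with `scaffold`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  utils::write.table(x[, c("scaffold", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert between 0-based half-open and 1-based inclusive coordinates
#'
#' BED-like interval sets are 0-based half-open; alignment-coordinate tables
#' are 1-based inclusive. These helpers convert a start/end pair between the
#' two conventions.
#'
#' @param start,end Coordinates in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
bed_to_onebased <- function(start, end) list(start = start + 1L, end = end)

#' @rdname bed_to_onebased
#' @export
onebased_to_bed <- function(start, end) list(start = start - 1L, end = end)

#' Read a three-species ortholog group table
#'
#' Reads a ProteinOrtho-style wide table: a header naming exactly three
#' species columns (any leading `# Species`, `Genes`, `Alg.-Conn.` bookkeeping
#' columns are dropped), then one row per ortholog group holding
#' comma-separated gene lists, with `*` or an empty cell for absence.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `ortholog_table` with columns `group_id` and one
#'   list-column of gene IDs per species; attribute `species` holds the three
#'   species names.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "")
  drop <- tolower(names(raw)) %in% c("# species", "#species", "species", "genes", "alg.-conn.")
  raw <- raw[, !drop, drop = FALSE]
  if (ncol(raw) != 3L) {
    stop("expected exactly 3 species columns, found ", ncol(raw), ": ",
         paste(names(raw), collapse = ", "))
  }
  species <- names(raw)
  members <- lapply(raw, function(col) {
    lapply(col, function(cell) {
      if (is.na(cell) || cell %in% c("", "*")) character() else
        trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
  })
  n_tot <- Reduce(`+`, lapply(members, lengths))
  if (any(n_tot == 0L)) stop("empty group(s) at row(s): ",
                             paste(which(n_tot == 0L), collapse = ", "))
  new_ortholog_table(members[[1]], members[[2]], members[[3]], species)
}

#' Construct an ortholog group table from in-memory gene lists
#'
#' @param g1,g2,g3 Lists of character vectors: per-group gene IDs for each
#'   species (empty vector for absence).
#' @param species Three species labels.
#' @return An `ortholog_table` tibble.
#' @export
new_ortholog_table <- function(g1, g2, g3, species = c("sp1", "sp2", "sp3")) {
  stopifnot(length(species) == 3L, length(g1) == length(g2), length(g2) == length(g3))
  all_ids <- c(unlist(g1), unlist(g2), unlist(g3))
  if (anyDuplicated(all_ids)) {
    stop("gene(s) listed in more than one group: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  out <- tibble(group_id = paste0("og", seq_along(g1)))
  out[[species[1]]] <- g1
  out[[species[2]]] <- g2
  out[[species[3]]] <- g3
  attr(out, "species") <- species
  class(out) <- c("ortholog_table", class(out))
  out
}

#' Write an ortholog group table as ProteinOrtho-style TSV
#' @param table An `ortholog_table` tibble.
#' @param path Output path.
#' @export
write_ortholog_table <- function(table, path) {
  species <- attr(table, "species")
  cells <- vapply(species, function(s) {
    vapply(table[[s]], function(g) if (length(g) == 0L) "*" else
      paste(g, collapse = ","), "")
  }, character(nrow(table)))
  cells <- matrix(cells, ncol = 3L)
  writeLines(c(paste(species, collapse = "\t"),
               apply(cells, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a secretion-prediction table
#'
#' Simplified SignalP-short-style TSV with columns: protein id, secreted flag
#' (Y/N or 1/0), optional 1-based cleavage position. A header line beginning
#' with `id` is tolerated.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `id`, `secreted` (logical), `cleavage_pos`
#'   (integer, NA when absent), `source`.
#' @export
read_secretion_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^id\\t", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  if (length(lines) == 0L) {
    return(tibble(id = character(), secreted = logical(),
                  cleavage_pos = integer(), source = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  id <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(id)) stop("duplicate secretion row(s) for: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  flag <- toupper(vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", ""))
  ok <- flag %in% c("Y", "N", "1", "0")
  if (!all(ok)) stop("unparsable secreted flag '", flag[!ok][1L],
                     "' for protein '", id[!ok][1L], "'")
  cleave <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  cleave[cleave == ""] <- NA_character_
  cpos <- suppressWarnings(as.integer(cleave))
  if (any(!is.na(cleave) & is.na(cpos))) stop("non-integer cleavage position")
  src <- vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "", "")
  tibble(id = id, secreted = flag %in% c("Y", "1"),
         cleavage_pos = cpos, source = src)
}

#' Write a secretion table
#' @param x Tibble as returned by [read_secretion_table()].
#' @param path Output path.
#' @export
write_secretion_table <- function(x, path) {
  out <- data.frame(id = x$id, secreted = ifelse(x$secreted, "Y", "N"),
                    cleavage_pos = ifelse(is.na(x$cleavage_pos), "", x$cleavage_pos),
                    source = if ("source" %in% names(x)) x$source else "")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read whole-genome alignment coordinates
#'
#' Parses a `show-coords -T`-style tab-separated table with columns:
#' ref_start, ref_end, qry_start, qry_end, ref_length, qry_length,
#' percent identity, ref id, qry id (1-based inclusive coordinates).
#'
#' @param path Path to the TSV.
#' @return A tibble of alignment matches with `pct_identity` in \[0, 100\].
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  # skip any header/ruler lines that do not start with an integer
  lines <- lines[grepl("^-?[0-9]+\t", lines)]
  if (length(lines) == 0L) {
    return(tibble(ref_id = character(), qry_id = character(),
                  ref_start = integer(), ref_end = integer(),
                  qry_start = integer(), qry_end = integer(),
                  length = integer(), pct_identity = double()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9L)) stop("coords line with fewer than 9 columns")
  num <- function(k) as.numeric(vapply(parts, `[[`, "", k))
  pid <- num(7L)
  if (any(is.na(pid) | pid < 0 | pid > 100)) {
    stop("percent identity outside [0,100]: ", pid[which(is.na(pid) | pid < 0 | pid > 100)[1L]])
  }
  len <- as.integer(num(5L))
  if (any(len <= 0L)) stop("non-positive match length")
  tibble(ref_id = vapply(parts, `[[`, "", 8L),
         qry_id = vapply(parts, `[[`, "", 9L),
         ref_start = as.integer(num(1L)), ref_end = as.integer(num(2L)),
         qry_start = as.integer(num(3L)), qry_end = as.integer(num(4L)),
         length = len, pct_identity = pid)
}
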