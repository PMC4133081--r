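MAT11_GENES <- c("MAT1-1-1", "MAT1-1-2", "MAT1-1-3")
MAT_GENES <- c(MAT11_GENES, "MAT1-2")

#' Classify mating-type composition (thallism) from MAT gene presence
#'
#' The MAT1-1 idiomorph (alpha-box) is represented by any of MAT1-1-1,
#' MAT1-1-2, MAT1-1-3; the MAT1-2 idiomorph by its single HMG-box gene. An
#' isolate carrying both idiomorphs is putatively homothallic (self-fertile);
#' one idiomorph gives the corresponding putative heterothallic label; an
#' empty complement is indeterminate. The MAT1-1 idiomorph is complete only
#' when all three MAT1-1 genes are present.
#'
#' @param present Character vector: subset of `MAT1-1-1`, `MAT1-1-2`,
#'   `MAT1-1-3`, `MAT1-2`.
#' @return One-row tibble: `thallism` (one of `putative_homothallic`,
#'   `putative_heterothallic_MAT1-1`, `putative_heterothallic_MAT1-2`,
#'   `indeterminate`), `mat1_1_present`, `mat1_2_present`,
#'   `idiomorph_complete`, and a `missing` list-column of absent MAT1-1 genes
#'   when that idiomorph is present.
#' @examples
#' classify_thallism(c("MAT1-1-1", "MAT1-1-2", "MAT1-1-3", "MAT1-2"))
#' classify_thallism("MAT1-2")
#' @export
classify_thallism <- function(present) {
  present <- unique(present)
  bad <- setdiff(present, MAT_GENES)
  if (length(bad)) stop("unrecognized MAT gene name(s): ",
                        paste(bad, collapse = ", "))
  mat11 <- any(present %in% MAT11_GENES)
  mat12 <- "MAT1-2" %in% present
  thallism <- if (mat11 && mat12) "putative_homothallic"
  else if (mat11) "putative_heterothallic_MAT1-1"
  else if (mat12) "putative_heterothallic_MAT1-2"
  else "indeterminate"
  missing <- if (mat11) setdiff(MAT11_GENES, present) else character()
  complete <- (!mat11 || length(missing) == 0L) && (mat11 || mat12)
  tibble(
    thallism = thallism,
    mat1_1_present = mat11,
    mat1_2_present = mat12,
    idiomorph_complete = if (thallism == "indeterminate") FALSE else complete,
    missing = list(missing)
  )
}
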