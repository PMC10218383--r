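#' Casebooks
#'
#' A casebook is one row per case: the physical anthropologist's sex and
#' ancestry estimate, the molecular calls (molecular sex plus the ancestry
#' call from each marker system) and, where the individual was later
#' identified, the antemortem sex and country of provenance.
#'
#' Ancestry call columns keep the laboratory's printed tokens verbatim;
#' `"NA"` (not available) and `"ND"` (not detectable) both count as missing
#' when agreement is scored — see [is_missing_call()].
#'
#' @param path CSV with columns `case_id`, `physical_sex`,
#'   `physical_ancestry`, `molecular_sex`, `str_call`, `y_call`, `mt_call`,
#'   `known_sex`, `known_provenance` (and optionally `y_haplogroup`,
#'   `mt_haplogroup`).
#' @return a `bga_casebook` tibble.
#' @export
read_casebook <- function(path) {
  if (!file.exists(path)) stop_strbga("no such file: ", path)
  cb <- readr::read_csv(path, na = "",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("case_id", "physical_sex", "physical_ancestry", "molecular_sex",
            "str_call", "y_call", "mt_call")
  if (!all(need %in% names(cb))) {
    stop_strbga(path, ": casebook needs columns ", paste(need, collapse = ", "))
  }
  for (col in c("known_sex", "known_provenance", "y_haplogroup", "mt_haplogroup")) {
    if (!col %in% names(cb)) cb[[col]] <- NA_character_
  }
  if (anyDuplicated(cb$case_id)) {
    stop_strbga(path, ": duplicate case_id: ",
                paste(unique(cb$case_id[duplicated(cb$case_id)]), collapse = ", "))
  }
  bad_sex <- setdiff(cb$physical_sex, c("M", "F", "IND"))
  if (length(bad_sex)) stop_strbga("physical_sex outside {M, F, IND}: ",
                                   paste(bad_sex, collapse = ", "))
  bad_mol <- setdiff(cb$molecular_sex, c("M", "F", "ND"))
  if (length(bad_mol)) stop_strbga("molecular_sex outside {M, F, ND}: ",
                                   paste(bad_mol, collapse = ", "))
  class(cb) <- c("bga_casebook", class(cb))
  cb
}

#' The built-in 24-case casebook
#'
#' Twenty-four forensic cases of skeletal remains: for each, the physical
#' sex/ancestry estimate, the molecular sex, the per-marker ancestry calls
#' (autosomal STR, Y-STR, mtDNA) and the assigned Y/mtDNA haplogroup labels.
#' Nine of the cases were subsequently identified; for those the antemortem
#' sex and country of provenance are recorded and serve as ground truth for
#' accuracy rates.
#'
#' @return a `bga_casebook` tibble with 24 rows.
#' @export
#' @examples
#' cb <- builtin_casebook()
#' nrow(cb)
#' sum(!is.na(cb$known_provenance))
builtin_casebook <- function() {
  read_casebook(system.file("extdata", "casebook.csv", package = "strbga",
                            mustWork = TRUE))
}

#' Is an ancestry call missing?
#'
#' `NA` cells and the tokens `"NA"` (not available) and `"ND"` (not
#' detectable) all mean no usable call.
#'
#' @param x character vector of calls.
#' @return logical vector.
#' @export
is_missing_call <- function(x) {
  is.na(x) | x %in% c("NA", "ND")
}

#' Built-in per-case haplogroup assignments
#'
#' The case-by-case Y and mtDNA haplogroup labels of the built-in casebook
#' together with the region/continent annotation recorded for each, used as
#' the regression fixture for [map_haplogroup()].
#'
#' @return a tibble with columns `case_id`, `y_label`, `y_region`,
#'   `mt_label`, `mt_subclade`, `continent`.
#' @export
builtin_haplogroup_assignments <- function() {
  readr::read_csv(system.file("extdata", "haplogroup_assignments.csv",
                              package = "strbga", mustWork = TRUE),
                  na = "",
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
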