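#' Macro-group label equivalences
#'
#' Physical anthropology, the three molecular marker systems and antemortem
#' records each use their own ancestry labels. Agreement is scored after
#' collapsing every label onto a broad continental macro group:
#' European (Eur_Am, EU, European, Europe), African (Afr_Am, AF, African,
#' Africa/Africa America), Asian (AS, Asian, South Asia, South Asian).
#' Countries of provenance resolve the same way (Italy, Germany, Ukraine are
#' European; Nigeria and Morocco African).
#'
#' @param extra_labels,extra_countries named character vectors extending or
#'   overriding the defaults (name = label/country, value = macro group).
#' @return a `bga_macro_map`.
#' @export
macro_group_map <- function(extra_labels = NULL, extra_countries = NULL) {
  labels <- c(
    Eur_Am = "European", EU = "European", European = "European",
    Europe = "European",
    Afr_Am = "African", AF = "African", African = "African",
    "Africa/Africa America" = "African",
    AS = "Asian", Asian = "Asian",
    "South Asia" = "Asian", "South Asian" = "Asian")
  countries <- c(Italy = "European", Germany = "European",
                 Ukraine = "European", Nigeria = "African",
                 Morocco = "African")
  if (!is.null(extra_labels)) labels[names(extra_labels)] <- extra_labels
  if (!is.null(extra_countries)) countries[names(extra_countries)] <- extra_countries
  structure(list(labels = labels, countries = countries),
            class = "bga_macro_map")
}

#' Resolve labels to macro groups
#'
#' @param x character vector of ancestry labels or country names.
#' @param map a [macro_group_map()].
#' @param what `"label"` or `"country"`.
#' @return macro group per element; missing calls (`NA`/`"NA"`/`"ND"`) give
#'   `NA`. A non-missing label with no entry is an error naming the label.
#' @export
to_macro_group <- function(x, map = macro_group_map(), what = c("label", "country")) {
  what <- match.arg(what)
  lut <- if (what == "label") map$labels else map$countries
  out <- rep(NA_character_, length(x))
  live <- !is_missing_call(x)
  hit <- lut[x[live]]
  if (anyNA(hit)) {
    stop_strbga("unmappable ", what, "(s): ",
                paste(unique(x[live][is.na(hit)]), collapse = ", "))
  }
  out[live] <- unname(hit)
  out
}

# per-case macro resolution shared by the scoring functions
casebook_macros <- function(casebook, map) {
  tibble::tibble(
    case_id = casebook$case_id,
    physical_macro = to_macro_group(casebook$physical_ancestry, map),
    str_macro = to_macro_group(casebook$str_call, map),
    y_macro = to_macro_group(casebook$y_call, map),
    mt_macro = to_macro_group(casebook$mt_call, map),
    known_macro = to_macro_group(casebook$known_provenance, map, "country"))
}

#' Cases where physical and molecular ancestry disagree
#'
#' A case is discrepant when any non-missing genetic call (autosomal STR,
#' Y-STR or mtDNA) resolves to a macro group different from the physical
#' estimate, or when two non-missing genetic calls resolve to different
#' groups. Missing calls (NA/ND) never create a discrepancy.
#'
#' @param casebook a `bga_casebook`.
#' @param map a [macro_group_map()].
#' @return tibble of discrepant cases with the resolved macro groups; the
#'   number of rows is the discrepancy count.
#' @export
ancestry_discrepancies <- function(casebook, map = macro_group_map()) {
  mac <- casebook_macros(casebook, map)
  disc <- purrr::pmap_lgl(mac, function(case_id, physical_macro, str_macro,
                                        y_macro, mt_macro, known_macro) {
    gen <- stats::na.omit(c(str_macro, y_macro, mt_macro))
    if (!length(gen)) return(FALSE)
    any(gen != physical_macro) || length(unique(gen)) > 1
  })
  mac[disc, c("case_id", "physical_macro", "str_macro", "y_macro", "mt_macro")]
}

#' Accuracy of a discipline against antemortem data
#'
#' Restricted to the identified cases (those with antemortem records):
#'
#' * `"sex"` — success when both the physical and the molecular sex call
#'   equal the known sex;
#' * `"physical"` — success when the physical ancestry estimate resolves to
#'   the known provenance's macro group;
#' * `"molecular"` — success when *all* non-missing marker calls resolve to
#'   the known macro group.
#'
#' Rates are percentages of the identified-case count, truncated (not
#' rounded) to one decimal, so 6/9 reports as 66.6.
#'
#' @param casebook a `bga_casebook`.
#' @param map a [macro_group_map()].
#' @param discipline which comparison to score.
#' @return list with `discipline`, `n`, `successes`, `failures` (case ids)
#'   and `rate` (percent).
#' @export
accuracy_vs_known <- function(casebook,
                              map = macro_group_map(),
                              discipline = c("sex", "physical", "molecular")) {
  discipline <- match.arg(discipline)
  idf <- if (discipline == "sex") !is.na(casebook$known_sex)
         else !is_missing_call(casebook$known_provenance)
  if (!any(idf)) stop_strbga("no identified cases in the casebook")
  cb <- casebook[idf, ]
  ok <- switch(discipline,
    sex = cb$physical_sex == cb$known_sex & cb$molecular_sex == cb$known_sex,
    physical = {
      mac <- casebook_macros(cb, map)
      mac$physical_macro == mac$known_macro
    },
    molecular = {
      mac <- casebook_macros(cb, map)
      purrr::pmap_lgl(mac, function(case_id, physical_macro, str_macro,
                                    y_macro, mt_macro, known_macro) {
        gen <- stats::na.omit(c(str_macro, y_macro, mt_macro))
        length(gen) > 0 && all(gen == known_macro)
      })
    })
  list(discipline = discipline, n = sum(idf),
       successes = cb$case_id[ok], failures = cb$case_id[!ok],
       rate = truncate_pct(sum(ok), sum(idf)))
}

#' Full concordance report for a casebook
#'
#' Scores sex and ancestry agreement between the physical, molecular and
#' (where identified) antemortem determinations of every case.
#'
#' @param casebook a `bga_casebook` (default: the built-in 24-case table).
#' @param map a [macro_group_map()].
#' @return a `bga_concordance` list; see [tidy()] and [glance()] methods for
#'   tabular views.
#' @export
#' @examples
#' rep <- concordance_report(builtin_casebook())
#' glance(rep)
concordance_report <- function(casebook = builtin_casebook(),
                               map = macro_group_map()) {
  if (!nrow(casebook)) stop_strbga("empty casebook")
  sex_tab <- table(factor(casebook$molecular_sex, c("M", "F", "ND")))
  both <- casebook$physical_sex %in% c("M", "F") & casebook$molecular_sex %in% c("M", "F")
  disc <- ancestry_discrepancies(casebook, map)
  identified <- !is_missing_call(casebook$known_provenance)
  structure(list(
    n_cases = nrow(casebook),
    molecular_sex_counts = c(M = unname(sex_tab["M"]), F = unname(sex_tab["F"]),
                             ND = unname(sex_tab["ND"])),
    sex_comparable = sum(both),
    sex_agreements = sum(casebook$physical_sex[both] == casebook$molecular_sex[both]),
    discrepancies = disc,
    n_discrepant = nrow(disc),
    n_identified = sum(identified),
    sex_accuracy = if (any(identified)) accuracy_vs_known(casebook, map, "sex"),
    physical_accuracy = if (any(identified)) accuracy_vs_known(casebook, map, "physical"),
    molecular_accuracy = if (any(identified)) accuracy_vs_known(casebook, map, "molecular"),
    macros = casebook_macros(casebook, map),
    casebook = casebook, map = map
  ), class = "bga_concordance")
}

#' @export
print.bga_concordance <- function(x, ...) {
  cat("<bga_concordance> ", x$n_cases, " cases\n", sep = "")
  cat(sprintf("  molecular sex: %d M, %d F, %d ND; physical/molecular sex agreement %d/%d\n",
              x$molecular_sex_counts["M"], x$molecular_sex_counts["F"],
              x$molecular_sex_counts["ND"], x$sex_agreements, x$sex_comparable))
  cat(sprintf("  ancestry-discrepant cases: %d (%s)\n", x$n_discrepant,
              paste(x$discrepancies$case_id, collapse = ", ")))
  if (x$n_identified) {
    cat(sprintf("  identified cases: %d\n", x$n_identified))
    cat(sprintf("    sex accuracy vs known:       %.1f%%\n", x$sex_accuracy$rate))
    cat(sprintf("    physical ancestry accuracy:  %.1f%% (failures: %s)\n",
                x$physical_accuracy$rate,
                paste(x$physical_accuracy$failures, collapse = ", ")))
    cat(sprintf("    molecular ancestry accuracy: %.1f%% (failures: %s)\n",
                x$molecular_accuracy$rate,
                paste(x$molecular_accuracy$failures, collapse = ", ")))
  }
  invisible(x)
}
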