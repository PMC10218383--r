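#' Tidy a fitted PLS-DA model
#'
#' One row per (feature, class) regression coefficient on the autoscaled
#' feature space.
#'
#' @param x a `bga_plsda`.
#' @param ... unused.
#' @return a tibble `term`, `class`, `estimate`.
#' @method tidy bga_plsda
#' @export
tidy.bga_plsda <- function(x, ...) {
  B <- x$coef
  tibble::tibble(
    term = rep(rownames(B) %||% x$features, times = ncol(B)),
    class = rep(x$class_set, each = nrow(B)),
    estimate = as.vector(B))
}

#' @rdname tidy.bga_plsda
#' @method glance bga_plsda
#' @export
glance.bga_plsda <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp,
    n_features = length(x$features),
    n_classes = length(x$class_set),
    n_train = if (!is.null(x$scores)) nrow(x$scores) else NA_integer_,
    threshold = x$threshold)
}

#' Tidy a cross-validation report
#'
#' @param x a `bga_cv_report`.
#' @param ... unused.
#' @return one row per repeat: `repeat_id`, `accuracy`, `chosen_A`.
#' @method tidy bga_cv_report
#' @export
tidy.bga_cv_report <- function(x, ...) {
  done <- !is.na(x$accuracy_per_repeat)
  tibble::tibble(
    repeat_id = seq_len(x$n_repeats)[done],
    accuracy = x$accuracy_per_repeat[done],
    chosen_A = x$chosen_A)
}

#' @rdname tidy.bga_cv_report
#' @method glance bga_cv_report
#' @export
glance.bga_cv_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    accuracy_sd = x$accuracy_sd,
    median_A = as.integer(stats::median(x$chosen_A)),
    n = x$n, n_repeats = x$n_repeats_done,
    mean_sensitivity = mean(x$per_class$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$per_class$specificity, na.rm = TRUE))
}

#' Per-case verdicts of a concordance report
#'
#' @param x a `bga_concordance`.
#' @param ... unused.
#' @return one row per case with resolved macro groups, discrepancy flag
#'   and, for identified cases, correctness against the antemortem record.
#' @method tidy bga_concordance
#' @export
tidy.bga_concordance <- function(x, ...) {
  mac <- x$macros
  mac$discrepant <- mac$case_id %in% x$discrepancies$case_id
  mac$identified <- !is.na(mac$known_macro)
  mac$physical_ok <- ifelse(mac$identified, mac$physical_macro == mac$known_macro, NA)
  mac$molecular_ok <- NA
  if (x$n_identified) {
    mac$molecular_ok[mac$identified] <-
      mac$case_id[mac$identified] %in% x$molecular_accuracy$successes
  }
  mac
}

#' @rdname tidy.bga_concordance
#' @method glance bga_concordance
#' @export
glance.bga_concordance <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_cases,
    molecular_males = unname(x$molecular_sex_counts["M"]),
    molecular_females = unname(x$molecular_sex_counts["F"]),
    n_discrepant = x$n_discrepant,
    n_identified = x$n_identified,
    sex_accuracy_pct = if (x$n_identified) x$sex_accuracy$rate else NA_real_,
    physical_ancestry_accuracy_pct = if (x$n_identified) x$physical_accuracy$rate else NA_real_,
    molecular_ancestry_accuracy_pct = if (x$n_identified) x$molecular_accuracy$rate else NA_real_)
}
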