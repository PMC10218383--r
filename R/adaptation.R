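#' Default minimum-locus thresholds for a confident call
#'
#' Below these, a query is answered with an explicit NO_CALL rather than a
#' prediction: 10 typed loci for autosomal STRs and Y-STRs, 100 called
#' positions for mtDNA. Casework behaviour brackets but does not pin these
#' numbers (9 Y loci yielded no prediction; 13+ autosomal loci usually
#' predicted), so they are exposed as configurable thresholds.
#'
#' @param marker_kind marker system.
#' @return integer threshold.
#' @export
default_min_loci <- function(marker_kind) {
  switch(check_marker_kind(marker_kind), autosomal = 10L, ystr = 10L, mtdna = 100L)
}

#' Adapt the reference model to a partial profile and predict
#'
#' Degraded skeletal DNA usually types only a subset of loci. Instead of
#' imputing the missing ones, the reference panel is restricted to exactly
#' the features the query carries, the classifier is refit on that
#' restricted matrix (LV count re-selected by the same venetian-blind CV
#' used in training), and the query is predicted by the refit model. A
#' query typing fewer than `min_loci` loci is answered NO_CALL with reason
#' `"low number of loci"`; a query sharing no features with the panel is
#' NO_CALL with reason `"no locus overlap with panel"`.
#'
#' @param panel a [new_panel()] reference panel.
#' @param query a `bga_profiles` tibble holding one sample of the panel's
#'   marker kind.
#' @param min_loci minimum typed loci (called positions for mtDNA); default
#'   [default_min_loci()].
#' @param a_max,k LV-selection controls (venetian-blind `k`-fold CV, LV
#'   count up to `a_max` capped at the restricted rank).
#' @param threshold reliability threshold on the winning prediction value.
#' @param scale autoscale features.
#' @param min_count vocabulary support threshold, as in
#'   [build_vocabulary()].
#' @return a one-row `bga_prediction`.
#' @export
adapt_and_predict <- function(panel, query, min_loci = NULL, a_max = 15,
                              k = 5, threshold = 0.8, scale = TRUE,
                              min_count = 1) {
  stopifnot(inherits(panel, "bga_panel"))
  kind <- marker_kind(panel$profiles)
  if (!identical(kind, marker_kind(query))) {
    stop_strbga("query marker kind (", marker_kind(query),
                ") does not match panel (", kind, ")")
  }
  sid <- unique(query$sample_id)
  if (length(sid) == 0) {
    # fully dropped-out profile: nothing typed at all
    return(no_call_prediction("<empty>", panel$class_set, 0L, "low number of loci"))
  }
  if (length(sid) != 1) stop_strbga("adapt_and_predict() takes a single-sample query")
  min_loci <- min_loci %||% default_min_loci(kind)
  class_set <- panel$class_set

  typed <- count_typed_loci(query)
  n_typed <- if (nrow(typed)) typed$n_loci[1] else 0L
  if (kind == "mtdna") {
    # completeness of a mitogenome is the number of called vocabulary
    # positions, not the number of observed variants
    vocab_full <- build_vocabulary(panel, min_count)
    Xq_full <- encode_profiles(query, vocab_full)
    n_typed <- sum(!Xq_full$missing[1, ])
  }
  if (n_typed < min_loci) {
    return(no_call_prediction(sid, class_set, n_typed, "low number of loci"))
  }

  if (kind != "mtdna") {
    vocab_full <- build_vocabulary(panel, min_count)
    Xq_full <- encode_profiles(query, vocab_full)
  }
  keep <- !Xq_full$missing[1, ]
  if (!any(keep)) {
    return(no_call_prediction(sid, class_set, n_typed, "no locus overlap with panel"))
  }
  vocab_r <- vocab_full[keep, , drop = FALSE]
  attr(vocab_r, "marker_kind") <- attr(vocab_full, "marker_kind")
  class(vocab_r) <- class(vocab_full)

  Xp <- encode_profiles(panel$profiles, vocab_r)
  ok <- rowSums(Xp$missing) == 0
  labels <- panel$labels[Xp$sample_id][ok]
  Xp_c <- Xp$values[ok, , drop = FALSE]
  if (length(unique(labels)) < 2) {
    stop_strbga("restricted panel degenerates to fewer than 2 classes")
  }
  sel <- select_ncomp(Xp_c, labels, a_max, k = k, scale = scale)
  m <- fit_capped(Xp_c, labels, sel$ncomp, scale = scale)
  Xq <- Xq_full$values[, keep, drop = FALSE]
  pv <- predict_values(m, Xq)
  # classes can drop out of pv if absent from the restricted panel
  full_pv <- matrix(NA_real_, 1, length(class_set),
                    dimnames = list(sid, class_set))
  full_pv[, colnames(pv)] <- pv
  as_prediction(full_pv, class_set, threshold = threshold,
                n_loci_used = n_typed, sample_id = sid)
}
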