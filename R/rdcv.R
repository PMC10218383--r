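#' Venetian-blind fold assignment
#'
#' Samples are ordered by class (classes in order of first appearance, input
#' order within class) and every k-th sample lands in the same fold, so
#' class proportions are approximately preserved in every fold and the
#' assignment is fully deterministic.
#'
#' @param labels class label per sample.
#' @param k number of folds (`k >= 2`, `k <= n`).
#' @param offset rotate the assignment; `offset = k` is identical to 0.
#' @return integer fold id (1..k) per sample, in input order.
#' @export
venetian_blinds <- function(labels, k, offset = 0) {
  n <- length(labels)
  if (k < 2) stop_strbga("k must be >= 2")
  if (k > n) stop_strbga("k (", k, ") exceeds the number of samples (", n, ")")
  ord <- order(match(labels, unique(labels)))  # stable: input order within class
  folds <- integer(n)
  folds[ord] <- ((seq_len(n) - 1 + offset) %% k) + 1L
  folds
}

# rank of the centered/scaled matrix actually seen by NIPALS
scaled_rank <- function(Xm, scale = TRUE) {
  s <- apply(Xm, 2, sd)
  keep <- if (scale) s > 0 else rep(TRUE, ncol(Xm))
  Xc <- sweep(Xm[, keep, drop = FALSE], 2, colMeans(Xm[, keep, drop = FALSE]))
  if (scale) Xc <- sweep(Xc, 2, s[keep], "/")
  qr(Xc)$rank
}

# fit capped at the training rank, silencing the zero-variance warning
# (both routine inside cross-validation folds)
fit_capped <- function(Xm, labels, ncomp, scale = TRUE) {
  r <- scaled_rank(Xm, scale)
  suppressWarnings(fit_plsda(Xm, labels, ncomp = min(ncomp, r), scale = scale))
}

#' Choose the number of latent variables by venetian-blind k-fold CV
#'
#' Misclassification over held-out folds is computed for every LV count up
#' to `a_max` (capped at the training rank); the count with the fewest
#' errors wins, ties going to the smaller model.
#'
#' @param X numeric matrix or complete feature matrix.
#' @param labels class labels.
#' @param a_max largest LV count considered.
#' @param k folds (default 5).
#' @param scale autoscale features.
#' @return list with `ncomp` and the per-A `misclassified` counts.
#' @export
select_ncomp <- function(X, labels, a_max, k = 5, scale = TRUE) {
  Xm <- as_complete_matrix(X)
  labels <- as.character(labels)
  folds <- venetian_blinds(labels, k)
  miss <- matrix(NA_real_, a_max, k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2) {
      stop_strbga("a class vanished from an inner training fold")
    }
    m <- fit_capped(Xm[tr, , drop = FALSE], labels[tr], a_max, scale)
    for (a in seq_len(m$ncomp)) {
      pv <- predict_values(m, Xm[!tr, , drop = FALSE], ncomp = a)
      pred <- m$class_set[apply(pv, 1, which.max)]
      miss[a, f] <- sum(pred != labels[!tr])
    }
  }
  a_use <- max(which(rowSums(!is.na(miss)) == k))
  total <- rowSums(miss[seq_len(a_use), , drop = FALSE])
  list(ncomp = which.min(total), misclassified = total)
}

#' Repeated double cross-validation of a PLS-DA classifier
#'
#' Nested cross-validation in the chemometric style: an outer venetian-blind
#' k-fold loop holds out each fold for testing; an inner k-fold loop on the
#' remaining samples selects the LV count (fewest misclassifications, ties
#' to the smaller model); the outer fold is then predicted by a model refit
#' on the whole outer-training set. The procedure is repeated over random
#' permutations of the sample order, and confusion counts are pooled, giving
#' an honest estimate of prediction accuracy together with its
#' across-repeat dispersion.
#'
#' @param X complete feature matrix (or numeric matrix).
#' @param labels class labels; every class needs at least `k_outer` samples.
#' @param k_outer,k_inner fold counts (default 5 and 5).
#' @param a_max largest LV count considered (default `min(15, rank)`).
#' @param n_repeats permuted repetitions (default 20).
#' @param seed RNG seed; the full report is reproducible from it.
#' @param scale autoscale features.
#' @return a `bga_cv_report`.
#' @export
double_cv <- function(X, labels, k_outer = 5, k_inner = 5, a_max = 15,
                      n_repeats = 20, seed = 1, scale = TRUE) {
  Xm <- as_complete_matrix(X)
  labels <- as.character(labels)
  n <- nrow(Xm)
  class_set <- unique(labels)
  if (min(table(labels)) < k_outer) {
    stop_strbga("every class needs at least k_outer = ", k_outer, " samples")
  }
  a_max <- min(a_max, scaled_rank(Xm, scale))
  set.seed(seed)
  conf <- matrix(0, length(class_set), length(class_set),
                 dimnames = list(class_set, class_set))
  acc_rep <- rep(NA_real_, n_repeats)
  chosen <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    perm <- sample.int(n)
    res <- tryCatch({
      Xp <- Xm[perm, , drop = FALSE]; lp <- labels[perm]
      folds <- venetian_blinds(lp, k_outer)
      pred <- character(n); a_sel <- integer(k_outer)
      for (f in seq_len(k_outer)) {
        tr <- folds != f
        sel <- select_ncomp(Xp[tr, , drop = FALSE], lp[tr], a_max, k_inner, scale)
        a_sel[f] <- sel$ncomp
        m <- fit_capped(Xp[tr, , drop = FALSE], lp[tr], sel$ncomp, scale)
        pv <- predict_values(m, Xp[!tr, , drop = FALSE])
        pred[!tr] <- m$class_set[apply(pv, 1, which.max)]
      }
      list(pred = pred, lp = lp, a_sel = a_sel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warn_strbga("repeat ", rep_i, " skipped: ", conditionMessage(res))
      next
    }
    conf <- conf + unclass(confusion_matrix(res$lp, res$pred, class_set))
    acc_rep[rep_i] <- mean(res$pred == res$lp)
    chosen[[rep_i]] <- res$a_sel
  }
  done <- !is.na(acc_rep)
  if (!any(done)) stop_strbga("all repeats failed")
  met <- plsda_metrics(conf)
  structure(list(
    confusion = conf,
    accuracy = met$accuracy,
    accuracy_per_repeat = acc_rep,
    accuracy_sd = sd(acc_rep[done]),
    per_class = met$per_class,
    chosen_A = vapply(chosen[done], function(a) as.integer(stats::median(a)), integer(1)),
    chosen_A_folds = chosen,
    n = n, n_repeats = n_repeats, n_repeats_done = sum(done),
    k_outer = k_outer, k_inner = k_inner, a_max = a_max,
    seed = seed, class_set = class_set
  ), class = "bga_cv_report")
}

#' @export
print.bga_cv_report <- function(x, ...) {
  cat("<bga_cv_report> ", x$n, " samples, ", x$n_repeats_done, "/", x$n_repeats,
      " repeats, ", x$k_outer, "x", x$k_inner, "-fold, A_max ", x$a_max, "\n",
      sep = "")
  cat(sprintf("  pooled accuracy %.3f (per-repeat sd %.3f), median chosen A = %d\n",
              x$accuracy, x$accuracy_sd, as.integer(stats::median(x$chosen_A))))
  print(x$confusion)
  invisible(x)
}

#' Refit the production model after cross-validation
#'
#' Fits on all samples using the median LV count chosen across rdCV
#' repeats.
#'
#' @param X complete feature matrix.
#' @param labels class labels.
#' @param report a [double_cv()] report.
#' @param ... passed to [fit_plsda()].
#' @return a `bga_plsda`.
#' @export
finalize_plsda <- function(X, labels, report, ...) {
  a <- as.integer(stats::median(report$chosen_A))
  fit_plsda(X, labels, ncomp = a, ...)
}
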