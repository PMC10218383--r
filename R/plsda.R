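#' Fit a PLS-DA classifier
#'
#' Partial least squares discriminant analysis: class membership is
#' dummy-coded (one 0/1 column per class) and regressed on the autoscaled
#' feature matrix by NIPALS PLS2. Each latent variable (LV) is a direction
#' in feature space chosen to maximise covariance with the class-membership
#' response; successive LVs are extracted after deflation, so PLS tolerates
#' noisy, collinear and redundant features. Predicted dummy values are left
#' uncalibrated (they are not forced onto a probability simplex) and are
#' read directly as per-class prediction values.
#'
#' @param X a complete [encode_profiles()] feature matrix (no masked
#'   entries; complete-case-restrict or adapt first) or a plain numeric
#'   matrix.
#' @param labels class label per row.
#' @param ncomp number of latent variables, `A >= 1` and at most the rank of
#'   the scaled training matrix.
#' @param scale autoscale features to unit variance (default TRUE; features
#'   with zero training variance are dropped with a warning).
#' @param threshold reliability threshold on the winning prediction value
#'   (default 0.8).
#' @param tol,max_iter NIPALS convergence control per LV.
#' @return a `bga_plsda` model.
#' @export
fit_plsda <- function(X, labels, ncomp, scale = TRUE, threshold = 0.8,
                      tol = 1e-10, max_iter = 500) {
  Xm <- as_complete_matrix(X)
  labels <- as.character(labels)
  if (nrow(Xm) != length(labels)) stop_strbga("labels must match rows of X")
  class_set <- unique(labels)
  if (length(class_set) < 2) stop_strbga("PLS-DA needs at least 2 classes")
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("V", seq_len(ncol(Xm)))

  x_means <- colMeans(Xm)
  x_sd <- apply(Xm, 2, sd)
  keep <- if (scale) x_sd > 0 else rep(TRUE, ncol(Xm))
  if (scale && any(!keep)) {
    warn_strbga(sum(!keep), " zero-variance feature(s) dropped: ",
                paste(head(colnames(Xm)[!keep]), collapse = ", "))
  }
  x_scales <- if (scale) x_sd[keep] else rep(1, sum(keep))
  Xc <- sweep(sweep(Xm[, keep, drop = FALSE], 2, x_means[keep]), 2, x_scales, "/")

  r <- qr(Xc)$rank
  if (ncomp < 1 || ncomp > r) {
    stop_strbga("ncomp must lie in 1..rank of the training matrix (rank = ", r, ")")
  }

  Y <- outer(labels, class_set, "==") * 1
  colnames(Y) <- class_set
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)

  p <- ncol(Xc); nc <- length(class_set)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, nc, ncomp); Tsc <- matrix(0, nrow(Xc), ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, nrow(Xd))
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      t_sc <- Xd %*% w
      q <- crossprod(Yd, t_sc) / sum(t_sc^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((t_sc - t_old)^2)) < tol * sqrt(sum(t_sc^2))) break
      t_old <- t_sc
    }
    p_load <- crossprod(Xd, t_sc) / sum(t_sc^2)
    Xd <- Xd - tcrossprod(t_sc, p_load)
    Yd <- Yd - tcrossprod(t_sc, q)
    W[, a] <- w; P[, a] <- p_load; Q[, a] <- q; Tsc[, a] <- t_sc
  }
  rownames(W) <- rownames(P) <- colnames(Xc)
  rownames(Q) <- class_set

  # projection matrix R maps scaled X directly to scores: T = Xs R
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)

  structure(list(
    ncomp = ncomp, class_set = class_set, threshold = threshold,
    features = colnames(Xc),
    x_means = x_means[keep], x_scales = x_scales, y_means = y_means,
    weights = W, x_loadings = P, y_loadings = Q, projection = R, coef = B,
    scores = Tsc, labels = labels, scaled = scale,
    vocabulary = if (inherits(X, "bga_feature_matrix")) X$vocabulary else NULL,
    sample_id = if (inherits(X, "bga_feature_matrix")) X$sample_id else rownames(Xm)
  ), class = "bga_plsda")
}

#' @export
print.bga_plsda <- function(x, ...) {
  cat("<bga_plsda> ", x$ncomp, " LV(s), ", length(x$features), " features, classes: ",
      paste(x$class_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# scale a query matrix onto the model's feature space
scale_query <- function(object, Xm) {
  if (is.null(colnames(Xm))) {
    if (ncol(Xm) != length(object$features)) {
      stop_strbga("query has ", ncol(Xm), " features; model expects ",
                  length(object$features))
    }
    colnames(Xm) <- object$features
  }
  if (!all(object$features %in% colnames(Xm))) {
    stop_strbga("query lacks model feature(s): ",
                paste(head(setdiff(object$features, colnames(Xm))), collapse = ", "))
  }
  Xm <- Xm[, object$features, drop = FALSE]
  sweep(sweep(Xm, 2, object$x_means), 2, object$x_scales, "/")
}

#' Latent-variable scores for new samples
#'
#' @param object a `bga_plsda` model.
#' @param X feature matrix on the model's vocabulary; omit for the training
#'   scores.
#' @return n x ncomp matrix of LV scores.
#' @export
plsda_scores <- function(object, X = NULL) {
  if (is.null(X)) {
    sc <- object$scores
  } else {
    sc <- scale_query(object, as_complete_matrix(X)) %*% object$projection
  }
  colnames(sc) <- paste0("LV", seq_len(ncol(sc)))
  sc
}

#' Predict class membership from a PLS-DA model
#'
#' Per-class prediction values are the raw dummy-regression predictions of
#' the query; the assigned class is the argmax (ties broken by class order
#' with a warning) and the call is flagged reliable when the winning
#' prediction value reaches the model threshold.
#'
#' @param object a `bga_plsda` model.
#' @param newdata feature matrix encoded on the model's vocabulary, complete
#'   on the model's features.
#' @param threshold override the model's reliability threshold.
#' @param ncomp predict using only the first `ncomp` LVs (default: all).
#' @param ... unused.
#' @return a `bga_prediction` tibble: `sample_id`, one `pv_<class>` column
#'   per class, `assigned_class`, `max_pv`, `reliable`, `n_loci_used`,
#'   `reason`.
#' @export
predict.bga_plsda <- function(object, newdata, threshold = NULL,
                              ncomp = NULL, ...) {
  pv <- predict_values(object, newdata, ncomp = ncomp)
  n_loci <- if (inherits(newdata, "bga_feature_matrix") &&
                !is.null(newdata$vocabulary)) {
    length(unique(newdata$vocabulary$locus[newdata$vocabulary$feature %in% object$features]))
  } else {
    length(unique(sub(":[^:]*$", "", object$features)))
  }
  as_prediction(pv, object$class_set,
                threshold = threshold %||% object$threshold,
                n_loci_used = n_loci)
}

# raw prediction values, optionally truncated to the first ncomp LVs
predict_values <- function(object, newdata, ncomp = NULL) {
  Xs <- scale_query(object, as_complete_matrix(newdata))
  B <- if (is.null(ncomp) || ncomp == object$ncomp) object$coef else {
    stopifnot(ncomp >= 1, ncomp <= object$ncomp)
    W <- object$weights[, seq_len(ncomp), drop = FALSE]
    P <- object$x_loadings[, seq_len(ncomp), drop = FALSE]
    Q <- object$y_loadings[, seq_len(ncomp), drop = FALSE]
    W %*% solve(crossprod(P, W)) %*% t(Q)
  }
  pv <- sweep(Xs %*% B, 2, object$y_means, "+")
  colnames(pv) <- object$class_set
  rownames(pv) <- rownames(Xs)
  pv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_prediction <- function(pv, class_set, threshold, n_loci_used,
                          sample_id = NULL) {
  sample_id <- sample_id %||% rownames(pv) %||% as.character(seq_len(nrow(pv)))
  assigned <- character(nrow(pv)); tie <- FALSE
  for (i in seq_len(nrow(pv))) {
    mx <- max(pv[i, ], na.rm = TRUE)
    at <- which(!is.na(pv[i, ]) & pv[i, ] >= mx - 1e-8)
    if (length(at) > 1) tie <- TRUE
    assigned[i] <- class_set[at[1]]
  }
  if (tie) warn_strbga("tied prediction values; ties broken by class order")
  out <- tibble::as_tibble(pv, .name_repair = "minimal")
  names(out) <- paste0("pv_", class_set)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id), out)
  out$assigned_class <- assigned
  out$max_pv <- apply(pv, 1, max, na.rm = TRUE)
  out$reliable <- out$max_pv >= threshold
  out$n_loci_used <- n_loci_used
  out$reason <- NA_character_
  class(out) <- c("bga_prediction", class(out))
  out
}

# an explicit no-call row in the same shape
no_call_prediction <- function(sample_id, class_set, n_loci_used, reason) {
  pv <- matrix(NA_real_, 1, length(class_set),
               dimnames = list(sample_id, class_set))
  out <- tibble::as_tibble(pv, .name_repair = "minimal")
  names(out) <- paste0("pv_", class_set)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id), out)
  out$assigned_class <- "NO_CALL"
  out$max_pv <- NA_real_
  out$reliable <- FALSE
  out$n_loci_used <- n_loci_used
  out$reason <- reason
  class(out) <- c("bga_prediction", class(out))
  out
}

#' Classification metrics from a confusion matrix
#'
#' @param confusion square class-by-class count matrix, rows = truth,
#'   columns = prediction.
#' @return list with `accuracy` and a per-class tibble of `sensitivity`
#'   (TP / (TP + FN)) and `specificity` (TN / (TN + FP)); zero-denominator
#'   metrics are `NA`, never 0.
#' @export
plsda_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!nrow(confusion) || nrow(confusion) != ncol(confusion)) {
    stop_strbga("confusion must be a non-empty square matrix")
  }
  total <- sum(confusion)
  if (total == 0) stop_strbga("empty confusion matrix")
  acc <- sum(diag(confusion)) / total
  per <- purrr::map_dfr(seq_len(nrow(confusion)), function(c) {
    tp <- confusion[c, c]
    fn <- sum(confusion[c, ]) - tp
    fp <- sum(confusion[, c]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = rownames(confusion)[c] %||% as.character(c),
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  })
  list(accuracy = acc, per_class = per)
}

confusion_matrix <- function(truth, pred, class_set) {
  table(factor(truth, class_set), factor(pred, class_set))
}

#' Linear discriminant analysis on PLS latent scores
#'
#' Fits a pooled-covariance linear discriminant on the model's LV scores.
#' With equal priors (the default) the class boundary between two classes is
#' the hyperplane through the midpoint of the class centroids, orthogonal to
#' their Mahalanobis difference; under a spherical pooled covariance this
#' reduces to nearest-centroid assignment.
#'
#' @param model a fitted `bga_plsda`.
#' @param X training feature matrix (omit to reuse the stored training
#'   scores).
#' @param labels class labels for the rows of `X`.
#' @param priors named class priors; default equal.
#' @return a `bga_lda` rule; `predict()` returns a tibble of posterior
#'   probabilities and the maximum-posterior class.
#' @export
lda_on_scores <- function(model, X = NULL, labels = model$labels,
                          priors = NULL) {
  sc <- plsda_scores(model, X)
  labels <- as.character(labels)
  stopifnot(nrow(sc) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2) stop_strbga("LDA needs at least 2 classes")
  if (is.null(priors)) priors <- setNames(rep(1 / length(classes), length(classes)), classes)
  mu <- t(vapply(classes, function(cl) colMeans(sc[labels == cl, , drop = FALSE]),
                 numeric(ncol(sc))))
  centered <- sc - mu[match(labels, classes), , drop = FALSE]
  Sp <- crossprod(centered) / (nrow(sc) - length(classes))
  Sp_inv <- tryCatch(solve(Sp), error = function(e) {
    stop_strbga("singular pooled covariance on ", ncol(sc),
                " LV scores; refit with fewer latent variables")
  })
  structure(list(classes = classes, means = mu, cov_inv = Sp_inv,
                 priors = priors[classes], ncomp = ncol(sc), model = model),
            class = "bga_lda")
}

#' @export
predict.bga_lda <- function(object, newdata = NULL, ...) {
  sc <- if (is.null(newdata)) plsda_scores(object$model)
        else plsda_scores(object$model, newdata)
  # linear discriminant scores delta_c(x)
  d <- sc %*% object$cov_inv %*% t(object$means)
  d <- sweep(d, 2, 0.5 * rowSums((object$means %*% object$cov_inv) * object$means))
  d <- sweep(d, 2, log(object$priors), "+")
  post <- exp(d - apply(d, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  out <- tibble::as_tibble(post, .name_repair = "minimal")
  names(out) <- paste0("post_", object$classes)
  out$assigned_class <- object$classes[apply(d, 1, which.max)]
  out
}

#' Serialise / restore a PLS-DA model as JSON
#'
#' Everything needed to reproduce predictions is written: feature names,
#' scaling parameters, W/P/Q loadings, regression coefficients, class set
#' and reliability threshold.
#'
#' @param model a `bga_plsda`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    ncomp = model$ncomp, class_set = model$class_set,
    threshold = model$threshold, features = model$features,
    x_means = model$x_means, x_scales = model$x_scales,
    y_means = as.list(setNames(model$y_means, model$class_set)),
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings, scaled = model$scaled,
    vocabulary = if (!is.null(model$vocabulary)) {
      list(marker_kind = attr(model$vocabulary, "marker_kind"),
           feature = model$vocabulary$feature,
           locus = model$vocabulary$locus,
           allele = model$vocabulary$allele)
    })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @param path path to a JSON model file.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(j$weights); P <- as.matrix(j$x_loadings); Q <- as.matrix(j$y_loadings)
  rownames(W) <- rownames(P) <- j$features
  rownames(Q) <- j$class_set
  R <- W %*% solve(crossprod(P, W))
  vocab <- NULL
  if (!is.null(j$vocabulary)) {
    vocab <- structure(
      tibble::tibble(feature = j$vocabulary$feature,
                     locus = j$vocabulary$locus,
                     allele = j$vocabulary$allele),
      marker_kind = j$vocabulary$marker_kind,
      class = c("bga_vocabulary", class(tibble::tibble())))
  }
  structure(list(
    ncomp = j$ncomp, class_set = j$class_set, threshold = j$threshold,
    features = j$features,
    x_means = setNames(unlist(j$x_means), j$features),
    x_scales = setNames(unlist(j$x_scales), j$features),
    y_means = setNames(unlist(j$y_means), j$class_set),
    weights = W, x_loadings = P, y_loadings = Q,
    projection = R, coef = R %*% t(Q),
    scores = NULL, labels = NULL, scaled = j$scaled,
    vocabulary = vocab, sample_id = NULL), class = "bga_plsda")
}
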