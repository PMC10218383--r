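test_that("full-rank PLS-DA reproduces OLS dummy regression", {
  set.seed(101)
  for (i in 1:3) {
    X <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, paste0("f", 1:3)))
    lab <- c("A", "A", "B", "B", "C", "C")
    m <- fit_plsda(X, lab, ncomp = 3)
    pv <- strbga:::predict_values(m, X)
    Xs <- scale(X)
    Y <- outer(lab, unique(lab), "==") * 1
    ols <- cbind(1, Xs) %*% qr.solve(cbind(1, Xs), Y)
    expect_lt(max(abs(pv - ols)), 1e-8)
    # NIPALS deflation leaves score vectors mutually orthogonal
    G <- crossprod(m$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
})

test_that("one informative feature separates two classes like nearest centroid", {
  set.seed(7)
  X <- cbind(sep = c(rnorm(15, -3), rnorm(15, 3)),
             noise = rnorm(30))
  lab <- rep(c("L", "R"), each = 15)
  m <- fit_plsda(X, lab, ncomp = 1)
  Xq <- cbind(sep = c(rnorm(10, -3), rnorm(10, 3)), noise = rnorm(20))
  got <- predict(m, Xq)$assigned_class
  expect_equal(got, nearest_centroid(scale(X),
                                     lab,
                                     scale(Xq, center = attr(scale(X), "scaled:center"),
                                           scale = attr(scale(X), "scaled:scale"))))
  expect_equal(got, rep(c("L", "R"), each = 10))
})

test_that("a duplicated feature column leaves full-rank predictions unchanged", {
  set.seed(11)
  X <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, paste0("f", 1:3)))
  lab <- rep(c("A", "B"), each = 4)
  Xd <- cbind(X, f3b = X[, 3])
  r <- qr(scale(X))$rank
  m1 <- fit_plsda(X, lab, ncomp = r)
  m2 <- fit_plsda(Xd, lab, ncomp = r)
  q <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, paste0("f", 1:3)))
  qd <- cbind(q, f3b = q[, 3])
  expect_equal(strbga:::predict_values(m1, q),
               strbga:::predict_values(m2, qd), tolerance = 1e-8)
})

test_that("prediction values are invariant to affine feature rescaling", {
  set.seed(23)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  lab <- rep(c("A", "B", "C"), each = 10)
  m1 <- fit_plsda(X, lab, ncomp = 2)
  X2 <- sweep(sweep(X, 2, c(3, 0.2, 10, 5), "*"), 2, c(-1, 4, 0, 100), "+")
  m2 <- fit_plsda(X2, lab, ncomp = 2)
  q <- X[1:5, ]
  q2 <- X2[1:5, ]
  expect_equal(strbga:::predict_values(m1, q),
               strbga:::predict_values(m2, q2), tolerance = 1e-10)
})

test_that("prediction object carries argmax class, threshold flag and ties", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20, -4), 10, 2), matrix(rnorm(20, 4), 10, 2))
  colnames(X) <- c("a", "b")
  lab <- rep(c("A", "B"), each = 10)
  m <- fit_plsda(X, lab, ncomp = 1)
  pr <- predict(m, X)
  expect_true(all(pr$assigned_class == lab))          # resubstitution, separable
  expect_true(all(pr$max_pv == pmax(pr$pv_A, pr$pv_B)))
  # a query at the global centroid of a balanced problem ties
  ctr <- matrix(colMeans(X), 1, dimnames = list("q", colnames(X)))
  expect_warning(tie <- predict(m, ctr), "tie")
  expect_equal(tie$assigned_class, "A")               # class_set order breaks ties
  expect_equal(tie$pv_A, tie$pv_B, tolerance = 1e-8)
  # sub-threshold winner is flagged unreliable (the 0.64 < 0.8 situation)
  expect_false(tie$reliable[1])
  expect_lt(tie$max_pv[1], 0.8)
})

test_that("requesting more LVs than the rank errors, as does a single class", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_error(fit_plsda(X, c("A", "A", "B", "B"), ncomp = 4), "rank")
  expect_error(fit_plsda(X, rep("A", 4), ncomp = 1), "2 classes")
})

test_that("classification metrics match hand computation and leave 0/0 undefined", {
  conf <- matrix(c(8, 3, 2, 7), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  met <- plsda_metrics(conf)
  expect_equal(met$accuracy, 0.75)
  expect_equal(met$per_class$sensitivity, c(0.8, 0.7))
  expect_equal(met$per_class$specificity, c(0.7, 0.8))
  perfect <- diag(c(5, 5, 5))
  met2 <- plsda_metrics(perfect)
  expect_equal(met2$accuracy, 1)
  expect_true(all(met2$per_class$sensitivity == 1))
  empty_row <- matrix(c(0, 0, 4, 6), 2, 2, byrow = TRUE,
                      dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(is.na(plsda_metrics(empty_row)$per_class$sensitivity[1]))
})

test_that("LDA on scores equals nearest centroid under a whitened covariance", {
  set.seed(31)
  X <- rbind(matrix(rnorm(40 * 3, 0), 40, 3), matrix(rnorm(40 * 3, 2), 40, 3))
  colnames(X) <- paste0("f", 1:3)
  lab <- rep(c("A", "B"), each = 40)
  m <- fit_plsda(X, lab, ncomp = 2)
  rule <- lda_on_scores(m)
  sc <- plsda_scores(m)
  # whiten the scores with the pooled covariance so it becomes the identity;
  # then the pooled-covariance discriminant is exactly nearest centroid
  mu <- rbind(colMeans(sc[lab == "A", ]), colMeans(sc[lab == "B", ]))
  ctrd <- sc - mu[match(lab, c("A", "B")), ]
  Sp <- crossprod(ctrd) / (nrow(sc) - 2)
  Wh <- solve(chol(Sp))
  scw <- sc %*% Wh
  nc <- nearest_centroid(scw, lab, scw)
  got <- predict(rule)$assigned_class
  expect_equal(got, nc)
  # and it agrees with the reference LDA implementation under equal priors
  ml <- MASS::lda(sc, grouping = lab, prior = c(0.5, 0.5))
  expect_equal(got, as.character(predict(ml, sc)$class))
})

test_that("three well-separated classes give perfect LDA resubstitution", {
  set.seed(41)
  X <- rbind(matrix(rnorm(30 * 4, -8), 30, 4),
             matrix(rnorm(30 * 4, 0), 30, 4),
             matrix(rnorm(30 * 4, 8), 30, 4))
  colnames(X) <- paste0("f", 1:4)
  lab <- rep(c("A", "B", "C"), each = 30)
  m <- fit_plsda(X, lab, ncomp = 2)
  rule <- lda_on_scores(m)
  expect_equal(mean(predict(rule)$assigned_class == lab), 1)
})

test_that("NIPALS agrees with an independent PLS-DA implementation", {
  set.seed(53)
  X <- rbind(matrix(rnorm(25 * 6, 0), 25, 6), matrix(rnorm(25 * 6, 1.2), 25, 6))
  colnames(X) <- paste0("f", 1:6)
  lab <- rep(c("A", "B"), each = 25)
  m <- fit_plsda(X, lab, ncomp = 3)
  mo <- mixOmics::plsda(X, factor(lab), ncomp = 3)
  for (a in 1:3) {
    s <- sign(sum(m$scores[, a] * mo$variates$X[, a]))
    expect_lt(max(abs(m$scores[, a] - s * mo$variates$X[, a])), 1e-6)
  }
  q <- matrix(rnorm(10 * 6, 0.6), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  ref <- predict(mo, q)$class$max.dist[, 3]
  expect_equal(unname(predict(m, q)$assigned_class), unname(ref))
})

test_that("models survive a JSON round trip", {
  set.seed(61)
  sim <- simulate_autosomal_panel(n_per_class = c(15, 15), class_names = c("A", "B"),
                                  n_loci = 5, fst = 0.3, seed = 2)
  pm <- panel_matrix(sim)
  m <- fit_plsda(pm$X, pm$labels, ncomp = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$coef, m$coef, tolerance = 1e-12)
  expect_equal(strbga:::predict_values(m2, pm$X$values),
               strbga:::predict_values(m, pm$X$values), tolerance = 1e-12)
  expect_identical(attr(m2$vocabulary, "marker_kind"), "autosomal")
})
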