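# shared fixtures built in code

# small autosomal profile tibble built by hand
tiny_autosomal <- function() {
  as_profiles(tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2", "S2", "S3"),
    locus     = c("AMEL", "L1", "L2", "L1", "AMEL", "L1"),
    allele_1  = c("X", "12", "9.3", "12", "X", "13"),
    allele_2  = c("Y", "12", "10", "13", "X", "13")), "autosomal")
}

# encode a simulated panel into a complete matrix + labels
panel_matrix <- function(sim, min_count = 1) {
  v <- build_vocabulary(sim$panel, min_count)
  X <- complete_rows(encode_profiles(sim$panel$profiles, v))
  list(X = X, labels = unname(sim$panel$labels[X$sample_id]), vocab = v)
}

# nearest-centroid classifier, the independent oracle for separable panels
nearest_centroid <- function(X_train, labels, X_test) {
  classes <- unique(labels)
  mu <- t(vapply(classes,
                 function(cl) colMeans(X_train[labels == cl, , drop = FALSE]),
                 numeric(ncol(X_train))))
  d2 <- vapply(seq_along(classes), function(c) {
    rowSums(sweep(X_test, 2, mu[c, ])^2)
  }, numeric(nrow(X_test)))
  classes[apply(matrix(d2, nrow(X_test)), 1, which.min)]
}

# Weir-Cockerham multiallelic FST estimator (ratio of averages), the
# independent oracle for the Balding-Nichols simulator. Genotypes arrive as
# a long tibble sample_id/locus/allele_1/allele_2 plus labels.
wc_fst <- function(profiles, labels) {
  tb <- tibble::as_tibble(profiles)
  tb$pop <- unname(labels[tb$sample_id])
  num <- 0; den <- 0
  for (lc in unique(tb$locus)) {
    sub <- tb[tb$locus == lc, ]
    pops <- unique(sub$pop)
    r <- length(pops)
    if (r < 2) next
    alleles <- unique(c(sub$allele_1, sub$allele_2))
    n_i <- vapply(pops, function(p) sum(sub$pop == p), numeric(1))
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(pops, function(p) {
        s <- sub[sub$pop == p, ]
        mean(c(s$allele_1 == al, s$allele_2 == al))
      }, numeric(1))
      h_i <- vapply(pops, function(p) {
        s <- sub[sub$pop == p, ]
        mean((s$allele_1 == al) != (s$allele_2 == al))
      }, numeric(1))
      p_bar <- sum(n_i * p_i) / (r * n_bar)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / (r * n_bar)
      a <- (n_bar / n_c) *
        (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
      b <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
      cc <- h_bar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# wide CSV writers used by I/O round-trip tests
write_tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
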