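test_that("autosomal simulation is seed-deterministic with proper frequencies", {
  s1 <- simulate_autosomal_panel(n_per_class = c(10, 10), class_names = c("A", "B"),
                                 n_loci = 4, fst = 0.2, seed = 42)
  s2 <- simulate_autosomal_panel(n_per_class = c(10, 10), class_names = c("A", "B"),
                                 n_loci = 4, fst = 0.2, seed = 42)
  expect_identical(tibble::as_tibble(s1$panel$profiles),
                   tibble::as_tibble(s2$panel$profiles))
  sums <- s1$frequencies |>
    dplyr::group_by(locus, class) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # fst = 0 degenerates to identical class frequencies (no class signal)
  s0 <- simulate_autosomal_panel(n_per_class = c(5, 5), class_names = c("A", "B"),
                                 n_loci = 3, fst = 0, seed = 1)
  wide <- tidyr::pivot_wider(s0$frequencies, names_from = class, values_from = freq)
  expect_equal(wide$A, wide$B)
  expect_error(simulate_autosomal_panel(fst = 0.7), "fst")
})

test_that("Weir-Cockerham FST recovered from a large panel approximates theta", {
  theta <- 0.2
  sim <- simulate_autosomal_panel(n_per_class = c(200, 200, 200),
                                  class_names = c("A", "B", "C"),
                                  n_loci = 20, fst = theta, seed = 77)
  est <- wc_fst(sim$panel$profiles, sim$panel$labels)
  expect_lt(abs(est - theta), 0.05)
})

test_that("Y simulation recovers founders and degenerates at zero mutation", {
  sim0 <- simulate_y_panel(n_per_class = c(20, 20), class_names = c("P", "Q"),
                           n_loci = 6, mutation_rate = 0, seed = 3)
  tb <- tibble::as_tibble(sim0$panel$profiles)
  per_class <- tb |>
    dplyr::mutate(class = sub("_.*", "", sample_id)) |>
    dplyr::group_by(class, locus) |>
    dplyr::summarise(n_distinct = dplyr::n_distinct(allele_1), .groups = "drop")
  expect_true(all(per_class$n_distinct == 1))
  # low mutation rate: the class modal haplotype equals the founder
  sim <- simulate_y_panel(n_per_class = c(40, 40), class_names = c("P", "Q"),
                          n_loci = 6, mutation_rate = 0.05, seed = 3)
  tb <- tibble::as_tibble(sim$panel$profiles)
  modal <- tb |>
    dplyr::mutate(class = sub("_.*", "", sample_id)) |>
    dplyr::group_by(class, locus) |>
    dplyr::summarise(mode = names(sort(table(allele_1), decreasing = TRUE))[1],
                     .groups = "drop")
  for (i in seq_len(nrow(modal))) {
    expect_equal(as.numeric(modal$mode[i]),
                 unname(sim$founders[modal$class[i], modal$locus[i]]))
  }
})

test_that("distant Y founders are near-perfectly classifiable", {
  founders <- rbind(rep(10L, 8), rep(16L, 8))   # 6 steps apart at every locus
  sim <- simulate_y_panel(n_per_class = c(30, 30), class_names = c("P", "Q"),
                          n_loci = 8, mutation_rate = 0.05,
                          founders = founders, seed = 15)
  pm <- panel_matrix(sim)
  rep <- double_cv(pm$X, pm$labels, a_max = 4, n_repeats = 3, seed = 6)
  expect_gte(rep$accuracy, 0.95)
})

test_that("mtDNA diagnostic blocks control class signal", {
  sep <- simulate_mt_panel(n_per_class = c(30, 30), class_names = c("EU", "AF"),
                           block_size = 10, n_positions = 60, seed = 8)
  pm <- panel_matrix(sep)
  rep <- double_cv(pm$X, pm$labels, a_max = 4, n_repeats = 3, seed = 2)
  expect_gte(rep$accuracy, 0.95)
  # reproducible from seed
  sep2 <- simulate_mt_panel(n_per_class = c(30, 30), class_names = c("EU", "AF"),
                            block_size = 10, n_positions = 60, seed = 8)
  expect_identical(tibble::as_tibble(sep$panel$profiles),
                   tibble::as_tibble(sep2$panel$profiles))
})

test_that("degradation drops loci reproducibly and respects amelogenin", {
  pr <- tiny_autosomal()
  expect_identical(tibble::as_tibble(degrade_profile(pr, n_drop = 0, seed = 1)),
                   tibble::as_tibble(pr))
  d1 <- degrade_profile(pr, n_drop = 1, seed = 5)
  d2 <- degrade_profile(pr, n_drop = 1, seed = 5)
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))
  expect_true(all(d1$locus[d1$sample_id == "S1"] != "" )) # still a valid table
  # AMEL survives by default
  dall <- degrade_profile(pr, n_drop = 99, seed = 1)
  expect_setequal(unique(dall$locus), "AMEL")
  expect_error(degrade_profile(pr, n_drop = 1, dropout_rate = 0.5), "exactly one")
})

test_that("fresh samples from the generating process match the rdCV estimate", {
  sim <- simulate_autosomal_panel(n_per_class = c(50, 50), class_names = c("A", "B"),
                                  n_loci = 8, fst = 0.25, seed = 30)
  pm <- panel_matrix(sim)
  rep <- double_cv(pm$X, pm$labels, a_max = 6, n_repeats = 3, seed = 11)
  m <- finalize_plsda(pm$X, pm$labels, rep)
  fresh <- simulate_autosomal_panel(n_per_class = c(50, 50), class_names = c("A", "B"),
                                    n_loci = 8, fst = 0.25, seed = 30)
  # same seed regenerates the same population frequencies; draw new genotypes
  fresh2 <- local({
    set.seed(31)
    f <- fresh$frequencies
    rows <- lapply(split(f, list(f$locus, f$class)), function(df) {
      n <- 30
      g1 <- sample(df$allele, n, TRUE, prob = df$freq)
      g2 <- sample(df$allele, n, TRUE, prob = df$freq)
      tibble::tibble(sample_id = sprintf("%s_new_%02d", df$class[1], 1:n),
                     locus = df$locus[1],
                     allele_1 = pmin(as.numeric(g1), as.numeric(g2)),
                     allele_2 = pmax(as.numeric(g1), as.numeric(g2)))
    })
    tb <- dplyr::bind_rows(rows) |>
      dplyr::mutate(allele_1 = as.character(allele_1),
                    allele_2 = as.character(allele_2))
    as_profiles(tb, "autosomal")
  })
  Xq <- encode_profiles(fresh2, pm$vocab)
  truth <- sub("_new.*", "", Xq$sample_id)
  suppressMessages(pred <- predict(m, complete_rows(Xq)))
  acc_fresh <- mean(pred$assigned_class == sub("_new.*", "", complete_rows(Xq)$sample_id))
  expect_lt(abs(acc_fresh - rep$accuracy), 0.05 + 1e-9)
})
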