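test_that("autosomal dosage encoding and masking follow the vocabulary", {
  pr <- tiny_autosomal()
  panel <- new_panel(pr, c(S1 = "A", S2 = "A", S3 = "B"))
  v <- build_vocabulary(panel)
  expect_equal(v$feature, c("L1:12", "L1:13", "L2:9.3", "L2:10"))
  X <- encode_profiles(pr, v)
  expect_equal(unname(X$values["S1", c("L1:12", "L1:13")]), c(2, 0))
  expect_equal(unname(X$values["S2", c("L1:12", "L1:13")]), c(1, 1))
  # untyped locus L2 fully masked for S2 and S3
  expect_true(all(X$missing[c("S2", "S3"), c("L2:9.3", "L2:10")]))
  expect_false(any(X$missing["S1", ]))
  # unmasked locus dosages sum to 2 over its features
  expect_equal(unname(rowSums(X$values[, c("L1:12", "L1:13")])), c(2, 2, 2))
})

test_that("min_count drops rare alleles from the vocabulary", {
  pr <- tiny_autosomal()
  panel <- new_panel(pr, c(S1 = "A", S2 = "A", S3 = "B"))
  v2 <- build_vocabulary(panel, min_count = 2)
  # allele 13 appears 3x (S2 het + S3 hom), 12 appears 3x; L2 alleles once each
  expect_setequal(v2$feature, c("L1:12", "L1:13"))
  # an allele at a catalogued locus but outside the vocabulary contributes
  # nothing, with a message
  rare <- as_profiles(tibble::tibble(sample_id = "S9", locus = "L1",
                                     allele_1 = "12", allele_2 = "17"), "autosomal")
  expect_message(X9 <- encode_profiles(rare, v2), "absent from vocabulary")
  expect_equal(unname(X9$values["S9", ]), c(1, 0))
  X <- encode_profiles(pr, v2)
  expect_equal(unname(X$values["S1", ]), c(2, 0))
})

test_that("Y encoding keeps repeat counts numeric and splits multi-copy loci", {
  pr <- as_profiles(tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    locus = c("DYS19", "DYS385", "DYS19"),
    allele_1 = c("14", "11", "15"),
    allele_2 = c(NA, "14", NA)), "ystr")
  panel <- new_panel(pr, c(S1 = "A", S2 = "B"))
  v <- build_vocabulary(panel)
  expect_setequal(v$feature, c("DYS19", "DYS385_a", "DYS385_b"))
  X <- encode_profiles(pr, v)
  expect_equal(unname(X$values["S1", c("DYS19", "DYS385_a", "DYS385_b")]),
               c(14, 11, 14))
  # untyped locus masked (the one-missing-locus situation)
  expect_true(all(X$missing["S2", c("DYS385_a", "DYS385_b")]))
  expect_false(X$missing["S2", "DYS19"])
})

test_that("mtDNA encoding is binary presence with N masking", {
  pr <- as_profiles(tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S3"),
    haplogroup = NA_character_,
    has_variants = TRUE,
    position = c(73L, 263L, 73L, NA),
    base = c("G", "G", "N", NA)), "mtdna")
  panel <- new_panel(pr, c(S1 = "A", S2 = "B", S3 = "B"))
  v1 <- build_vocabulary(panel, min_count = 1)
  expect_equal(v1$feature, c("73", "263"))
  # an N never counts as support, so 73 is a singleton and min_count=2 drops all
  expect_error(build_vocabulary(panel, min_count = 2), "empty")
  X <- encode_profiles(pr, v1)
  expect_equal(unname(X$values["S1", ]), rep(1, ncol(X$values)))
  # S3 is rCRS-identical: all zeros, nothing masked
  expect_equal(unname(X$values["S3", ]), rep(0, ncol(X$values)))
  expect_false(any(X$missing["S3", ]))
  # S2 has an N at 73 -> masked there
  expect_true(X$missing["S2", "73"])
  # haplogroup-only records are routed to the mapping module
  hg_only <- as_profiles(tibble::tibble(
    sample_id = "H", haplogroup = "U5a", has_variants = FALSE,
    position = NA_integer_, base = NA_character_), "mtdna")
  expect_error(encode_profiles(hg_only, v1), "map_haplogroup")
})

test_that("encoding is invariant to vocabulary permutation", {
  sim <- simulate_autosomal_panel(n_per_class = c(10, 10), class_names = c("A", "B"),
                                  n_loci = 4, fst = 0.2, seed = 5)
  v <- build_vocabulary(sim$panel)
  X <- encode_profiles(sim$panel$profiles, v)
  perm <- sample(nrow(v))
  vp <- v[perm, ]
  attr(vp, "marker_kind") <- attr(v, "marker_kind")
  class(vp) <- class(v)
  Xp <- encode_profiles(sim$panel$profiles, vp)
  expect_equal(Xp$values[, v$feature], X$values)
  expect_equal(Xp$missing[, v$feature], X$missing)
})
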