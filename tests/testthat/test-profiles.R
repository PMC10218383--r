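test_that("autosomal CSV parsing follows the paired-column conventions", {
  f <- write_tmp_csv(c(
    "sample_id,AMEL_1,AMEL_2,L1_1,L1_2,L2_1,L2_2",
    "S1,X,Y,12,12,9.3,10",
    "S2,X,X,12,13,,",
    "S3,,,13,13,8,9"))
  pr <- read_profiles(f, "autosomal")
  expect_s3_class(pr, "bga_profiles")
  expect_identical(marker_kind(pr), "autosomal")
  s1 <- pr[pr$sample_id == "S1" & pr$locus == "L1", ]
  expect_equal(c(s1$allele_1, s1$allele_2), c("12", "12"))
  # blank cells are absent loci, not zeros
  expect_false(any(pr$sample_id == "S2" & pr$locus == "L2"))
  # microvariant survives as an exact decimal string
  expect_true("9.3" %in% pr$allele_1[pr$locus == "L2"])
})

test_that("autosomal parse errors name the offending cell", {
  bad_token <- write_tmp_csv(c("sample_id,L1_1,L1_2", "S1,12,x9"))
  expect_error(read_profiles(bad_token, "autosomal"), "malformed allele 'x9'.*L1_2")
  half <- write_tmp_csv(c("sample_id,L1_1,L1_2", "S1,12,"))
  expect_error(read_profiles(half, "autosomal"), "half-typed")
  dup <- write_tmp_csv(c("sample_id,L1_1,L1_2", "S1,12,12", "S1,13,13"))
  expect_error(read_profiles(dup, "autosomal"), "duplicate sample_id")
  zero <- write_tmp_csv(c("sample_id,L1_1,L1_2", "S1,0,12"))
  expect_error(read_profiles(zero, "autosomal"), "malformed allele")
})

test_that("Y-STR multi-copy cells are sorted and single-copy loci enforced", {
  f <- write_tmp_csv(c(
    "sample_id,DYS19,DYS385,DYS389II",
    "S1,14,\"14,11\",30",
    "S2,15,12,"))
  pr <- read_profiles(f, "ystr")
  d385 <- pr[pr$sample_id == "S1" & pr$locus == "DYS385", ]
  expect_equal(c(d385$allele_1, d385$allele_2), c("11", "14"))
  # one value at a multi-copy locus is allowed
  expect_true(is.na(pr$allele_2[pr$sample_id == "S2" & pr$locus == "DYS385"]))
  expect_false(any(pr$sample_id == "S2" & pr$locus == "DYS389II"))
  two_at_single <- write_tmp_csv(c("sample_id,DYS19", "S1,\"14,15\""))
  expect_error(read_profiles(two_at_single, "ystr"), "single-copy")
})

test_that("mtDNA variant lists parse with rCRS bounds and N handling", {
  f <- write_tmp_csv(c(
    "sample_id,haplogroup,variants",
    "S1,H1,73G;263G",
    "S2,,16189N;152C",
    "S3,U5a1b1g,",
    "S4,,rCRS"))
  pr <- read_profiles(f, "mtdna")
  expect_equal(sort(pr$position[pr$sample_id == "S1"]), c(73L, 263L))
  expect_true("N" %in% pr$base[pr$sample_id == "S2"])
  expect_false(any(pr$has_variants[pr$sample_id == "S3"]))
  expect_true(all(pr$has_variants[pr$sample_id == "S4"]))
  out_of_range <- write_tmp_csv(c("sample_id,haplogroup,variants", "S1,,16570G"))
  expect_error(read_profiles(out_of_range, "mtdna"), "16569")
  empty_rec <- write_tmp_csv(c("sample_id,haplogroup,variants", "S1,,"))
  expect_error(read_profiles(empty_rec, "mtdna"), "neither haplogroup nor variant")
})

test_that("write_profiles() round-trips every marker kind cell-for-cell", {
  for (case in list(
    list(kind = "autosomal",
         lines = c("sample_id,AMEL_1,AMEL_2,L1_1,L1_2,L2_1,L2_2",
                   "S1,X,Y,12,12,9.3,10", "S2,X,X,12,13,,")),
    list(kind = "ystr",
         lines = c("sample_id,DYS19,DYS385",
                   "S1,14,\"11,14\"", "S2,15,")),
    list(kind = "mtdna",
         lines = c("sample_id,haplogroup,variants",
                   "S1,H1,73G;263G", "S2,U5a,", "S3,,rCRS")))) {
    f <- write_tmp_csv(case$lines)
    pr <- read_profiles(f, case$kind)
    g <- withr::local_tempfile(fileext = ".csv")
    write_profiles(pr, g)
    expect_identical(readr::read_csv(g, col_types = readr::cols(.default = "c")),
                     readr::read_csv(f, col_types = readr::cols(.default = "c")),
                     label = case$kind)
  }
})

test_that("molecular sex combines amelogenin and Y evidence", {
  pr <- tiny_autosomal()   # S1 = X,Y; S2 = X,X; S3 has no amelogenin
  sex <- derive_molecular_sex(pr)
  expect_equal(sex$molecular_sex[match(c("S1", "S2", "S3"), sex$sample_id)],
               c("M", "F", "ND"))
  # typed Y loci alone prove maleness even when autosomal typing failed
  ypr <- as_profiles(tibble::tibble(sample_id = "S3", locus = "DYS19",
                                    allele_1 = "14", allele_2 = NA_character_), "ystr")
  sex2 <- derive_molecular_sex(pr, ypr)
  expect_equal(sex2$molecular_sex[sex2$sample_id == "S3"], "M")
  # X,X amelogenin plus typed Y loci is a flagged conflict -> ND
  ypr2 <- as_profiles(tibble::tibble(sample_id = "S2", locus = "DYS19",
                                     allele_1 = "14", allele_2 = NA_character_), "ystr")
  expect_warning(sex3 <- derive_molecular_sex(pr, ypr2), "conflict")
  expect_equal(sex3$molecular_sex[sex3$sample_id == "S2"], "ND")
  expect_true(sex3$conflict[sex3$sample_id == "S2"])
})

test_that("panels validate labels and fittability", {
  pr <- tiny_autosomal()
  labels <- c(S1 = "A", S2 = "A", S3 = "B")
  p <- new_panel(pr, labels)
  expect_equal(p$class_set, c("A", "B"))
  expect_error(new_panel(pr, labels[1:2]), "labels missing")
  expect_error(strbga:::check_fittable_panel(p), ">= 2 classes")
})

test_that("the built-in casebook matches its published structure", {
  cb <- builtin_casebook()
  expect_equal(nrow(cb), 24)
  expect_equal(sum(!is.na(cb$known_provenance)), 9)
  e12 <- cb[cb$case_id == "Evidence 12", ]
  expect_equal(e12$physical_ancestry, "European")
  expect_equal(c(e12$str_call, e12$y_call, e12$mt_call), c("Eur_Am", "EU", "AF"))
  expect_equal(e12$known_provenance, "Morocco")
  e10 <- cb[cb$case_id == "Evidence 10", ]
  expect_equal(e10$physical_sex, "IND")
  expect_equal(e10$molecular_sex, "F")
})
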