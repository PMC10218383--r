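Package: strbga
Title: Biogeographical Ancestry and Sex Inference from Forensic STR and
    Mitochondrial Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the sex and biogeographical ancestry of
    unidentified skeletal remains from routine forensic genetic markers:
    autosomal short tandem repeats (STRs), Y-chromosome STR haplotypes and
    mitochondrial DNA. Provides profile readers with explicit missing-locus
    bookkeeping, multi-allelic feature encodings, a partial least squares
    discriminant analysis (PLS-DA) classifier fitted by NIPALS with repeated
    double cross-validation for latent-variable selection, per-query model
    adaptation for partial profiles, deterministic haplogroup-to-region
    mapping, simulation of population-structured reference panels under the
    Balding-Nichols model, and a concordance engine comparing physical,
    molecular and antemortem determinations of sex and ancestry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    mixOmics,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
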