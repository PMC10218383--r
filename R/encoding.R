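#' Feature vocabularies
#'
#' A vocabulary fixes the ordered set of numeric features a marker system is
#' encoded on, so that panels and queries always agree column-for-column:
#'
#' * autosomal: one feature per (locus, allele) pair observed at least
#'   `min_count` times in the panel; the encoded value is the allele dosage
#'   (0, 1 or 2);
#' * Y-STR: one numeric slot per locus copy (multi-copy loci are split into
#'   `<locus>_a`/`<locus>_b`); the encoded value is the repeat count itself,
#'   which preserves the single-step mutational metric;
#' * mtDNA: one binary presence/absence feature per rCRS position
#'   polymorphic in at least `min_count` panel members.
#'
#' @param panel a [new_panel()] reference panel.
#' @param min_count minimum panel support for a feature (default 1,
#'   appropriate for desk-scale panels).
#' @return a `bga_vocabulary`: tibble of feature keys plus a `marker_kind`.
#' @export
build_vocabulary <- function(panel, min_count = 1) {
  stopifnot(inherits(panel, "bga_panel"))
  kind <- marker_kind(panel$profiles)
  tb <- tibble::as_tibble(panel$profiles)
  if (!nrow(tb)) stop_strbga("empty panel")
  feats <- switch(kind,
    autosomal = {
      long <- tb |>
        dplyr::filter(.data$locus != "AMEL") |>
        tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
        dplyr::count(.data$locus, .data$allele)
      long |>
        dplyr::filter(.data$n >= min_count) |>
        dplyr::arrange(.data$locus, as.numeric(.data$allele)) |>
        dplyr::transmute(feature = paste0(.data$locus, ":", .data$allele),
                         locus = .data$locus, allele = .data$allele)
    },
    ystr = {
      loci <- unique(tb$locus[tb$locus != "AMEL"])
      purrr::map_dfr(loci, function(lc) {
        if (lc %in% Y_MULTICOPY) {
          tibble::tibble(feature = paste0(lc, c("_a", "_b")),
                         locus = lc, allele = NA_character_)
        } else {
          tibble::tibble(feature = lc, locus = lc, allele = NA_character_)
        }
      })
    },
    mtdna = {
      if (!any(tb$has_variants)) {
        stop_strbga("mtDNA panel carries no variant lists; haplogroup-only ",
                    "records are handled by map_haplogroup()")
      }
      counts <- tb |>
        dplyr::filter(!is.na(.data$position), .data$base != "N") |>
        dplyr::distinct(.data$sample_id, .data$position) |>
        dplyr::count(.data$position)
      counts |>
        dplyr::filter(.data$n >= min_count) |>
        dplyr::arrange(.data$position) |>
        dplyr::transmute(feature = as.character(.data$position),
                         locus = as.character(.data$position),
                         allele = NA_character_)
    })
  if (!nrow(feats)) stop_strbga("vocabulary is empty at min_count = ", min_count)
  structure(feats, marker_kind = kind,
            class = c("bga_vocabulary", class(tibble::tibble())))
}

#' Encode profiles on a vocabulary
#'
#' Produces an n-samples by n-features numeric matrix plus a boolean mask of
#' the same shape flagging entries that carry no information (untyped loci,
#' no-call positions). Masked entries are excluded from scaling and fitting
#' downstream; they are never imputed as zero. Alleles observed in a query
#' but absent from the vocabulary contribute nothing (a message is emitted).
#'
#' @param profiles a `bga_profiles` tibble of the vocabulary's marker kind.
#' @param vocab a [build_vocabulary()] result.
#' @return a `bga_feature_matrix`: list with `values` (matrix), `missing`
#'   (logical matrix, `TRUE` = no information), `sample_id`, `vocabulary`.
#' @export
encode_profiles <- function(profiles, vocab) {
  kind <- marker_kind(profiles)
  if (!identical(kind, attr(vocab, "marker_kind"))) {
    stop_strbga("vocabulary is for ", attr(vocab, "marker_kind"),
                " but profiles are ", kind)
  }
  switch(kind,
    autosomal = encode_autosomal(profiles, vocab),
    ystr      = encode_y(profiles, vocab),
    mtdna     = encode_mt(profiles, vocab))
}

new_feature_matrix <- function(values, missing, sample_id, vocab) {
  dimnames(values) <- list(sample_id, vocab$feature)
  dimnames(missing) <- dimnames(values)
  structure(list(values = values, missing = missing,
                 sample_id = sample_id, vocabulary = vocab),
            class = "bga_feature_matrix")
}

#' @export
print.bga_feature_matrix <- function(x, ...) {
  cat("<bga_feature_matrix> ", length(x$sample_id), " samples x ",
      ncol(x$values), " features (", attr(x$vocabulary, "marker_kind"),
      "), ", sum(x$missing), " masked entries\n", sep = "")
  invisible(x)
}

encode_autosomal <- function(profiles, vocab) {
  tb <- tibble::as_tibble(profiles) |> dplyr::filter(.data$locus != "AMEL")
  ids <- unique(profiles$sample_id)
  p <- nrow(vocab)
  values <- matrix(0, length(ids), p)
  missing <- matrix(TRUE, length(ids), p)
  feat_of <- setNames(seq_len(p), vocab$feature)
  cols_of_locus <- split(seq_len(p), vocab$locus)
  unknown <- character(0)
  for (i in seq_along(ids)) {
    sub <- tb[tb$sample_id == ids[i], ]
    for (r in seq_len(nrow(sub))) {
      lc <- sub$locus[r]
      cols <- cols_of_locus[[lc]]
      if (is.null(cols)) next      # locus absent from panel vocabulary
      missing[i, cols] <- FALSE    # typed locus: all its features informative
      for (al in c(sub$allele_1[r], sub$allele_2[r])) {
        j <- feat_of[paste0(lc, ":", al)]
        if (is.na(j)) unknown <- c(unknown, paste0(lc, ":", al))
        else values[i, j] <- values[i, j] + 1
      }
    }
  }
  if (length(unknown)) {
    message("alleles absent from vocabulary (contribute nothing): ",
            paste(unique(unknown), collapse = ", "))
  }
  new_feature_matrix(values, missing, ids, vocab)
}

encode_y <- function(profiles, vocab) {
  tb <- tibble::as_tibble(profiles)
  ids <- unique(profiles$sample_id)
  p <- nrow(vocab)
  values <- matrix(0, length(ids), p)
  missing <- matrix(TRUE, length(ids), p)
  feat_of <- setNames(seq_len(p), vocab$feature)
  for (i in seq_along(ids)) {
    sub <- tb[tb$sample_id == ids[i], ]
    for (r in seq_len(nrow(sub))) {
      lc <- sub$locus[r]
      if (lc %in% Y_MULTICOPY) {
        ja <- feat_of[paste0(lc, "_a")]; jb <- feat_of[paste0(lc, "_b")]
        if (is.na(ja)) next
        a2 <- if (is.na(sub$allele_2[r])) sub$allele_1[r] else sub$allele_2[r]
        values[i, ja] <- as.numeric(sub$allele_1[r]); missing[i, ja] <- FALSE
        values[i, jb] <- as.numeric(a2);              missing[i, jb] <- FALSE
      } else {
        j <- feat_of[lc]
        if (is.na(j)) next
        values[i, j] <- as.numeric(sub$allele_1[r]); missing[i, j] <- FALSE
      }
    }
  }
  new_feature_matrix(values, missing, ids, vocab)
}

encode_mt <- function(profiles, vocab) {
  tb <- tibble::as_tibble(profiles)
  no_var <- tb |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(hv = any(.data$has_variants), .groups = "drop")
  if (any(!no_var$hv)) {
    stop_strbga("haplogroup-only mtDNA record(s) cannot be encoded (",
                paste(no_var$sample_id[!no_var$hv], collapse = ", "),
                "); use map_haplogroup() for label-based assignment")
  }
  ids <- unique(profiles$sample_id)
  pos <- as.integer(vocab$locus)
  values <- matrix(0, length(ids), nrow(vocab))
  missing <- matrix(FALSE, length(ids), nrow(vocab))
  for (i in seq_along(ids)) {
    sub <- tb[tb$sample_id == ids[i] & !is.na(tb$position), ]
    called <- match(sub$position[sub$base != "N"], pos)
    values[i, called[!is.na(called)]] <- 1
    ncall <- match(sub$position[sub$base == "N"], pos)
    missing[i, ncall[!is.na(ncall)]] <- TRUE
  }
  new_feature_matrix(values, missing, ids, vocab)
}

#' Restrict a feature matrix to complete rows
#'
#' @param X a `bga_feature_matrix`.
#' @return the same structure keeping only rows without masked entries.
#' @export
complete_rows <- function(X) {
  keep <- rowSums(X$missing) == 0
  new_feature_matrix(X$values[keep, , drop = FALSE],
                     X$missing[keep, , drop = FALSE],
                     X$sample_id[keep], X$vocabulary)
}

# plain numeric matrix from either a bga_feature_matrix (must be complete)
# or a matrix
as_complete_matrix <- function(X) {
  if (inherits(X, "bga_feature_matrix")) {
    if (any(X$missing)) {
      stop_strbga("feature matrix has masked entries; restrict to typed loci ",
                  "(complete_rows()) or use adapt_and_predict() for partial profiles")
    }
    return(X$values)
  }
  as.matrix(X)
}
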