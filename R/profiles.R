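#' Genetic profile tables
#'
#' Profiles of one marker system are stored as a tidy tibble of class
#' `bga_profiles` with a `marker_kind` attribute:
#'
#' * `autosomal` — one row per typed locus: `sample_id`, `locus`,
#'   `allele_1`, `allele_2`. Homozygotes repeat the allele; loci that failed
#'   to type are simply absent (never encoded as 0). Amelogenin travels as
#'   locus `"AMEL"` with alleles `X`/`Y`.
#' * `ystr` — one row per typed locus: `sample_id`, `locus`, `allele_1`,
#'   `allele_2`. `allele_2` is `NA` except at designated multi-copy loci
#'   (DYS385), where the two copies are stored sorted ascending.
#' * `mtdna` — one row per variant relative to the rCRS plus the sample's
#'   haplogroup label: `sample_id`, `haplogroup`, `has_variants`, `position`,
#'   `base`. `has_variants` records whether the variant list was observed at
#'   all: a sequenced, rCRS-identical sample has `has_variants = TRUE` and a
#'   single all-`NA` variant row, while a haplogroup-only record has
#'   `has_variants = FALSE`. Base `"N"` marks a no-call at a position.
#'
#' Allele designations are exact decimal strings compared numerically, so
#' the microvariant 9.3 is a different allele from 9.
#'
#' @param x a data frame with the columns above.
#' @param marker_kind one of `"autosomal"`, `"ystr"`, `"mtdna"`.
#' @return a `bga_profiles` tibble.
#' @export
as_profiles <- function(x, marker_kind) {
  marker_kind <- check_marker_kind(marker_kind)
  x <- tibble::as_tibble(x)
  validate_profiles(x, marker_kind)
  structure(x, marker_kind = marker_kind,
            class = c("bga_profiles", class(tibble::tibble())))
}

#' @export
#' @rdname as_profiles
marker_kind <- function(x) attr(x, "marker_kind")

validate_profiles <- function(x, marker_kind) {
  if (marker_kind %in% c("autosomal", "ystr")) {
    need <- c("sample_id", "locus", "allele_1", "allele_2")
    if (!all(need %in% names(x))) {
      stop_strbga("profile table must have columns ", paste(need, collapse = ", "))
    }
    non_amel <- x[x$locus != "AMEL", ]
    if (marker_kind == "autosomal" && anyNA(non_amel$allele_2)) {
      stop_strbga("autosomal loci need exactly 2 allele entries ",
                  "(repeat the allele for homozygotes)")
    }
    alle <- c(non_amel$allele_1, non_amel$allele_2)
    alle <- alle[!is.na(alle)]
    bad <- alle[!valid_allele_token(alle)]
    if (length(bad)) {
      stop_strbga("malformed allele designation(s): ",
                  paste(unique(bad), collapse = ", "))
    }
    if (marker_kind == "ystr") {
      two <- non_amel[!is.na(non_amel$allele_2), ]
      if (nrow(two) && !all(two$locus %in% Y_MULTICOPY)) {
        stop_strbga("two alleles at single-copy Y locus: ",
                    paste(unique(setdiff(two$locus, Y_MULTICOPY)), collapse = ", "))
      }
    }
    dup <- x |>
      dplyr::count(.data$sample_id, .data$locus) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      stop_strbga("duplicated locus within sample: ",
                  paste(dup$sample_id, dup$locus, sep = "/", collapse = ", "))
    }
  } else {
    need <- c("sample_id", "haplogroup", "has_variants", "position", "base")
    if (!all(need %in% names(x))) {
      stop_strbga("mtDNA profile table must have columns ", paste(need, collapse = ", "))
    }
    pos <- x$position[!is.na(x$position)]
    if (length(pos) && (any(pos < 1) || any(pos > RCRS_LENGTH))) {
      stop_strbga("variant positions must lie in 1..", RCRS_LENGTH)
    }
    per <- x |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        any_info = any(!is.na(.data$haplogroup)) || any(.data$has_variants),
        .groups = "drop")
    if (any(!per$any_info)) {
      stop_strbga("mtDNA record without haplogroup or variant list: ",
                  paste(per$sample_id[!per$any_info], collapse = ", "))
    }
  }
  invisible(x)
}

#' Read genetic profiles from a wide CSV
#'
#' The on-disk layout is one row per sample, comma-separated, UTF-8:
#'
#' * autosomal: a `sample_id` column plus paired allele columns
#'   `<locus>_1`, `<locus>_2` (including `AMEL_1`/`AMEL_2` if typed);
#' * Y-STR: a `sample_id` column plus one column per locus; multi-copy
#'   loci hold both values in one (quoted) cell, e.g. `"11,14"`;
#' * mtDNA: columns `sample_id`, `haplogroup`, `variants`, the last a
#'   `;`-separated list of `<position><base>` tokens (e.g. `73G;263G`), or
#'   the literal `rCRS` for a sequenced sample identical to the reference.
#'
#' Blank cells (and the tokens `NA`/`ND`) mean the locus was not typed and
#' become absent loci, never zero alleles.
#'
#' @param path path to a CSV file.
#' @param marker_kind `"autosomal"`, `"ystr"` or `"mtdna"`.
#' @return a [as_profiles()] tibble.
#' @export
read_profiles <- function(path, marker_kind) {
  marker_kind <- check_marker_kind(marker_kind)
  if (!file.exists(path)) stop_strbga("no such file: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sample_id" %in% names(raw)) {
    stop_strbga(path, ": header must declare a sample_id column")
  }
  if (anyDuplicated(raw$sample_id)) {
    stop_strbga(path, ": duplicate sample_id: ",
                paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  }
  switch(marker_kind,
    autosomal = parse_autosomal(raw, path),
    ystr      = parse_ystr(raw, path),
    mtdna     = parse_mtdna(raw, path))
}

parse_autosomal <- function(raw, path) {
  allele_cols <- setdiff(names(raw), c("sample_id", "class"))
  bad <- allele_cols[!grepl("_[12]$", allele_cols)]
  if (length(bad)) {
    stop_strbga(path, ": autosomal allele columns must be <locus>_1/<locus>_2; got ",
                paste(bad, collapse = ", "))
  }
  loci <- unique(sub("_[12]$", "", allele_cols))
  rows <- purrr::map(loci, function(lc) {
    c1 <- paste0(lc, "_1"); c2 <- paste0(lc, "_2")
    if (!all(c(c1, c2) %in% names(raw))) {
      stop_strbga(path, ": locus ", lc, " is missing one of its paired columns")
    }
    a1 <- raw[[c1]]; a2 <- raw[[c2]]
    m1 <- is_missing_token(a1); m2 <- is_missing_token(a2)
    if (any(m1 != m2)) {
      i <- which(m1 != m2)[1]
      stop_strbga(path, ": half-typed locus at row ", i, " (sample ",
                  raw$sample_id[i], "), column ", if (m1[i]) c1 else c2)
    }
    keep <- !m1
    if (!any(keep)) return(NULL)
    check_cells(a1[keep], raw$sample_id[keep], c1, path, amel = lc == "AMEL")
    check_cells(a2[keep], raw$sample_id[keep], c2, path, amel = lc == "AMEL")
    tibble::tibble(sample_id = raw$sample_id[keep], locus = lc,
                   allele_1 = normalise_allele(a1[keep]),
                   allele_2 = normalise_allele(a2[keep]))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(match(.data$sample_id, raw$sample_id), match(.data$locus, loci))
  as_profiles(out, "autosomal")
}

check_cells <- function(vals, ids, col, path, amel = FALSE) {
  ok <- if (amel) vals %in% c("X", "Y") else valid_allele_token(vals)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop_strbga(path, ": malformed allele '", vals[i], "' in column ", col,
                ", sample ", ids[i])
  }
}

parse_ystr <- function(raw, path) {
  loci <- setdiff(names(raw), c("sample_id", "class"))
  rows <- purrr::map(loci, function(lc) {
    cell <- raw[[lc]]
    keep <- !is_missing_token(cell)
    if (!any(keep)) return(NULL)
    parts <- stringr::str_split(trimws(cell[keep]), ",")
    n_all <- lengths(parts)
    if (any(n_all > 2)) {
      i <- which(n_all > 2)[1]
      stop_strbga(path, ": more than two alleles at ", lc, ", sample ",
                  raw$sample_id[keep][i])
    }
    multi <- n_all == 2
    if (any(multi) && !lc %in% Y_MULTICOPY) {
      i <- which(multi)[1]
      stop_strbga(path, ": two alleles at single-copy locus ", lc,
                  ", sample ", raw$sample_id[keep][i])
    }
    flat <- trimws(unlist(parts))
    bad <- flat[!valid_allele_token(flat)]
    if (length(bad)) {
      stop_strbga(path, ": malformed allele '", bad[1], "' in column ", lc)
    }
    sorted <- purrr::map(parts, function(p) {
      p <- normalise_allele(p)
      p[order(as.numeric(p))]
    })
    tibble::tibble(
      sample_id = raw$sample_id[keep], locus = lc,
      allele_1 = purrr::map_chr(sorted, 1),
      allele_2 = purrr::map_chr(sorted, function(p) if (length(p) == 2) p[2] else NA_character_))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(match(.data$sample_id, raw$sample_id), match(.data$locus, loci))
  as_profiles(out, "ystr")
}

parse_mtdna <- function(raw, path) {
  if (!"haplogroup" %in% names(raw)) raw$haplogroup <- NA_character_
  if (!"variants" %in% names(raw)) raw$variants <- NA_character_
  rows <- purrr::pmap(list(raw$sample_id, raw$haplogroup, raw$variants),
                      function(sid, hg, var) {
    hg <- if (is_missing_token(hg)) NA_character_ else trimws(hg)
    if (is_missing_token(var)) {
      if (is.na(hg)) {
        stop_strbga(path, ": sample ", sid,
                    " has neither haplogroup nor variant list")
      }
      return(tibble::tibble(sample_id = sid, haplogroup = hg,
                            has_variants = FALSE,
                            position = NA_integer_, base = NA_character_))
    }
    var <- trimws(var)
    if (toupper(var) %in% c("RCRS", ".")) {
      return(tibble::tibble(sample_id = sid, haplogroup = hg,
                            has_variants = TRUE,
                            position = NA_integer_, base = NA_character_))
    }
    toks <- trimws(stringr::str_split(var, ";")[[1]])
    toks <- toks[toks != ""]
    m <- stringr::str_match(toks, "^([0-9]+)([ACGTNacgtn])$")
    if (anyNA(m[, 1])) {
      stop_strbga(path, ": malformed variant token '", toks[which(is.na(m[, 1]))[1]],
                  "' for sample ", sid)
    }
    pos <- as.integer(m[, 2])
    if (any(pos < 1 | pos > RCRS_LENGTH)) {
      stop_strbga(path, ": variant position outside 1..", RCRS_LENGTH,
                  " for sample ", sid)
    }
    tibble::tibble(sample_id = sid, haplogroup = hg, has_variants = TRUE,
                   position = pos, base = toupper(m[, 3]))
  })
  as_profiles(dplyr::bind_rows(rows), "mtdna")
}

#' Write genetic profiles back to the wide CSV layout
#'
#' Inverse of [read_profiles()]: for a valid file,
#' `write_profiles(read_profiles(f), g)` reproduces the table cell for cell.
#'
#' @param profiles a `bga_profiles` tibble.
#' @param path output CSV path.
#' @param class_labels optional named character vector (by sample id) written
#'   as a `class` column, used for labelled reference panels.
#' @export
write_profiles <- function(profiles, path, class_labels = NULL) {
  kind <- marker_kind(profiles)
  if (is.null(kind)) stop_strbga("not a bga_profiles object")
  wide <- switch(kind,
    autosomal = {
      loci <- unique(profiles$locus)
      out <- tidyr::pivot_wider(
        tibble::as_tibble(profiles), id_cols = "sample_id",
        names_from = "locus", values_from = c("allele_1", "allele_2"),
        names_glue = "{locus}_{ifelse(.value == 'allele_1', 1, 2)}")
      ord <- c("sample_id", as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
      out[, ord]
    },
    ystr = {
      tb <- tibble::as_tibble(profiles)
      tb$cell <- ifelse(is.na(tb$allele_2), tb$allele_1,
                        paste(tb$allele_1, tb$allele_2, sep = ","))
      tidyr::pivot_wider(tb, id_cols = "sample_id",
                         names_from = "locus", values_from = "cell")
    },
    mtdna = {
      tibble::as_tibble(profiles) |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(
          haplogroup = dplyr::first(.data$haplogroup),
          variants = if (!any(.data$has_variants)) NA_character_
                     else if (all(is.na(.data$position))) "rCRS"
                     else paste0(.data$position[!is.na(.data$position)],
                                 .data$base[!is.na(.data$position)], collapse = ";"),
          .groups = "drop")
    })
  if (!is.null(class_labels)) {
    wide$class <- unname(class_labels[wide$sample_id])
  }
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Loci typed per sample
#'
#' Counts successfully typed loci (autosomal/Y, amelogenin excluded) or
#' called variant positions (mtDNA), the quantity the partial-profile
#' no-call rules are expressed in.
#'
#' @param profiles a `bga_profiles` tibble.
#' @return a tibble `sample_id`, `n_loci`.
#' @export
count_typed_loci <- function(profiles) {
  kind <- marker_kind(profiles)
  tb <- tibble::as_tibble(profiles)
  if (kind %in% c("autosomal", "ystr")) {
    tb |>
      dplyr::filter(.data$locus != "AMEL") |>
      dplyr::count(.data$sample_id, name = "n_loci")
  } else {
    tb |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(n_loci = sum(!is.na(.data$position) & .data$base != "N"),
                       .groups = "drop")
  }
}

#' Molecular sex from amelogenin and Y-STR evidence
#'
#' A sample is called male if amelogenin shows X,Y or any Y-STR locus typed;
#' female if amelogenin shows X,X with no Y evidence; not determinable (ND)
#' when neither marker gave a result. An X,X amelogenin together with typed
#' Y loci is contradictory: the sample is flagged and returned as ND with a
#' warning.
#'
#' @param profiles autosomal `bga_profiles` (may be empty).
#' @param y_profiles optional Y-STR `bga_profiles`.
#' @return tibble `sample_id`, `molecular_sex` (`"M"`, `"F"`, `"ND"`),
#'   `conflict`.
#' @export
derive_molecular_sex <- function(profiles, y_profiles = NULL) {
  tb <- tibble::as_tibble(profiles)
  ids <- unique(c(tb$sample_id,
                  if (!is.null(y_profiles)) y_profiles$sample_id))
  amel <- tb |>
    dplyr::filter(.data$locus == "AMEL") |>
    dplyr::select("sample_id", "allele_1", "allele_2")
  y_typed <- if (is.null(y_profiles)) character(0) else {
    count_typed_loci(y_profiles) |>
      dplyr::filter(.data$n_loci > 0) |>
      dplyr::pull("sample_id")
  }
  out <- purrr::map(ids, function(sid) {
    am <- amel[amel$sample_id == sid, ]
    has_y <- sid %in% y_typed
    if (nrow(am)) {
      is_xy <- "Y" %in% c(am$allele_1, am$allele_2)
      if (is_xy) return(tibble::tibble(sample_id = sid, molecular_sex = "M", conflict = FALSE))
      if (has_y) {
        warn_strbga("sample ", sid, ": amelogenin X,X conflicts with typed Y loci; returning ND")
        return(tibble::tibble(sample_id = sid, molecular_sex = "ND", conflict = TRUE))
      }
      return(tibble::tibble(sample_id = sid, molecular_sex = "F", conflict = FALSE))
    }
    if (has_y) return(tibble::tibble(sample_id = sid, molecular_sex = "M", conflict = FALSE))
    tibble::tibble(sample_id = sid, molecular_sex = "ND", conflict = FALSE)
  })
  dplyr::bind_rows(out)
}

#' Reference panels
#'
#' A reference panel couples profiles of one marker kind with a class label
#' per sample. Model fitting requires at least two classes with at least two
#' samples each.
#'
#' @param profiles a `bga_profiles` tibble.
#' @param labels named character vector or tibble (`sample_id`, `class`).
#' @param class_set ordered class names; defaults to order of appearance.
#' @param provenance free-text description of where the panel comes from.
#' @return a `bga_panel` list.
#' @export
new_panel <- function(profiles, labels, class_set = NULL, provenance = "") {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$class, labels$sample_id)
  }
  ids <- unique(profiles$sample_id)
  if (!all(ids %in% names(labels))) {
    stop_strbga("panel labels missing for: ",
                paste(head(setdiff(ids, names(labels))), collapse = ", "))
  }
  labels <- labels[ids]
  if (is.null(class_set)) class_set <- unique(unname(labels))
  if (!all(labels %in% class_set)) {
    stop_strbga("labels outside class_set: ",
                paste(unique(setdiff(labels, class_set)), collapse = ", "))
  }
  structure(list(profiles = profiles, labels = labels,
                 class_set = class_set, provenance = provenance),
            class = "bga_panel")
}

#' @export
print.bga_panel <- function(x, ...) {
  cat("<bga_panel> ", marker_kind(x$profiles), ", ",
      length(x$labels), " samples, classes: ",
      paste(sprintf("%s (%d)", x$class_set,
                    tabulate(factor(x$labels, x$class_set),
                             nbins = length(x$class_set))), collapse = ", "),
      "\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

check_fittable_panel <- function(panel) {
  tab <- table(factor(panel$labels, panel$class_set))
  if (sum(tab >= 2) < 2) {
    stop_strbga("model fitting needs >= 2 classes with >= 2 samples each")
  }
  invisible(panel)
}

#' Read a labelled reference panel from CSV
#'
#' Same layout as [read_profiles()] plus a `class` column.
#'
#' @inheritParams read_profiles
#' @param provenance free-text provenance note.
#' @return a `bga_panel`.
#' @export
read_panel <- function(path, marker_kind, provenance = path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"class" %in% names(raw)) stop_strbga(path, ": panel CSV needs a class column")
  profiles <- read_profiles(path, marker_kind)
  new_panel(profiles, setNames(raw$class, raw$sample_id), provenance = provenance)
}
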