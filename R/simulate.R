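#' Simulate an autosomal STR reference panel (Balding–Nichols model)
#'
#' Ancestral allele frequencies at each locus are drawn from a flat
#' Dirichlet; each class (population) then receives its own frequencies
#' from a Dirichlet centred on the ancestral vector with concentration
#' `(1 - fst) / fst`, the Balding–Nichols model, so `fst` is a single
#' interpretable separability knob. Genotypes are sampled under
#' Hardy–Weinberg equilibrium within class. At `fst = 0` every class shares
#' the ancestral frequencies exactly and the panel carries no class signal.
#'
#' The default class sizes (181, 49, 171) mirror, at half scale, the
#' composition of a standard three-population forensic STR reference
#' dataset (European American : Asian : African American of 361 : 97 : 341).
#'
#' @param n_per_class samples per class.
#' @param class_names class labels.
#' @param n_loci loci (default 23, a modern autosomal multiplex).
#' @param alleles_per_locus alleles segregating per locus (default 8;
#'   allele designations are consecutive repeat counts from 8).
#' @param fst Balding–Nichols divergence, in `[0, 0.5]`.
#' @param seed RNG seed; the panel is reproducible from it.
#' @return list with `panel` (a [new_panel()]) and `frequencies` (tibble of
#'   the true per-class allele frequencies).
#' @export
simulate_autosomal_panel <- function(n_per_class = c(181, 49, 171),
                                     class_names = c("Eur_Am", "Asian", "Afr_Am"),
                                     n_loci = 23, alleles_per_locus = 8,
                                     fst = 0.05, seed = 1) {
  stopifnot(length(n_per_class) == length(class_names),
            all(n_per_class > 0), n_loci > 0, alleles_per_locus >= 2)
  if (fst < 0 || fst > 0.5) stop_strbga("fst must lie in [0, 0.5]")
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  alleles <- as.character(seq(8, length.out = alleles_per_locus))
  freqs <- list(); rows <- list()
  for (lc in loci) {
    p_anc <- rdirichlet1(rep(1, alleles_per_locus))
    class_freq <- lapply(class_names, function(cl) {
      if (fst == 0) p_anc else rdirichlet1(p_anc * (1 - fst) / fst)
    })
    names(class_freq) <- class_names
    freqs[[lc]] <- purrr::imap_dfr(class_freq, function(f, cl) {
      tibble::tibble(locus = lc, class = cl, allele = alleles, freq = f)
    })
    for (ci in seq_along(class_names)) {
      n <- n_per_class[ci]
      g1 <- sample(alleles, n, replace = TRUE, prob = class_freq[[ci]])
      g2 <- sample(alleles, n, replace = TRUE, prob = class_freq[[ci]])
      rows[[paste(lc, ci)]] <- tibble::tibble(
        sample_id = class_sample_ids(class_names[ci], n),
        locus = lc,
        allele_1 = pmin(as.numeric(g1), as.numeric(g2)),
        allele_2 = pmax(as.numeric(g1), as.numeric(g2)))
    }
  }
  tb <- dplyr::bind_rows(rows) |>
    dplyr::mutate(allele_1 = as.character(.data$allele_1),
                  allele_2 = as.character(.data$allele_2)) |>
    dplyr::arrange(match(.data$sample_id, unlist(purrr::map2(class_names, n_per_class, class_sample_ids))),
                   match(.data$locus, loci))
  labels <- setNames(rep(class_names, n_per_class),
                     unlist(purrr::map2(class_names, n_per_class, class_sample_ids)))
  list(panel = new_panel(as_profiles(tb, "autosomal"), labels,
                         class_set = class_names,
                         provenance = sprintf("Balding-Nichols simulation, fst = %g, seed = %d", fst, seed)),
       frequencies = dplyr::bind_rows(freqs))
}

class_sample_ids <- function(class_name, n) {
  sprintf("%s_%03d", class_name, seq_len(n))
}

#' Simulate a Y-STR haplotype reference panel
#'
#' Each class descends from a founder haplotype of integer repeat counts;
#' every individual receives, independently at each locus, a symmetric
#' single-step mutation (+1 or -1 repeat) with probability `mutation_rate`.
#' With rate 0 all haplotypes in a class equal the founder. The default
#' class sizes scale a five-continent Y-haplotype reference set
#' (3651 : 1327 : 13227 : 733 : 556) down by a factor of 50.
#'
#' @param n_per_class samples per class.
#' @param class_names class labels.
#' @param n_loci Y loci (default 23).
#' @param mutation_rate per-locus probability of a single +/-1 step.
#' @param founders optional matrix (class x locus) of founder repeat
#'   counts; defaults to independent draws in 10..20.
#' @param seed RNG seed.
#' @return list with `panel` and `founders`.
#' @export
simulate_y_panel <- function(n_per_class = c(73, 27, 265, 15, 11),
                             class_names = c("Asian", "African", "European",
                                             "Mixed American", "Native American"),
                             n_loci = 23, mutation_rate = 0.05,
                             founders = NULL, seed = 1) {
  stopifnot(length(n_per_class) == length(class_names), all(n_per_class > 0))
  set.seed(seed)
  loci <- sprintf("DYS%03d", 400 + seq_len(n_loci))
  if (is.null(founders)) {
    founders <- matrix(sample(10:20, length(class_names) * n_loci, replace = TRUE),
                       length(class_names), n_loci,
                       dimnames = list(class_names, loci))
  } else {
    stopifnot(nrow(founders) == length(class_names), ncol(founders) == n_loci)
    dimnames(founders) <- list(class_names, loci)
  }
  rows <- list()
  for (ci in seq_along(class_names)) {
    n <- n_per_class[ci]
    ids <- class_sample_ids(class_names[ci], n)
    for (lj in seq_len(n_loci)) {
      step <- stats::rbinom(n, 1, mutation_rate) *
        sample(c(-1L, 1L), n, replace = TRUE)
      rows[[paste(ci, lj)]] <- tibble::tibble(
        sample_id = ids, locus = loci[lj],
        allele_1 = as.character(pmax(founders[ci, lj] + step, 1L)),
        allele_2 = NA_character_)
    }
  }
  ids_all <- unlist(purrr::map2(class_names, n_per_class, class_sample_ids))
  tb <- dplyr::bind_rows(rows) |>
    dplyr::arrange(match(.data$sample_id, ids_all), match(.data$locus, loci))
  labels <- setNames(rep(class_names, n_per_class), ids_all)
  list(panel = new_panel(as_profiles(tb, "ystr"), labels,
                         class_set = class_names,
                         provenance = sprintf("stepwise-mutation simulation, rate = %g, seed = %d", mutation_rate, seed)),
       founders = founders)
}

#' Simulate an mtDNA variant-list reference panel
#'
#' Each class owns a block of `block_size` diagnostic positions carried at
#' frequency 0.9 within the class and 0.05 elsewhere; individuals
#' additionally pick up private noise variants (Poisson, mean
#' `noise_mean`) at the remaining catalogued positions. With block size 0
#' classes are exchangeable and classification is at chance. Default class
#' sizes scale a five-continent mitogenome reference set
#' (6021 : 3762 : 11421 : 2984 : 1030) down by a factor of 100.
#'
#' @param n_per_class samples per class.
#' @param class_names class labels.
#' @param block_size diagnostic positions per class.
#' @param n_positions catalogued polymorphic positions overall.
#' @param in_freq,out_freq diagnostic-variant frequency inside/outside the
#'   owning class.
#' @param noise_mean mean number of private noise variants per individual.
#' @param seed RNG seed.
#' @return list with `panel` and `diagnostic_positions` (tibble class,
#'   position).
#' @export
simulate_mt_panel <- function(n_per_class = c(60, 38, 114, 30, 10),
                              class_names = c("Asia", "Africa", "Europe",
                                              "America", "Oceania"),
                              block_size = 10, n_positions = 200,
                              in_freq = 0.9, out_freq = 0.05,
                              noise_mean = 1, seed = 1) {
  stopifnot(length(n_per_class) == length(class_names), all(n_per_class > 0),
            block_size >= 0,
            n_positions >= block_size * length(class_names))
  set.seed(seed)
  positions <- sort(sample(seq_len(RCRS_LENGTH), n_positions))
  blocks <- if (block_size > 0) {
    split(positions[seq_len(block_size * length(class_names))],
          rep(class_names, each = block_size))
  } else {
    setNames(rep(list(integer(0)), length(class_names)), class_names)
  }
  rows <- list()
  for (ci in seq_along(class_names)) {
    cl <- class_names[ci]
    ids <- class_sample_ids(cl, n_per_class[ci])
    for (i in seq_along(ids)) {
      carried <- unlist(lapply(class_names, function(other) {
        f <- if (other == cl) in_freq else out_freq
        b <- blocks[[other]]
        b[stats::runif(length(b)) < f]
      }))
      free <- setdiff(positions, unlist(blocks))
      n_noise <- min(stats::rpois(1, noise_mean), length(free))
      noise <- if (n_noise > 0) sample(free, n_noise) else integer(0)
      var_pos <- sort(unique(c(carried, noise)))
      rows[[paste(ci, i)]] <- if (length(var_pos)) {
        tibble::tibble(sample_id = ids[i], haplogroup = NA_character_,
                       has_variants = TRUE, position = as.integer(var_pos),
                       base = sample(c("A", "C", "G", "T"), length(var_pos),
                                     replace = TRUE))
      } else {
        tibble::tibble(sample_id = ids[i], haplogroup = NA_character_,
                       has_variants = TRUE, position = NA_integer_,
                       base = NA_character_)
      }
    }
  }
  ids_all <- unlist(purrr::map2(class_names, n_per_class, class_sample_ids))
  labels <- setNames(rep(class_names, n_per_class), ids_all)
  list(panel = new_panel(as_profiles(dplyr::bind_rows(rows), "mtdna"), labels,
                         class_set = class_names,
                         provenance = sprintf("diagnostic-block simulation, block = %d, seed = %d", block_size, seed)),
       diagnostic_positions = purrr::imap_dfr(blocks, function(b, cl) {
         tibble::tibble(class = cl, position = b)
       }))
}

#' Remove loci from a profile to emulate degradation
#'
#' Drops typed loci uniformly at random without replacement, producing the
#' partial profiles typical of degraded skeletal DNA. Amelogenin is kept by
#' default so molecular sex survives degradation.
#'
#' @param profiles a `bga_profiles` tibble (autosomal or Y).
#' @param n_drop number of loci to remove per sample (mutually exclusive
#'   with `dropout_rate`).
#' @param dropout_rate probability that each locus drops out.
#' @param seed RNG seed; a fixed seed gives an identical dropout pattern.
#' @param keep_amelogenin protect the AMEL locus from dropout.
#' @return a `bga_profiles` tibble with fewer loci.
#' @export
degrade_profile <- function(profiles, n_drop = NULL, dropout_rate = NULL,
                            seed = 1, keep_amelogenin = TRUE) {
  if (is.null(n_drop) == is.null(dropout_rate)) {
    stop_strbga("give exactly one of n_drop or dropout_rate")
  }
  kind <- marker_kind(profiles)
  if (kind == "mtdna") stop_strbga("degrade_profile() handles locus-based profiles")
  set.seed(seed)
  tb <- tibble::as_tibble(profiles)
  out <- tb |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      droppable <- which(!(keep_amelogenin & df$locus == "AMEL"))
      nd <- if (!is.null(n_drop)) min(n_drop, length(droppable))
            else stats::rbinom(1, length(droppable), dropout_rate)
      if (nd > 0) {
        drop <- sample(droppable, nd)
        df <- df[-drop, , drop = FALSE]
      }
      df
    }) |>
    dplyr::ungroup()
  out <- out[, names(tb)]
  as_profiles(out, kind)
}
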