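#' Simulate reference panels to disk
#'
#' Writes one labelled panel CSV per marker system (autosomal, Y-STR,
#' mtDNA) using the package simulators. Configuration is a nested list (or
#' a YAML/JSON file parsed to one) whose `autosomal`, `ystr` and `mtdna`
#' entries override the simulator defaults.
#'
#' @param out_dir output directory (created if needed).
#' @param config nested list or path to a YAML/JSON config file.
#' @param seed RNG seed applied to every simulator (identical seed, the
#'   same files).
#' @return tibble of written files with sample counts.
#' @export
run_simulate <- function(out_dir, config = list(), seed = 1) {
  config <- load_config(config)
  if (!is.null(config$seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jobs <- list(
    autosomal = list(fun = simulate_autosomal_panel, file = "autosomal_panel.csv"),
    ystr = list(fun = simulate_y_panel, file = "y_panel.csv"),
    mtdna = list(fun = simulate_mt_panel, file = "mt_panel.csv"))
  purrr::imap_dfr(jobs, function(job, kind) {
    args <- modifyList(list(seed = seed), config[[kind]] %||% list())
    sim <- do.call(job$fun, args)
    path <- file.path(out_dir, job$file)
    write_profiles(sim$panel$profiles, path, class_labels = sim$panel$labels)
    tibble::tibble(marker_kind = kind, path = path,
                   n_samples = length(sim$panel$labels),
                   n_classes = length(sim$panel$class_set))
  })
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_strbga("no such config file: ", config)
    if (grepl("\\.json$", config)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_strbga("YAML config needs the yaml package; use JSON instead")
      }
      config <- yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop_strbga("config must be a list or a file path")
  config
}

#' Train a PLS-DA ancestry model with rdCV
#'
#' Reads a labelled panel CSV, encodes it, estimates accuracy by repeated
#' double cross-validation, refits the production model on all samples with
#' the median selected LV count, and serialises the model to JSON.
#'
#' @param panel_csv labelled panel CSV (see [read_panel()]).
#' @param marker_kind marker system of the panel.
#' @param out_model path for the model JSON.
#' @param out_report optional path for the CV report JSON.
#' @param out_scores optional path for a CSV of per-sample LV1..LV3 score
#'   coordinates (for score plots).
#' @param n_repeats,k_outer,k_inner,a_max rdCV controls; see [double_cv()].
#' @param min_count vocabulary support threshold.
#' @param threshold reliability threshold stored in the model.
#' @param seed RNG seed.
#' @return the `bga_cv_report`, invisibly with attribute `model`.
#' @export
run_train <- function(panel_csv, marker_kind, out_model,
                      out_report = NULL, out_scores = NULL,
                      n_repeats = 20, k_outer = 5, k_inner = 5, a_max = 15,
                      min_count = 1, threshold = 0.8, seed = 1) {
  panel <- read_panel(panel_csv, marker_kind)
  check_fittable_panel(panel)
  vocab <- build_vocabulary(panel, min_count)
  X <- complete_rows(encode_profiles(panel$profiles, vocab))
  labels <- panel$labels[X$sample_id]
  report <- double_cv(X, labels, k_outer = k_outer, k_inner = k_inner,
                      a_max = a_max, n_repeats = n_repeats, seed = seed)
  model <- finalize_plsda(X, labels, report, threshold = threshold)
  write_model(model, out_model)
  if (!is.null(out_report)) write_cv_report(report, out_report)
  if (!is.null(out_scores)) {
    sc <- plsda_scores(model)
    keep <- seq_len(min(3, ncol(sc)))
    readr::write_csv(dplyr::bind_cols(
      tibble::tibble(sample_id = X$sample_id, class = labels),
      tibble::as_tibble(sc[, keep, drop = FALSE])), out_scores)
  }
  attr(report, "model") <- model
  invisible(report)
}

write_cv_report <- function(report, path) {
  jsonlite::write_json(list(
    n = report$n, n_repeats = report$n_repeats,
    n_repeats_done = report$n_repeats_done,
    k_outer = report$k_outer, k_inner = report$k_inner,
    a_max = report$a_max, seed = report$seed,
    accuracy = report$accuracy, accuracy_sd = report$accuracy_sd,
    accuracy_per_repeat = report$accuracy_per_repeat,
    chosen_A = report$chosen_A,
    per_class = report$per_class,
    confusion = as.data.frame.matrix(report$confusion)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Predict queries with a trained model
#'
#' Complete queries are predicted directly. Partial queries are handled by
#' per-query adaptation when the training panel is supplied; without a
#' panel they are answered NO_CALL with an explanatory reason. Queries
#' below `min_loci` typed loci are always NO_CALL.
#'
#' @param model_json path to a [write_model()] JSON.
#' @param query_csv query profiles CSV (same layout as [read_profiles()]).
#' @param out_csv output CSV; prediction values are echoed to 2 decimals.
#' @param panel_csv optional training panel CSV enabling adaptation.
#' @param min_loci minimum typed loci for a call; default
#'   [default_min_loci()].
#' @param threshold reliability threshold; default the model's.
#' @param a_max,k_inner adaptation refit controls.
#' @return the predictions tibble, invisibly.
#' @export
run_predict <- function(model_json, query_csv, out_csv, panel_csv = NULL,
                        min_loci = NULL, threshold = NULL,
                        a_max = 15, k_inner = 5) {
  model <- read_model(model_json)
  if (is.null(model$vocabulary)) {
    stop_strbga(model_json, ": model carries no vocabulary; cannot encode queries")
  }
  kind <- attr(model$vocabulary, "marker_kind")
  queries <- read_profiles(query_csv, kind)
  threshold <- threshold %||% model$threshold
  min_loci <- min_loci %||% default_min_loci(kind)
  panel <- if (!is.null(panel_csv)) read_panel(panel_csv, kind)
  X <- encode_profiles(queries, model$vocabulary)
  typed <- count_typed_loci(queries)
  preds <- purrr::map_dfr(seq_along(X$sample_id), function(i) {
    sid <- X$sample_id[i]
    n_typed <- typed$n_loci[match(sid, typed$sample_id)]
    if (is.na(n_typed)) n_typed <- 0L
    if (kind == "mtdna") n_typed <- sum(!X$missing[i, ])
    if (n_typed < min_loci) {
      return(no_call_prediction(sid, model$class_set, n_typed, "low number of loci"))
    }
    complete_on_model <- !any(X$missing[i, colnames(X$missing) %in% model$features])
    if (complete_on_model) {
      Xi <- X$values[i, , drop = FALSE]
      rownames(Xi) <- sid
      pv <- predict_values(model, Xi)
      return(as_prediction(pv, model$class_set, threshold = threshold,
                           n_loci_used = n_typed, sample_id = sid))
    }
    if (is.null(panel)) {
      return(no_call_prediction(sid, model$class_set, n_typed,
                                "partial profile and no panel supplied for adaptation"))
    }
    one <- as_profiles(tibble::as_tibble(queries)[queries$sample_id == sid, ], kind)
    adapt_and_predict(panel, one, min_loci = min_loci, a_max = a_max,
                      k = k_inner, threshold = threshold)
  })
  out <- preds
  pv_cols <- grep("^pv_", names(out), value = TRUE)
  out[pv_cols] <- lapply(out[pv_cols], function(v) sprintf("%.2f", v))
  out$max_pv <- ifelse(is.na(preds$max_pv), "", sprintf("%.2f", preds$max_pv))
  readr::write_csv(out, out_csv, na = "")
  invisible(preds)
}

#' Score casebook concordance from the command line or scripts
#'
#' @param casebook_csv casebook CSV, or `NULL` for the built-in casebook.
#' @param macro_map_json optional JSON with `labels` and `countries` maps
#'   overriding [macro_group_map()] defaults.
#' @param out_json,out_text optional report outputs.
#' @return the `bga_concordance` report, invisibly.
#' @export
run_concordance <- function(casebook_csv = NULL, macro_map_json = NULL,
                            out_json = NULL, out_text = NULL) {
  cb <- if (is.null(casebook_csv)) builtin_casebook() else read_casebook(casebook_csv)
  map <- macro_group_map()
  if (!is.null(macro_map_json)) {
    j <- jsonlite::read_json(macro_map_json, simplifyVector = TRUE)
    map <- macro_group_map(extra_labels = unlist(j$labels),
                           extra_countries = unlist(j$countries))
  }
  rep <- concordance_report(cb, map)
  if (!is.null(out_json)) {
    jsonlite::write_json(concordance_as_list(rep), out_json,
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out_text)) {
    sink(out_text); print(rep); sink()
  }
  invisible(rep)
}

concordance_as_list <- function(rep) {
  list(
    n_cases = rep$n_cases,
    molecular_sex_counts = as.list(rep$molecular_sex_counts),
    sex_agreements = rep$sex_agreements,
    sex_comparable = rep$sex_comparable,
    n_discrepant = rep$n_discrepant,
    discrepant_cases = rep$discrepancies$case_id,
    n_identified = rep$n_identified,
    sex_accuracy_pct = rep$sex_accuracy$rate,
    physical_ancestry_accuracy_pct = rep$physical_accuracy$rate,
    physical_ancestry_failures = rep$physical_accuracy$failures,
    molecular_ancestry_accuracy_pct = rep$molecular_accuracy$rate,
    molecular_ancestry_successes = rep$molecular_accuracy$successes,
    molecular_ancestry_failures = rep$molecular_accuracy$failures)
}

#' In-process command-line entry point
#'
#' Dispatches `simulate`, `train`, `predict` and `concordance` verbs over
#' the `run_*()` functions. An `Rscript` wrapper is installed under
#' `inst/cli/strbga.R`; `bga_cli()` itself takes the argument vector so the
#' same interface is testable in-process.
#'
#' @param args character vector, e.g.
#'   `c("concordance", "--builtin", "--out-json", "report.json")`.
#' @return 0 invisibly on success; errors propagate.
#' @export
bga_cli <- function(args) {
  if (!length(args)) {
    stop_strbga("usage: strbga <simulate|train|predict|concordance> [options]")
  }
  verb <- args[1]
  opts <- parse_cli_opts(args[-1])
  val <- function(name, default = NULL) opts$named[[name]] %||% default
  need <- function(name) val(name) %||% stop_strbga("missing required option --", name)
  switch(verb,
    simulate = {
      files <- run_simulate(out_dir = need("out-dir"),
                            config = val("config", list()),
                            seed = as.integer(val("seed", "1")))
      message(paste(files$path, collapse = "\n"))
    },
    train = {
      panel_csv <- need("panel"); marker <- need("marker")
      out_model <- need("out-model")
      rep <- run_train(panel_csv = panel_csv,
                       marker_kind = marker,
                       out_model = out_model,
                       out_report = val("out-report"),
                       out_scores = val("out-scores"),
                       n_repeats = as.integer(val("repeats", "20")),
                       a_max = as.integer(val("a-max", "15")),
                       seed = as.integer(val("seed", "1")))
      message(sprintf("rdCV pooled accuracy %.3f", rep$accuracy))
    },
    predict = {
      model <- need("model"); queries <- need("queries"); out <- need("out")
      run_predict(model_json = model, query_csv = queries,
                  out_csv = out, panel_csv = val("panel"),
                  min_loci = if (!is.null(val("min-loci"))) as.integer(val("min-loci")),
                  threshold = if (!is.null(val("threshold"))) as.numeric(val("threshold")))
    },
    concordance = {
      run_concordance(
        casebook_csv = if (!"builtin" %in% opts$flags) need("casebook"),
        macro_map_json = val("macro-map"),
        out_json = val("out-json"), out_text = val("out-text"))
    },
    stop_strbga("unknown verb '", verb,
                "'; expected simulate, train, predict or concordance"))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  named <- list(); flags <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_strbga("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      named[[key]] <- args[i + 1]; i <- i + 2
    } else {
      flags <- c(flags, key); i <- i + 1
    }
  }
  list(named = named, flags = flags)
}
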