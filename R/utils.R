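# internal helpers shared across modules

is_missing_token <- function(x) {
  is.na(x) | trimws(x) %in% c("", "NA", "ND", "NO RESULT", "-")
}

#' @noRd
check_marker_kind <- function(marker_kind) {
  match.arg(marker_kind, MARKER_KINDS)
}

# allele designations are kept as exact decimal strings ("9.3" != "9") but
# must parse to a positive number
valid_allele_token <- function(x) {
  grepl("^[0-9]+(\\.[0-9]+)?$", x) & suppressWarnings(as.numeric(x)) > 0
}

# canonical string form so that "12.0" and "12" do not silently diverge
normalise_allele <- function(x) {
  sub("\\.0+$", "", trimws(x))
}

stop_strbga <- function(...) {
  stop(paste0(...), call. = FALSE)
}

warn_strbga <- function(...) {
  warning(paste0(...), call. = FALSE)
}

# truncate (never round) a percentage to one decimal: 6/9 -> 66.6
truncate_pct <- function(successes, n) {
  floor(1000 * successes / n) / 10
}

# Dirichlet sampler via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) {
    # numerically degenerate concentration; fall back to the mode
    g <- alpha
  }
  g / sum(g)
}
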