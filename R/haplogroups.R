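#' Haplogroup-to-region lookup tables
#'
#' Uniparental haplogroups are strongly geographically clustered, so a
#' haplogroup label assigned by an external predictor (a Y haplogroup
#' predictor, or a mitochondrial tree classifier) can be mapped to the
#' region where that haplogroup reaches its highest frequency. The mapping
#' is a deterministic longest-prefix lookup over an editable table, shipped
#' as JSON and seeded from the built-in casework annotations.
#'
#' Two entries are phylogeographically debatable but kept verbatim so the
#' built-in casebook reproduces exactly: mt U6a (common in North Africa) is
#' annotated "Europe", and mt R0 is annotated "South Asian" (elsewhere the
#' same table spells the region "South Asia"). Edit the JSON to override.
#'
#' @param marker_kind `"Y"` or `"mt"`.
#' @param path optional path to a custom JSON table with fields
#'   `marker_kind` and `entries` (a map from haplogroup prefix to region).
#' @return a `bga_haplogroup_table`.
#' @export
haplogroup_table <- function(marker_kind = c("mt", "Y"), path = NULL) {
  marker_kind <- match.arg(marker_kind)
  if (is.null(path)) {
    file <- if (marker_kind == "Y") "haplogroups_y.json" else "haplogroups_mt.json"
    path <- system.file("extdata", file, package = "strbga", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path)
  entries <- vapply(raw$entries, as.character, character(1))
  if (!length(entries)) stop_strbga("haplogroup table has no entries: ", path)
  structure(list(marker_kind = marker_kind, entries = entries),
            class = "bga_haplogroup_table")
}

#' @export
print.bga_haplogroup_table <- function(x, ...) {
  cat("<bga_haplogroup_table> ", x$marker_kind, ", ",
      length(x$entries), " prefixes\n", sep = "")
  invisible(x)
}

#' Map haplogroup labels to regions
#'
#' Longest-prefix match of each label against the table; labels matching no
#' prefix return `"NO_MATCH"` (a value, not an error), as do missing labels.
#'
#' @param label character vector of haplogroup labels (e.g. `"U5a1b1g"`,
#'   `"R1b M269"`).
#' @param table a [haplogroup_table()].
#' @return character vector of region labels.
#' @export
#' @examples
#' map_haplogroup("L2a1c1", haplogroup_table("mt"))
#' map_haplogroup("ZZZ9", haplogroup_table("mt"))
map_haplogroup <- function(label, table) {
  stopifnot(inherits(table, "bga_haplogroup_table"))
  prefixes <- names(table$entries)
  # longest prefix wins; check longer prefixes first
  prefixes <- prefixes[order(nchar(prefixes), decreasing = TRUE)]
  vapply(label, function(lb) {
    if (is.na(lb) || !nzchar(trimws(lb))) return("NO_MATCH")
    lb <- trimws(lb)
    hit <- prefixes[startsWith(lb, prefixes)]
    if (length(hit)) unname(table$entries[hit[1]]) else "NO_MATCH"
  }, character(1), USE.NAMES = FALSE)
}
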