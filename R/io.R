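#' Read a scored interactome from a tab-delimited edge list
#'
#' Expects at least three tab-separated columns per row: `idA`, `idB`,
#' `confidence` (a number in \[0, 1\]). Lines starting with `#` and blank
#' lines are ignored; a leading header row (third field non-numeric) is
#' skipped. Malformed rows (too few fields, non-numeric or out-of-range
#' confidence) are rejected and counted, never fatal. Self-interactions are
#' dropped and duplicated pairs keep the maximum confidence.
#'
#' @param path Path to the edge-list file.
#' @param id_map Optional identifier map (see [read_id_map()]): a named
#'   character vector or two-column data frame mapping source identifiers to
#'   canonical gene symbols. Rows with unmappable identifiers are dropped and
#'   counted.
#' @param min_confidence Rows with confidence below this threshold are
#'   dropped. Default 0 keeps every well-formed row.
#' @param name Label for the resulting network.
#'
#' @return An [interactome]. The attribute `"read_report"` holds a list with
#'   counts of parsed, rejected, unmapped, self-loop and below-threshold rows.
#' @export
read_edge_list <- function(path, id_map = NULL, min_confidence = 0, name = NULL) {
  if (!file.exists(path)) abort(sprintf("Edge-list file not found: '%s'", path))
  assert_scalar_number(min_confidence, "min_confidence", 0, 1)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)

  # A header row is tolerated: first row whose third field is non-numeric.
  if (length(parts) > 0 && length(parts[[1]]) >= 3 &&
      is.na(suppressWarnings(as.numeric(parts[[1]][3])))) {
    parts <- parts[-1]
  }

  n_total <- length(parts)
  ok_shape <- lengths(parts) >= 3L
  parts <- parts[ok_shape]
  a <- canon_id(map_chr(parts, 1, .default = NA_character_))
  b <- canon_id(map_chr(parts, 2, .default = NA_character_))
  conf <- suppressWarnings(as.numeric(map_chr(parts, 3, .default = NA_character_)))
  ok_conf <- !is.na(conf) & conf >= 0 & conf <= 1 & nzchar(a) & nzchar(b)
  n_rejected <- sum(!ok_shape) + sum(!ok_conf)
  if (n_rejected > 0) {
    inform(sprintf("read_edge_list: rejected %d malformed row(s).", n_rejected))
  }
  a <- a[ok_conf]; b <- b[ok_conf]; conf <- conf[ok_conf]

  n_unmapped <- 0L
  if (!is.null(id_map)) {
    map <- as_id_map(id_map)
    ma <- unname(map[a]); mb <- unname(map[b])
    mappable <- !is.na(ma) & !is.na(mb)
    n_unmapped <- sum(!mappable)
    if (n_unmapped > 0) {
      inform(sprintf("read_edge_list: dropped %d row(s) with unmappable identifiers.", n_unmapped))
    }
    a <- ma[mappable]; b <- mb[mappable]; conf <- conf[mappable]
  }

  n_self <- sum(a == b)
  below <- conf < min_confidence
  n_below <- sum(below & a != b)
  keep <- !below
  net <- interactome(
    tibble(from = a[keep], to = b[keep], confidence = conf[keep]),
    name = name
  )
  if (n_edges(net) == 0L) {
    warn("read_edge_list: no edges survived parsing/filtering; returning an empty interactome.")
  }
  attr(net, "read_report") <- list(
    n_rows = n_total, n_rejected = n_rejected, n_unmapped = n_unmapped,
    n_self_loops = n_self, n_below_threshold = n_below,
    n_edges_kept = n_edges(net)
  )
  net
}

as_id_map <- function(id_map) {
  if (is.data.frame(id_map)) {
    if (ncol(id_map) < 2) abort("`id_map` data frame needs two columns: source, symbol.")
    out <- setNames(canon_id(id_map[[2]]), canon_id(id_map[[1]]))
  } else if (is.character(id_map) && !is.null(names(id_map))) {
    out <- setNames(canon_id(id_map), canon_id(names(id_map)))
  } else {
    abort("`id_map` must be a named character vector or a two-column data frame.")
  }
  if (any(!nzchar(out))) abort("`id_map` canonical symbols must be non-empty.")
  out[!duplicated(names(out))]
}

#' Read an identifier map (source id to gene symbol)
#'
#' Two-column tab-separated file: source identifier, canonical symbol.
#' `#` comments and blank lines are ignored.
#'
#' @param path Path to the mapping file.
#' @return A named character vector (names = source ids, values = symbols).
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("Id-map file not found: '%s'", path))
  df <- readr::read_tsv(path, col_names = c("source", "symbol"),
                        col_types = "cc", comment = "#", progress = FALSE)
  as_id_map(as.data.frame(df))
}

#' Read a protein universe list
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#' Identifiers are upper-cased and deduplicated, so the result is an
#' order-independent set.
#'
#' @param path Path to the list file.
#' @return A sorted character vector of unique protein identifiers.
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Protein-list file not found: '%s'", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- sort_c(unique(canon_id(lines)))
  if (length(out) == 0L) abort("Protein list is empty: a universe of zero proteins is meaningless.")
  out
}

#' Read a replicate-by-protein concentration table
#'
#' Tab-separated with a header: a `protein` column followed by one column per
#' biological replicate, values are non-negative concentrations (nominally
#' pg/ml). Duplicated proteins, negative values and missing cells are errors —
#' no imputation is performed.
#'
#' @param path Path to the TSV file.
#' @param condition Optional condition label attached to the table.
#' @return A `concentration_table`: a tibble with a `protein` column and one
#'   numeric column per replicate.
#' @export
read_concentrations <- function(path, condition = NULL) {
  if (!file.exists(path)) abort(sprintf("Concentration file not found: '%s'", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), comment = "#", progress = FALSE)
  if (ncol(df) < 2) abort("Concentration table needs a protein column plus >= 1 replicate column.")
  names(df)[1] <- "protein"
  df$protein <- canon_id(df$protein)
  concentration_table(df, condition = condition %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct/validate a concentration table
#'
#' @param df Data frame: `protein` column plus numeric replicate columns.
#' @param condition Condition label.
#' @return A validated `concentration_table` tibble.
#' @export
concentration_table <- function(df, condition = "condition") {
  df <- as_tibble(df)
  if (!"protein" %in% names(df)) abort("Concentration table needs a `protein` column.")
  df$protein <- canon_id(df$protein)
  if (anyDuplicated(df$protein)) {
    abort(sprintf("Duplicated protein rows in concentration table: %s",
                  paste(unique(df$protein[duplicated(df$protein)]), collapse = ", ")))
  }
  reps <- setdiff(names(df), "protein")
  if (length(reps) == 0L) abort("Concentration table needs >= 1 replicate column.")
  mat <- as.matrix(df[reps])
  if (!is.numeric(mat)) abort("Replicate columns must be numeric.")
  if (anyNA(mat)) abort("Missing concentration values are not allowed (no imputation).")
  if (any(mat < 0)) abort("Concentrations must be non-negative.")
  attr(df, "condition") <- condition
  class(df) <- c("concentration_table", class(df))
  df
}

#' Write an interactome to disk
#'
#' `format = "tsv"` writes a tab-separated edge list with header
#' `idA idB confidence` (plus a `#nodes:` comment preserving isolated nodes)
#' that round-trips through [read_edge_list()]; `format = "graphml"` writes
#' GraphML for graph viewers.
#'
#' @param net An [interactome].
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(is_interactome(net))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  ed <- edge_table(net)
  iso <- setdiff(net_nodes(net), unique(c(ed$from, ed$to)))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(iso) > 0) {
    writeLines(sprintf("#nodes: %s", paste(iso, collapse = ",")), con)
  }
  writeLines("idA\tidB\tconfidence", con)
  if (nrow(ed) > 0) {
    writeLines(sprintf("%s\t%s\t%.*g", ed$from, ed$to, 17L, ed$confidence), con)
  }
  invisible(path)
}

#' Read an interactome written by [write_interactome()]
#'
#' Thin wrapper over [read_edge_list()] that additionally restores isolated
#' nodes recorded on the `#nodes:` comment line.
#'
#' @inheritParams read_edge_list
#' @return An [interactome].
#' @export
read_interactome <- function(path, name = NULL) {
  net <- read_edge_list(path, name = name)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "#nodes:")) {
    iso <- canon_id(strsplit(sub("^#nodes:\\s*", "", first), ",")[[1]])
    iso <- iso[nzchar(iso)]
    if (length(iso) > 0) {
      net <- interactome(edge_table(net), nodes = c(net_nodes(net), iso),
                         name = net_name(net))
    }
  }
  net
}
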