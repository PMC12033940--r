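#' Define an experimental case
#'
#' A condition spec names one experimental case: which data set kind drives
#' the seeding (multiplex secretome concentrations vs. a mass-spectrometry
#' proteome), the tissue phenotype it belongs to, the seed proteins, and the
#' stimulus proteins (cytokines such as IL4, IL10, IL1B) added for that
#' condition.
#'
#' @param name Unique case label, e.g. `"degenerated_il4"`.
#' @param dataset_kind `"secretome"` or `"mass_spec"`.
#' @param phenotype Tissue/phenotype label (e.g. `"trauma"`, `"degenerated"`,
#'   `"explant"`, `"young"`, `"old"`). Free-form.
#' @param seeds Seed protein identifiers (non-empty).
#' @param stimuli Stimulus protein identifiers (may be empty).
#' @param concentration_source Optional `concentration_table` (required for
#'   secretome cases when scoring).
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(name, dataset_kind = c("secretome", "mass_spec"),
                           phenotype = "unspecified", seeds, stimuli = character(),
                           concentration_source = NULL) {
  dataset_kind <- match.arg(dataset_kind)
  seeds <- unique(canon_id(seeds))
  stimuli <- unique(canon_id(stimuli))
  if (length(seeds) == 0L) abort("A condition needs at least one seed protein.")
  structure(
    list(
      name = name, dataset_kind = dataset_kind, phenotype = phenotype,
      seeds = seeds, stimuli = stimuli,
      concentration_source = concentration_source
    ),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition '%s'> %s / %s\n", x$name, x$dataset_kind, x$phenotype))
  cat("  seeds:  ", paste(x$seeds, collapse = ", "), "\n")
  cat("  stimuli:", if (length(x$stimuli)) paste(x$stimuli, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Min-max scale a vector of concentrations
#'
#' Rescales values to \[0, 1\] as (X - Xmin) / (Xmax - Xmin), so the least
#' expressed protein maps to 0 and the most expressed to 1. A constant input
#' (Xmax = Xmin) degenerates to all zeros with a warning rather than dividing
#' by zero.
#'
#' @param values Named non-negative numeric vector (protein -> concentration).
#' @return Named numeric vector in \[0, 1\], same names and order.
#' @export
minmax_scale <- function(values) {
  if (length(values) == 0L) abort("`values` must be non-empty.")
  if (!is.numeric(values) || anyNA(values)) abort("`values` must be numeric without NA.")
  if (any(values < 0)) abort("Concentrations must be non-negative.")
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    warn("Degenerate input: all values equal; min-max scaling returns zeros.")
    return(setNames(rep(0, length(values)), names(values)))
  }
  (values - lo) / (hi - lo)
}

#' Score vector container
#'
#' A score vector maps every node of a network to an initial or propagated
#' relevance score in \[0, 1\] (propagated scores are kept normalized to a
#' maximum of 1).
#'
#' @param scores Named numeric vector or tibble with `node`, `score`.
#' @param provenance One of `"binary"`, `"scaled_concentration"`,
#'   `"propagated"`.
#' @return A `score_vector` tibble with columns `node`, `score`.
#' @export
score_vector <- function(scores, provenance = c("binary", "scaled_concentration", "propagated")) {
  provenance <- match.arg(provenance)
  if (is.data.frame(scores)) {
    df <- tibble(node = canon_id(scores$node), score = as.numeric(scores$score))
  } else {
    if (is.null(names(scores))) abort("`scores` must be named by node.")
    df <- tibble(node = canon_id(names(scores)), score = as.numeric(scores))
  }
  if (anyDuplicated(df$node)) abort("Duplicate nodes in score vector.")
  if (anyNA(df$score) || any(df$score < -1e-12) || any(df$score > 1 + 1e-12)) {
    abort("Scores must lie in [0, 1].")
  }
  df$score <- pmin(pmax(df$score, 0), 1)
  df <- arrange(df, .data$node)
  attr(df, "provenance") <- provenance
  class(df) <- c("score_vector", class(df))
  df
}

as_named_scores <- function(x) {
  if (is.data.frame(x)) setNames(x$score, x$node) else x
}

#' Score a secretome-based case
#'
#' Per protein, the biological replicates are averaged, the panel-wide means
#' are min-max scaled (over the measured analytes, before restriction to the
#' network), scores are restricted to network nodes (unmeasured nodes score
#' 0), and finally each stimulus protein is forced to 1 — the score of the
#' most expressed protein — to emulate the in-vitro/ex-vivo stimulation.
#'
#' @param table A `concentration_table` for this condition.
#' @param spec The [condition_spec] (`dataset_kind = "secretome"`).
#' @param net The case [interactome] (must contain the stimuli).
#' @return A `score_vector` over all nodes of `net`
#'   (provenance `"scaled_concentration"`).
#' @export
score_secretome_case <- function(table, spec, net) {
  stopifnot(inherits(spec, "condition_spec"), is_interactome(net))
  if (spec$dataset_kind != "secretome") abort("`spec` is not a secretome case.")
  if (!inherits(table, "concentration_table")) table <- concentration_table(table)
  reps <- setdiff(names(table), "protein")
  means <- setNames(rowMeans(as.matrix(table[reps])), table$protein)
  scaled <- minmax_scale(means)
  nodes <- net_nodes(net)
  s <- setNames(rep(0, length(nodes)), nodes)
  common <- intersect(nodes, names(scaled))
  s[common] <- scaled[common]
  missing_stim <- setdiff(spec$stimuli, nodes)
  if (length(missing_stim) > 0) {
    abort(sprintf("Stimulus protein(s) absent from the network: %s (add them when building the network).",
                  paste(missing_stim, collapse = ", ")))
  }
  s[spec$stimuli] <- 1
  score_vector(s, provenance = "scaled_concentration")
}

#' Score a mass-spectrometry-based case
#'
#' Each seed present in the network scores 1, the stimuli score 1, all other
#' nodes 0. Seeds absent from the network are skipped with a message; a case
#' with no seed in the network is an error.
#'
#' @param spec The [condition_spec] (`dataset_kind = "mass_spec"`).
#' @param net The case [interactome].
#' @return A `score_vector` over all nodes of `net` (provenance `"binary"`).
#' @export
score_ms_case <- function(spec, net) {
  stopifnot(inherits(spec, "condition_spec"), is_interactome(net))
  if (spec$dataset_kind != "mass_spec") abort("`spec` is not a mass-spectrometry case.")
  nodes <- net_nodes(net)
  absent <- setdiff(spec$seeds, nodes)
  if (length(absent) > 0) {
    inform(sprintf("Seed(s) absent from the network, skipped: %s", paste(absent, collapse = ", ")))
  }
  present <- intersect(spec$seeds, nodes)
  if (length(present) == 0L) abort("No seed protein is present in the network.")
  missing_stim <- setdiff(spec$stimuli, nodes)
  if (length(missing_stim) > 0) {
    abort(sprintf("Stimulus protein(s) absent from the network: %s", paste(missing_stim, collapse = ", ")))
  }
  s <- setNames(rep(0, length(nodes)), nodes)
  s[c(present, spec$stimuli)] <- 1
  score_vector(s, provenance = "binary")
}

#' Score any case by its dataset kind
#'
#' Dispatches to [score_secretome_case()] or [score_ms_case()].
#'
#' @inheritParams score_secretome_case
#' @param table Concentration table; defaults to `spec$concentration_source`.
#' @return A `score_vector`.
#' @export
score_case <- function(spec, net, table = NULL) {
  if (spec$dataset_kind == "secretome") {
    table <- table %||% spec$concentration_source
    if (is.null(table)) abort("Secretome case needs a concentration table.")
    score_secretome_case(table, spec, net)
  } else {
    score_ms_case(spec, net)
  }
}
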