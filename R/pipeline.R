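#' Assemble a full pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the reference interactome,
#' per-phenotype protein universes, the experimental cases, per-condition
#' concentration tables for secretome cases, optional annotation, the
#' percentages at which candidates are selected, the propagation settings
#' and the RNG seed.
#'
#' @param reference An [interactome] (the global reference).
#' @param universes Named list: phenotype -> character vector of universe
#'   proteins. Each condition's phenotype must have a universe.
#' @param conditions Named list of [condition_spec] objects.
#' @param concentrations Named list: condition name -> `concentration_table`
#'   (secretome cases only; falls back to `spec$concentration_source`).
#' @param annotation Optional protein -> category map (see [categorize()]).
#' @param top_percents Percentages for candidate selection (default `c(5, 2)`).
#' @param propagation A [propagation_config()].
#' @param contrasts List of character vectors of condition names to compare;
#'   `NULL` (default) compares, within each phenotype, every stimulated
#'   condition against the phenotype's baseline (the condition with no
#'   stimuli).
#' @param compare_at Percentage used for the comparisons (default the first
#'   of `top_percents`).
#' @param include_seeds Whether seed neighbourhoods are expanded during
#'   network building (default `FALSE`; stimuli always are).
#' @param rng_seed Integer seed (Louvain etc.).
#' @param out_dir Optional output directory; when given, [run_all()] writes
#'   per-condition TSV/JSON artifacts there.
#' @return A `run_config` list.
#' @export
run_config <- function(reference, universes, conditions, concentrations = list(),
                       annotation = NULL, top_percents = c(5, 2),
                       propagation = propagation_config(), contrasts = NULL,
                       compare_at = top_percents[1], include_seeds = FALSE,
                       rng_seed = 1L, out_dir = NULL) {
  stopifnot(is_interactome(reference))
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    names(conditions) <- map_chr(conditions, "name")
  }
  if (anyDuplicated(names(conditions))) abort("Condition names must be unique.")
  structure(
    list(reference = reference, universes = universes, conditions = conditions,
         concentrations = concentrations, annotation = annotation,
         top_percents = top_percents, propagation = propagation,
         contrasts = contrasts, compare_at = compare_at,
         include_seeds = include_seeds, rng_seed = as.integer(rng_seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

run_one_condition <- function(config, spec) {
  universe <- config$universes[[spec$phenotype]]
  if (is.null(universe)) {
    abort(sprintf("No universe supplied for phenotype '%s'.", spec$phenotype))
  }
  built <- build_case_network(
    config$reference, universe,
    condition_proteins = spec$stimuli,
    seeds = spec$seeds, include_seeds = config$include_seeds,
    name = spec$name
  )
  table <- config$concentrations[[spec$name]] %||% spec$concentration_source
  scores <- score_case(spec, built$network, table = table)
  prop <- propagate(built$network, scores, config$propagation)
  prior <- prioritize(prop, top_percents = config$top_percents, condition = spec$name)
  metrics <- network_metrics(built$network, rng_seed = config$rng_seed)
  list(condition = spec$name, build_report = built$report, network = built$network,
       scores = scores, propagation = prop, prioritization = prior,
       metrics = metrics)
}

default_contrasts <- function(conditions) {
  phen <- map_chr(conditions, "phenotype")
  n_stim <- map_int(conditions, function(sp) length(sp$stimuli))
  out <- list()
  for (ph in unique(phen)) {
    idx <- which(phen == ph)
    base <- idx[n_stim[idx] == 0L]
    if (length(base) == 0L) next
    base <- base[1]
    for (i in setdiff(idx, base)) {
      out[[length(out) + 1L]] <- c(names(conditions)[base], names(conditions)[i])
    }
  }
  out
}

write_condition_outputs <- function(res, dir) {
  d <- file.path(dir, res$condition)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_interactome(res$network, file.path(d, "network.tsv"))
  readr::write_tsv(tidy(res$propagation), file.path(d, "ranking.tsv"))
  jsonlite::write_json(
    c(as.list(res$build_report), as.list(glance(res$metrics))),
    file.path(d, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(d)
}

#' Run the whole pipeline over every experimental case
#'
#' For each condition: builds the case network (filter to universe, add
#' stimuli and neighbours, connect through shortest paths), scores the
#' seeds, propagates, prioritizes top-k% candidates and computes network
#' metrics; then runs every declared (or default baseline-vs-treatment)
#' candidate comparison. A failing condition is logged and reported without
#' aborting the others. Identical config + seed gives identical output.
#'
#' @param config A [run_config()].
#' @return A `pipeline_run`: list with `results` (per successful condition),
#'   `comparisons`, `summary` (one row per condition: status, build counts,
#'   metrics), and `errors`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  results <- list()
  errors <- list()
  rows <- list()
  for (nm in names(config$conditions)) {
    spec <- config$conditions[[nm]]
    res <- tryCatch(
      run_one_condition(config, spec),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      inform(sprintf("Condition '%s' failed: %s", nm, conditionMessage(res)))
      rows[[nm]] <- tibble(condition = nm, status = "error")
      next
    }
    results[[nm]] <- res
    if (!is.null(config$out_dir)) write_condition_outputs(res, config$out_dir)
    rows[[nm]] <- dplyr::bind_cols(
      tibble(condition = nm, status = "ok"),
      res$build_report,
      glance(res$metrics) |> select(-"network", -"n_nodes", -"n_edges")
    )
  }

  contrasts <- config$contrasts %||% default_contrasts(config$conditions)
  comparisons <- list()
  for (ct in contrasts) {
    ok <- ct[ct %in% names(results)]
    if (length(ok) < 2L) next
    key <- paste(ok, collapse = "_vs_")
    comparisons[[key]] <- compare_conditions(
      lapply(ok, function(x) results[[x]]$prioritization),
      k_percent = config$compare_at
    )
  }

  summary <- bind_rows(rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
    jsonlite::write_json(
      list(
        n_conditions = length(config$conditions),
        n_succeeded = length(results),
        n_failed = length(errors),
        errors = errors,
        comparisons = lapply(comparisons, function(cmp) {
          list(shared = cmp$shared, unique = cmp$unique)
        })
      ),
      file.path(config$out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  structure(
    list(results = results, comparisons = comparisons, summary = summary,
         errors = errors, config = config),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d/%d condition(s) succeeded, %d comparison(s)\n",
              length(x$results), nrow(x$summary), length(x$comparisons)))
  print(x$summary)
  invisible(x)
}

#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  tibble(
    n_conditions = nrow(x$summary),
    n_succeeded = length(x$results),
    n_failed = length(x$errors),
    n_comparisons = length(x$comparisons)
  )
}

#' @method tidy pipeline_run
#' @export
tidy.pipeline_run <- function(x, ...) x$summary
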