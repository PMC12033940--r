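#' Read an experimental-case table
#'
#' Parses a YAML condition file describing the case networks (dataset kind,
#' phenotype, baseline seed proteins) and the per-condition stimulus
#' proteins, returning one [condition_spec] per experimental case. The
#' packaged fixture ([np_conditions()]) encodes the nucleus pulposus study
#' design: three secretome-based networks each seeded by their most
#' expressed analyte (SERPINE1 for trauma, MMP2 for degenerated and
#' explant) and two mass-spectrometry-based networks (young, old) seeded by
#' 25 previously described NP cellular mediators, under IL-4 / IL-10 /
#' IL-1B stimulation conditions.
#'
#' @param path Path to a YAML file with top-level keys `networks` (each with
#'   `dataset_kind`, `phenotype`, `seeds`) and `conditions` (each with
#'   `name`, `network`, `stimuli`).
#' @return A named list of [condition_spec] objects (one per condition); the
#'   attribute `"networks"` holds the per-network metadata.
#' @export
read_condition_specs <- function(path) {
  if (!file.exists(path)) abort(sprintf("Condition file not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$networks) || is.null(cfg$conditions)) {
    abort("Condition file needs `networks` and `conditions` sections.")
  }
  specs <- lapply(cfg$conditions, function(cc) {
    nw <- cfg$networks[[cc$network]]
    if (is.null(nw)) abort(sprintf("Condition '%s' references unknown network '%s'.", cc$name, cc$network))
    condition_spec(
      name = cc$name,
      dataset_kind = nw$dataset_kind,
      phenotype = nw$phenotype %||% cc$network,
      seeds = unlist(nw$seeds),
      stimuli = unlist(cc$stimuli) %||% character()
    )
  })
  names(specs) <- map_chr(cfg$conditions, "name")
  if (anyDuplicated(names(specs))) abort("Condition names must be unique.")
  attr(specs, "networks") <- cfg$networks
  specs
}

#' @rdname read_condition_specs
#' @export
np_conditions <- function() {
  read_condition_specs(system.file("extdata", "conditions.yaml", package = "prionet"))
}

#' Summarize condition specs as a tibble
#'
#' @param specs A list of [condition_spec] objects (see
#'   [read_condition_specs()]).
#' @return A tibble with one row per condition: name, dataset kind,
#'   phenotype, seed and stimulus counts, and the seed list.
#' @export
condition_table <- function(specs) {
  bind_rows(lapply(specs, function(sp) {
    tibble(
      condition = sp$name,
      dataset_kind = sp$dataset_kind,
      phenotype = sp$phenotype,
      n_seeds = length(sp$seeds),
      n_stimuli = length(sp$stimuli),
      seeds = paste(sp$seeds, collapse = ","),
      stimuli = paste(sp$stimuli, collapse = ",")
    )
  }))
}
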