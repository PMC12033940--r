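#' Generate a planted-community interactome
#'
#' Draws a planted-partition (stochastic block model) graph: node pairs
#' within the same community interact with probability `p_in`, pairs across
#' communities with probability `p_out < p_in`. Edge confidences are drawn
#' uniformly from \[0.5, 1\] (mimicking a curated, scored interactome).
#' One community is designated the disease module and seed proteins are
#' sampled from it, giving every downstream stage a known ground truth. The
#' same `rng_seed` always yields the identical graph.
#'
#' An optional degree-corrected variant (`degree_heterogeneity > 0`) tilts
#' per-node connection propensities log-normally, emulating hub-dominated
#' degree distributions.
#'
#' @param n_nodes Total number of proteins (default 400).
#' @param n_communities Number of planted communities (default 4, as equal
#'   in size as possible).
#' @param p_in Within-community edge probability (default 0.3).
#' @param p_out Between-community edge probability (default 0.01); must be
#'   strictly less than `p_in`.
#' @param rng_seed Integer seed.
#' @param n_seeds Number of true seed proteins sampled inside the disease
#'   module (default 5).
#' @param disease_module Community id (1-based) designated as the disease
#'   module (default 1).
#' @param degree_heterogeneity Standard deviation of the log-normal node
#'   propensities; 0 (default) gives the plain planted-partition model.
#' @return A list with `network` (an [interactome]) and `ground_truth` (a
#'   `synthetic_ground_truth`: `partition` tibble, `disease_module`, `seeds`,
#'   and the generation parameters). The generator warns when the expected
#'   degree is low enough that disconnection is likely.
#' @export
generate_interactome <- function(n_nodes = 400, n_communities = 4,
                                 p_in = 0.3, p_out = 0.01, rng_seed = 1L,
                                 n_seeds = 5, disease_module = 1L,
                                 degree_heterogeneity = 0) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 1L)
  n_communities <- assert_count(n_communities, "n_communities", min = 1L)
  assert_scalar_number(p_in, "p_in", 0, 1)
  assert_scalar_number(p_out, "p_out", 0, 1)
  if (n_communities > 1 && p_out >= p_in) {
    abort("`p_out` must be strictly less than `p_in`.")
  }
  if (n_nodes < n_communities) abort("`n_nodes` must be >= `n_communities`.")
  n_seeds <- assert_count(n_seeds, "n_seeds", min = 0L)
  disease_module <- assert_count(disease_module, "disease_module", min = 1L)
  if (disease_module > n_communities) abort("`disease_module` exceeds `n_communities`.")

  nodes <- sprintf("P%04d", seq_len(n_nodes))
  memb <- sort(rep_len(seq_len(n_communities), n_nodes))

  out <- with_seed(rng_seed, {
    pair <- which(upper.tri(matrix(FALSE, n_nodes, n_nodes)), arr.ind = TRUE)
    i <- pair[, 1]; j <- pair[, 2]
    p <- ifelse(memb[i] == memb[j], p_in, p_out)
    if (degree_heterogeneity > 0) {
      w <- exp(rnorm(n_nodes, sd = degree_heterogeneity))
      w <- w / mean(w)
      p <- pmin(1, p * w[i] * w[j])
    }
    keep <- runif(length(p)) < p
    ed <- tibble(
      from = nodes[i[keep]],
      to = nodes[j[keep]],
      confidence = runif(sum(keep), 0.5, 1)
    )
    module_nodes <- nodes[memb == disease_module]
    seeds <- if (n_seeds > 0) sort_c(sample(module_nodes, min(n_seeds, length(module_nodes)))) else character()
    list(edges = ed, seeds = seeds)
  })

  net <- interactome(out$edges, nodes = nodes, name = "synthetic_interactome")
  exp_deg <- p_in * (n_nodes / n_communities - 1) + p_out * (n_nodes - n_nodes / n_communities)
  if (exp_deg < log(n_nodes)) {
    warn(sprintf("Expected degree %.2f is below log(N); the graph may be disconnected.", exp_deg))
  }
  gt <- structure(
    list(
      partition = tibble(node = nodes, community = as.integer(memb)),
      disease_module = as.integer(disease_module),
      seeds = out$seeds,
      params = list(n_nodes = n_nodes, n_communities = n_communities,
                    p_in = p_in, p_out = p_out, rng_seed = as.integer(rng_seed),
                    degree_heterogeneity = degree_heterogeneity)
    ),
    class = "synthetic_ground_truth"
  )
  list(network = net, ground_truth = gt)
}

# Default analyte labels for the synthetic secretome panel: a handful of
# canonical secreted factors, then anonymous analytes up to `n`.
secretome_analyte_names <- function(n) {
  known <- c(
    "SERPINE1", "MMP2", "MMP3", "MMP13", "TIMP1", "TIMP2", "IL6", "CXCL8",
    "CCL2", "CCL5", "VEGFA", "TNF", "IGF1", "TGFB1", "FGF2", "EGF", "LIF",
    "OSM", "CSF3", "THBS1"
  )
  if (n <= length(known)) return(known[seq_len(n)])
  c(known, sprintf("ANL%03d", seq_len(n - length(known))))
}

#' Generate a synthetic secretome concentration panel
#'
#' Emulates a multiplex immunoassay panel: ~73 analytes measured in 3
#' biological replicates per condition. Baseline concentrations are
#' log-normal (right-skewed, as Luminex panels are), a per-protein
#' multiplicative `condition_effects` models treatment response, and
#' replicates carry multiplicative log-normal noise. Deterministic per seed.
#'
#' @param n_proteins Number of analytes (default 73).
#' @param n_replicates Biological replicates (default 3).
#' @param condition_effects Named numeric vector of multiplicative effects
#'   (> 0) applied to specific proteins; others default to 1.
#' @param rng_seed Integer seed.
#' @param proteins Optional analyte names (length `n_proteins`).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters
#'   (defaults 4 and 1, i.e. concentrations around e^4 ~ 55 pg/ml).
#' @param noise_sdlog Replicate noise on the log scale (default 0.2).
#' @param condition Condition label for the table.
#' @return A `concentration_table` (`protein` + one column per replicate).
#' @export
generate_secretome_panel <- function(n_proteins = 73, n_replicates = 3,
                                     condition_effects = NULL, rng_seed = 1L,
                                     proteins = NULL,
                                     baseline_meanlog = 4, baseline_sdlog = 1,
                                     noise_sdlog = 0.2, condition = "baseline") {
  n_proteins <- assert_count(n_proteins, "n_proteins", min = 1L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  proteins <- canon_id(proteins %||% secretome_analyte_names(n_proteins))
  if (length(proteins) != n_proteins) abort("`proteins` must have length `n_proteins`.")
  effects <- setNames(rep(1, n_proteins), proteins)
  if (!is.null(condition_effects)) {
    if (any(condition_effects <= 0)) abort("Condition effects must be positive.")
    ce <- setNames(as.numeric(condition_effects), canon_id(names(condition_effects)))
    known <- intersect(names(ce), proteins)
    effects[known] <- ce[known]
  }
  mat <- with_seed(rng_seed, {
    base <- rlnorm(n_proteins, meanlog = baseline_meanlog, sdlog = baseline_sdlog)
    noise <- matrix(rlnorm(n_proteins * n_replicates, meanlog = 0, sdlog = noise_sdlog),
                    nrow = n_proteins)
    base * effects * noise
  })
  df <- as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(df) <- paste0("rep_", seq_len(n_replicates))
  df <- dplyr::bind_cols(tibble(protein = proteins), df)
  concentration_table(df, condition = condition)
}

#' Generate a mass-spectrometry-style protein universe
#'
#' Produces an identifier set of exactly `n_proteins` symbols containing
#' `must_include` (e.g. the case's seed proteins and stimuli), emulating the
#' ~14,000-protein universes an MS proteome yields. Deterministic per seed.
#'
#' @param n_proteins Universe size.
#' @param must_include Identifiers guaranteed to be present.
#' @param rng_seed Integer seed.
#' @return A sorted character vector of length `n_proteins`.
#' @export
generate_ms_universe <- function(n_proteins = 14500, must_include = character(),
                                 rng_seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins", min = 1L)
  must_include <- unique(canon_id(must_include))
  if (length(must_include) > n_proteins) {
    abort("`must_include` is larger than the requested universe.")
  }
  n_fill <- n_proteins - length(must_include)
  fill <- character()
  if (n_fill > 0) {
    pool <- sprintf("MSP%05d", seq_len(max(n_fill * 2L, 10L)))
    pool <- setdiff(pool, must_include)
    fill <- with_seed(rng_seed, sample(pool, n_fill))
  }
  sort_c(unique(c(must_include, fill)))
}
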