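#' Select the top k% candidates of a ranking
#'
#' Takes the first `floor(k_percent / 100 * N)` nodes of a deterministic
#' ranking (ties already resolved by [rank_nodes()]). The floor rule makes
#' candidate-set sizes reproducible: a 782-node network yields 39 candidates
#' at 5% and 15 at 2%.
#'
#' @param ranking A tibble from [rank_nodes()] (columns `node`, `score`,
#'   `rank`), or a `propagation_result`.
#' @param k_percent Percentage in (0, 100].
#' @return Character vector of candidate nodes, in rank order.
#' @export
select_top <- function(ranking, k_percent) {
  if (inherits(ranking, "propagation_result")) ranking <- rank_nodes(ranking)
  assert_scalar_number(k_percent, "k_percent", lower = 1e-9, upper = 100)
  n <- nrow(ranking)
  if (n == 0L) abort("`ranking` is empty.")
  size <- floor(k_percent / 100 * n)
  if (size == 0L) {
    abort(sprintf("Top %.3g%% of %d nodes selects zero candidates; use a larger k.", k_percent, n))
  }
  ranking$node[seq_len(size)]
}

#' Bundle a condition's ranking and its top-k% candidate sets
#'
#' @param ranking Ranking tibble or `propagation_result`.
#' @param top_percents Percentages to extract (e.g. `c(5, 2)` for secretome
#'   networks, `c(2, 0.25)` for MS networks).
#' @param condition Condition label.
#' @return A `prioritization_result`: list with `condition`, `ranking`, and
#'   `top_sets` (named list, names are the percentages). Top sets are nested:
#'   a smaller percentage is always a subset of a larger one.
#' @export
prioritize <- function(ranking, top_percents = c(5, 2), condition = "condition") {
  if (inherits(ranking, "propagation_result")) ranking <- rank_nodes(ranking)
  tops <- lapply(top_percents, function(k) select_top(ranking, k))
  names(tops) <- formatC(top_percents, format = "g")
  structure(
    list(condition = condition, ranking = ranking, top_sets = tops,
         top_percents = top_percents),
    class = "prioritization_result"
  )
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf("<prioritization_result> condition '%s', %d ranked nodes\n",
              x$condition, nrow(x$ranking)))
  for (k in names(x$top_sets)) {
    cat(sprintf("  top %s%%: %d candidates\n", k, length(x$top_sets[[k]])))
  }
  invisible(x)
}

#' @method tidy prioritization_result
#' @export
tidy.prioritization_result <- function(x, ...) {
  out <- x$ranking
  for (k in names(x$top_sets)) {
    out[[paste0("top_", k, "_pct")]] <- out$node %in% x$top_sets[[k]]
  }
  mutate(out, condition = x$condition, .before = 1)
}

#' @method glance prioritization_result
#' @export
glance.prioritization_result <- function(x, ...) {
  tibble(
    condition = x$condition,
    n_nodes = nrow(x$ranking),
    !!!setNames(
      lapply(x$top_sets, length),
      paste0("n_top_", names(x$top_sets), "_pct")
    )
  )
}

get_top_set <- function(result, k_percent) {
  key <- formatC(k_percent, format = "g")
  if (inherits(result, "prioritization_result")) {
    if (!key %in% names(result$top_sets)) {
      abort(sprintf("Condition '%s' has no top %s%% set.", result$condition, key))
    }
    result$top_sets[[key]]
  } else {
    select_top(result, k_percent)
  }
}

#' Compare candidate sets across conditions
#'
#' Given prioritizations of two or more conditions at a common top-k%,
#' computes the candidates shared by all conditions and those unique to each.
#' With `unique_vs = "all"` (the default) a candidate is unique to a
#' condition when no other compared condition selected it; with
#' `unique_vs = "baseline"` uniqueness is judged against the first condition
#' only (the no-treatment baseline), mirroring per-treatment contrasts.
#'
#' @param results List of `prioritization_result` objects (>= 2), each
#'   carrying a top set at `k_percent`.
#' @param k_percent The percentage to compare at (must be present in every
#'   result).
#' @param unique_vs `"all"` or `"baseline"`.
#' @return A `candidate_comparison`: list with `conditions`, `k_percent`,
#'   `shared` (intersection of all top sets), `unique` (named list per
#'   condition), and `membership` (tibble of node x condition flags — the
#'   tabular twin of a Venn diagram).
#' @export
compare_conditions <- function(results, k_percent, unique_vs = c("all", "baseline")) {
  unique_vs <- match.arg(unique_vs)
  if (length(results) < 2L) abort("Need at least two conditions to compare.")
  tops <- lapply(results, get_top_set, k_percent = k_percent)
  names(tops) <- map_chr(results, function(r) {
    if (inherits(r, "prioritization_result")) r$condition else "condition"
  })
  if (anyDuplicated(names(tops))) abort("Condition names must be unique.")
  shared <- sort_c(Reduce(intersect, tops))
  uniq <- imap(tops, function(set, nm) {
    others <- if (unique_vs == "all") {
      unlist(tops[setdiff(names(tops), nm)], use.names = FALSE)
    } else {
      if (nm == names(tops)[1]) {
        unlist(tops[-1], use.names = FALSE)  # baseline is contrasted with the rest
      } else {
        tops[[1]]
      }
    }
    sort_c(setdiff(set, others))
  })
  all_nodes <- sort_c(unique(unlist(tops, use.names = FALSE)))
  membership <- tibble(node = all_nodes)
  for (nm in names(tops)) membership[[nm]] <- all_nodes %in% tops[[nm]]
  structure(
    list(conditions = names(tops), k_percent = k_percent, unique_vs = unique_vs,
         top_sets = tops, shared = shared, unique = uniq, membership = membership),
    class = "candidate_comparison"
  )
}

#' @export
print.candidate_comparison <- function(x, ...) {
  cat(sprintf("<candidate_comparison> top %g%% across %d conditions (unique vs %s)\n",
              x$k_percent, length(x$conditions), x$unique_vs))
  cat(sprintf("  shared by all: %d\n", length(x$shared)))
  for (nm in x$conditions) {
    cat(sprintf("  unique to %s: %d\n", nm, length(x$unique[[nm]])))
  }
  invisible(x)
}

#' @method tidy candidate_comparison
#' @export
tidy.candidate_comparison <- function(x, ...) {
  x$membership |>
    mutate(
      shared_by_all = .data$node %in% x$shared,
      unique_to = map_chr(.data$node, function(nd) {
        hit <- names(x$unique)[map_lgl(x$unique, function(u) nd %in% u)]
        if (length(hit) == 1L) hit else NA_character_
      })
    )
}

#' Classify candidates by functional category
#'
#' Counts candidate proteins per annotation category (e.g. immune system,
#' ECM anabolic/catabolic, adhesion, intracellular signalling). The category
#' vocabulary is whatever the annotation table supplies; candidates missing
#' from the annotation are counted as `"unannotated"`. Counts always sum to
#' the candidate-set size.
#'
#' @param candidates Character vector of candidate proteins.
#' @param annotation Named character vector (protein -> category) or a data
#'   frame with columns `protein`, `category`.
#' @return A `category_profile` tibble with columns `category`, `n`.
#' @export
categorize <- function(candidates, annotation) {
  candidates <- unique(canon_id(candidates))
  if (is.data.frame(annotation)) {
    ann <- setNames(as.character(annotation$category), canon_id(annotation$protein))
  } else {
    ann <- setNames(as.character(annotation), canon_id(names(annotation)))
  }
  if (length(candidates) == 0L) {
    out <- tibble(category = character(), n = integer())
  } else {
    cats <- ann[candidates]
    cats[is.na(cats)] <- "unannotated"
    tab <- table(cats)
    out <- tibble(category = names(tab), n = as.integer(tab)) |>
      arrange(dplyr::desc(.data$n), .data$category)
  }
  class(out) <- c("category_profile", class(out))
  attr(out, "n_candidates") <- length(candidates)
  out
}
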