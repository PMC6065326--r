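#' Four centralities of the targets in a module
#'
#' Computes degree, betweenness, closeness and eigenvector centrality for
#' the targets of one module. By default (`scope = "module_subgraph"`) the
#' graph analysed is the subgraph induced by the module's targets, matching
#' the within-module normalisation of the integrated importance indicator;
#' `scope = "full_network"` computes centralities on the whole TPT network
#' and then restricts the rows to the module.
#'
#' Definitions: degree is the plain node degree (or the sum of edge weights
#' in weighted mode); betweenness is unnormalised shortest-path betweenness;
#' closeness is the inverse mean shortest-path distance to the other nodes
#' of the node's connected component (0 for nodes isolated in scope);
#' eigenvector centrality is the principal-eigenvector score (deterministic
#' power iteration, tolerance 1e-8, at most 1000 iterations) scaled so its
#' maximum is 1. In weighted mode edge weight acts as connection strength
#' for degree/eigenvector and `1/weight` as distance for closeness and
#' betweenness.
#'
#' @param network An igraph object from [build_tpt()].
#' @param module_targets Character vector (length >= 2) of target ids, a
#'   subset of the network's nodes.
#' @param scope `"module_subgraph"` (default) or `"full_network"`.
#' @param weighted Use edge weights; default `FALSE` (paper-style
#'   unweighted topology).
#' @return A tibble with columns `target_id`, `dc`, `bc`, `cc`, `ec`.
#' @export
compute_centralities <- function(network, module_targets,
                                 scope = c("module_subgraph", "full_network"),
                                 weighted = FALSE) {
  scope <- match.arg(scope)
  module_targets <- unique(module_targets)
  stray <- setdiff(module_targets, igraph::V(network)$name)
  if (length(stray) > 0) {
    abort(paste0("module targets absent from the network: ",
                 paste(head(stray, 5), collapse = ", ")),
          class = "tpt_usage_error")
  }
  if (length(module_targets) < 2) {
    abort("centrality analysis needs a module with at least two targets",
          class = "tpt_degenerate_module_error")
  }
  g <- if (scope == "module_subgraph") {
    igraph::induced_subgraph(network, module_targets)
  } else {
    network
  }
  strength_w <- if (weighted) igraph::E(g)$weight else NA
  dist_w <- if (weighted) 1 / igraph::E(g)$weight else NA

  dc <- if (weighted) igraph::strength(g) else igraph::degree(g)
  bc <- igraph::betweenness(g, weights = dist_w, normalized = FALSE)
  cc <- inverse_mean_distance(g, dist_w)
  ec <- principal_eigenvector(g, weighted = weighted)
  out <- tibble(target_id = igraph::V(g)$name,
                dc = as.numeric(dc), bc = as.numeric(bc),
                cc = as.numeric(cc), ec = as.numeric(ec))
  out <- out[out$target_id %in% module_targets, , drop = FALSE]
  dplyr::arrange(out, .data$target_id)
}

# Eigenvector centrality by deterministic power iteration on A + I (the
# diagonal shift preserves eigenvectors while preventing the oscillation a
# bipartite spectrum would cause), uniform start, convergence tolerance 1e-8
# in the max norm, at most 1000 iterations, scaled so the maximum is 1.
# A fixed start vector keeps repeated runs bit-identical, which a randomly
# started Krylov solver does not guarantee.
principal_eigenvector <- function(g, weighted = FALSE, tol = 1e-8,
                                  max_iter = 1000) {
  n <- igraph::vcount(g)
  if (n == 0) return(numeric(0))
  if (igraph::ecount(g) == 0) return(rep(0, n))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE,
                                   attr = if (weighted) "weight" else NULL)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    x_new <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(rep(0, n))
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      return(x_new / max(x_new))
    }
    x <- x_new
  }
  abort(paste0("eigenvector centrality did not converge in ", max_iter,
               " iterations (residual ", format(max(abs(x_new - x))), ")"),
        class = "tpt_convergence_error")
}

# closeness as 1 / mean shortest-path distance within each node's component;
# 0 for isolated nodes (no finite distances)
inverse_mean_distance <- function(g, dist_w) {
  d <- igraph::distances(g, weights = dist_w)
  apply(d, 1, function(row) {
    finite <- row[is.finite(row) & row > 0]
    if (length(finite) == 0) 0 else 1 / mean(finite)
  })
}

#' Integrated target-importance ranking
#'
#' The target importance of node i is the mean of its four centralities,
#' each normalised by the maximum over the module's targets:
#' `TI = (DC/max DC + BC/max BC + CC/max CC + EC/max EC) / 4`.
#' TI lies in \[0, 1\] and equals 1 exactly when a target attains all four
#' maxima. A centrality whose maximum is zero across the module (e.g. all
#' betweenness zero in a clique) contributes 0 for every node while the
#' denominator stays 4.
#'
#' @param centralities A tibble from [compute_centralities()].
#' @param module_id Optional module identifier recorded in the result.
#' @param scope Optional scope label recorded in the result.
#' @return A tibble of class `tpt_ranking` with columns `rank`, `target_id`,
#'   `dc`, `bc`, `cc`, `ec`, `ti`, sorted by decreasing `ti` with ties
#'   broken by target id.
#' @export
target_importance <- function(centralities, module_id = NA, scope = NA) {
  if (nrow(centralities) < 2) {
    abort("degenerate module: target importance needs at least two targets",
          class = "tpt_degenerate_module_error")
  }
  norm_col <- function(x) {
    mx <- max(x)
    if (mx <= 0) rep(0, length(x)) else x / mx
  }
  ranking <- centralities |>
    dplyr::mutate(ti = (norm_col(.data$dc) + norm_col(.data$bc) +
                        norm_col(.data$cc) + norm_col(.data$ec)) / 4) |>
    dplyr::arrange(dplyr::desc(.data$ti), .data$target_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "target_id", "dc", "bc", "cc", "ec", "ti")
  class(ranking) <- c("tpt_ranking", class(ranking))
  attr(ranking, "module_id") <- module_id
  attr(ranking, "scope") <- scope
  ranking
}

#' Select the top fraction of a target ranking
#'
#' Returns the first `ceiling(fraction * n)` rows of the ranking (so a 10%
#' cut of 199 targets selects 20).
#'
#' @param ranking A `tpt_ranking` from [target_importance()].
#' @param fraction Fraction in (0, 1], default 0.1.
#' @return The selected rows of the ranking, in rank order.
#' @export
top_fraction <- function(ranking, fraction = 0.1) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  head(ranking, ceiling(fraction * nrow(ranking)))
}

#' Attach predicted compounds to selected targets
#'
#' Joins the compound-target prediction table onto a target selection,
#' preserving the selection order. Each target gets a (possibly empty)
#' nested tibble of its compounds with the `above_threshold` flag marking
#' predictions stronger than the predictor's similarity cutoff.
#'
#' @param selection A `tpt_ranking` (or any tibble with `target_id`), e.g.
#'   the output of [top_fraction()].
#' @param compounds A compound-target table
#'   (see [compound_target_table()]).
#' @return A tibble with the selection's columns plus a `compounds`
#'   list-column of tibbles (`compound_id`, `above_threshold`).
#' @export
attach_compounds <- function(selection, compounds) {
  sel <- as_tibble(selection)
  sel$compounds <- lapply(sel$target_id, function(tid) {
    hits <- compounds[compounds$target_id == tid,
                      c("compound_id", "above_threshold"), drop = FALSE]
    as_tibble(hits)
  })
  sel
}
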