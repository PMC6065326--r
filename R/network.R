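#' Build the targets-(pathways)-targets network
#'
#' Projects the bipartite target-pathway annotation onto its target mode:
#' every target becomes a node, and two targets are joined by an edge
#' whenever they are annotated to at least one common pathway. The edge
#' carries the set of shared pathways (attribute `pathways`, `;`-joined in
#' sorted order) and an integer `weight` equal to their number. Targets
#' whose pathways have no other member become isolated nodes.
#'
#' @param annotation An annotation table (see [annotation_table()]).
#' @return An undirected igraph object with vertex attribute `name` and edge
#'   attributes `pathways` and `weight`.
#' @export
#' @examples
#' ann <- tibble::tibble(target_id = c("A", "B", "A", "B"),
#'                       pathway_id = c("p1", "p1", "p2", "p2"))
#' g <- build_tpt(annotation_table(ann))
#' igraph::E(g)$weight  # 2: the pair shares p1 and p2
build_tpt <- function(annotation) {
  if (nrow(annotation) == 0) {
    abort("annotation table is empty", class = "tpt_empty_input_error")
  }
  annotation <- dplyr::distinct(annotation[c("target_id", "pathway_id")])
  targets <- sort(unique(annotation$target_id))
  edges <- annotation |>
    dplyr::inner_join(annotation, by = "pathway_id",
                      relationship = "many-to-many",
                      suffix = c("", "_2")) |>
    dplyr::filter(.data$target_id < .data$target_id_2) |>
    dplyr::group_by(.data$target_id, .data$target_id_2) |>
    dplyr::summarise(
      pathways = paste(sort(unique(.data$pathway_id)), collapse = ";"),
      weight = dplyr::n_distinct(.data$pathway_id),
      .groups = "drop") |>
    dplyr::arrange(.data$target_id, .data$target_id_2)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = targets)
}

#' Detect network modules by Louvain modularity optimisation
#'
#' Partitions the TPT network into modules with the Louvain algorithm at the
#' given resolution. Edge weights (number of shared pathways) are used by
#' default; `weighting = "unweighted"` ignores them. The run is seeded, so a
#' fixed seed reproduces the same partition bit for bit. Isolated nodes form
#' singleton modules. Module ids are canonicalised to consecutive integers
#' ordered by decreasing module size, ties broken by the lexicographically
#' smallest member target id.
#'
#' @param network An igraph object from [build_tpt()].
#' @param resolution Positive resolution parameter (1.0 reproduces plain
#'   modularity).
#' @param seed Integer seed for the stochastic node-visit order.
#' @param weighting `"shared_pathway_count"` (default) or `"unweighted"`.
#' @return An object of class `tpt_partition`: a list with `assignment`
#'   (tibble `target_id`, `module`), `modules` (integer module ids),
#'   `modularity`, `resolution`, `seed`, and `weighting`.
#' @export
detect_modules <- function(network, resolution = 1.0, seed = 1L,
                           weighting = c("shared_pathway_count", "unweighted")) {
  weighting <- match.arg(weighting)
  if (igraph::vcount(network) == 0) {
    abort("network has no nodes", class = "tpt_empty_input_error")
  }
  w <- if (weighting == "unweighted") NA else NULL
  cl <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(network, weights = w, resolution = resolution))
  raw <- igraph::membership(cl)
  assignment <- tibble(target_id = igraph::V(network)$name,
                       module = as.integer(raw))
  assignment$module <- canonical_module_ids(assignment)
  mod <- igraph::modularity(network, assignment$module,
                            weights = if (weighting == "unweighted") NULL
                                      else igraph::E(network)$weight,
                            resolution = resolution)
  structure(list(assignment = assignment,
                 modules = sort(unique(assignment$module)),
                 modularity = mod,
                 resolution = resolution,
                 seed = as.integer(seed),
                 weighting = weighting),
            class = "tpt_partition")
}

# relabel raw module ids 1..I by decreasing size, ties by smallest member id
canonical_module_ids <- function(assignment) {
  stats_df <- assignment |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(size = dplyr::n(),
                     first_member = min(.data$target_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_member)
  lookup <- setNames(seq_len(nrow(stats_df)), stats_df$module)
  as.integer(lookup[as.character(assignment$module)])
}

#' Module-pathway incidence and the pathway module count u
#'
#' A module is incident to a pathway when at least one of its member targets
#' is annotated to that pathway. `u[p]` counts the modules incident to
#' pathway `p`; in the contribution-scoring algorithm each incident module
#' contributes `1/u[p]` to the pathway, so the incident-module shares of any
#' covered pathway always sum to one. Pathways whose annotated targets are
#' all absent from the partition get `u = 0` and are flagged with a warning;
#' downstream scoring excludes them.
#'
#' @param partition A `tpt_partition` from [detect_modules()].
#' @param annotation The annotation table the network was built from.
#' @return An object of class `tpt_incidence`: list with `incidence`
#'   (tibble `module`, `pathway_id`) and `u` (tibble `pathway_id`, `u`).
#' @export
module_pathway_incidence <- function(partition, annotation) {
  stopifnot(inherits(partition, "tpt_partition"))
  joined <- annotation |>
    dplyr::inner_join(partition$assignment, by = "target_id")
  incidence <- joined |>
    dplyr::distinct(.data$module, .data$pathway_id) |>
    dplyr::arrange(.data$module, .data$pathway_id)
  u <- incidence |>
    dplyr::count(.data$pathway_id, name = "u") |>
    dplyr::mutate(u = as.integer(.data$u))
  uncovered <- setdiff(unique(annotation$pathway_id), u$pathway_id)
  if (length(uncovered) > 0) {
    warn(paste0(length(uncovered), " pathway(s) annotate only targets absent",
                " from the network and get u = 0: ",
                paste(head(uncovered, 5), collapse = ", ")),
         class = "tpt_uncovered_pathway_warning")
    u <- dplyr::bind_rows(u, tibble(pathway_id = uncovered, u = 0L)) |>
      dplyr::arrange(.data$pathway_id)
  }
  structure(list(incidence = incidence, u = u), class = "tpt_incidence")
}
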