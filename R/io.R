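#' Read a pairwise interaction table
#'
#' Reads one of the four tab-separated tables the pipeline consumes: the
#' target-pathway annotation, the pathway-disease links, the approved-drug
#' targets with ATC codes, or the compound-target predictions. Files must be
#' UTF-8 TSV with a header row; lines starting with `#` are skipped.
#' Duplicate rows are collapsed with a warning stating how many were dropped.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"annotation"`, `"pathway_disease"`, `"drug_target"`,
#'   `"compound_target"`; decides the expected columns and validation rules.
#' @param tc_threshold For `kind = "compound_target"` only: when the file has
#'   a numeric `score` column instead of a logical `above_threshold` column,
#'   the Tanimoto-style similarity cutoff above which a pair is flagged.
#'
#' @return A validated tibble. Annotation tables have columns `target_id`,
#'   `pathway_id`; pathway-disease tables `pathway_id`, `disease_id`;
#'   drug-target tables `target_id`, `drug_name`, `atc_code`; compound-target
#'   tables `compound_id`, `target_id`, `above_threshold`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("target_id\tpathway_id", "T1\tP1", "T2\tP1"), tf)
#' read_pairs_table(tf, "annotation")
read_pairs_table <- function(path,
                             kind = c("annotation", "pathway_disease",
                                      "drug_target", "compound_target"),
                             tc_threshold = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "tpt_io_error")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE, col_types = readr::cols(.default = "c"))
  switch(kind,
    annotation       = annotation_table(df),
    pathway_disease  = pathway_disease_table(df),
    drug_target      = drug_target_table(df),
    compound_target  = compound_target_table(df, tc_threshold = tc_threshold)
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tpt_schema_error")
  }
  if (nrow(df) == 0) {
    abort(paste0(what, " has a header but no data rows"),
          class = "tpt_empty_input_error")
  }
  df
}

trim_ids <- function(df, cols, what) {
  for (col in cols) {
    df[[col]] <- trimws(as.character(df[[col]]))
    if (any(is.na(df[[col]]) | df[[col]] == "")) {
      abort(paste0(what, ": column '", col, "' contains empty identifiers"),
            class = "tpt_schema_error")
    }
  }
  df
}

collapse_duplicates <- function(df, what) {
  n_before <- nrow(df)
  df <- dplyr::distinct(df)
  n_dup <- n_before - nrow(df)
  if (n_dup > 0) {
    warn(paste0(what, ": collapsed ", n_dup, " duplicate row(s)"),
         class = "tpt_duplicate_warning")
  }
  df
}

#' Validate a target-pathway annotation table
#'
#' Identifiers are opaque, case-sensitive strings; whitespace is trimmed,
#' duplicate pairs collapsed with a warning, empty identifiers rejected.
#'
#' @param df A data frame with columns `target_id` and `pathway_id`.
#' @return A tibble of distinct (target, pathway) pairs.
#' @export
annotation_table <- function(df) {
  df <- as_tibble(df)
  df <- require_columns(df, c("target_id", "pathway_id"), "annotation table")
  df <- trim_ids(df, c("target_id", "pathway_id"), "annotation table")
  collapse_duplicates(df[c("target_id", "pathway_id")], "annotation table")
}

#' Validate a pathway-disease table
#'
#' @param df A data frame with columns `pathway_id` and `disease_id`.
#' @return A tibble of distinct (pathway, disease) pairs.
#' @export
pathway_disease_table <- function(df) {
  df <- as_tibble(df)
  df <- require_columns(df, c("pathway_id", "disease_id"), "pathway-disease table")
  df <- trim_ids(df, c("pathway_id", "disease_id"), "pathway-disease table")
  collapse_duplicates(df[c("pathway_id", "disease_id")], "pathway-disease table")
}

#' Validate a drug-target table
#'
#' Each row links a protein target to an approved drug with its Anatomical
#' Therapeutic Chemical (ATC) code. The first character of the ATC code must
#' be one of the level-1 anatomical-system letters A-V.
#'
#' @param df A data frame with columns `target_id`, `drug_name`, `atc_code`.
#' @return A tibble with one row per (target, drug) pair.
#' @export
drug_target_table <- function(df) {
  df <- as_tibble(df)
  df <- require_columns(df, c("target_id", "drug_name", "atc_code"),
                        "drug-target table")
  df <- trim_ids(df, c("target_id", "drug_name", "atc_code"), "drug-target table")
  atc_level1(df$atc_code)  # validates the leading letter
  collapse_duplicates(df[c("target_id", "drug_name", "atc_code")],
                      "drug-target table")
}

#' Validate a compound-target table
#'
#' Accepts either a logical `above_threshold` column flagging pairs whose
#' predicted similarity exceeds the predictor's cutoff, or a numeric `score`
#' column plus `tc_threshold` from which the flag is derived.
#'
#' @param df A data frame with columns `compound_id`, `target_id`, and either
#'   `above_threshold` or `score`.
#' @param tc_threshold Similarity cutoff used when only `score` is present.
#' @return A tibble with columns `compound_id`, `target_id`, `above_threshold`.
#' @export
compound_target_table <- function(df, tc_threshold = NULL) {
  df <- as_tibble(df)
  df <- require_columns(df, c("compound_id", "target_id"), "compound-target table")
  df <- trim_ids(df, c("compound_id", "target_id"), "compound-target table")
  if ("above_threshold" %in% names(df)) {
    flag <- toupper(trimws(as.character(df$above_threshold)))
    df$above_threshold <- flag %in% c("TRUE", "T", "1", "YES")
  } else if ("score" %in% names(df)) {
    if (is.null(tc_threshold)) {
      abort("compound-target table has a 'score' column; supply tc_threshold",
            class = "tpt_schema_error")
    }
    df$above_threshold <- as.numeric(df$score) > tc_threshold
  } else {
    abort("compound-target table needs an 'above_threshold' or 'score' column",
          class = "tpt_schema_error")
  }
  collapse_duplicates(df[c("compound_id", "target_id", "above_threshold")],
                      "compound-target table")
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' Louvain resolution 1.0, over-representation FDR threshold 0.01, top
#' fraction 0.1 of ranked targets, edge weights equal to the number of
#' shared pathways, and centralities computed on the module-induced subgraph.
#'
#' @param resolution Positive Louvain resolution parameter.
#' @param random_seed Integer seed driving module detection and simulation.
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff in (0, 1].
#' @param top_fraction Fraction in (0, 1] of ranked targets to select.
#' @param edge_weighting `"shared_pathway_count"` or `"unweighted"`.
#' @param centrality_scope `"module_subgraph"` or `"full_network"`.
#' @return A list of class `tpt_config`.
#' @export
tpt_config <- function(resolution = 1.0,
                       random_seed = 1L,
                       fdr_threshold = 0.01,
                       top_fraction = 0.1,
                       edge_weighting = c("shared_pathway_count", "unweighted"),
                       centrality_scope = c("module_subgraph", "full_network")) {
  edge_weighting <- match.arg(edge_weighting)
  centrality_scope <- match.arg(centrality_scope)
  stopifnot(is.numeric(resolution), resolution > 0,
            is.numeric(fdr_threshold), fdr_threshold > 0, fdr_threshold <= 1,
            is.numeric(top_fraction), top_fraction > 0, top_fraction <= 1)
  structure(list(resolution = as.numeric(resolution),
                 random_seed = as.integer(random_seed),
                 fdr_threshold = as.numeric(fdr_threshold),
                 top_fraction = as.numeric(top_fraction),
                 edge_weighting = edge_weighting,
                 centrality_scope = centrality_scope),
            class = "tpt_config")
}

#' Write and read a pipeline configuration
#'
#' Serialised as YAML (`.yml`/`.yaml`) or JSON (`.json`) by file extension.
#'
#' @param config A [tpt_config()] object.
#' @param path Destination (or source) file path.
#' @return `read_config()` returns a `tpt_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tpt_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(unclass(config), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  } else {
    abort(paste0("Unknown config format: .", ext), class = "tpt_usage_error")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort(paste0("Unknown config format: .", ext), class = "tpt_usage_error")
  }
  do.call(tpt_config, raw)
}

#' Export a TPT network to disk
#'
#' Writes the network with node identifiers, shared-pathway edge labels and
#' integer edge weights so that [read_network()] recovers an identical graph.
#' `edge_tsv` is a plain edge list (`source`, `target`, `pathways`, `weight`,
#' pathways joined by `;`); isolated nodes are appended as rows with an empty
#' `target` field so round-trips preserve them. `graphml` uses the GraphML
#' writer of igraph; `gexf` writes GEXF 1.2.
#'
#' @param network An igraph object from [build_tpt()].
#' @param path Destination file.
#' @param format `"edge_tsv"`, `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("edge_tsv", "graphml", "gexf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       paste0("Unknown network format: ", format[1]),
                       class = "tpt_usage_error"))
  stopifnot(inherits(network, "igraph"))
  switch(format,
    edge_tsv = {
      el <- network_edges(network)
      iso <- setdiff(igraph::V(network)$name, c(el$source, el$target))
      if (length(iso) > 0) {
        el <- dplyr::bind_rows(el, tibble(source = iso, target = "",
                                          pathways = "", weight = NA_integer_))
      }
      readr::write_tsv(el, path, progress = FALSE)
    },
    graphml = igraph::write_graph(network, path, format = "graphml"),
    gexf = write_gexf(network, path)
  )
  invisible(path)
}

#' Read a TPT network written by [write_network()]
#'
#' @param path Source file.
#' @param format `"edge_tsv"`, `"graphml"` or `"gexf"`.
#' @return An igraph object with `name` vertex attribute and `pathways`,
#'   `weight` edge attributes.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml", "gexf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       paste0("Unknown network format: ", format[1]),
                       class = "tpt_usage_error"))
  g <- switch(format,
    edge_tsv = {
      el <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              source = "c", target = "c",
                              pathways = "c", weight = "i"))
      iso <- el$source[is.na(el$target) | el$target == ""]
      el <- el[!(is.na(el$target) | el$target == ""), , drop = FALSE]
      nodes <- sort(unique(c(el$source, el$target, iso)))
      g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                         vertices = nodes)
      g
    },
    graphml = igraph::read_graph(path, format = "graphml"),
    gexf = read_gexf(path)
  )
  if (!is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight <- as.integer(igraph::E(g)$weight)
  }
  g
}

network_edges <- function(network) {
  if (igraph::ecount(network) == 0) {
    return(tibble(source = character(), target = character(),
                  pathways = character(), weight = integer()))
  }
  ends <- igraph::as_edgelist(network)
  tibble(source = ends[, 1], target = ends[, 2],
         pathways = igraph::E(network)$pathways,
         weight = as.integer(igraph::E(network)$weight))
}

write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "pathways",
                      type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (v in igraph::V(network)$name) {
    xml2::xml_add_child(nodes, "node", id = v, label = v)
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- network_edges(network)
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      e <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                               source = el$source[i], target = el$target[i],
                               weight = as.character(el$weight[i]))
      av <- xml2::xml_add_child(e, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "0", value = el$pathways[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- xml2::xml_attr(node_els, "id")
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  el <- tibble(
    source = xml2::xml_attr(edge_els, "source"),
    target = xml2::xml_attr(edge_els, "target"),
    weight = as.integer(xml2::xml_attr(edge_els, "weight")),
    pathways = vapply(edge_els, function(e) {
      av <- xml2::xml_find_first(e, ".//g:attvalue", ns)
      xml2::xml_attr(av, "value")
    }, character(1))
  )
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = sort(nodes))
}
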