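#' Run the full TPT network pipeline
#'
#' Chains the stages of the method: optional pathway over-representation
#' filtering, one-mode TPT network construction, Louvain module detection,
#' contribution scoring of modules toward diseases, chi-square validation
#' of the module-disease association, selection of the module contributing
#' most to the formula-relevant diseases, centrality and target-importance
#' ranking inside that module, top-fraction selection, and (optionally)
#' attachment of predicted compounds and approved-drug validation.
#'
#' Inputs may be tibbles or TSV file paths. When `out_dir` is given, every
#' stage result is written there as TSV (plus GraphML for the network) along
#' with a JSON run manifest recording the configuration, input checksums,
#' stage timings and session versions. A stage failure aborts with the
#' stage name and leaves a `.partial` marker file in `out_dir`.
#'
#' @param annotation Annotation table or path; pairs of target and pathway.
#' @param pathway_disease Pathway-disease table or path.
#' @param relevant_diseases Character vector of disease ids (or a file with
#'   one id per line) defining the formula-relevant diseases.
#' @param config A [tpt_config()].
#' @param drugs Optional drug-target table or path for ATC validation.
#' @param compounds Optional compound-target table or path.
#' @param universe_annotation Optional background annotation; when supplied
#'   the pipeline first keeps only pathways over-represented (FDR below
#'   `config$fdr_threshold`) in the input annotation's target set.
#' @param universe_size Optional background size for the enrichment stage.
#' @param out_dir Optional output directory.
#' @return An object of class `tpt_run`: list with `network`, `partition`,
#'   `contribution`, `association` (chi-square), `relevance`,
#'   `selected_module`, `centralities`, `ranking`, `selection`,
#'   `validation` (or `NULL`), `enrichment` (or `NULL`), `config`, and
#'   `manifest`.
#' @export
run_pipeline <- function(annotation, pathway_disease, relevant_diseases,
                         config = tpt_config(), drugs = NULL,
                         compounds = NULL, universe_annotation = NULL,
                         universe_size = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "tpt_config"))
  timings <- c()
  partial_marker <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    partial_marker <- file.path(out_dir, ".partial")
    file.create(partial_marker)
  }
  input_paths <- list(annotation = annotation,
                      pathway_disease = pathway_disease,
                      drugs = drugs, compounds = compounds)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "tpt_stage_error", parent = e)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 4)
    res
  }

  annotation <- stage("read_annotation", load_table(annotation, "annotation"))
  pathway_disease <- stage("read_pathway_disease",
                           load_table(pathway_disease, "pathway_disease"))
  if (is.character(relevant_diseases) && length(relevant_diseases) == 1 &&
      file.exists(relevant_diseases)) {
    relevant_diseases <- readLines(relevant_diseases)
    relevant_diseases <- trimws(relevant_diseases)
    relevant_diseases <- relevant_diseases[relevant_diseases != ""]
  }
  if (!is.null(drugs)) drugs <- stage("read_drugs",
                                      load_table(drugs, "drug_target"))
  if (!is.null(compounds)) {
    compounds <- stage("read_compounds", load_table(compounds, "compound_target"))
  }

  enrichment <- NULL
  if (!is.null(universe_annotation)) {
    universe_annotation <- load_table(universe_annotation, "annotation")
    enrichment <- stage("enrich", enrich_pathways(
      unique(annotation$target_id), universe_annotation,
      universe_size = universe_size, fdr_threshold = config$fdr_threshold))
    annotation <- stage("filter_annotation",
                        filter_annotation(annotation, enrichment))
  }

  network <- stage("build_tpt", build_tpt(annotation))
  partition <- stage("detect_modules", detect_modules(
    network, resolution = config$resolution, seed = config$random_seed,
    weighting = config$edge_weighting))
  incidence <- stage("incidence",
                     module_pathway_incidence(partition, annotation))
  contribution <- stage("contribution_scores",
                        contribution_scores(incidence, pathway_disease))
  association <- stage("chisquare", tryCatch(
    module_disease_chisquare(contribution),
    tpt_test_infeasible_error = function(e) NULL))
  relevance <- stage("relevant_disease_ratio",
                     relevant_disease_ratio(contribution, relevant_diseases))
  selected_module <- relevance$selected_module
  module_targets <- partition$assignment$target_id[
    partition$assignment$module == selected_module]
  centralities <- stage("centralities", compute_centralities(
    network, module_targets, scope = config$centrality_scope))
  ranking <- stage("target_importance", target_importance(
    centralities, module_id = selected_module,
    scope = config$centrality_scope))
  selection <- stage("top_fraction",
                     top_fraction(ranking, config$top_fraction))
  if (!is.null(compounds)) {
    selection <- stage("attach_compounds",
                       attach_compounds(selection, compounds))
  }
  validation <- NULL
  if (!is.null(drugs)) {
    validation <- stage("drug_validation",
                        drug_target_validation(partition, drugs))
  }

  manifest <- list(
    config = unclass(config),
    inputs = input_checksums(input_paths),
    relevant_diseases = relevant_diseases,
    selected_module = selected_module,
    stage_timings_sec = as.list(timings),
    versions = list(r = as.character(getRversion()),
                    tptnet = as.character(utils::packageVersion("tptnet")),
                    igraph = as.character(utils::packageVersion("igraph"))))

  result <- structure(list(network = network, partition = partition,
                           contribution = contribution,
                           association = association, relevance = relevance,
                           selected_module = selected_module,
                           centralities = centralities, ranking = ranking,
                           selection = selection, validation = validation,
                           enrichment = enrichment, config = config,
                           manifest = manifest),
                      class = "tpt_run")
  if (!is.null(out_dir)) {
    write_run(result, out_dir)
    unlink(partial_marker)
  }
  result
}

load_table <- function(x, kind) {
  if (is.character(x) && length(x) == 1) {
    read_pairs_table(x, kind)
  } else {
    switch(kind,
      annotation = annotation_table(x),
      pathway_disease = pathway_disease_table(x),
      drug_target = drug_target_table(x),
      compound_target = compound_target_table(x))
  }
}

input_checksums <- function(paths) {
  lapply(paths, function(p) {
    if (is.character(p) && length(p) == 1 && file.exists(p)) {
      unname(tools::md5sum(p))
    } else if (is.null(p)) NULL else "in-memory"
  })
}

write_run <- function(result, out_dir) {
  write_network(result$network, file.path(out_dir, "network.graphml"),
                "graphml")
  write_network(result$network, file.path(out_dir, "edges.tsv"), "edge_tsv")
  readr::write_tsv(result$partition$assignment,
                   file.path(out_dir, "modules.tsv"), progress = FALSE)
  cs_wide <- contribution_matrix(result$contribution, "cs")
  readr::write_tsv(
    dplyr::bind_cols(tibble(module = as.integer(rownames(cs_wide))),
                     as_tibble(cs_wide)),
    file.path(out_dir, "contribution.tsv"), progress = FALSE)
  readr::write_tsv(result$relevance$scores,
                   file.path(out_dir, "relevance.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(result$ranking),
                   file.path(out_dir, "ranking.tsv"), progress = FALSE)
  sel <- as_tibble(result$selection)
  if ("compounds" %in% names(sel)) {
    sel$compounds <- vapply(sel$compounds, function(cc) {
      paste(sprintf("%s%s", cc$compound_id,
                    ifelse(cc$above_threshold, "*", "")), collapse = ";")
    }, character(1))
  }
  readr::write_tsv(sel, file.path(out_dir, "selection.tsv"), progress = FALSE)
  if (!is.null(result$association)) {
    jsonlite::write_json(
      list(statistic = result$association$statistic,
           dof = result$association$dof,
           p_value = result$association$p_value),
      file.path(out_dir, "association.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$validation)) {
    readr::write_tsv(result$validation$counts,
                     file.path(out_dir, "drug_validation.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(as_tibble(result$enrichment),
                     file.path(out_dir, "enrichment.tsv"), progress = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
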