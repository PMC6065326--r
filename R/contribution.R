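#' Contribution scores of modules toward diseases
#'
#' Implements the contribution-scoring algorithm. A pathway incident to `u`
#' modules hands each of them a share `1/u`; a disease supported by `v`
#' pathways receives `1/v` from each. The contribution score of module `m`
#' toward disease `d` is the sum of `(1/u[p]) * (1/v[d])` over the pathways
#' `p` relevant to both, so for any disease whose supporting pathways are
#' all covered by the network the scores add up to exactly 1 across modules.
#'
#' `v[d]` counts all pathways linked to `d` in the pathway-disease table;
#' pathways with `u = 0` (not covered by the network) are excluded from the
#' sums, and diseases all of whose pathways are uncovered are dropped with
#' a warning.
#'
#' @param incidence A `tpt_incidence` from [module_pathway_incidence()].
#' @param pathway_disease A pathway-disease table
#'   (see [pathway_disease_table()]).
#' @return An object of class `tpt_contribution`: list with `scores`
#'   (tibble `module`, `disease_id`, `cs`, `n_shared_pathways`, complete
#'   over all module-disease pairs), `links` (the pathway-level terms),
#'   `u`, and `v` (tibble `disease_id`, `v`).
#' @export
contribution_scores <- function(incidence, pathway_disease) {
  stopifnot(inherits(incidence, "tpt_incidence"))
  modules <- sort(unique(incidence$incidence$module))
  if (nrow(pathway_disease) == 0) {
    warn("pathway-disease table is empty; contribution matrix is empty",
         class = "tpt_empty_warning")
    return(structure(list(
      scores = tibble(module = integer(), disease_id = character(),
                      cs = numeric(), n_shared_pathways = integer()),
      links = tibble(module = integer(), disease_id = character(),
                     pathway_id = character(), term = numeric()),
      u = incidence$u,
      v = tibble(disease_id = character(), v = integer())),
      class = "tpt_contribution"))
  }
  pathway_disease <- dplyr::distinct(pathway_disease[c("pathway_id", "disease_id")])
  v <- pathway_disease |>
    dplyr::count(.data$disease_id, name = "v") |>
    dplyr::mutate(v = as.integer(.data$v))

  covered <- incidence$u$pathway_id[incidence$u$u > 0]
  dropped <- pathway_disease |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::summarise(any_covered = any(.data$pathway_id %in% covered),
                     .groups = "drop")
  if (any(!dropped$any_covered)) {
    warn(paste0("omitting ", sum(!dropped$any_covered), " disease(s) whose ",
                "pathways are all uncovered by the network"),
         class = "tpt_uncovered_disease_warning")
  }
  diseases <- sort(dropped$disease_id[dropped$any_covered])

  # X_ij: pathways relevant to module i and disease j simultaneously
  links <- incidence$incidence |>
    dplyr::inner_join(pathway_disease, by = "pathway_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$disease_id %in% diseases) |>
    dplyr::inner_join(incidence$u, by = "pathway_id") |>
    dplyr::inner_join(v, by = "disease_id") |>
    dplyr::mutate(term = 1 / (.data$u * .data$v)) |>
    dplyr::select("module", "disease_id", "pathway_id", "term") |>
    dplyr::arrange(.data$module, .data$disease_id, .data$pathway_id)

  scores <- links |>
    dplyr::group_by(.data$module, .data$disease_id) |>
    dplyr::summarise(cs = sum(.data$term),
                     n_shared_pathways = dplyr::n(), .groups = "drop") |>
    tidyr::complete(module = modules, disease_id = diseases,
                    fill = list(cs = 0, n_shared_pathways = 0L)) |>
    dplyr::mutate(n_shared_pathways = as.integer(.data$n_shared_pathways)) |>
    dplyr::arrange(.data$module, .data$disease_id)

  structure(list(scores = scores, links = links, u = incidence$u,
                 v = dplyr::filter(v, .data$disease_id %in% diseases)),
            class = "tpt_contribution")
}

#' Contribution matrix in wide (heat-map) layout
#'
#' @param cm A `tpt_contribution`.
#' @param value `"cs"` for contribution scores or `"n_shared_pathways"` for
#'   the integer pathway-link counts.
#' @return A numeric matrix, modules in rows, diseases in columns.
#' @export
contribution_matrix <- function(cm, value = c("cs", "n_shared_pathways")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(cm$scores[c("module", "disease_id", value)],
                             names_from = "disease_id",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$module)
  m
}

#' Chi-square test of module-disease association
#'
#' Pearson's chi-square test of independence on the module-by-disease
#' contingency table. The default (and only built-in) table builder uses
#' the integer pathway-link counts `|X_ij|` - the number of pathways
#' relevant to both module i and disease j - since the test requires count
#' data rather than the real-valued score matrix.
#'
#' @param cm A `tpt_contribution`.
#' @param table_builder Name of the contingency-table builder; currently
#'   `"pathway_link_counts"`.
#' @param correct Apply Yates continuity correction (2x2 tables only);
#'   default off, and never applied to larger tables.
#' @return An object of class `tpt_chisq`: list with `statistic`, `dof`,
#'   `p_value`, and `table` (the contingency matrix used).
#' @export
module_disease_chisquare <- function(cm, table_builder = "pathway_link_counts",
                                     correct = FALSE) {
  table_builder <- match.arg(table_builder)
  tab <- contribution_matrix(cm, "n_shared_pathways")
  chisq_of_table(tab, correct = correct)
}

chisq_of_table <- function(tab, correct = FALSE) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("chi-square test infeasible: contingency table needs at least two
           non-empty rows and columns",
          class = "tpt_test_infeasible_error")
  }
  if (!(nrow(tab) == 2 && ncol(tab) == 2)) correct <- FALSE
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  if (any(ht$expected <= 0)) {
    abort("chi-square test infeasible: zero expected counts",
          class = "tpt_test_infeasible_error")
  }
  structure(list(statistic = unname(ht$statistic),
                 dof = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 table = tab),
            class = "tpt_chisq")
}

#' ATC level-1 class of a drug code
#'
#' The Anatomical Therapeutic Chemical classification's first character is
#' the level-1 organ/anatomical-system class (e.g. `N` nervous system, `L`
#' antineoplastic and immunomodulating agents). Vectorised; lowercase input
#' is normalised.
#'
#' @param atc_code Character vector of ATC codes (1-7 characters).
#' @return Character vector of single uppercase letters A-V.
#' @export
#' @examples
#' atc_level1("L01XE06")  # "L" - dasatinib, antineoplastic/immunomodulating
atc_level1 <- function(atc_code) {
  if (length(atc_code) == 0 || any(is.na(atc_code) | nchar(atc_code) == 0)) {
    abort("ATC code must be non-empty", class = "tpt_invalid_code_error")
  }
  lvl1 <- toupper(substr(atc_code, 1, 1))
  bad <- !lvl1 %in% LETTERS[1:22]  # A through V
  if (any(bad)) {
    abort(paste0("invalid ATC code(s): ",
                 paste(head(unique(atc_code[bad]), 5), collapse = ", "),
                 " (level-1 letter must be A-V)"),
          class = "tpt_invalid_code_error")
  }
  lvl1
}

#' Validate modules against approved-drug ATC classes
#'
#' For each requested ATC level-1 class, counts the distinct network targets
#' having at least one approved drug of that class, grouped by module, and
#' tests the module-by-class count table for independence with Pearson's
#' chi-square (restricted to modules with a nonzero margin). A target with
#' drugs in several classes counts once in each class.
#'
#' @param partition A `tpt_partition`.
#' @param drugs A drug-target table (see [drug_target_table()]).
#' @param classes Character vector of level-1 letters to tally; defaults to
#'   all classes present in `drugs`.
#' @return An object of class `tpt_validation`: list with `counts` (tibble
#'   `module`, `atc_class`, `n_targets`, complete over modules and classes)
#'   and `test` (a `tpt_chisq`, or `NULL` when the table is degenerate).
#' @export
drug_target_validation <- function(partition, drugs, classes = NULL) {
  stopifnot(inherits(partition, "tpt_partition"))
  drugs <- dplyr::mutate(drugs, atc_class = atc_level1(.data$atc_code))
  if (is.null(classes)) classes <- sort(unique(drugs$atc_class))
  drugged <- drugs |>
    dplyr::filter(.data$atc_class %in% classes) |>
    dplyr::inner_join(partition$assignment, by = "target_id")
  if (nrow(drugged) == 0) {
    warn("no drugged targets present in the network",
         class = "tpt_empty_warning")
    return(structure(list(
      counts = tibble(module = integer(), atc_class = character(),
                      n_targets = integer()),
      test = NULL), class = "tpt_validation"))
  }
  counts <- drugged |>
    dplyr::distinct(.data$module, .data$atc_class, .data$target_id) |>
    dplyr::count(.data$module, .data$atc_class, name = "n_targets") |>
    tidyr::complete(module = sort(unique(partition$assignment$module)),
                    atc_class = classes, fill = list(n_targets = 0L)) |>
    dplyr::mutate(n_targets = as.integer(.data$n_targets)) |>
    dplyr::arrange(.data$module, .data$atc_class)
  tab <- tidyr::pivot_wider(counts, names_from = "atc_class",
                            values_from = "n_targets")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab$module)
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  test <- tryCatch(chisq_of_table(mat),
                   tpt_test_infeasible_error = function(e) NULL)
  structure(list(counts = counts, test = test), class = "tpt_validation")
}

#' Module contributions restricted to relevant diseases
#'
#' Selects the contribution-score columns of the formula-relevant diseases
#' (scores are already normalised to sum to 1 over modules per disease) and
#' identifies the module with the largest mean score across them - the
#' candidate therapeutic module. Ties go to the smallest module id.
#'
#' @param cm A `tpt_contribution`.
#' @param relevant Character vector of disease ids present in `cm`.
#' @return An object of class `tpt_relevance`: list with `scores` (tibble
#'   `module`, `disease_id`, `cs` for relevant diseases), `mean_cs` (tibble
#'   `module`, `mean_cs`), and `selected_module` (integer).
#' @export
relevant_disease_ratio <- function(cm, relevant) {
  stopifnot(inherits(cm, "tpt_contribution"))
  known <- unique(cm$scores$disease_id)
  unknown <- setdiff(relevant, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown disease id(s): ", paste(unknown, collapse = ", ")),
          class = "tpt_lookup_error")
  }
  scores <- dplyr::filter(cm$scores, .data$disease_id %in% relevant)[
    c("module", "disease_id", "cs")]
  mean_cs <- scores |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(mean_cs = mean(.data$cs), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_cs), .data$module)
  structure(list(scores = scores, mean_cs = mean_cs,
                 selected_module = mean_cs$module[1]),
            class = "tpt_relevance")
}
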