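#' @export
print.tpt_partition <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat("TPT module partition:", nrow(x$assignment), "targets in",
      length(x$modules), "modules\n")
  cat("  modularity:", format(x$modularity, digits = 4),
      " resolution:", x$resolution, " seed:", x$seed,
      " weighting:", x$weighting, "\n")
  cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.tpt_contribution <- function(x, ...) {
  cat("Contribution scores:", length(unique(x$scores$module)), "modules x",
      length(unique(x$scores$disease_id)), "diseases\n")
  print(contribution_matrix(x), digits = 3)
  invisible(x)
}

#' @export
print.tpt_chisq <- function(x, ...) {
  cat("Chi-square test of module-disease independence\n")
  cat("  X-squared =", format(x$statistic, digits = 5),
      " df =", x$dof, " p-value =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @export
print.tpt_relevance <- function(x, ...) {
  cat("Module contributions to", length(unique(x$scores$disease_id)),
      "relevant disease(s); selected module:", x$selected_module, "\n")
  print(x$mean_cs, n = 5)
  invisible(x)
}

#' @export
print.tpt_run <- function(x, ...) {
  cat("TPT pipeline run\n")
  cat("  network:", igraph::vcount(x$network), "targets,",
      igraph::ecount(x$network), "edges\n")
  cat("  modules:", length(x$partition$modules),
      "(modularity", format(x$partition$modularity, digits = 4), ")\n")
  if (!is.null(x$association)) {
    cat("  module-disease chi-square p =",
        format.pval(x$association$p_value, digits = 4), "\n")
  }
  cat("  selected module:", x$selected_module, "->",
      nrow(x$selection), "top targets\n")
  invisible(x)
}

#' Tidy a module partition
#'
#' @param x A `tpt_partition`.
#' @param ... Unused.
#' @return A tibble with one row per target: `target_id`, `module`.
#' @exportS3Method generics::tidy
tidy.tpt_partition <- function(x, ...) x$assignment

#' One-row summary of a module partition
#'
#' @param x A `tpt_partition`.
#' @param ... Unused.
#' @return A tibble with `n_targets`, `n_modules`, `modularity`,
#'   `resolution`, `seed`, `weighting`.
#' @exportS3Method generics::glance
glance.tpt_partition <- function(x, ...) {
  tibble(n_targets = nrow(x$assignment), n_modules = length(x$modules),
         modularity = x$modularity, resolution = x$resolution,
         seed = x$seed, weighting = x$weighting)
}

#' Tidy a contribution-score matrix
#'
#' @param x A `tpt_contribution`.
#' @param ... Unused.
#' @return A long tibble: `module`, `disease_id`, `cs`, `n_shared_pathways`.
#' @exportS3Method generics::tidy
tidy.tpt_contribution <- function(x, ...) x$scores

#' One-row summary of a contribution-score matrix
#'
#' @param x A `tpt_contribution`.
#' @param ... Unused.
#' @return A tibble with `n_modules`, `n_diseases`, `n_pathways_covered`.
#' @exportS3Method generics::glance
glance.tpt_contribution <- function(x, ...) {
  tibble(n_modules = length(unique(x$scores$module)),
         n_diseases = length(unique(x$scores$disease_id)),
         n_pathways_covered = sum(x$u$u > 0))
}

#' Tidy a chi-square association test
#'
#' @param x A `tpt_chisq`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `dof`, `p_value`.
#' @exportS3Method generics::tidy
tidy.tpt_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, dof = x$dof, p_value = x$p_value)
}

#' Tidy a target-importance ranking
#'
#' @param x A `tpt_ranking`.
#' @param ... Unused.
#' @return The ranking as a plain tibble.
#' @exportS3Method generics::tidy
tidy.tpt_ranking <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tpt_ranking")
  out
}

#' One-row summary of a target-importance ranking
#'
#' @param x A `tpt_ranking`.
#' @param ... Unused.
#' @return A tibble with `n_targets`, `module_id`, `scope`, `max_ti`,
#'   `min_ti`.
#' @exportS3Method generics::glance
glance.tpt_ranking <- function(x, ...) {
  tibble(n_targets = nrow(x),
         module_id = attr(x, "module_id"),
         scope = attr(x, "scope"),
         max_ti = max(x$ti), min_ti = min(x$ti))
}

#' Heat map of contribution scores
#'
#' Modules in rows, diseases in columns, white (0) to deep blue (high CS).
#'
#' @param object A `tpt_contribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tpt_contribution <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease_id,
                                   y = factor(.data$module),
                                   fill = .data$cs)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306B",
                                 limits = c(0, 1), name = "CS") +
    ggplot2::labs(x = "Disease", y = "Module") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Target-importance profile of a ranked module
#'
#' Lollipop chart of TI with the four normalised centralities overlaid.
#'
#' @param object A `tpt_ranking`.
#' @param top_n Show only the first `top_n` targets (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tpt_ranking <- function(object, top_n = nrow(object), ...) {
  df <- head(as_tibble(object), top_n)
  df$target_id <- factor(df$target_id, levels = rev(df$target_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ti, y = .data$target_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$ti,
                                       yend = .data$target_id),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "#08306B", size = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Target importance (TI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Approved-drug validation counts per module
#'
#' Grouped bar chart of the number of drugged targets per module and ATC
#' level-1 class.
#'
#' @param validation A `tpt_validation` from [drug_target_validation()].
#' @return A ggplot object.
#' @export
plot_validation_counts <- function(validation) {
  stopifnot(inherits(validation, "tpt_validation"))
  ggplot2::ggplot(validation$counts,
                  ggplot2::aes(x = factor(.data$module),
                               y = .data$n_targets,
                               fill = .data$atc_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Module", y = "Drugged targets",
                  fill = "ATC level 1") +
    ggplot2::theme_minimal()
}
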