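#' Worked-example fixture: three planted modules, five pathways, one disease
#'
#' The didactic 24-target instance used throughout the documentation and
#' tests: nine targets (T-A1..T-A9) form module 1, eight (T-B1..T-B8)
#' module 2, and seven (T-C1..T-C7) module 3. Pathways p1 and p2 annotate
#' only module-1 targets; p3 annotates targets from modules 1 and 2; p4
#' from modules 1 and 3; p5 from all three. Disease d1 is supported by all
#' five pathways, so u = (1, 1, 2, 2, 3), v\[d1\] = 5, and the contribution
#' scores are 2/3, 1/6 and 1/6 for modules 1-3.
#'
#' The exact within-group wiring (which members carry the cross-module
#' pathways) is a package choice: each group is annotated in full to at
#' least one pathway so it is internally connected, and weighted Louvain at
#' resolution 1.0 recovers the three groups for every seed.
#'
#' @return An object of class `tpt_instance`: list with `annotation`,
#'   `pathway_disease`, `truth` (list of `modules` and `disease_modules`
#'   tibbles), and `seed` (`NA`; the fixture is deterministic).
#' @export
#' @examples
#' fx <- fig7_fixture()
#' g <- build_tpt(fx$annotation)
#' igraph::vcount(g)  # 24
fig7_fixture <- function() {
  grp_a <- sprintf("T-A%d", 1:9)
  grp_b <- sprintf("T-B%d", 1:8)
  grp_c <- sprintf("T-C%d", 1:7)
  members <- list(
    p1 = grp_a,
    p2 = grp_a,
    p3 = c("T-A1", grp_b),
    p4 = c("T-A3", grp_c),
    p5 = c("T-A2", "T-B2", "T-C2")
  )
  annotation <- purrr::imap_dfr(members, function(tgts, pw) {
    tibble(target_id = tgts, pathway_id = pw)
  })
  pathway_disease <- tibble(pathway_id = paste0("p", 1:5), disease_id = "d1")
  truth <- list(
    modules = tibble(target_id = c(grp_a, grp_b, grp_c),
                     module = rep(1:3, c(9, 8, 7))),
    disease_modules = tibble(disease_id = "d1", module = 1L))
  structure(list(annotation = annotation_table(annotation),
                 pathway_disease = pathway_disease_table(pathway_disease),
                 truth = truth, seed = NA_integer_),
            class = "tpt_instance")
}

#' Random planted-module instance generator
#'
#' Generates a bipartite target-pathway annotation with planted modules and
#' a pathway-disease table with module-specific disease propensity, for
#' property tests and power studies. Each module receives
#' `pathways_per_module` private pathways: the first annotates all of the
#' module's targets (guaranteeing internal connectivity and full target
#' coverage), the rest annotate random subsets of at least two targets.
#' `round(cross_pathway_rate * n_modules * pathways_per_module)` additional
#' cross pathways each annotate two random targets from each of two random
#' modules. Every disease is owned by one module (cycled over modules) and
#' linked to `pathways_per_module` pathways; each link comes from the
#' owner's private pathways with probability `propensity` and from the
#' remaining pathways otherwise.
#'
#' @param n_modules Number of planted modules (>= 1).
#' @param targets_per_module Targets in each module (>= 2).
#' @param pathways_per_module Private pathways per module (>= 1).
#' @param cross_pathway_rate Rate in \[0, 1\] of cross-module pathways
#'   relative to the number of private pathways.
#' @param n_diseases Number of diseases (>= 1).
#' @param propensity Probability in (0, 1\] that a disease link goes to its
#'   owner module's private pathways.
#' @param seed Integer seed; the instance is reproducible from it.
#' @return A `tpt_instance` (see [fig7_fixture()]) whose `truth` records
#'   the planted module of every target and the owner module of every
#'   disease.
#' @export
generate_planted <- function(n_modules = 5, targets_per_module = 20,
                             pathways_per_module = 5,
                             cross_pathway_rate = 0.1,
                             n_diseases = n_modules, propensity = 0.9,
                             seed = 1L) {
  if (n_modules < 1 || targets_per_module < 2 || n_diseases < 1) {
    abort("counts must be positive (and >= 2 targets per module)",
          class = "tpt_usage_error")
  }
  if (pathways_per_module < 1) {
    abort("parameters imply zero pathways", class = "tpt_usage_error")
  }
  stopifnot(cross_pathway_rate >= 0, cross_pathway_rate <= 1,
            propensity > 0, propensity <= 1)

  withr::with_seed(as.integer(seed), {
    targets <- lapply(seq_len(n_modules), function(i) {
      sprintf("M%02d-T%03d", i, seq_len(targets_per_module))
    })
    private <- lapply(seq_len(n_modules), function(i) {
      sprintf("M%02d-P%03d", i, seq_len(pathways_per_module))
    })

    ann <- list()
    for (i in seq_len(n_modules)) {
      ann[[length(ann) + 1]] <- tibble(target_id = targets[[i]],
                                       pathway_id = private[[i]][1])
      if (pathways_per_module > 1) {
        for (k in 2:pathways_per_module) {
          size <- sample(2:targets_per_module, 1)
          ann[[length(ann) + 1]] <- tibble(
            target_id = sample(targets[[i]], size),
            pathway_id = private[[i]][k])
        }
      }
    }

    n_cross <- round(cross_pathway_rate * n_modules * pathways_per_module)
    cross <- character(0)
    if (n_cross > 0 && n_modules >= 2) {
      for (k in seq_len(n_cross)) {
        pw <- sprintf("X-P%03d", k)
        cross <- c(cross, pw)
        mods <- sample(n_modules, 2)
        picks <- c(sample(targets[[mods[1]]], min(2, targets_per_module)),
                   sample(targets[[mods[2]]], min(2, targets_per_module)))
        ann[[length(ann) + 1]] <- tibble(target_id = picks, pathway_id = pw)
      }
    }
    annotation <- dplyr::distinct(dplyr::bind_rows(ann))

    all_pathways <- c(unlist(private), cross)
    owner <- ((seq_len(n_diseases) - 1) %% n_modules) + 1
    pd <- list()
    for (j in seq_len(n_diseases)) {
      own_pool <- private[[owner[j]]]
      other_pool <- setdiff(all_pathways, own_pool)
      k <- pathways_per_module
      n_own <- stats::rbinom(1, k, propensity)
      n_own <- min(n_own, length(own_pool))
      n_other <- min(k - n_own, length(other_pool))
      picked <- c(sample(own_pool, n_own),
                  if (n_other > 0) sample(other_pool, n_other))
      if (length(picked) == 0) picked <- sample(own_pool, 1)
      pd[[j]] <- tibble(pathway_id = unique(picked),
                        disease_id = sprintf("D%03d", j))
    }
    pathway_disease <- dplyr::bind_rows(pd)

    truth <- list(
      modules = tibble(target_id = unlist(targets),
                       module = rep(seq_len(n_modules),
                                    each = targets_per_module)),
      disease_modules = tibble(disease_id = sprintf("D%03d",
                                                    seq_len(n_diseases)),
                               module = as.integer(owner)))
    structure(list(annotation = annotation_table(annotation),
                   pathway_disease = pathway_disease_table(pathway_disease),
                   truth = truth, seed = as.integer(seed)),
              class = "tpt_instance")
  })
}

#' Write a synthetic instance to TSV files
#'
#' Emits `annotation.tsv`, `pathway_disease.tsv`, `truth_modules.tsv` and
#' `truth_diseases.tsv` in the same formats the pipeline reads, so
#' generated instances double as end-to-end fixtures.
#'
#' @param instance A `tpt_instance`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "tpt_instance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(instance$annotation, file.path(dir, "annotation.tsv"),
                   progress = FALSE)
  readr::write_tsv(instance$pathway_disease,
                   file.path(dir, "pathway_disease.tsv"), progress = FALSE)
  readr::write_tsv(instance$truth$modules,
                   file.path(dir, "truth_modules.tsv"), progress = FALSE)
  readr::write_tsv(instance$truth$disease_modules,
                   file.path(dir, "truth_diseases.tsv"), progress = FALSE)
  invisible(dir)
}
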