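# Independent brute-force oracles used to cross-check the implementation.

# Upper-tail hypergeometric probability by exhaustive enumeration of every
# possible query draw from the universe (feasible for small universes).
brute_hyper_p <- function(universe_size, pathway_size, query_size, overlap) {
  universe <- seq_len(universe_size)
  members <- seq_len(pathway_size)  # which elements belong to the pathway
  draws <- utils::combn(universe, query_size)
  hits <- apply(draws, 2, function(d) sum(d %in% members) >= overlap)
  mean(hits)
}

# Contribution scores by a plain triple loop over (module, disease, pathway),
# written against the definitions only: a pathway hands 1/u to each incident
# module, a disease receives 1/v from each of its pathways.
brute_cs <- function(assignment, annotation, pathway_disease) {
  mod_of <- setNames(assignment$module, assignment$target_id)
  pathways <- unique(annotation$pathway_id)
  diseases <- unique(pathway_disease$disease_id)
  modules <- sort(unique(assignment$module))

  mods_of_pathway <- lapply(setNames(pathways, pathways), function(p) {
    sort(unique(mod_of[annotation$target_id[annotation$pathway_id == p]]))
  })
  u <- vapply(mods_of_pathway, length, integer(1))
  v <- vapply(setNames(diseases, diseases), function(d) {
    length(unique(pathway_disease$pathway_id[pathway_disease$disease_id == d]))
  }, integer(1))

  out <- matrix(0, nrow = length(modules), ncol = length(diseases),
                dimnames = list(as.character(modules), diseases))
  for (m in modules) {
    for (d in diseases) {
      rel <- unique(pathway_disease$pathway_id[pathway_disease$disease_id == d])
      for (p in rel) {
        if (p %in% pathways && m %in% mods_of_pathway[[p]]) {
          out[as.character(m), d] <- out[as.character(m), d] +
            1 / (u[[p]] * v[[d]])
        }
      }
    }
  }
  out
}

# Wrap a ground-truth module assignment as a partition object so scoring can
# be tested independently of Louvain.
partition_from_truth <- function(truth_modules) {
  structure(list(assignment = truth_modules[c("target_id", "module")],
                 modules = sort(unique(truth_modules$module)),
                 modularity = NA_real_, resolution = 1,
                 seed = NA_integer_, weighting = "shared_pathway_count"),
            class = "tpt_partition")
}

# Long contribution scores -> named matrix for easy comparison.
cs_matrix <- function(cm) tptnet::contribution_matrix(cm, "cs")

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
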