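# toy graphs expressed as annotations: one pathway per edge
graph_from_edges <- function(edges) {
  ann <- tibble::tibble(
    target_id = c(edges[, 1], edges[, 2]),
    pathway_id = rep(sprintf("e%03d", seq_len(nrow(edges))), 2))
  build_tpt(annotation_table(ann))
}

test_that("the hub of a star maximises all four centralities with TI 1", {
  edges <- cbind("HUB", sprintf("S%d", 1:4))
  g <- graph_from_edges(edges)
  cent <- compute_centralities(g, igraph::V(g)$name)
  ranking <- target_importance(cent)
  hub <- ranking[ranking$target_id == "HUB", ]
  expect_equal(hub$ti, 1)
  expect_equal(hub$rank, 1L)
  leaves <- ranking[ranking$target_id != "HUB", ]
  expect_true(all(leaves$ti < 1))
  expect_lt(diff(range(leaves$ti)), 1e-12)  # symmetric leaves
})

test_that("the middle of a path carries all the betweenness", {
  g <- graph_from_edges(rbind(c("A", "B"), c("B", "C")))
  cent <- compute_centralities(g, c("A", "B", "C"))
  bc <- setNames(cent$bc, cent$target_id)
  expect_equal(bc[["A"]], 0)
  expect_equal(bc[["C"]], 0)
  expect_gt(bc[["B"]], 0)
  expect_equal(bc[["B"]], 1)  # one shortest path A-C passes through B
})

test_that("vertex-transitive cycles give every node identical TI", {
  n <- 6
  edges <- cbind(sprintf("N%d", 1:n), sprintf("N%d", c(2:n, 1)))
  g <- graph_from_edges(edges)
  cent <- compute_centralities(g, igraph::V(g)$name)
  ranking <- target_importance(cent)
  expect_lt(diff(range(ranking$ti)), 1e-12)
  expect_lt(diff(range(cent$dc)), 1e-12)
  expect_lt(diff(range(cent$bc)), 1e-12)
  expect_lt(diff(range(cent$cc)), 1e-12)
  expect_lt(diff(range(cent$ec)), 1e-12)
})

test_that("TI equals its definition recomputed from the raw columns", {
  inst <- generate_planted(n_modules = 2, targets_per_module = 10,
                           pathways_per_module = 4,
                           cross_pathway_rate = 0.2, seed = 7)
  g <- build_tpt(inst$annotation)
  mod1 <- inst$truth$modules$target_id[inst$truth$modules$module == 1]
  cent <- compute_centralities(g, mod1)
  ranking <- target_importance(cent)
  norm <- function(x) if (max(x) <= 0) rep(0, length(x)) else x / max(x)
  manual <- (norm(cent$dc) + norm(cent$bc) + norm(cent$cc) + norm(cent$ec)) / 4
  manual <- manual[order(-manual, cent$target_id)]
  expect_equal(ranking$ti, unname(manual), tolerance = 1e-12)
  expect_true(all(ranking$ti >= 0 & ranking$ti <= 1))
})

test_that("rescaling one centrality column leaves TI unchanged", {
  inst <- generate_planted(n_modules = 2, targets_per_module = 8, seed = 3)
  g <- build_tpt(inst$annotation)
  mod1 <- inst$truth$modules$target_id[inst$truth$modules$module == 1]
  cent <- compute_centralities(g, mod1)
  base <- target_importance(cent)
  for (col in c("dc", "bc", "cc", "ec")) {
    scaled <- cent
    scaled[[col]] <- scaled[[col]] * 37.5
    expect_equal(target_importance(scaled)$ti, base$ti, tolerance = 1e-12)
    expect_equal(target_importance(scaled)$target_id, base$target_id)
  }
})

test_that("an all-zero centrality contributes 0 while the denominator stays 4", {
  # a clique has zero betweenness everywhere; remaining three ratios are 1
  edges <- t(utils::combn(sprintf("K%d", 1:4), 2))
  g <- graph_from_edges(edges)
  cent <- compute_centralities(g, igraph::V(g)$name)
  expect_true(all(cent$bc == 0))
  ranking <- target_importance(cent)
  expect_equal(ranking$ti, rep(3 / 4, 4), tolerance = 1e-12)
})

test_that("degenerate modules are rejected", {
  g <- graph_from_edges(rbind(c("A", "B")))
  expect_error(compute_centralities(g, "A"),
               class = "tpt_degenerate_module_error")
  expect_error(target_importance(tibble::tibble(
    target_id = "A", dc = 1, bc = 0, cc = 1, ec = 1)),
    class = "tpt_degenerate_module_error")
  # a two-node module is symmetric; betweenness is zero for both, so its
  # normalised term contributes 0 and both targets get ti = 3/4
  both <- target_importance(compute_centralities(g, c("A", "B")))
  expect_equal(both$ti, c(3 / 4, 3 / 4))
})

test_that("scope controls whether centralities see the whole network", {
  fx <- fig7_fixture()
  g <- build_tpt(fx$annotation)
  mod1 <- fx$truth$modules$target_id[fx$truth$modules$module == 1]
  sub <- compute_centralities(g, mod1, scope = "module_subgraph")
  full <- compute_centralities(g, mod1, scope = "full_network")
  expect_setequal(sub$target_id, full$target_id)
  # T-A1 bridges to module 2 only in the full network, where it gains
  # degree and betweenness over its subgraph values
  a1_sub <- sub[sub$target_id == "T-A1", ]
  a1_full <- full[full$target_id == "T-A1", ]
  expect_gt(a1_full$dc, a1_sub$dc)
  expect_gt(a1_full$bc, a1_sub$bc)
})

test_that("top-fraction selection uses ceiling semantics", {
  fake <- tibble::tibble(
    target_id = sprintf("T%03d", 1:199),
    dc = 199:1, bc = 0, cc = 199:1, ec = 199:1)
  ranking <- target_importance(fake)
  expect_equal(nrow(top_fraction(ranking, 0.1)), 20)
  expect_equal(nrow(top_fraction(head(ranking, 10), 1.0)), 10)
  expect_equal(nrow(top_fraction(head(ranking, 7), 0.1)), 1)
  expect_equal(top_fraction(ranking, 0.1)$rank, 1:20)
  expect_error(top_fraction(ranking, 0))
})

test_that("compound attachment preserves order and tolerates absent targets", {
  compounds <- compound_target_table(tibble::tibble(
    compound_id = c("C1", "C2", "C3"),
    target_id = c("T1", "T1", "T3"),
    above_threshold = c(TRUE, FALSE, TRUE)))
  sel <- tibble::tibble(target_id = c("T2", "T1"))
  out <- attach_compounds(sel, compounds)
  expect_equal(out$target_id, c("T2", "T1"))
  expect_equal(nrow(out$compounds[[1]]), 0)
  expect_equal(out$compounds[[2]]$compound_id, c("C1", "C2"))
  expect_equal(out$compounds[[2]]$above_threshold, c(TRUE, FALSE))
})

test_that("eigenvector scores agree with an independent eigensolver", {
  inst <- generate_planted(n_modules = 1, targets_per_module = 12,
                           pathways_per_module = 4, seed = 13)
  g <- build_tpt(inst$annotation)
  cent <- compute_centralities(g, igraph::V(g)$name)
  ref <- igraph::eigen_centrality(g, weights = NA)$vector
  expect_equal(cent$ec, unname(ref[cent$target_id]), tolerance = 1e-6)
})
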