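# Small deterministic graph and annotation builders shared by the tests.

# weighted graph from an edge data.frame (a, b, w) + optional isolated
# vertices; vertex names sorted as build_nip() would
fixture_graph <- function(edges = NULL, isolated = character()) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  vs <- sort(unique(c(if (!is.null(edges)) c(edges$a, edges$b), isolated)))
  g <- igraph::add_vertices(g, length(vs), name = vs,
                            category = rep("uncategorized", length(vs)))
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b), weight = edges$w)
  }
  g$taxon_id <- "fixture"
  g
}

# Erdos-Renyi-ish random weighted graph; weights from {1,2,4,8} so that
# reciprocal lengths are exact dyadic doubles (no floating near-ties in
# weighted shortest paths between implementation and oracle)
random_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  vs <- sprintf("P%02d", seq_len(n))
  pairs <- utils::combn(vs, 2)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- if (any(keep)) {
    data.frame(a = pairs[1, keep], b = pairs[2, keep],
               w = sample(c(1, 2, 4, 8), sum(keep), replace = TRUE))
  }
  fixture_graph(edges, isolated = vs)
}

# random pathway->metabolite annotation for NIP-construction properties
random_annotation <- function(n_pathways, n_metabolites, mean_size = 4,
                              seed = 1) {
  set.seed(seed)
  mets <- sprintf("m%03d", seq_len(n_metabolites))
  pw <- lapply(seq_len(n_pathways), function(i) {
    sort(unique(sample(mets, max(1, stats::rpois(1, mean_size)))))
  })
  stats::setNames(pw, sprintf("P%02d", seq_len(n_pathways)))
}

write_annotation_fixture <- function(dir, rows, taxa) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_path <- file.path(dir, "annotations.tsv")
  writeLines(c("taxon_id\tpathway_id\tmetabolite_id", rows), ann_path)
  taxa_path <- file.path(dir, "taxa.tsv")
  writeLines(taxa, taxa_path)
  list(annotations = ann_path, taxa = taxa_path)
}

# scaled-down analogue of default_scenario() for fast file-level tests
default_scenario_small <- function(effect_size = 1) {
  group_effect_spec(
    contrast_name = "lifestyle",
    groups = list(
      list(label = "rich", n_taxa = 5, pathway_retention = 0.90),
      list(label = "reduced", n_taxa = 5, pathway_retention = 0.50,
           retention_bias_by_category = c(lipid = 0.5, glycan = 0.5))),
    effect_size = effect_size)
}

k4_nip <- function() {
  build_nip(list(P1 = c("a", "b", "c"), P2 = c("a", "d", "e"),
                 P3 = c("b", "d", "f"), P4 = c("c", "e", "f")))
}
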