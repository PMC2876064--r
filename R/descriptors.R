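#' Pairwise pathway distances in a NIP
#'
#' Unweighted distances are hop counts; weighted distances use edge length
#' `1/weight`, so pathway pairs exchanging many metabolites are effectively
#' closer. Unreachable pairs are `Inf`.
#'
#' @param nip A NIP graph.
#' @param weighted Use reciprocal-weight edge lengths?
#' @return Symmetric numeric matrix with vertex names as dimnames.
#' @export
nip_distances <- function(nip, weighted = FALSE) {
  w <- if (weighted) edge_lengths(nip) else NA
  igraph::distances(nip, weights = w, algorithm = "dijkstra")
}

edge_lengths <- function(nip) {
  if (igraph::ecount(nip) == 0) return(numeric())
  1 / igraph::E(nip)$weight
}

#' Shortest-path betweenness of pathways or pathway links
#'
#' Brandes-style betweenness: the fraction of shortest paths between all
#' vertex pairs that pass through a vertex (or edge), with equal-length path
#' multiplicity split evenly. Vertex values are normalized by
#' `(n-1)(n-2)/2` (the unordered pairs that exclude the vertex), edge values
#' by `n(n-1)/2`. The weighted variant measures the fraction of metabolite
#' exchange routed through an element, using `1/weight` edge lengths.
#'
#' @param nip A NIP graph.
#' @param element `"vertex"` or `"edge"`.
#' @param weighted Use reciprocal-weight edge lengths?
#' @return Named numeric vector (edges named `"a|b"` with sorted endpoints).
#' @export
nip_betweenness <- function(nip, element = c("vertex", "edge"),
                            weighted = FALSE) {
  element <- match.arg(element)
  n <- igraph::vcount(nip)
  w <- if (weighted) edge_lengths(nip) else NA
  if (element == "vertex") {
    if (n < 3) {
      return(stats::setNames(rep(0, n), igraph::V(nip)$name))
    }
    b <- igraph::betweenness(nip, directed = FALSE, weights = w)
    return(stats::setNames(as.numeric(b) / ((n - 1) * (n - 2) / 2),
                           igraph::V(nip)$name))
  }
  m <- igraph::ecount(nip)
  if (m == 0) return(stats::setNames(numeric(), character()))
  b <- igraph::edge_betweenness(nip, directed = FALSE, weights = w)
  el <- igraph::as_edgelist(nip)
  nm <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  stats::setNames(as.numeric(b) / (n * (n - 1) / 2), nm)
}

#' Harmonic closeness centrality of pathways
#'
#' `C(v) = (1/(n-1)) * sum_{u != v} 1/d(v,u)`, with `1/Inf = 0`, so the
#' measure is well defined on disconnected NIPs. The weighted variant uses
#' `1/weight` edge lengths.
#'
#' @param nip A NIP graph.
#' @param weighted Use reciprocal-weight edge lengths?
#' @return Named numeric vector in `[0, 1]` for unweighted graphs.
#' @export
nip_closeness <- function(nip, weighted = FALSE) {
  n <- igraph::vcount(nip)
  if (n <= 1) return(stats::setNames(rep(0, n), igraph::V(nip)$name))
  d <- nip_distances(nip, weighted = weighted)
  diag(d) <- Inf
  stats::setNames(rowSums(1 / d) / (n - 1), igraph::V(nip)$name)
}

#' Clustering coefficient of pathways
#'
#' Unweighted: the fraction of a pathway's neighbour pairs that are
#' themselves linked. Weighted: the Barrat coefficient
#' `C_w(i) = 1/(s_i (k_i - 1)) * sum over triangles (i,j,h) of
#' (w_ij + w_ih)/2`, which rewards strong cross-talk within closed triads.
#' Vertices of degree < 2 get 0.
#'
#' @param nip A NIP graph.
#' @param weighted Use the Barrat weighted formulation?
#' @return Named numeric vector in `[0, 1]`.
#' @export
nip_clustering <- function(nip, weighted = FALSE) {
  n <- igraph::vcount(nip)
  if (n == 0) return(stats::setNames(numeric(), character()))
  if (weighted) {
    cc <- igraph::transitivity(nip, type = "barrat",
                               weights = igraph::E(nip)$weight,
                               isolates = "zero")
  } else {
    cc <- igraph::transitivity(nip, type = "local", isolates = "zero")
  }
  cc[!is.finite(cc)] <- 0
  stats::setNames(as.numeric(cc), igraph::V(nip)$name)
}

#' Maximal cliques of a NIP
#'
#' All maximal cliques (Bron–Kerbosch with pivoting), i.e. completely
#' inter-connected pathway subsets not extendable by any pathway. Isolated
#' vertices form singleton maximal cliques. Output is deterministic: each
#' clique sorted by vertex name, cliques sorted by size then lexicographic
#' content.
#'
#' @param nip A NIP graph.
#' @return List of character vectors of pathway ids.
#' @export
nip_maximal_cliques <- function(nip) {
  if (igraph::vcount(nip) == 0) return(list())
  cl <- igraph::max_cliques(nip)
  cl <- lapply(cl, function(v) sort(igraph::V(nip)$name[as.integer(v)]))
  key <- vapply(cl, paste, "", collapse = "\r")
  cl[order(lengths(cl), key)]
}

#' Shannon-type information index of an equivalence distribution
#'
#' Graph elements (vertices, edges, pairs, cliques) are partitioned into
#' classes of equal value of some integer-valued quantity; the class sizes
#' `n_1..n_k` (summing to `N`) define the index:
#' \describe{
#'   \item{AI (average information)}{`-sum (n_i/N) log2(n_i/N)`}
#'   \item{TI (total information)}{`N log2 N - sum n_i log2 n_i`}
#'   \item{NI (normalized information)}{`AI / log2 N`, defined as 0 when
#'     `N = 1`}
#' }
#'
#' @param sizes Positive integer class sizes.
#' @param variant `"AI"`, `"NI"` or `"TI"`.
#' @return A single numeric value.
#' @export
information_index <- function(sizes, variant = c("AI", "NI", "TI")) {
  variant <- match.arg(variant)
  if (!length(sizes) || any(!is.finite(sizes)) || any(sizes <= 0) ||
      any(sizes != round(sizes))) {
    stop("class sizes must be positive integers")
  }
  n <- sum(sizes)
  p <- sizes / n
  ai <- -sum(p * log2(p))
  switch(variant,
         AI = ai,
         TI = n * log2(n) - sum(sizes * log2(sizes)),
         NI = if (n == 1) 0 else ai / log2(n))
}

equiv_sizes <- function(values) {
  if (!length(values)) return(integer())
  as.integer(table(as.character(values)))
}

info_triplet <- function(values) {
  sz <- equiv_sizes(values)
  if (!length(sz)) return(c(NaN, NaN, NaN))
  c(information_index(sz, "AI"), information_index(sz, "NI"),
    information_index(sz, "TI"))
}

info_distributions <- c("degree", "strength", "edge_weight", "distance_sum",
                        "eccentricity", "distance", "clique_size",
                        "clique_membership", "triangle")

#' The canonical 52-descriptor registry
#'
#' 25 basic descriptors of NIP structure (degree/adjacency, distance,
#' centrality, clique/clustering families) and 27 information-theoretic
#' derivatives: average (AI), normalized (NI) and total (TI) information of
#' nine equivalence distributions of integer-valued graph quantities (vertex
#' degrees, vertex strengths, edge weights, vertex distance sums, vertex
#' eccentricities, finite pairwise distances, maximal-clique sizes,
#' per-vertex maximal-clique membership counts, per-vertex triangle counts).
#'
#' @return Data frame with columns `id`, `family`, `weighted`, `derived`,
#'   exactly 52 rows, in the column order of [compute_descriptors()].
#' @export
descriptor_registry <- function() {
  basic <- data.frame(
    id = c("n_vertices", "n_edges", "total_adjacency", "avg_degree",
           "degree_range", "connectedness", "total_weight", "avg_strength",
           "strength_range",
           "radius", "diameter", "total_distance", "avg_distance",
           "node_distance_range", "weighted_avg_distance",
           "avg_degree_centrality", "avg_closeness", "avg_vertex_betweenness",
           "avg_edge_betweenness", "weighted_avg_vertex_betweenness",
           "weighted_avg_edge_betweenness",
           "avg_clustering", "weighted_avg_clustering", "n_maximal_cliques",
           "max_clique_size"),
    family = c(rep("degree", 9), rep("distance", 6), rep("centrality", 6),
               rep("clique", 4)),
    weighted = c(rep(FALSE, 6), TRUE, TRUE, TRUE,
                 rep(FALSE, 5), TRUE,
                 FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                 FALSE, TRUE, FALSE, FALSE),
    derived = FALSE,
    stringsAsFactors = FALSE
  )
  derived <- data.frame(
    id = as.vector(t(outer(info_distributions, c("ai", "ni", "ti"),
                           function(d, v) paste(v, d, sep = "_")))),
    family = rep(c("degree", "degree", "degree", "distance", "distance",
                   "distance", "clique", "clique", "clique"), each = 3),
    weighted = rep(c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE), each = 3),
    derived = TRUE,
    stringsAsFactors = FALSE
  )
  rbind(basic, derived)
}

#' Compute the 52-descriptor profile of a NIP
#'
#' See [descriptor_registry()] for the descriptor list. Distance descriptors
#' on disconnected NIPs are computed over reachable pairs only;
#' eccentricities are within-component. Quantities undefined on a given
#' graph (e.g. edge-weight information of an edgeless graph, average
#' distance when no pair is reachable) are `NaN`.
#'
#' @param nip A NIP graph.
#' @return Named numeric vector of length 52, in registry order.
#' @export
compute_descriptors <- function(nip) {
  reg <- descriptor_registry()
  out <- stats::setNames(rep(NaN, nrow(reg)), reg$id)
  n <- igraph::vcount(nip)
  if (n == 0) {
    warning("empty NIP: all descriptors NaN")
    return(out)
  }
  m <- igraph::ecount(nip)
  deg <- igraph::degree(nip)
  wts <- if (m > 0) igraph::E(nip)$weight else numeric()
  str <- igraph::strength(nip, weights = wts)

  out["n_vertices"] <- n
  out["n_edges"] <- m
  out["total_adjacency"] <- sum(deg)
  out["avg_degree"] <- mean(deg)
  out["degree_range"] <- max(deg) - min(deg)
  out["connectedness"] <- if (n > 1) 2 * m / (n * (n - 1)) else NaN
  out["total_weight"] <- sum(wts)
  out["avg_strength"] <- mean(str)
  out["strength_range"] <- max(str) - min(str)

  d <- nip_distances(nip, weighted = FALSE)
  diag(d) <- NA
  ecc <- apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r)) max(r) else 0
  })
  dist_sums <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  up <- d[upper.tri(d)]
  up <- up[is.finite(up)]
  out["radius"] <- min(ecc)
  out["diameter"] <- max(ecc)
  out["total_distance"] <- if (length(up)) sum(up) else NaN
  out["avg_distance"] <- if (length(up)) mean(up) else NaN
  out["node_distance_range"] <- max(dist_sums) - min(dist_sums)
  dw <- nip_distances(nip, weighted = TRUE)
  diag(dw) <- NA
  upw <- dw[upper.tri(dw)]
  upw <- upw[is.finite(upw)]
  out["weighted_avg_distance"] <- if (length(upw)) mean(upw) else NaN

  out["avg_degree_centrality"] <- if (n > 1) mean(deg / (n - 1)) else NaN
  out["avg_closeness"] <- mean(nip_closeness(nip))
  out["avg_vertex_betweenness"] <- mean(nip_betweenness(nip, "vertex"))
  eb <- nip_betweenness(nip, "edge")
  out["avg_edge_betweenness"] <- if (m > 0) mean(eb) else NaN
  out["weighted_avg_vertex_betweenness"] <-
    mean(nip_betweenness(nip, "vertex", weighted = TRUE))
  ebw <- nip_betweenness(nip, "edge", weighted = TRUE)
  out["weighted_avg_edge_betweenness"] <- if (m > 0) mean(ebw) else NaN

  out["avg_clustering"] <- mean(nip_clustering(nip))
  out["weighted_avg_clustering"] <- mean(nip_clustering(nip, weighted = TRUE))
  # integer-index clique enumeration; the sorted user-facing variant is
  # nip_maximal_cliques(), too slow for graphs with many thousands of cliques
  cliques <- lapply(igraph::max_cliques(nip), as.integer)
  clique_sizes <- lengths(cliques)
  out["n_maximal_cliques"] <- length(cliques)
  out["max_clique_size"] <- max(clique_sizes)
  memb <- tabulate(unlist(cliques), nbins = n)
  tri <- igraph::count_triangles(nip)

  dists <- list(
    degree = deg,
    strength = str,
    edge_weight = wts,
    distance_sum = dist_sums,
    eccentricity = ecc,
    distance = up,
    clique_size = clique_sizes,
    clique_membership = memb,
    triangle = tri
  )
  for (nm in info_distributions) {
    tri3 <- info_triplet(dists[[nm]])
    out[paste(c("ai", "ni", "ti"), nm, sep = "_")] <- tri3
  }
  out
}

#' Descriptor table for a set of NIPs
#'
#' @param nips Named list of NIP graphs (names = taxon ids), e.g. from
#'   [build_nips()].
#' @return Data frame: one row per taxon, column `taxon_id` plus the 52
#'   descriptor columns in registry order.
#' @export
descriptor_table <- function(nips) {
  stopifnot(is.list(nips), !is.null(names(nips)))
  vals <- t(vapply(nips, compute_descriptors,
                   numeric(nrow(descriptor_registry()))))
  df <- data.frame(taxon_id = names(nips), vals,
                   stringsAsFactors = FALSE, row.names = NULL,
                   check.names = FALSE)
  df[order(df$taxon_id), , drop = FALSE]
}

#' Write / read a descriptor table as TSV
#'
#' Values are written with full (17 significant digit) precision so
#' round-trips and repeated runs are byte-identical.
#'
#' @param desc Data frame from [descriptor_table()].
#' @param path TSV path.
#' @return `write_descriptors`: invisibly `path`; `read_descriptors`: the
#'   data frame.
#' @export
write_descriptors <- function(desc, path) {
  cells <- vapply(desc[-1], function(col) {
    sprintf("%.17g", col)
  }, character(nrow(desc)))
  if (nrow(desc) == 1) cells <- matrix(cells, nrow = 1)
  writeLines(c(paste(names(desc), collapse = "\t"),
               paste(desc$taxon_id, apply(cells, 1, paste, collapse = "\t"),
                     sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(taxon_id = "character"))
  df
}
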