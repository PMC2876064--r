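# Naive, independent reference implementations used to cross-check the
# package's descriptor suite. They work from the raw edge list only and use
# none of the package's computational code paths (no igraph algorithms):
# Floyd-Warshall distances, DP path counting, exhaustive simple-path
# enumeration, 2^n subset clique enumeration, direct formula evaluation.

o_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  list(v = sort(igraph::V(g)$name), a = el[, 1], b = el[, 2], w = w)
}

o_length_matrix <- function(ed, weighted) {
  n <- length(ed$v)
  L <- matrix(Inf, n, n, dimnames = list(ed$v, ed$v))
  diag(L) <- 0
  len <- if (weighted) 1 / ed$w else rep(1, length(ed$w))
  for (k in seq_along(ed$a)) {
    L[ed$a[k], ed$b[k]] <- len[k]
    L[ed$b[k], ed$a[k]] <- len[k]
  }
  L
}

# Floyd-Warshall all-pairs shortest distances
o_dist <- function(g, weighted = FALSE) {
  ed <- o_edges(g)
  D <- o_length_matrix(ed, weighted)
  n <- nrow(D)
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# shortest-path counts sigma[s, t] via DP over targets in distance order
o_sigma <- function(L, D) {
  n <- nrow(D)
  S <- matrix(0, n, n, dimnames = dimnames(D))
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s) { S[s, s] <- 1; next }
      if (!is.finite(D[s, t])) next
      acc <- 0
      for (u in seq_len(n)) {
        if (u != t && is.finite(L[u, t]) && L[u, t] > 0 &&
            D[s, u] + L[u, t] == D[s, t]) {
          acc <- acc + S[s, u]
        }
      }
      S[s, t] <- acc
    }
  }
  S
}

o_betweenness_vertex <- function(g, weighted = FALSE) {
  ed <- o_edges(g)
  L <- o_length_matrix(ed, weighted)
  D <- o_dist(g, weighted)
  S <- o_sigma(L, D)
  n <- nrow(D)
  bc <- stats::setNames(rep(0, n), ed$v)
  if (n < 3) return(bc)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || S[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

o_betweenness_edge <- function(g, weighted = FALSE) {
  ed <- o_edges(g)
  L <- o_length_matrix(ed, weighted)
  D <- o_dist(g, weighted)
  S <- o_sigma(L, D)
  n <- nrow(D)
  m <- length(ed$a)
  nm <- paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b), sep = "|")
  bc <- stats::setNames(rep(0, m), nm)
  if (m == 0 || n < 2) return(bc)
  ai <- match(ed$a, ed$v); bi <- match(ed$b, ed$v)
  len <- if (weighted) 1 / ed$w else rep(1, m)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || S[s, t] == 0) next
    for (k in seq_len(m)) {
      u <- ai[k]; v <- bi[k]
      acc <- 0
      if (is.finite(D[s, u]) && is.finite(D[v, t]) &&
          D[s, u] + len[k] + D[v, t] == D[s, t]) {
        acc <- acc + S[s, u] * S[v, t]
      }
      if (is.finite(D[s, v]) && is.finite(D[u, t]) &&
          D[s, v] + len[k] + D[u, t] == D[s, t]) {
        acc <- acc + S[s, v] * S[u, t]
      }
      bc[k] <- bc[k] + acc / S[s, t]
    }
  }
  bc / (n * (n - 1) / 2)
}

# exhaustive simple-path enumeration (only for tiny graphs): returns, for
# each ordered pair, the list of all shortest paths
o_all_shortest_paths <- function(g, weighted = FALSE) {
  ed <- o_edges(g)
  L <- o_length_matrix(ed, weighted)
  n <- nrow(L)
  out <- list()
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- list(); best <- Inf
    dfs <- function(path, len) {
      v <- path[length(path)]
      if (v == t) {
        if (len < best - 1e-15) { best <<- len; paths <<- list(path) }
        else if (len <= best) paths <<- c(paths, list(path))
        return()
      }
      for (u in seq_len(n)) {
        if (is.finite(L[v, u]) && L[v, u] > 0 && !(u %in% path)) {
          if (len + L[v, u] <= best) dfs(c(path, u), len + L[v, u])
        }
      }
    }
    dfs(s, 0)
    out[[paste(s, t)]] <- list(paths = paths, len = best)
  }
  list(pairs = out, v = ed$v)
}

o_betweenness_enum <- function(g, weighted = FALSE) {
  sp <- o_all_shortest_paths(g, weighted)
  n <- length(sp$v)
  bc <- stats::setNames(rep(0, n), sp$v)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    pr <- sp$pairs[[paste(s, t)]]
    if (!length(pr$paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(pr$paths, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / length(pr$paths)
    }
  }
  if (n < 3) return(bc)
  bc / ((n - 1) * (n - 2) / 2)
}

o_closeness <- function(g, weighted = FALSE) {
  D <- o_dist(g, weighted)
  n <- nrow(D)
  if (n <= 1) return(stats::setNames(rep(0, n), rownames(D)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- D[i, -i]
    out[i] <- sum(ifelse(is.finite(r) & r > 0, 1 / r, 0)) / (n - 1)
  }
  stats::setNames(out, rownames(D))
}

o_weight_matrix <- function(g) {
  ed <- o_edges(g)
  n <- length(ed$v)
  W <- matrix(0, n, n, dimnames = list(ed$v, ed$v))
  for (k in seq_along(ed$a)) {
    W[ed$a[k], ed$b[k]] <- ed$w[k]
    W[ed$b[k], ed$a[k]] <- ed$w[k]
  }
  W
}

o_clustering <- function(g, weighted = FALSE) {
  W <- o_weight_matrix(g)
  A <- (W > 0) * 1
  n <- nrow(A)
  out <- stats::setNames(rep(0, n), rownames(A))
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    if (!weighted) {
      tri <- 0
      for (j in nb) for (h in nb) if (j < h && A[j, h] > 0) tri <- tri + 1
      out[i] <- tri / (k * (k - 1) / 2)
    } else {
      s <- sum(W[i, ])
      acc <- 0
      for (j in nb) for (h in nb) {   # ordered pairs (Barrat)
        if (j != h && A[j, h] > 0) acc <- acc + (W[i, j] + W[i, h]) / 2
      }
      out[i] <- acc / (s * (k - 1))
    }
  }
  out
}

o_triangles <- function(g) {
  A <- (o_weight_matrix(g) > 0) * 1
  n <- nrow(A)
  out <- stats::setNames(rep(0, n), rownames(A))
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    for (j in nb) for (h in nb) if (j < h && A[j, h] > 0) out[i] <- out[i] + 1
  }
  out
}

# brute force: test all 2^n subsets for maximal-clique-ness (n <= ~12)
o_cliques_brute <- function(g) {
  A <- (o_weight_matrix(g) > 0) * 1
  n <- nrow(A)
  v <- rownames(A)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(A[idx, idx][upper.tri(diag(length(idx)))] == 1)
  }
  out <- list()
  for (code in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx) || !is_clique(idx)) next
    extendable <- any(vapply(setdiff(seq_len(n), idx), function(u) {
      all(A[u, idx] == 1)
    }, logical(1)))
    if (!extendable) out[[length(out) + 1L]] <- sort(v[idx])
  }
  key <- vapply(out, paste, "", collapse = "\r")
  out[order(lengths(out), key)]
}

# plain recursive Bron-Kerbosch without pivoting (for <= ~30 vertices)
o_cliques_rec <- function(g) {
  A <- (o_weight_matrix(g) > 0) * 1
  n <- nrow(A)
  v <- rownames(A)
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(v[R])
      return()
    }
    for (u in P) {
      nb <- which(A[u, ] > 0)
      bk(c(R, u), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, u)
      X <- c(X, u)
    }
  }
  bk(integer(), seq_len(n), integer())
  key <- vapply(out, paste, "", collapse = "\r")
  out[order(lengths(out), key)]
}

o_info <- function(sizes, variant) {
  N <- sum(sizes)
  p <- sizes / N
  ai <- -sum(p * log2(p))
  switch(variant,
         AI = ai,
         TI = N * log2(N) - sum(sizes * log2(sizes)),
         NI = if (N == 1) 0 else ai / log2(N))
}

o_info_triplet <- function(values) {
  if (!length(values)) return(c(NaN, NaN, NaN))
  sz <- as.integer(table(as.character(values)))
  c(o_info(sz, "AI"), o_info(sz, "NI"), o_info(sz, "TI"))
}

# full 52-descriptor vector from the naive routines only
o_descriptors <- function(g, cliques = o_cliques_rec(g)) {
  ed <- o_edges(g)
  n <- length(ed$v)
  m <- length(ed$a)
  W <- o_weight_matrix(g)
  A <- (W > 0) * 1
  deg <- rowSums(A)
  str <- rowSums(W)
  D <- o_dist(g, FALSE)
  Dw <- o_dist(g, TRUE)
  diag(D) <- NA; diag(Dw) <- NA
  ecc <- apply(D, 1, function(r) { r <- r[is.finite(r)]; if (length(r)) max(r) else 0 })
  dsum <- apply(D, 1, function(r) sum(r[is.finite(r)]))
  up <- D[upper.tri(D)]; up <- up[is.finite(up)]
  upw <- Dw[upper.tri(Dw)]; upw <- upw[is.finite(upw)]
  memb <- table(factor(unlist(cliques), levels = ed$v))
  out <- c(
    n_vertices = n, n_edges = m, total_adjacency = sum(deg),
    avg_degree = mean(deg), degree_range = max(deg) - min(deg),
    connectedness = if (n > 1) 2 * m / (n * (n - 1)) else NaN,
    total_weight = sum(ed$w), avg_strength = mean(str),
    strength_range = max(str) - min(str),
    radius = min(ecc), diameter = max(ecc),
    total_distance = if (length(up)) sum(up) else NaN,
    avg_distance = if (length(up)) mean(up) else NaN,
    node_distance_range = max(dsum) - min(dsum),
    weighted_avg_distance = if (length(upw)) mean(upw) else NaN,
    avg_degree_centrality = if (n > 1) mean(deg / (n - 1)) else NaN,
    avg_closeness = mean(o_closeness(g)),
    avg_vertex_betweenness = mean(o_betweenness_vertex(g)),
    avg_edge_betweenness = if (m) mean(o_betweenness_edge(g)) else NaN,
    weighted_avg_vertex_betweenness = mean(o_betweenness_vertex(g, TRUE)),
    weighted_avg_edge_betweenness = if (m) mean(o_betweenness_edge(g, TRUE)) else NaN,
    avg_clustering = mean(o_clustering(g)),
    weighted_avg_clustering = mean(o_clustering(g, TRUE)),
    n_maximal_cliques = length(cliques),
    max_clique_size = max(lengths(cliques))
  )
  dists <- list(degree = deg, strength = str, edge_weight = ed$w,
                distance_sum = dsum, eccentricity = ecc, distance = up,
                clique_size = lengths(cliques),
                clique_membership = as.integer(memb),
                triangle = o_triangles(g))
  for (nm in names(dists)) {
    tri3 <- o_info_triplet(dists[[nm]])
    out[paste(c("ai", "ni", "ti"), nm, sep = "_")] <- tri3
  }
  out
}
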