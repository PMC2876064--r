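#' Build the network of interacting pathways (NIP) for one taxon
#'
#' Vertices are the taxon's metabolic pathways; two pathways are linked when
#' they share at least one metabolite, and the edge weight is the number of
#' shared metabolites. Pathways sharing no metabolite with any other pathway
#' are kept as isolated vertices. The graph is undirected and simple.
#'
#' @param pathways Named list mapping pathway id to a non-empty character
#'   vector of metabolite ids (already exclusion-filtered).
#' @param categories Optional named character vector mapping pathway id to a
#'   functional category; pathways without a category are labeled
#'   `"uncategorized"` with a warning.
#' @param taxon_id Optional taxon identifier stored as a graph attribute.
#' @return An [igraph::igraph] object with vertex attributes `name` and
#'   `category`, edge attribute `weight`, and graph attribute `taxon_id`.
#' @export
build_nip <- function(pathways, categories = NULL, taxon_id = NA_character_) {
  stopifnot(is.list(pathways))
  ids <- names(pathways)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("pathways must be a uniquely named list")
  }
  if (any(lengths(pathways) == 0)) stop("empty metabolite set in pathways")
  ids <- sort(ids)
  pathways <- pathways[ids]
  n <- length(ids)
  mets <- sort(unique(unlist(pathways, use.names = FALSE)))
  inc <- matrix(FALSE, n, length(mets), dimnames = list(ids, mets))
  for (p in ids) inc[p, pathways[[p]]] <- TRUE
  w <- tcrossprod(inc * 1L)     # pairwise shared-metabolite counts
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  cat_v <- rep("uncategorized", n)
  if (!is.null(categories)) {
    hit <- ids %in% names(categories)
    cat_v[hit] <- unname(categories[ids[hit]])
    if (any(!hit)) {
      warning("no category for pathway(s): ",
              paste(ids[!hit], collapse = ", "),
              "; set to 'uncategorized'")
    }
  }
  igraph::V(g)$category <- cat_v
  g$taxon_id <- taxon_id
  g
}

#' Build NIPs for every taxon of an annotation set
#'
#' @param ann An [annotation_set()].
#' @param categories Optional pathway-to-category map (see [build_nip()]).
#' @return Named list of NIP graphs, one per taxon, in taxon-id order.
#' @export
build_nips <- function(ann, categories = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  out <- lapply(names(ann$taxa), function(tx) {
    build_nip(ann$taxa[[tx]], categories = categories, taxon_id = tx)
  })
  stats::setNames(out, names(ann$taxa))
}

nip_format_from_path <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
}

#' Write a NIP to disk
#'
#' Two formats are supported: GraphML (weights as edge attribute `weight`,
#' categories as vertex attribute `category`) and a plain weighted edge-list
#' TSV whose header comments carry the taxon id and one `# vertex:` line per
#' vertex, so isolated vertices and categories survive the round trip.
#'
#' @param nip A NIP graph from [build_nip()].
#' @param path Output file; format chosen by extension (`.graphml` or
#'   anything else for TSV) unless `format` is given.
#' @param format `"graphml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_nip <- function(nip, path, format = nip_format_from_path(path)) {
  format <- match.arg(format, c("graphml", "tsv"))
  nip <- sort_nip(nip)
  if (format == "graphml") {
    igraph::write_graph(nip, path, format = "graphml")
    return(invisible(path))
  }
  v <- igraph::V(nip)$name
  cats <- igraph::V(nip)$category
  if (is.null(cats)) cats <- rep("uncategorized", length(v))
  header <- c(
    paste0("# taxon_id: ", if (is.null(nip$taxon_id)) NA else nip$taxon_id),
    paste0("# vertex: ", v, "\t", cats),
    "pathway_a\tpathway_b\tweight"
  )
  el <- igraph::as_edgelist(nip)
  rows <- character()
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    ord <- order(a, b)
    rows <- paste(a[ord], b[ord],
                  format_weight(igraph::E(nip)$weight[ord]), sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

format_weight <- function(w) {
  ifelse(w == round(w), format(as.integer(round(w))), format(w, digits = 15))
}

sort_nip <- function(nip) {
  perm <- order(igraph::V(nip)$name)
  igraph::permute(nip, order(perm))
}

#' Read a NIP written by [write_nip()]
#'
#' @param path Input file.
#' @param format `"graphml"` or `"tsv"`; default guessed from the extension.
#' @return A NIP graph.
#' @export
read_nip <- function(path, format = nip_format_from_path(path)) {
  format <- match.arg(format, c("graphml", "tsv"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- sort_nip(g)
    check_nip_weights(g, path)
    return(g)
  }
  lines <- readLines(path, warn = FALSE)
  taxon <- NA_character_
  tx_line <- grep("^# taxon_id: ", lines, value = TRUE)
  if (length(tx_line)) {
    taxon <- sub("^# taxon_id: ", "", tx_line[1])
    if (taxon == "NA") taxon <- NA_character_
  }
  v_lines <- grep("^# vertex: ", lines, value = TRUE)
  vparts <- strsplit(sub("^# vertex: ", "", v_lines), "\t", fixed = TRUE)
  vnames <- vapply(vparts, `[`, "", 1)
  vcats <- vapply(vparts, function(p) if (length(p) > 1) p[2] else "uncategorized", "")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body) || body[1] != "pathway_a\tpathway_b\tweight") {
    stop("bad NIP edge-list header in ", path)
  }
  body <- body[-1]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ord <- order(vnames)
  g <- igraph::add_vertices(g, length(vnames), name = vnames[ord],
                            category = vcats[ord])
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3)) stop("malformed edge row in ", path)
    m <- do.call(rbind, parts)
    w <- as.numeric(m[, 3])
    if (any(is.na(w))) stop("non-numeric weight in ", path)
    g <- igraph::add_edges(g, rbind(m[, 1], m[, 2]), weight = w)
  }
  g$taxon_id <- taxon
  g <- sort_nip(g)
  check_nip_weights(g, path)
  g
}

check_nip_weights <- function(g, path) {
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) > 0 && (is.null(w) || any(!is.finite(w)) || any(w <= 0))) {
    stop("format error in ", path, ": NIP edge weights must be positive")
  }
  invisible(g)
}
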