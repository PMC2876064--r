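#' Construct an annotation set
#'
#' An `annotation_set` holds, for every taxon, the metabolite content of each
#' of its metabolic pathways, together with per-taxon metadata (ORF count and
#' group labels for one or more contrasts). It is the raw material from which
#' networks of interacting pathways are built.
#'
#' @param taxa Named list; one element per taxon, each a named list mapping
#'   pathway id to a character vector of metabolite ids. Metabolite sets must
#'   be non-empty.
#' @param metadata Data frame with columns `taxon_id`, `orf_count` and one
#'   column per contrast (character labels, `NA` = unlabeled). Must cover
#'   every taxon in `taxa`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(taxa, metadata) {
  stopifnot(is.list(taxa), is.data.frame(metadata))
  if (!length(taxa)) taxa <- stats::setNames(list(), character())
  if (!all(c("taxon_id", "orf_count") %in% names(metadata))) {
    stop("metadata must have columns 'taxon_id' and 'orf_count'")
  }
  if (anyDuplicated(names(taxa))) stop("duplicate taxon ids in annotations")
  if (anyDuplicated(metadata$taxon_id)) stop("duplicate taxon ids in metadata")
  missing <- setdiff(names(taxa), metadata$taxon_id)
  if (length(missing)) {
    stop("taxa present in annotations but absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(metadata$orf_count)) || any(metadata$orf_count < 1)) {
    stop("orf_count must be >= 1 for every taxon")
  }
  for (tx in names(taxa)) {
    pw <- taxa[[tx]]
    if (anyDuplicated(names(pw))) stop("duplicate pathway ids in taxon ", tx)
    if (any(lengths(pw) == 0)) {
      stop("empty metabolite set in taxon ", tx)
    }
  }
  metadata <- metadata[order(metadata$taxon_id), , drop = FALSE]
  rownames(metadata) <- NULL
  taxa <- taxa[order(names(taxa))]
  taxa <- lapply(taxa, function(pw) {
    pw <- lapply(pw, function(m) sort(unique(as.character(m))))
    pw[order(names(pw))]
  })
  structure(list(taxa = taxa, metadata = metadata), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  np <- lengths(x$taxa)
  cat("Annotation set:", length(x$taxa), "taxa,",
      length(unique(unlist(lapply(x$taxa, names)))), "distinct pathways\n")
  if (length(np)) {
    cat("Pathways per taxon:", min(np), "-", max(np),
        "(median", stats::median(np), ")\n")
  }
  contrasts <- setdiff(names(x$metadata), c("taxon_id", "orf_count"))
  if (length(contrasts)) cat("Contrasts:", paste(contrasts, collapse = ", "), "\n")
  invisible(x)
}

#' Number of taxa in an annotation set
#' @param ann An `annotation_set`.
#' @return Integer.
#' @export
n_taxa <- function(ann) length(ann$taxa)

read_tsv_checked <- function(path, n_fields) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad)) {
    stop(sprintf("malformed row in %s at line %d: expected %d tab-separated fields",
                 path, bad[1], n_fields))
  }
  do.call(rbind, parts)
}

#' Read annotation tables
#'
#' Reads a taxon/pathway/metabolite membership table and a taxon metadata
#' table, removes excluded (currency) metabolites from every pathway, and
#' drops pathways whose metabolite set becomes empty. By convention all
#' currency metabolites are kept except water, so the default exclusion list
#' is the single KEGG identifier for water.
#'
#' @param annotations_path TSV with header `taxon_id  pathway_id
#'   metabolite_id`, one row per membership.
#' @param taxa_path TSV with header `taxon_id  orf_count  <contrast>...`;
#'   empty cells mean "unlabeled for that contrast".
#' @param exclusions Character vector of metabolite ids to strip; default the
#'   KEGG id of water (`"C00001"`).
#' @return An [annotation_set()]. Only taxa present in the annotations table
#'   are retained (their metadata rows are required).
#' @export
read_annotations <- function(annotations_path, taxa_path,
                             exclusions = "C00001") {
  for (p in c(annotations_path, taxa_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  mat <- read_tsv_checked(annotations_path, 3L)
  meta <- read_taxa_table(taxa_path)
  if (is.null(mat)) {
    return(annotation_set(stats::setNames(list(), character()),
                          meta[0, , drop = FALSE]))
  }
  hdr <- mat[1, ]
  if (!identical(hdr, c("taxon_id", "pathway_id", "metabolite_id"))) {
    stop("bad header in ", annotations_path,
         ": expected taxon_id\tpathway_id\tmetabolite_id")
  }
  mat <- mat[-1, , drop = FALSE]
  pairs_before <- unique(paste(mat[, 1], mat[, 2], sep = "\t"))
  keep <- !(mat[, 3] %in% exclusions)
  mat <- mat[keep, , drop = FALSE]
  taxa <- list()
  if (nrow(mat)) {
    by_taxon <- split.data.frame(mat[, 2:3, drop = FALSE], mat[, 1])
    taxa <- lapply(by_taxon, function(m) {
      pw <- lapply(split(m[, 2], m[, 1]), function(x) sort(unique(x)))
      pw[order(names(pw))]
    })
  }
  pairs_after <- unique(paste(mat[, 1], mat[, 2], sep = "\t"))
  dropped <- setdiff(pairs_before, pairs_after)
  if (length(dropped)) {
    message(length(dropped),
            " taxon/pathway entries dropped (empty after exclusion): ",
            paste(utils::head(gsub("\t", ":", dropped), 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  missing_meta <- setdiff(names(taxa), meta$taxon_id)
  if (length(missing_meta)) {
    stop("taxa present in annotations but absent from ", taxa_path, ": ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[meta$taxon_id %in% names(taxa), , drop = FALSE]
  annotation_set(taxa, meta)
}

read_taxa_table <- function(taxa_path) {
  lines <- readLines(taxa_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty taxa table: ", taxa_path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2 || hdr[1] != "taxon_id" || hdr[2] != "orf_count") {
    stop("bad header in ", taxa_path, ": expected taxon_id\torf_count\t<contrasts>")
  }
  body <- lines[-1]
  meta <- data.frame(taxon_id = character(), orf_count = integer(),
                     stringsAsFactors = FALSE)
  for (ct in hdr[-(1:2)]) meta[[ct]] <- character()
  if (!length(body)) return(meta)
  parts <- strsplit(body, "\t", fixed = TRUE)
  # trailing empty cells are legal (unlabeled contrasts)
  parts <- lapply(parts, function(p) {
    if (length(p) > length(hdr)) {
      stop("malformed row in ", taxa_path, ": too many fields")
    }
    c(p, rep("", length(hdr) - length(p)))
  })
  m <- do.call(rbind, parts)
  orf <- suppressWarnings(as.integer(m[, 2]))
  if (any(is.na(orf))) {
    stop("malformed row in ", taxa_path, " at line ",
         which(is.na(orf))[1] + 1L, ": orf_count not an integer")
  }
  meta <- data.frame(taxon_id = m[, 1], orf_count = orf,
                     stringsAsFactors = FALSE)
  for (j in seq_along(hdr[-(1:2)])) {
    v <- m[, j + 2L]
    v[v == ""] <- NA_character_
    meta[[hdr[j + 2L]]] <- v
  }
  meta
}

#' Write an annotation set back to canonical TSV files
#'
#' Rows are emitted in sorted (taxon, pathway, metabolite) order so that
#' read/write round-trips are byte-identical.
#'
#' @param ann An [annotation_set()].
#' @param annotations_path,taxa_path Output paths.
#' @return Invisibly, the annotation set.
#' @export
write_annotations <- function(ann, annotations_path, taxa_path) {
  rows <- character()
  for (tx in names(ann$taxa)) {
    for (pw in names(ann$taxa[[tx]])) {
      rows <- c(rows, paste(tx, pw, ann$taxa[[tx]][[pw]], sep = "\t"))
    }
  }
  writeLines(c("taxon_id\tpathway_id\tmetabolite_id", rows), annotations_path)
  meta <- ann$metadata
  cells <- as.matrix(meta)
  cells[is.na(cells)] <- ""
  writeLines(c(paste(names(meta), collapse = "\t"),
               apply(cells, 1, paste, collapse = "\t")),
             taxa_path)
  invisible(ann)
}

#' Filter taxa with inconsistent pathway annotation
#'
#' Annotation consistency is judged by regressing each taxon's pathway count
#' on the natural logarithm of its ORF count (ordinary least squares). Taxa
#' whose residuals fall in the lowest `quantile` fraction — i.e. taxa with
#' far fewer annotated pathways than their genome size predicts — are removed
#' as under-annotated.
#'
#' @param ann An [annotation_set()] with at least 3 taxa.
#' @param quantile Fraction of taxa to drop, in `[0, 1)`; `floor(quantile *
#'   n)` taxa with the most negative residuals are removed (residual ties are
#'   broken by taxon id).
#' @return A list with components `annotations` (the filtered
#'   [annotation_set()]) and `filter`, an object of class
#'   `consistency_filter` holding `slope`, `intercept`, `r_squared`,
#'   `residuals` (named by taxon), `removed` and `quantile`.
#' @export
filter_consistent_taxa <- function(ann, quantile = 0.05) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile < 0 || quantile >= 1) {
    stop("quantile must be a single number in [0, 1)")
  }
  n <- n_taxa(ann)
  if (n < 3) stop("need at least 3 taxa to fit the consistency regression")
  npath <- lengths(ann$taxa)
  meta <- ann$metadata
  orf <- meta$orf_count[match(names(npath), meta$taxon_id)]
  x <- log(orf)
  if (stats::sd(x) == 0) {
    stop("degenerate fit: all taxa have identical orf_count")
  }
  fit <- stats::lm(npath ~ x)
  res <- stats::setNames(stats::residuals(fit), names(npath))
  r2 <- summary(fit)$r.squared
  k <- floor(quantile * n)
  removed <- character()
  if (k > 0) {
    ord <- order(res, names(res))  # most negative first, ties by taxon id
    removed <- names(res)[ord[seq_len(k)]]
  }
  keep <- setdiff(names(ann$taxa), removed)
  filtered <- annotation_set(
    ann$taxa[keep],
    meta[meta$taxon_id %in% keep, , drop = FALSE]
  )
  flt <- structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    residuals = res,
    removed = sort(removed),
    quantile = quantile
  ), class = "consistency_filter")
  list(annotations = filtered, filter = flt)
}

#' @export
print.consistency_filter <- function(x, ...) {
  cat(sprintf("Annotation consistency filter: r^2 = %.3f, removed %d of %d taxa (quantile %.3g)\n",
              x$r_squared, length(x$removed), length(x$residuals), x$quantile))
  invisible(x)
}

#' Merge strains of the same species into single taxa
#'
#' Pathway sets of merged strains are unioned and metabolite sets of shared
#' pathways are unioned: a merged taxon's metabolic capability is at least
#' that of each strain. `orf_count` is the maximum over strains. Group labels
#' must agree across merged strains (missing labels are filled from labeled
#' strains).
#'
#' @param ann An [annotation_set()].
#' @param strain_map Named character vector mapping taxon id to merged taxon
#'   id; taxa not named are kept as-is.
#' @return A merged [annotation_set()].
#' @export
merge_strains <- function(ann, strain_map) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!length(strain_map)) return(ann)
  if (is.null(names(strain_map))) stop("strain_map must be a named vector")
  unknown <- setdiff(names(strain_map), names(ann$taxa))
  if (length(unknown)) {
    stop("strain_map names not in annotation set: ",
         paste(unknown, collapse = ", "))
  }
  target <- stats::setNames(names(ann$taxa), names(ann$taxa))
  target[names(strain_map)] <- unname(strain_map)
  contrasts <- setdiff(names(ann$metadata), c("taxon_id", "orf_count"))
  groups <- split(names(target), unname(target))
  taxa <- list()
  meta_rows <- list()
  for (new_id in names(groups)) {
    members <- groups[[new_id]]
    pw <- list()
    for (tx in members) {
      for (p in names(ann$taxa[[tx]])) {
        pw[[p]] <- union(pw[[p]], ann$taxa[[tx]][[p]])
      }
    }
    taxa[[new_id]] <- pw
    mm <- ann$metadata[ann$metadata$taxon_id %in% members, , drop = FALSE]
    row <- data.frame(taxon_id = new_id, orf_count = max(mm$orf_count),
                      stringsAsFactors = FALSE)
    for (ct in contrasts) {
      labs <- unique(stats::na.omit(mm[[ct]]))
      if (length(labs) > 1) {
        stop(sprintf(
          "conflicting '%s' labels in merge group '%s': %s",
          ct, new_id, paste(labs, collapse = " vs ")))
      }
      row[[ct]] <- if (length(labs)) labs else NA_character_
    }
    meta_rows[[new_id]] <- row
  }
  annotation_set(taxa, do.call(rbind, meta_rows))
}

#' Read a pathway-to-category map
#'
#' @param path TSV with header `pathway_id  category`.
#' @return Named character vector mapping pathway id to functional category.
#' @export
read_categories <- function(path) {
  mat <- read_tsv_checked(path, 2L)
  if (is.null(mat)) return(stats::setNames(character(), character()))
  if (!identical(mat[1, ], c("pathway_id", "category"))) {
    stop("bad header in ", path, ": expected pathway_id\tcategory")
  }
  mat <- mat[-1, , drop = FALSE]
  stats::setNames(mat[, 2], mat[, 1])
}

#' Write a pathway-to-category map
#' @param categories Named character vector (names = pathway ids).
#' @param path Output TSV path.
#' @return Invisibly, `categories`.
#' @export
write_categories <- function(categories, path) {
  ids <- sort(names(categories))
  writeLines(c("pathway_id\tcategory",
               paste(ids, categories[ids], sep = "\t")), path)
  invisible(categories)
}
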