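#' Fixed functional-category list for synthetic pathways
#'
#' Eleven names mirroring KEGG top-level metabolism classes, so category
#' summaries of [compare_pathways()] are exercised by generated data.
#'
#' @return Character vector of 11 category names.
#' @export
nip_categories <- function() {
  c("carbohydrate", "energy", "lipid", "amino acid", "glycan",
    "xenobiotics", "secondary metabolites", "nucleotide",
    "cofactor/vitamin", "terpenoid/polyketide", "other")
}

#' Generate a synthetic pathway/metabolite universe
#'
#' Emulates the KEGG-like structure of real pathway annotations: every
#' pathway draws private metabolites from a large shared pool, and overlap
#' between pathways comes from two tiers of "hub" metabolites — a handful of
#' globally shared currency-like compounds joining any pathway with
#' probability `hub_prob`, and per-category hubs (shared intermediates of a
#' functional class) joining same-category pathways with probability
#' `category_hub_prob`. The resulting full-retention NIP sits in the regime
#' of real pathway networks: dense (density ~0.3), clustered, diameter 2-4,
#' with a right-skewed degree distribution.
#'
#' @param n_pathways Number of pathways (>= 2).
#' @param n_metabolites Size of the metabolite pool.
#' @param metabolites_per_pathway Mean private metabolites per pathway
#'   (Poisson; at least 1 is always drawn).
#' @param hub_fraction Fraction of the pool designated hub metabolites, in
#'   `[0, 1]`; up to 6 of them are global hubs, the rest are split evenly
#'   across categories.
#' @param hub_prob Probability that each global hub joins a given pathway.
#' @param category_hub_prob Probability that a category hub joins a pathway
#'   of its category.
#' @param categories Category names cycled over pathways.
#' @param seed Integer seed; generation is fully deterministic given the
#'   arguments.
#' @return List with `pathways` (named list pathway -> metabolite ids) and
#'   `categories` (named character vector pathway -> category).
#' @export
generate_universe <- function(n_pathways = 150, n_metabolites = 2000,
                              metabolites_per_pathway = 10,
                              hub_fraction = 0.025, hub_prob = 0.18,
                              category_hub_prob = 0.5,
                              categories = nip_categories(), seed = 17) {
  if (n_pathways < 2) stop("n_pathways must be >= 2")
  if (hub_fraction < 0 || hub_fraction > 1) stop("hub_fraction must be in [0, 1]")
  if (metabolites_per_pathway > n_metabolites) {
    stop("metabolites_per_pathway cannot exceed n_metabolites")
  }
  set.seed(seed)
  mets <- sprintf("M%05d", seq_len(n_metabolites))
  n_hub <- round(hub_fraction * n_metabolites)
  n_global <- min(n_hub, 6L)
  global_hubs <- mets[seq_len(n_global)]
  cat_hub_pool <- mets[n_global + seq_len(n_hub - n_global)]
  cat_hubs <- split(cat_hub_pool,
                    rep_len(categories, length(cat_hub_pool)))
  others <- if (n_hub) mets[-seq_len(n_hub)] else mets
  pids <- sprintf("P%04d", seq_len(n_pathways))
  cat_map <- stats::setNames(rep_len(categories, n_pathways), pids)
  pathways <- lapply(pids, function(p) {
    k <- max(1L, stats::rpois(1, metabolites_per_pathway))
    own <- sample(others, min(k, length(others)))
    g_in <- global_hubs[stats::runif(n_global) < hub_prob]
    ch <- cat_hubs[[cat_map[p]]]
    c_in <- if (length(ch)) ch[stats::runif(length(ch)) < category_hub_prob]
            else character()
    sort(unique(c(own, g_in, c_in)))
  })
  names(pathways) <- pids
  list(pathways = pathways, categories = cat_map)
}

#' Specify a two-or-more-group synthetic contrast
#'
#' @param contrast_name Name of the contrast column written to the taxa
#'   table.
#' @param groups List of group specs, each a list with `label`, `n_taxa`
#'   (>= 2), `pathway_retention` (baseline probability that a taxon keeps a
#'   pathway), optional `retention_bias_by_category` (named multipliers) and
#'   optional `overlap_boost` (extra retention of hub-rich pathways).
#' @param orf_model Numeric `c(a, b, sd)`: `orf_count =
#'   round(exp((n_pathways - a)/b + rnorm(1, 0, sd)))`, the inverse of the
#'   pathways-vs-log(ORF) annotation-consistency relation.
#' @param effect_size Scales every between-group difference; 0 makes all
#'   groups draw from the pooled average (exchangeable null).
#' @return List of class `group_effect_spec`.
#' @export
group_effect_spec <- function(contrast_name, groups,
                              orf_model = c(a = -180, b = 40, sd = 0.15),
                              effect_size = 1) {
  for (g in groups) {
    stopifnot(!is.null(g$label), !is.null(g$n_taxa), !is.null(g$pathway_retention))
    if (g$n_taxa < 2) stop("each group needs n_taxa >= 2")
  }
  structure(list(contrast_name = contrast_name, groups = groups,
                 orf_model = orf_model, effect_size = effect_size),
            class = "group_effect_spec")
}

retention_matrix <- function(universe, effects) {
  pids <- names(universe$pathways)
  cats <- universe$categories[pids]
  # hub-richness of a pathway: fraction of its metabolites that are hubs
  all_counts <- table(unlist(universe$pathways, use.names = FALSE))
  shared <- names(all_counts)[all_counts > length(universe$pathways) * 0.05]
  hubness <- vapply(universe$pathways,
                    function(m) mean(m %in% shared), numeric(1))
  raw <- vapply(effects$groups, function(g) {
    r <- rep(g$pathway_retention, length(pids))
    bias <- g$retention_bias_by_category
    if (!is.null(bias)) {
      hit <- cats %in% names(bias)
      r[hit] <- r[hit] * unlist(bias)[cats[hit]]
    }
    if (!is.null(g$overlap_boost) && g$overlap_boost != 0) {
      r <- r * (1 + g$overlap_boost * hubness)
    }
    r
  }, numeric(length(pids)))
  pooled <- rowMeans(raw)
  eff <- pooled + effects$effect_size * (raw - pooled)
  eff[] <- pmin(1, pmax(0, eff))
  dimnames(eff) <- list(pids, vapply(effects$groups, `[[`, "", "label"))
  eff
}

#' Generate a synthetic annotation dataset with planted group effects
#'
#' Each taxon keeps each pathway independently with its group's
#' (category-biased, effect-scaled) retention probability; its ORF count
#' follows the log-linear `orf_model` so the annotation-consistency
#' regression holds by construction. With `effect_size = 0` the groups are
#' exchangeable.
#'
#' @param universe From [generate_universe()].
#' @param effects A [group_effect_spec()].
#' @param seed Integer seed.
#' @return List of class `synthetic_dataset`: `annotations` (an
#'   [annotation_set()]), `categories`, and `ground_truth` (planted
#'   retentions, biased categories, effect size, marked inconsistent taxa).
#' @export
generate_taxa <- function(universe, effects, seed = 17) {
  stopifnot(inherits(effects, "group_effect_spec"))
  set.seed(seed)
  ret <- retention_matrix(universe, effects)
  if (any(colSums(ret) < 2)) {
    stop("a group's expected pathway count is below 2; raise retention")
  }
  pids <- names(universe$pathways)
  a <- effects$orf_model[[1]]; b <- effects$orf_model[[2]]
  sd_orf <- effects$orf_model[[3]]
  taxa <- list(); meta <- list()
  i <- 0
  for (g in effects$groups) {
    for (k in seq_len(g$n_taxa)) {
      i <- i + 1
      tx <- sprintf("T%04d", i)
      keep <- stats::runif(length(pids)) < ret[, g$label]
      if (!any(keep)) keep[sample.int(length(pids), 2)] <- TRUE
      taxa[[tx]] <- universe$pathways[pids[keep]]
      orf <- max(2, round(exp((sum(keep) - a) / b +
                                stats::rnorm(1, 0, sd_orf))))
      row <- data.frame(taxon_id = tx, orf_count = orf,
                        stringsAsFactors = FALSE)
      row[[effects$contrast_name]] <- g$label
      meta[[tx]] <- row
    }
  }
  ann <- annotation_set(taxa, do.call(rbind, meta))
  planted <- lapply(effects$groups, function(g) {
    list(label = g$label, n_taxa = g$n_taxa,
         pathway_retention = g$pathway_retention,
         retention_bias_by_category = g$retention_bias_by_category,
         overlap_boost = g$overlap_boost)
  })
  structure(list(
    annotations = ann,
    categories = universe$categories,
    ground_truth = list(
      contrast_name = effects$contrast_name,
      effect_size = effects$effect_size,
      groups = planted,
      seed = seed,
      inconsistent_taxa = character()
    )
  ), class = "synthetic_dataset")
}

#' Plant annotation-inconsistent taxa
#'
#' A random `fraction` of taxa lose a `deflation` fraction of their pathways
#' while keeping their ORF count, creating known targets for
#' [filter_consistent_taxa()]; the marked taxa are recorded in the ground
#' truth.
#'
#' @param dataset A `synthetic_dataset`.
#' @param fraction Fraction of taxa to deflate, in `(0, 1)`.
#' @param deflation Fraction of each marked taxon's pathways to remove.
#' @param seed Integer seed.
#' @return The modified `synthetic_dataset`.
#' @export
make_inconsistent <- function(dataset, fraction = 0.05, deflation = 0.5,
                              seed = 17) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  ann <- dataset$annotations
  ids <- names(ann$taxa)
  n_mark <- max(1L, round(fraction * length(ids)))
  marked <- sort(sample(ids, n_mark))
  for (tx in marked) {
    pw <- ann$taxa[[tx]]
    n_drop <- floor(deflation * length(pw))
    if (n_drop > 0 && length(pw) - n_drop >= 1) {
      drop <- sample(names(pw), n_drop)
      ann$taxa[[tx]] <- pw[setdiff(names(pw), drop)]
    }
  }
  dataset$annotations <- annotation_set(ann$taxa, ann$metadata)
  dataset$ground_truth$inconsistent_taxa <- marked
  dataset$ground_truth$deflation <- deflation
  dataset
}

#' The default planted two-group scenario
#'
#' Two groups of 50 taxa with baseline pathway retention 0.90 ("rich", e.g.
#' free-living-like) versus 0.50 ("reduced", e.g. host-associated-like), the
#' reduced group additionally biased against lipid and glycan pathways
#' (multiplier 0.5). `effect_size = 0` collapses both groups onto their
#' pooled average.
#'
#' @param effect_size Between-group effect scale.
#' @return A [group_effect_spec()].
#' @export
default_scenario <- function(effect_size = 1) {
  group_effect_spec(
    contrast_name = "lifestyle",
    groups = list(
      list(label = "rich", n_taxa = 50, pathway_retention = 0.90),
      list(label = "reduced", n_taxa = 50, pathway_retention = 0.50,
           retention_bias_by_category = c("lipid" = 0.5, "glycan" = 0.5))
    ),
    effect_size = effect_size
  )
}

#' Write a synthetic dataset to a directory
#'
#' Emits `annotations.tsv`, `taxa.tsv`, `pathway_categories.tsv` and
#' `ground_truth.json`, all of which round-trip through the annotation
#' readers unchanged.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotations(dataset$annotations,
                    file.path(dir, "annotations.tsv"),
                    file.path(dir, "taxa.tsv"))
  used <- sort(unique(unlist(lapply(dataset$annotations$taxa, names))))
  write_categories(dataset$categories[used],
                   file.path(dir, "pathway_categories.tsv"))
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  gt <- x$ground_truth
  cat("Synthetic dataset: contrast '", gt$contrast_name, "', effect size ",
      gt$effect_size, "\n", sep = "")
  print(x$annotations)
  invisible(x)
}
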