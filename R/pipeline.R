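#' Run the full NIP comparison pipeline
#'
#' Chains the analysis stages: read annotations -> annotation-consistency
#' filter -> strain merging (optional) -> NIP construction -> 52-descriptor
#' table -> group classification per contrast -> per-pathway group
#' statistics. A JSON manifest records inputs, seed, per-stage status and
#' output checksums; any stage failure leaves partial outputs plus a
#' manifest marking the failure point.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{annotations, taxa, pathway_categories}{input TSV paths
#'       (`pathway_categories` optional)}
#'     \item{exclusions}{optional path to a one-metabolite-per-line
#'       exclusion list; default: the single water identifier}
#'     \item{contrasts}{character vector of metadata columns to classify;
#'       default: every contrast column found}
#'     \item{pathway_groups}{optional named list `contrast = c(group_a,
#'       group_b)` selecting the two groups compared by
#'       [compare_pathways()]; default: the two most frequent labels}
#'     \item{quantile}{consistency-filter quantile (default 0.05)}
#'     \item{strain_map}{optional named list/vector taxon -> merged id}
#'     \item{folds, seed, tolerance}{classification settings (defaults 10,
#'       1, 0.01)}
#'     \item{out_dir}{output directory}
#'   }
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(quantile = 0.05, folds = 10, seed = 1, tolerance = 0.01)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("annotations", "taxa", "out_dir")) {
    if (is.null(config[[nm]])) stop("config entry missing: ", nm)
  }
  for (nm in c("annotations", "taxa", "pathway_categories", "exclusions")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config: input file not found: ", p)
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(inputs = config[c("annotations", "taxa",
                                     "pathway_categories", "exclusions")],
                   seed = config$seed, stages = list())
  t0 <- Sys.time()
  finish <- function(status) {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    manifest$status <- status
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    manifest
  }
  stage <- function(name, outputs = character()) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, status = "ok",
      outputs = as.list(tools::md5sum(outputs)))
  }
  run <- function() {
    exclusions <- if (!is.null(config$exclusions)) {
      readLines(config$exclusions, warn = FALSE)
    } else "C00001"
    ann <- read_annotations(config$annotations, config$taxa,
                            exclusions = exclusions)
    stage("read")
    flt <- filter_consistent_taxa(ann, quantile = config$quantile)
    ann <- flt$annotations
    utils::write.table(
      data.frame(taxon_id = names(flt$filter$residuals),
                 residual = flt$filter$residuals,
                 removed = names(flt$filter$residuals) %in% flt$filter$removed),
      file.path(out_dir, "consistency_filter.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    stage("filter", file.path(out_dir, "consistency_filter.tsv"))
    if (!is.null(config$strain_map)) {
      ann <- merge_strains(ann, unlist(config$strain_map))
    }
    stage("merge")
    categories <- if (!is.null(config$pathway_categories)) {
      read_categories(config$pathway_categories)
    }
    nips <- suppressWarnings(build_nips(ann, categories = categories))
    stage("nips")
    desc <- descriptor_table(nips)
    desc_path <- file.path(out_dir, "descriptors.tsv")
    write_descriptors(desc, desc_path)
    stage("descriptors", desc_path)
    contrasts <- config$contrasts
    if (is.null(contrasts)) {
      contrasts <- setdiff(names(ann$metadata), c("taxon_id", "orf_count"))
    }
    cls_paths <- character()
    for (ct in contrasts) {
      tab <- training_table(desc, ann$metadata, ct)
      path <- file.path(out_dir, paste0("classification_", ct, ".json"))
      classify_contrast(tab, path, folds = config$folds, seed = config$seed,
                        tolerance = config$tolerance)
      cls_paths <- c(cls_paths, path)
    }
    stage("classify", cls_paths)
    pw_paths <- character()
    for (ct in contrasts) {
      labels <- ann$metadata[[ct]]
      pair <- config$pathway_groups[[ct]]
      if (is.null(pair)) {
        pair <- names(sort(table(labels), decreasing = TRUE))[1:2]
        pair <- sort(pair)
      }
      if (any(is.na(pair))) next
      ids_a <- ann$metadata$taxon_id[!is.na(labels) & labels == pair[1]]
      ids_b <- ann$metadata$taxon_id[!is.na(labels) & labels == pair[2]]
      cmp <- compare_pathways(nips[ids_a], nips[ids_b],
                              categories = categories,
                              group_a = pair[1], group_b = pair[2])
      p1 <- file.path(out_dir, paste0("pathway_stats_", ct, ".tsv"))
      p2 <- file.path(out_dir, paste0("category_summary_", ct, ".tsv"))
      utils::write.table(cmp$comparisons, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(cmp$categories, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      pw_paths <- c(pw_paths, p1, p2)
    }
    stage("pathway_stats", pw_paths)
  }
  err <- NULL
  tryCatch(run(), error = function(e) err <<- conditionMessage(e))
  if (!is.null(err)) {
    manifest$stages[[length(manifest$stages) + 1L]] <- list(
      name = "failed", status = "error", message = err)
    finish("error")
    stop("pipeline failed: ", err)
  }
  invisible(finish("ok"))
}
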