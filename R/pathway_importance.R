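#' Fraction of taxa in a group possessing a pathway
#'
#' @param group Named list of per-taxon pathway annotations (each a named
#'   list pathway -> metabolites) or a list of NIP graphs.
#' @param pathway_id Pathway to look up.
#' @return Frequency in `[0, 1]`.
#' @export
pathway_frequency <- function(group, pathway_id) {
  if (!length(group)) stop("empty group of taxa")
  has <- vapply(group, function(tx) {
    ids <- if (inherits(tx, "igraph")) igraph::V(tx)$name else names(tx)
    pathway_id %in% ids
  }, logical(1))
  mean(has)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value from the hypergeometric distribution: the total probability
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table))) {
    stop("need a 2x2 matrix of non-negative integer counts")
  }
  min(1, stats::fisher.test(table)$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when `n_x * n_y <= 400` and there are no ties;
#' otherwise the normal approximation with midranks and tie correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (the Mann-Whitney statistic for `x`) and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    # all observations tied: no evidence of a shift
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom. When all observations are identical, `H = 0` and
#' `p = 1`.
#'
#' @param samples List of at least 2 non-empty numeric samples.
#' @return List with `H` and `p_value`.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2 || any(lengths(samples) == 0)) {
    stop("need a list of >= 2 non-empty samples")
  }
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, p_value = 1))
  }
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' p-values; input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

pathway_score_names <- c("frequency", "degree", "strength", "closeness",
                         "betweenness", "weighted_betweenness")

#' Per-taxon pathway connectivity and centrality scores
#'
#' For every pathway of every NIP: vertex degree, strength (weighted
#' degree), harmonic closeness, and unweighted/weighted betweenness.
#'
#' @param nips Named list of NIP graphs.
#' @return Long data frame with columns `taxon_id`, `pathway_id`, `degree`,
#'   `strength`, `closeness`, `betweenness`, `weighted_betweenness`.
#' @export
pathway_scores <- function(nips) {
  rows <- lapply(names(nips), function(tx) {
    g <- nips[[tx]]
    nm <- igraph::V(g)$name
    data.frame(
      taxon_id = tx,
      pathway_id = nm,
      degree = as.numeric(igraph::degree(g)),
      strength = as.numeric(igraph::strength(
        g, weights = if (igraph::ecount(g)) igraph::E(g)$weight else numeric())),
      closeness = as.numeric(nip_closeness(g)),
      betweenness = as.numeric(nip_betweenness(g, "vertex")),
      weighted_betweenness = as.numeric(nip_betweenness(g, "vertex",
                                                        weighted = TRUE)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare pathway importance between two groups of taxa
#'
#' For every pathway, the frequency shift between groups is tested with
#' Fisher's exact test on presence/absence counts, and each
#' connectivity/centrality score with a Mann-Whitney U test on the per-taxon
#' values of the taxa that possess the pathway (presence itself is captured
#' by the frequency score, so absent taxa contribute no zero). Amplitudes
#' are `median(group_b) - median(group_a)` (frequency: `freq_b - freq_a`).
#' All (pathway, score) p-values of the contrast form one Benjamini-Hochberg
#' family. Category summaries are per-category medians of amplitude and FDR
#' with a direction given by the sign of the median amplitude.
#'
#' @param nips_a,nips_b Named lists of NIP graphs for groups A and B (at
#'   least 2 taxa each).
#' @param categories Named character vector pathway -> category.
#' @param group_a,group_b Group labels used in the output.
#' @param min_per_group Minimum taxa possessing a pathway, per group, for
#'   the Mann-Whitney tests (pathways below it are skipped with a message).
#' @return List with `comparisons` (pathway-level data frame: `pathway_id`,
#'   `category`, `score_name`, `group_a`, `group_b`, `amplitude`, `p_value`,
#'   `fdr`) and `categories` (category-level data frame: `category`,
#'   `score_name`, `median_amplitude`, `median_fdr`, `direction`).
#' @export
compare_pathways <- function(nips_a, nips_b, categories = NULL,
                             group_a = "A", group_b = "B",
                             min_per_group = 2) {
  if (length(nips_a) < 2 || length(nips_b) < 2) {
    stop("both groups need at least 2 taxa")
  }
  sc_a <- pathway_scores(nips_a)
  sc_b <- pathway_scores(nips_b)
  pathways <- sort(union(sc_a$pathway_id, sc_b$pathway_id))
  na <- length(nips_a); nb <- length(nips_b)
  rows <- list()
  skipped <- character()
  for (pw in pathways) {
    va <- sc_a[sc_a$pathway_id == pw, , drop = FALSE]
    vb <- sc_b[sc_b$pathway_id == pw, , drop = FALSE]
    ka <- nrow(va); kb <- nrow(vb)
    if (ka == 0 && kb == 0) next
    freq_a <- ka / na; freq_b <- kb / nb
    p_f <- fisher_exact(matrix(c(ka, na - ka, kb, nb - kb), 2))
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pw, score_name = "frequency",
      amplitude = freq_b - freq_a, p_value = p_f,
      stringsAsFactors = FALSE)
    if (ka >= min_per_group && kb >= min_per_group) {
      for (sn in setdiff(pathway_score_names, "frequency")) {
        mw <- mann_whitney(va[[sn]], vb[[sn]])
        rows[[length(rows) + 1L]] <- data.frame(
          pathway_id = pw, score_name = sn,
          amplitude = stats::median(vb[[sn]]) - stats::median(va[[sn]]),
          p_value = mw$p_value, stringsAsFactors = FALSE)
      }
    } else {
      skipped <- c(skipped, pw)
    }
  }
  if (length(skipped)) {
    message(length(skipped),
            " pathway(s) skipped for rank tests (too few taxa possess them): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  cmp <- do.call(rbind, rows)
  cmp$fdr <- adjust_pvalues(cmp$p_value, "bh")
  cmp$group_a <- group_a
  cmp$group_b <- group_b
  cmp$category <- if (is.null(categories)) "uncategorized" else {
    ifelse(cmp$pathway_id %in% names(categories),
           categories[cmp$pathway_id], "uncategorized")
  }
  cmp <- cmp[, c("pathway_id", "category", "score_name", "group_a", "group_b",
                 "amplitude", "p_value", "fdr")]
  rownames(cmp) <- NULL
  agg <- split(cmp, list(cmp$category, cmp$score_name), drop = TRUE)
  cats <- do.call(rbind, lapply(agg, function(d) {
    ma <- stats::median(d$amplitude)
    data.frame(
      category = d$category[1], score_name = d$score_name[1],
      median_amplitude = ma,
      median_fdr = stats::median(d$fdr),
      direction = if (ma > 0) "increase" else if (ma < 0) "decrease" else "none",
      stringsAsFactors = FALSE)
  }))
  cats <- cats[order(cats$category, cats$score_name), , drop = FALSE]
  rownames(cats) <- NULL
  list(comparisons = cmp, categories = cats)
}

#' Descriptor-level group comparison
#'
#' Tests, for each of the 52 descriptors, the hypothesis that its value is
#' the same across groups: Mann-Whitney U for two groups, Kruskal-Wallis for
#' three or more, with Bonferroni correction over the descriptors. Per-group
#' means and standard deviations are reported alongside.
#'
#' @param desc Descriptor table from [descriptor_table()].
#' @param groups Factor or character vector of group labels aligned with
#'   `desc` rows (`NA` rows are dropped).
#' @return Data frame: `descriptor_id`, `statistic`, `p_value`,
#'   `p_bonferroni`, then `mean_<group>` and `sd_<group>` columns.
#' @export
compare_descriptors <- function(desc, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(desc))
  keep <- !is.na(groups)
  desc <- desc[keep, , drop = FALSE]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  ids <- setdiff(names(desc), "taxon_id")
  rows <- lapply(ids, function(id) {
    v <- desc[[id]]
    ok <- is.finite(v)
    samples <- split(v[ok], groups[ok])
    res <- if (any(lengths(samples) == 0)) {
      list(H = NA_real_, p_value = NA_real_)
    } else if (nlevels(groups) == 2) {
      mw <- mann_whitney(samples[[1]], samples[[2]])
      list(H = mw$U, p_value = mw$p_value)
    } else {
      kruskal_wallis(samples)
    }
    row <- data.frame(descriptor_id = id, statistic = res$H,
                      p_value = res$p_value, stringsAsFactors = FALSE)
    for (g in levels(groups)) {
      row[[paste0("mean_", g)]] <- mean(v[groups == g], na.rm = TRUE)
      row[[paste0("sd_", g)]] <- stats::sd(v[groups == g], na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  out$p_bonferroni <- NA_real_
  out$p_bonferroni[ok] <- adjust_pvalues(out$p_value[ok], "bonferroni")
  cols <- c("descriptor_id", "statistic", "p_value", "p_bonferroni")
  out <- out[, c(cols, setdiff(names(out), cols))]
  rownames(out) <- NULL
  out
}
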