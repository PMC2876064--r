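#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/N` and chance agreement `p_e = sum_i row_i *
#' col_i / N^2`. Returns 0 when `p_e = 1` (a single occupied class).
#'
#' @param confusion Square matrix of non-negative counts (rows = reference,
#'   columns = prediction).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_statistic <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix has zero total count")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Build a training table for one contrast
#'
#' Joins a descriptor table with taxon metadata and keeps the taxa labeled
#' for the requested contrast. Columns that are constant over the retained
#' taxa are flagged in the `"constant_columns"` attribute (they carry no
#' discriminative signal but are kept so feature indices match the
#' registry).
#'
#' @param desc Descriptor table from [descriptor_table()].
#' @param metadata Taxon metadata data frame (`taxon_id`, `orf_count`,
#'   contrast columns).
#' @param contrast Name of the metadata column holding the group labels.
#' @return Data frame with `taxon_id`, the descriptor columns and a factor
#'   column `group`; attribute `contrast` records the contrast name.
#' @export
training_table <- function(desc, metadata, contrast) {
  if (!contrast %in% names(metadata)) {
    stop("unknown contrast: ", contrast)
  }
  lab <- metadata[[contrast]][match(desc$taxon_id, metadata$taxon_id)]
  keep <- !is.na(lab)
  tab <- desc[keep, , drop = FALSE]
  tab$group <- factor(lab[keep])
  feat <- setdiff(names(tab), c("taxon_id", "group"))
  const <- feat[vapply(tab[feat], function(x) {
    x <- x[is.finite(x)]
    length(unique(x)) <= 1
  }, logical(1))]
  attr(tab, "contrast") <- contrast
  attr(tab, "constant_columns") <- const
  rownames(tab) <- NULL
  tab
}

#' Available classification models
#'
#' Model ids accepted by [evaluate_models()]: `"logistic"` (logistic /
#' multinomial regression), `"mlp"` (single-hidden-layer perceptron),
#' `"tree"` (recursive-partitioning rule learner), `"oner"` (best
#' single-descriptor threshold rule, implemented in this package), `"knn1"`
#' (1-nearest-neighbour), `"rf"` (random forest), `"svm"` (RBF support
#' vector machine).
#'
#' @return Character vector of model ids.
#' @export
model_registry <- function() {
  c("logistic", "mlp", "tree", "oner", "knn1", "rf", "svm")
}

# Fit on standardized training features, return a predict(newdata) closure.
fit_model <- function(model_id, x, y) {
  lv <- levels(y)
  switch(model_id,
    logistic = {
      if (length(lv) == 2) {
        df <- data.frame(x, .y = y)
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                           family = stats::binomial()))
        function(newx) {
          # correlated descriptors make the fit rank-deficient; prediction
          # on the estimable subspace is all we need
          p <- suppressWarnings(stats::predict(fit, newdata = data.frame(newx),
                                               type = "response"))
          factor(lv[1 + (p > 0.5)], levels = lv)
        }
      } else {
        df <- data.frame(x, .y = y)
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                              maxit = 200, MaxNWts = 5000)
        function(newx) {
          factor(as.character(stats::predict(fit, newdata = data.frame(newx))),
                 levels = lv)
        }
      }
    },
    mlp = {
      fit <- nnet::nnet(x, stats::model.matrix(~ y - 1), size = 5,
                        decay = 0.01, maxit = 200, trace = FALSE,
                        softmax = TRUE, MaxNWts = 5000)
      function(newx) {
        p <- stats::predict(fit, newx)
        factor(lv[max.col(p)], levels = lv)
      }
    },
    tree = {
      df <- data.frame(x, .y = y)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      function(newx) {
        factor(as.character(stats::predict(fit, data.frame(newx),
                                           type = "class")), levels = lv)
      }
    },
    oner = fit_oner(x, y),
    knn1 = {
      function(newx) {
        class::knn(train = x, test = newx, cl = y, k = 1)
      }
    },
    rf = {
      fit <- randomForest::randomForest(x, y, ntree = 200)
      function(newx) {
        factor(as.character(stats::predict(fit, newx)), levels = lv)
      }
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = "radial", scale = FALSE)
      function(newx) {
        factor(as.character(stats::predict(fit, newx)), levels = lv)
      }
    },
    stop("unknown model id: ", model_id)
  )
}

# OneR: the single feature + threshold split that best predicts the class on
# the training data; each side predicts its majority class.
fit_oner <- function(x, y) {
  lv <- levels(y)
  best <- list(acc = -1, j = 1, thr = Inf, lo = lv[1], hi = lv[1])
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (all(!is.finite(v))) next
    u <- sort(unique(v[is.finite(v)]))
    thrs <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    if (length(thrs) > 64) {
      thrs <- stats::quantile(v[is.finite(v)], probs = seq(0.02, 0.98, length.out = 64),
                              names = FALSE, type = 1)
    }
    for (thr in thrs) {
      side <- v <= thr
      lo_tab <- table(y[side]); hi_tab <- table(y[!side])
      lo <- if (sum(lo_tab)) names(which.max(lo_tab)) else lv[1]
      hi <- if (sum(hi_tab)) names(which.max(hi_tab)) else lv[1]
      acc <- (sum(y[side] == lo) + sum(y[!side] == hi)) / length(y)
      if (acc > best$acc) best <- list(acc = acc, j = j, thr = thr,
                                       lo = lo, hi = hi)
    }
  }
  force(best)
  function(newx) {
    v <- newx[, best$j]
    factor(ifelse(v <= best$thr, best$lo, best$hi), levels = lv)
  }
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

scale_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(train = scale(xtr, mu, sdev), test = scale(xte, mu, sdev))
}

feature_matrix <- function(table, features) {
  x <- as.matrix(table[features])
  x[!is.finite(x)] <- 0       # NaN descriptors (degenerate graphs) -> 0
  storage.mode(x) <- "double"
  x
}

cv_model <- function(model_id, x, y, fold_id, folds) {
  lv <- levels(y)
  pred <- factor(rep(lv[1], length(y)), levels = lv)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    if (!any(te)) next
    sc <- scale_train_test(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    model <- fit_model(model_id, sc$train, y[!te])
    pred[te] <- model(sc$test)
  }
  pred
}

#' Evaluate classification models on a training table
#'
#' Stratified k-fold cross-validation with a fixed seed; per-fold feature
#' standardization is fit on the training folds only. For each model the
#' pooled cross-validated accuracy and Cohen's kappa are reported together
#' with whole-set (resubstitution) accuracy and kappa. Models are ranked by
#' cross-validated accuracy, ties broken by kappa.
#'
#' @param table Training table from [training_table()].
#' @param models Model ids, see [model_registry()].
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed fixing fold assignment and stochastic model
#'   fits.
#' @return Object of class `model_evaluation`: a list with `results` (data
#'   frame, ranked), `confusion` (named list of pooled CV confusion
#'   matrices), `contrast`, `folds`, `seed`, `features`.
#' @export
evaluate_models <- function(table, models = model_registry(), folds = 10,
                            seed = 1) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  unknown <- setdiff(models, model_registry())
  if (length(unknown)) stop("unknown model id: ", paste(unknown, collapse = ", "))
  y <- droplevels(table$group)
  if (nlevels(y) < 2) stop("training table has a single class")
  if (min(table(y)) < 2) stop("each class needs at least 2 taxa")
  if (min(table(y)) < folds) {
    warning("smallest class (", min(table(y)), ") has fewer rows than folds (",
            folds, "); stratification degrades gracefully")
  }
  features <- setdiff(names(table), c("taxon_id", "group"))
  x <- feature_matrix(table, features)
  fold_id <- stratified_folds(y, folds, seed)
  rows <- list(); conf <- list()
  for (mid in models) {
    set.seed(seed)
    pred_cv <- cv_model(mid, x, y, fold_id, folds)
    cm_cv <- table(reference = y, prediction = pred_cv)
    set.seed(seed)
    sc <- scale_train_test(x, x)
    fit_all <- fit_model(mid, sc$train, y)
    pred_tr <- fit_all(sc$test)
    cm_tr <- table(reference = y, prediction = pred_tr)
    rows[[mid]] <- data.frame(
      model_id = mid,
      cv_accuracy = sum(diag(cm_cv)) / sum(cm_cv),
      cv_kappa = kappa_statistic(cm_cv),
      train_accuracy = sum(diag(cm_tr)) / sum(cm_tr),
      train_kappa = kappa_statistic(cm_tr),
      stringsAsFactors = FALSE
    )
    conf[[mid]] <- cm_cv
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$cv_accuracy, -res$cv_kappa, res$model_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, confusion = conf,
                 contrast = attr(table, "contrast"),
                 folds = folds, seed = seed, features = features),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("Model evaluation (", x$folds, "-fold CV, seed ", x$seed,
      if (!is.null(x$contrast)) paste0(", contrast '", x$contrast, "'"),
      ")\n", sep = "")
  print(transform(x$results,
                  cv_accuracy = round(cv_accuracy, 4),
                  cv_kappa = round(cv_kappa, 4),
                  train_accuracy = round(train_accuracy, 4),
                  train_kappa = round(train_kappa, 4)))
  invisible(x)
}

cv_kappa_for <- function(model_id, x, y, fold_id, folds, seed) {
  set.seed(seed)
  pred <- cv_model(model_id, x, y, fold_id, folds)
  kappa_statistic(table(reference = y, prediction = pred))
}

#' Greedy minimal descriptor subset selection
#'
#' Forward selection maximizing cross-validated kappa of `model_id`: starting
#' from the empty set, each round adds the descriptor giving the largest
#' kappa gain (ties broken by registry order) and stops as soon as the
#' subset's kappa is within `tolerance` of the full-descriptor kappa, or when
#' no candidate improves it. Fold assignment is shared across all candidate
#' evaluations so subsets are compared on identical splits.
#'
#' @param table Training table from [training_table()].
#' @param model_id Model to evaluate subsets with (typically the best model
#'   from [evaluate_models()]).
#' @param tolerance Allowed kappa shortfall relative to the full set.
#' @param folds,seed As in [evaluate_models()].
#' @param max_size Safety cap on subset size.
#' @return Object of class `feature_subset`: list with `descriptor_ids`,
#'   `cv_kappa_with_subset`, `cv_kappa_full`, `tolerance`, `degenerate`
#'   (TRUE when the full-set kappa is indistinguishable from chance).
#' @export
select_features <- function(table, model_id, tolerance = 0.01, folds = 10,
                            seed = 1, max_size = 15) {
  y <- droplevels(table$group)
  features <- setdiff(names(table), c("taxon_id", "group"))
  x <- feature_matrix(table, features)
  fold_id <- stratified_folds(y, folds, seed)
  full_kappa <- cv_kappa_for(model_id, x, y, fold_id, folds, seed)
  chosen <- character()
  current_kappa <- -Inf
  while (length(chosen) < min(max_size, length(features))) {
    if (length(chosen) && current_kappa >= full_kappa - tolerance) break
    cand <- setdiff(features, chosen)
    kappas <- vapply(cand, function(f) {
      cv_kappa_for(model_id, x[, c(chosen, f), drop = FALSE], y,
                   fold_id, folds, seed)
    }, numeric(1))
    best <- which.max(kappas)     # first max = registry order tie-break
    if (length(chosen) && kappas[best] <= current_kappa) break
    chosen <- c(chosen, cand[best])
    current_kappa <- kappas[best]
  }
  structure(list(
    descriptor_ids = chosen,
    cv_kappa_with_subset = current_kappa,
    cv_kappa_full = full_kappa,
    tolerance = tolerance,
    degenerate = abs(full_kappa) < 0.1,
    model_id = model_id, folds = folds, seed = seed
  ), class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("Selected", length(x$descriptor_ids), "descriptor(s) [", x$model_id,
      "]: ", paste(x$descriptor_ids, collapse = ", "), "\n")
  cat(sprintf("cv kappa %.3f (full set %.3f, tolerance %.3g)%s\n",
              x$cv_kappa_with_subset, x$cv_kappa_full, x$tolerance,
              if (x$degenerate) " [degenerate: full-set kappa near chance]" else ""))
  invisible(x)
}

#' Run classification for one contrast and write a JSON report
#'
#' @param table Training table.
#' @param path Output JSON path.
#' @param models,folds,seed,tolerance Passed through to [evaluate_models()]
#'   and [select_features()].
#' @return Invisibly, the report list.
#' @export
classify_contrast <- function(table, path = NULL, models = model_registry(),
                              folds = 10, seed = 1, tolerance = 0.01) {
  ev <- evaluate_models(table, models = models, folds = folds, seed = seed)
  best <- ev$results$model_id[1]
  fs <- select_features(table, best, tolerance = tolerance, folds = folds,
                        seed = seed)
  report <- list(
    contrast = attr(table, "contrast"),
    models = ev$results,
    best_model = best,
    selected_features = fs$descriptor_ids,
    selected_cv_kappa = fs$cv_kappa_with_subset,
    seed = seed,
    folds = folds
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(report)
}
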