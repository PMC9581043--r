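# Multimodal fusion, random-forest recursive feature elimination (RF-RFE),
# nested stratified k-fold cross-validation, and the final IDH classifier.
#
# All preprocessing (median imputation, z-score standardization) and feature
# selection are fitted strictly on training folds; test folds only ever pass
# through frozen transforms.

#' Fuse per-modality feature tables with clinical covariates
#'
#' Column-wise concatenation on subject id: one row per subject present in
#' every modality table. Subjects missing a modality are dropped with a
#' warning, since the multimodal model needs every block.
#'
#' @param tables named list of data frames, each with a `subject_id` column
#'   and provenance-tagged feature columns.
#' @param clinical data frame with `subject_id`, `age`, `sex` and `label`.
#' @return a fused feature table (data frame): `subject_id`, features of every
#'   modality, `age`, `sex`, `label`.
#' @export
fuse <- function(tables, clinical) {
  stop_if_not(length(tables) >= 1, "need at least one modality table")
  stop_if_not(all(c("subject_id", "age", "sex", "label") %in% names(clinical)),
              "clinical table must have subject_id, age, sex, label")
  ids <- Reduce(intersect, c(lapply(tables, `[[`, "subject_id"),
                             list(clinical$subject_id)))
  if (length(ids) == 0) stop("no subjects shared across all modalities")
  n_all <- length(unique(unlist(lapply(tables, `[[`, "subject_id"))))
  if (length(ids) < n_all) {
    warning(sprintf("%d subject(s) missing a modality were excluded",
                    n_all - length(ids)))
  }
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    feat <- tb[match(ids, tb$subject_id), setdiff(names(tb), "subject_id"),
               drop = FALSE]
    out <- cbind(out, feat)
  }
  cl <- clinical[match(ids, clinical$subject_id), ]
  out$age <- cl$age
  out$sex <- cl$sex
  out$label <- cl$label
  rownames(out) <- NULL
  out
}

# -- internal preprocessing ---------------------------------------------------

# numeric design matrix (sex -> indicator) and label factor from a table
ft_design <- function(table) {
  stop_if_not("label" %in% names(table), "table must have a label column")
  y <- factor(table$label, levels = c("wildtype", "mutant"))
  stop_if_not(!any(is.na(y)), "labels must be 'mutant' or 'wildtype'")
  drop <- intersect(c("subject_id", "label"), names(table))
  x <- table[, setdiff(names(table), drop), drop = FALSE]
  if ("sex" %in% names(x)) {
    x$sex <- as.numeric(x$sex == "M")
    names(x)[names(x) == "sex"] <- "sex_M"
  }
  x <- as.matrix(as.data.frame(lapply(x, as.numeric),
                               check.names = FALSE, optional = TRUE))
  list(x = x, y = y)
}

impute_fit <- function(x) apply(x, 2, function(v) {
  m <- median(v, na.rm = TRUE)
  if (is.na(m)) 0 else m
})

impute_apply <- function(x, med) {
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  x
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

standardize_apply <- function(x, fit) {
  scale(x, center = fit$center, scale = fit$scale)[, , drop = FALSE]
}

# x is kept as a numeric matrix throughout: data frames would mangle the
# provenance-tagged feature names (dashes in filter tags) and silently break
# importance lookups
fit_rf <- function(x, y, num_trees, seed, importance = "none") {
  # min.node.size = 1 (the classification default): probability forests
  # otherwise default to 10 and refuse to split small-cohort training folds
  ranger::ranger(x = x, y = y, num.trees = num_trees,
                 probability = TRUE, importance = importance,
                 min.node.size = 1, seed = seed, num.threads = 1)
}

rf_accuracy <- function(fit, x, y) {
  p <- predict(fit, data = x, num.threads = 1)$predictions
  mean((p[, "mutant"] > 0.5) == (y == "mutant"))
}

stratified_folds <- function(y, k, seed) {
  stop_if_not(min(table(y)) >= k || k == 1,
              "too few subjects per class for the requested folds")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# -- RF-RFE -------------------------------------------------------------------

#' Random-forest recursive feature elimination
#'
#' Iteratively fits a random forest, ranks features by impurity importance,
#' and removes the lowest-importance `step` fraction until one feature
#' remains (or `target_size` is reached). With `target_size = NULL` the
#' returned subset is the candidate set maximizing internal stratified
#' `inner_folds`-fold accuracy; ties go to the smaller set. Importance ties
#' are broken by column order. Deterministic under `seed`.
#'
#' @param x numeric feature matrix (preprocessed; no missing values).
#' @param y binary factor with levels `wildtype`, `mutant`.
#' @param step fraction of remaining features removed per iteration.
#' @param target_size stop at this many features and return them (skips the
#'   internal accuracy search); `NULL` for automatic size selection.
#' @param num_trees forest size per fit.
#' @param inner_folds internal CV folds for the automatic size search.
#' @param seed integer seed.
#' @return object of class `rf_rfe`: `selected` (feature names), `path`
#'   (candidate sizes with internal accuracies), `ranking` (final importance
#'   ranks of the selected features).
#' @export
rf_rfe <- function(x, y, step = 0.1, target_size = NULL, num_trees = 500,
                   inner_folds = 5, seed = 1) {
  stop_if_not(ncol(x) >= 2, "need at least 2 features")
  y <- factor(y, levels = c("wildtype", "mutant"))
  stop_if_not(nlevels(droplevels(y)) == 2, "training data must contain both classes")
  stop_if_not(min(table(y)) >= 4, "need >= 4 subjects per class")
  current <- colnames(x)
  auto <- is.null(target_size)
  inner <- if (auto) stratified_folds(y, inner_folds, derive_seed(seed, "inner")) else NULL
  path <- list()
  best <- list(acc = -1, set = current)
  importances <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    fit <- fit_rf(x[, current, drop = FALSE], y, num_trees,
                  derive_seed(seed, paste0("rank", it)), importance = "impurity")
    imp <- fit$variable.importance[current]
    if (auto) {
      acc <- mean(vapply(seq_len(inner_folds), function(f) {
        tr <- inner != f
        m <- fit_rf(x[tr, current, drop = FALSE], y[tr], num_trees,
                    derive_seed(seed, paste0("cv", it, "-", f)))
        rf_accuracy(m, x[!tr, current, drop = FALSE], y[!tr])
      }, 0))
      path[[it]] <- data.frame(size = length(current), accuracy = acc)
      # prefer higher accuracy; on ties the smaller (later) set wins
      if (acc >= best$acc) best <- list(acc = acc, set = current, imp = imp)
    }
    if (!auto && length(current) <= target_size) break
    if (length(current) <= 1) break
    n_drop <- max(1L, floor(step * length(current)))
    if (!auto) n_drop <- min(n_drop, length(current) - target_size)
    # order: lowest importance first, ties broken by reverse column order so
    # the earliest column survives longest
    ord <- order(imp, match(current, colnames(x)), decreasing = c(FALSE, TRUE),
                 method = "radix")
    current <- setdiff(current, current[ord[seq_len(n_drop)]])
  }
  if (auto) {
    sel <- best$set
    ranks <- rank(-best$imp[sel], ties.method = "first")
  } else {
    sel <- current
    fit <- fit_rf(x[, sel, drop = FALSE], y, num_trees,
                  derive_seed(seed, "final-rank"), importance = "impurity")
    ranks <- rank(-fit$variable.importance[sel], ties.method = "first")
  }
  structure(list(selected = sel, ranking = ranks,
                 path = if (length(path)) do.call(rbind, path) else NULL,
                 seed = seed),
            class = "rf_rfe")
}

#' @export
print.rf_rfe <- function(x, ...) {
  cat(sprintf("<rf_rfe: %d features selected>\n", length(x$selected)))
  invisible(x)
}

# -- nested cross-validation --------------------------------------------------

#' Nested cross-validated evaluation of the IDH classifier
#'
#' Stratified `k`-fold cross-validation with RF-RFE feature selection,
#' median imputation and z-score standardization refit inside each training
#' fold, so selection never sees the test fold. Reports per-fold accuracy
#' (mean and sd), pooled test-fold ROC and AUC, and the per-fold selected
#' features.
#'
#' @param table a fused feature table (see [fuse()] or
#'   [make_feature_table()]).
#' @param k folds (default 10).
#' @param seed integer seed controlling folds and every forest fit.
#' @param step,num_trees,inner_folds,target_size passed to [rf_rfe()].
#' @param select run RF-RFE inside folds (`TRUE`) or use all features.
#' @return object of class `idh_cv`.
#' @export
cv_evaluate <- function(table, k = 10, seed = 1, step = 0.1, num_trees = 500,
                        inner_folds = 5, target_size = NULL, select = TRUE) {
  des <- ft_design(table)
  stop_if_not(length(des$y) >= k, "need at least k subjects")
  folds <- stratified_folds(des$y, k, derive_seed(seed, "folds"))
  acc <- numeric(k)
  probs <- numeric(length(des$y))
  sel_list <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(des$y[!tr])) < 1 || length(unique(des$y[tr])) < 2) {
      stop("a fold lost a class; reduce k or rebalance")
    }
    med <- impute_fit(des$x[tr, , drop = FALSE])
    xtr <- impute_apply(des$x[tr, , drop = FALSE], med)
    sc <- standardize_fit(xtr)
    xtr <- standardize_apply(xtr, sc)
    xte <- standardize_apply(impute_apply(des$x[!tr, , drop = FALSE], med), sc)
    feats <- colnames(des$x)
    if (select) {
      rfe <- rf_rfe(xtr, des$y[tr], step = step, target_size = target_size,
                    num_trees = num_trees, inner_folds = inner_folds,
                    seed = derive_seed(seed, paste0("rfe", f)))
      feats <- rfe$selected
    }
    sel_list[[f]] <- feats
    fit <- fit_rf(xtr[, feats, drop = FALSE], des$y[tr], num_trees,
                  derive_seed(seed, paste0("fit", f)))
    p <- predict(fit, data = xte[, feats, drop = FALSE],
                 num.threads = 1)$predictions[, "mutant"]
    probs[!tr] <- p
    acc[f] <- mean((p > 0.5) == (des$y[!tr] == "mutant"))
  }
  roc <- pROC::roc(response = des$y, predictor = probs,
                   levels = c("wildtype", "mutant"), direction = "<",
                   quiet = TRUE)
  structure(list(fold_accuracy = acc, accuracy_mean = mean(acc),
                 accuracy_sd = sd(acc), auc = as.numeric(pROC::auc(roc)),
                 roc_points = data.frame(specificity = roc$specificities,
                                         sensitivity = roc$sensitivities),
                 probabilities = probs, labels = des$y,
                 selected = sel_list, k = k, seed = seed,
                 config = list(step = step, num_trees = num_trees,
                               inner_folds = inner_folds,
                               target_size = target_size, select = select)),
            class = "idh_cv")
}

#' @export
print.idh_cv <- function(x, ...) {
  cat(sprintf("IDH classifier, %d-fold cross-validation\n", x$k))
  cat(sprintf("  accuracy: %.2f (+/- %.2f)   AUC: %.2f\n",
              x$accuracy_mean, x$accuracy_sd, x$auc))
  invisible(x)
}

#' @export
summary.idh_cv <- function(object, ...) {
  sel <- sort(table(unlist(object$selected)), decreasing = TRUE)
  cat(sprintf("IDH classifier, %d-fold cross-validation (seed %d)\n",
              object$k, object$seed))
  cat(sprintf("  per-fold accuracy: %s\n",
              paste(sprintf("%.2f", object$fold_accuracy), collapse = " ")))
  cat(sprintf("  accuracy: %.3f +/- %.3f\n  AUC: %.3f\n",
              object$accuracy_mean, object$accuracy_sd, object$auc))
  cat("  most frequently selected features:\n")
  print(head(sel, 10))
  invisible(object)
}

#' @export
plot.idh_cv <- function(x, ...) {
  ord <- order(1 - x$roc_points$specificity, x$roc_points$sensitivity)
  plot(1 - x$roc_points$specificity[ord], x$roc_points$sensitivity[ord],
       type = "l", xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("Pooled ROC (AUC = %.2f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

# -- final model --------------------------------------------------------------

#' Fit the final IDH random-forest classifier
#'
#' Fits imputation, standardization and (optionally) RF-RFE on the full
#' table, then trains the probability forest on the selected features. The
#' fitted object carries its preprocessing, the selected-feature registry
#' hash, and the training sex distribution (used when perturbing the
#' categorical covariate in explanations).
#'
#' @inheritParams cv_evaluate
#' @param features optional character vector of feature names to use; `NULL`
#'   runs RF-RFE.
#' @return object of class `idh_rf` with a [predict.idh_rf()] method.
#' @export
idh_rf <- function(table, features = NULL, seed = 1, num_trees = 500,
                   step = 0.1, inner_folds = 5, target_size = NULL) {
  des <- ft_design(table)
  med <- impute_fit(des$x)
  x <- impute_apply(des$x, med)
  sc <- standardize_fit(x)
  xs <- standardize_apply(x, sc)
  if (is.null(features)) {
    rfe <- rf_rfe(xs, des$y, step = step, target_size = target_size,
                  num_trees = num_trees, inner_folds = inner_folds,
                  seed = derive_seed(seed, "rfe-final"))
    features <- rfe$selected
  }
  stop_if_not(all(features %in% colnames(xs)),
              "selected features not all present in the table")
  fit <- fit_rf(xs[, features, drop = FALSE], des$y, num_trees,
                derive_seed(seed, "final"), importance = "impurity")
  structure(list(forest = fit, features = features, center = sc$center,
                 scale = sc$scale, medians = med,
                 feature_hash = fnv1a_hash(features),
                 sex_p_male = if ("sex_M" %in% colnames(x)) mean(x[, "sex_M"]) else NA,
                 levels = levels(des$y), seed = seed, num_trees = num_trees),
            class = "idh_rf")
}

#' Predict IDH mutation probability
#'
#' @param object an [idh_rf()] fit.
#' @param newdata data frame with the model's feature columns (raw scale;
#'   `sex` may be given as `"M"`/`"F"`), or a numeric matrix already in the
#'   model's standardized space (`standardized = TRUE`).
#' @param type `"prob"` for class probabilities, `"class"` for labels.
#' @param standardized `newdata` is already imputed and standardized.
#' @param ... unused.
#' @return probability matrix with columns `wildtype`, `mutant` (rows sum to
#'   1), or a character vector of labels.
#' @export
predict.idh_rf <- function(object, newdata, type = c("prob", "class"),
                           standardized = FALSE, ...) {
  type <- match.arg(type)
  if (standardized) {
    xs <- as.matrix(newdata)
    miss <- setdiff(object$features, colnames(xs))
    if (length(miss)) stop("feature schema mismatch; missing: ",
                           paste(head(miss, 5), collapse = ", "))
  } else {
    nd <- as.data.frame(newdata)
    if ("sex" %in% names(nd) && !is.numeric(nd$sex)) {
      nd$sex_M <- as.numeric(nd$sex == "M"); nd$sex <- NULL
    }
    need <- names(object$medians)
    miss <- setdiff(object$features, names(nd))
    if (length(miss)) stop("feature schema mismatch; missing: ",
                           paste(head(miss, 5), collapse = ", "))
    x <- matrix(NA_real_, nrow(nd), length(need), dimnames = list(NULL, need))
    for (j in intersect(need, names(nd))) x[, j] <- as.numeric(nd[[j]])
    x <- impute_apply(x, object$medians)
    xs <- standardize_apply(x, list(center = object$center, scale = object$scale))
  }
  p <- predict(object$forest, data = xs[, object$features, drop = FALSE],
               num.threads = 1)$predictions
  if (type == "class") {
    ifelse(p[, "mutant"] > 0.5, "mutant", "wildtype")
  } else {
    p[, c("wildtype", "mutant"), drop = FALSE]
  }
}

#' @export
print.idh_rf <- function(x, ...) {
  cat(sprintf("IDH random-forest classifier: %d features, %d trees (hash %s)\n",
              length(x$features), x$num_trees, x$feature_hash))
  invisible(x)
}
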