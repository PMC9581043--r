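# Fusion, RF-RFE, nested cross-validation and the final classifier.

prep_xy <- function(tb) {
  des <- radpath:::ft_design(tb)
  med <- radpath:::impute_fit(des$x)
  x <- radpath:::impute_apply(des$x, med)
  sc <- radpath:::standardize_fit(x)
  list(x = radpath:::standardize_apply(x, sc), y = des$y)
}

test_that("fusion joins modalities on subject id with clinical covariates", {
  a <- data.frame(subject_id = c("s1", "s2", "s3"), f1 = 1:3, f2 = 4:6)
  b <- data.frame(subject_id = c("s3", "s1", "s2"), g1 = 7:9)
  clin <- data.frame(subject_id = c("s1", "s2", "s3"), age = c(40, 50, 60),
                     sex = c("M", "F", "M"),
                     label = c("mutant", "wildtype", "mutant"))
  fused <- fuse(list(A = a, B = b), clin)
  expect_equal(ncol(fused), 1 + 2 + 1 + 2 + 1)  # id + p1 + p2 + (age, sex) + label
  expect_equal(fused$g1[fused$subject_id == "s1"], 8)  # row alignment by id
  # disjoint ids: error
  b2 <- data.frame(subject_id = c("x1", "x2"), g1 = 1:2)
  expect_error(fuse(list(A = a, B = b2), clin), "no subjects shared")
  # a subject missing one modality is dropped with a warning
  b3 <- b[1:2, ]
  expect_warning(f2 <- fuse(list(A = a, B = b3), clin), "excluded")
  expect_equal(nrow(f2), 2)
})

test_that("training-fold standardization gives mean 0 and sd 1", {
  tb <- make_feature_table(30, 2, 4, effect_size = 1, seed = 2)
  p <- prep_xy(tb)
  expect_lt(max(abs(colMeans(p$x))), 1e-9)
  expect_lt(max(abs(apply(p$x, 2, sd) - 1)), 1e-9)
})

test_that("RFE with target_size = p is the identity and respects target sizes", {
  tb <- make_feature_table(24, 2, 8, effect_size = 2, seed = 3)
  p <- prep_xy(tb)
  r <- rf_rfe(p$x, p$y, target_size = ncol(p$x), seed = 1)
  expect_setequal(r$selected, colnames(p$x))
  r4 <- rf_rfe(p$x, p$y, target_size = 4, seed = 1)
  expect_length(r4$selected, 4)
})

test_that("RFE retains injected informative features and is seed-deterministic", {
  hits <- 0
  for (s in 1:5) {
    tb <- make_feature_table(60, 2, 50, effect_size = 3, seed = 100 + s)
    p <- prep_xy(tb)
    r <- rf_rfe(p$x, p$y, seed = s)
    hits <- hits + all(c("inf_1", "inf_2") %in% r$selected)
  }
  expect_gte(hits, 4)   # acceptance runs the full 20-seed version
  tb <- make_feature_table(40, 2, 20, effect_size = 3, seed = 7)
  p <- prep_xy(tb)
  expect_identical(rf_rfe(p$x, p$y, seed = 5)$selected,
                   rf_rfe(p$x, p$y, seed = 5)$selected)
})

test_that("constant features fall back to the documented column-order tie-break", {
  x <- matrix(0, 16, 6, dimnames = list(NULL, paste0("c", 1:6)))
  y <- factor(rep(c("wildtype", "mutant"), each = 8),
              levels = c("wildtype", "mutant"))
  r <- rf_rfe(x, y, target_size = 2, seed = 1)
  expect_equal(r$selected, c("c1", "c2"))
})

test_that("degenerate single-class training data is rejected", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep("mutant", 10), levels = c("wildtype", "mutant"))
  expect_error(rf_rfe(x, y, seed = 1), "both classes")
})

test_that("nested CV is perfect on a separable table and chance on permuted labels", {
  tb <- make_feature_table(40, 2, 8, effect_size = 6, seed = 4)
  cv <- cv_evaluate(tb, k = 5, seed = 2, num_trees = 300, inner_folds = 3)
  expect_equal(cv$accuracy_mean, 1.0)
  expect_equal(cv$auc, 1.0)
  expect_length(cv$fold_accuracy, 5)
  # label permutation breaks the signal; selection inside folds must not leak
  tbp <- tb
  set.seed(9); tbp$label <- sample(tbp$label)
  cvp <- cv_evaluate(tbp, k = 5, seed = 2, num_trees = 300, inner_folds = 3)
  expect_gt(cvp$accuracy_mean, 0.2)
  expect_lt(cvp$accuracy_mean, 0.8)
})

test_that("mean CV accuracy responds monotonically to the injected effect", {
  accs <- vapply(c(0.3, 1.2, 3), function(eff) {
    tb <- make_feature_table(40, 2, 8, effect_size = eff, seed = 21)
    cv_evaluate(tb, k = 5, seed = 3, num_trees = 200, select = FALSE)$accuracy_mean
  }, 0)
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], accs[1])
})

test_that("fusing two modalities with independent signal beats either alone", {
  n <- 40
  labels <- rep(c("mutant", "wildtype"), each = n / 2)
  set.seed(31)
  shift <- ifelse(labels == "mutant", 1.1, 0)
  modA <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     a_inf = rnorm(n, shift), a_n1 = rnorm(n), a_n2 = rnorm(n))
  modB <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     b_inf = rnorm(n, shift), b_n1 = rnorm(n), b_n2 = rnorm(n))
  clin <- data.frame(subject_id = sprintf("s%02d", 1:n),
                     age = rnorm(n, 55, 10), sex = rep(c("M", "F"), n / 2),
                     label = labels)
  accs <- vapply(list(list(A = modA), list(B = modB), list(A = modA, B = modB)),
                 function(mods) {
                   cv_evaluate(fuse(mods, clin), k = 5, seed = 6,
                               num_trees = 300, select = FALSE)$accuracy_mean
                 }, 0)
  expect_gte(accs[3], max(accs[1:2]) - 0.05)
})

test_that("the final classifier predicts coherently and reproducibly", {
  tb <- make_feature_table(40, 2, 10, effect_size = 4, seed = 8)
  fit <- idh_rf(tb, seed = 3, num_trees = 300, inner_folds = 3)
  p <- predict(fit, tb)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p[tb$label == "mutant", "mutant"] > 0.5))
  expect_equal(unname(predict(fit, tb, type = "class")), tb$label)
  # same seed, same fit, identical predictions
  fit2 <- idh_rf(tb, seed = 3, num_trees = 300, inner_folds = 3)
  expect_identical(predict(fit2, tb), p)
  # schema mismatch is an explicit error
  bad <- tb[, setdiff(names(tb), fit$features[1])]
  expect_error(predict(fit, bad), "schema")
  expect_match(fit$feature_hash, "^[0-9a-f]{8}$")
})

test_that("stratified folds always contain both classes", {
  tb <- make_feature_table(22, 1, 3, effect_size = 1, seed = 12,
                           class_balance = 0.5)
  des <- radpath:::ft_design(tb)
  folds <- radpath:::stratified_folds(des$y, 5, seed = 4)
  for (f in 1:5) expect_equal(nlevels(droplevels(des$y[folds == f])), 2)
  expect_error(radpath:::stratified_folds(des$y, 12, seed = 1), "too few")
})
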