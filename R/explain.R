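# LIME-style local surrogate explanation: Gaussian perturbations around a
# standardized instance, proximity-weighted ridge regression of the
# classifier's mutant probability, signed per-feature weights.

#' Explain one prediction with a local linear surrogate
#'
#' Draws `n_samples` Gaussian perturbations (unit variance per feature)
#' around the standardized instance, weights them by the proximity kernel
#' \eqn{\exp(-d^2 / w^2)} with \eqn{d} the Euclidean distance, and fits a
#' weighted least squares with an L2 penalty to the model's predicted mutant
#' probability. Binary features (the sex indicator) are perturbed by
#' resampling the training distribution instead of adding noise. Weights are
#' signed: a positive weight means increasing the feature increases the
#' predicted mutation probability near this instance.
#'
#' @param model an [idh_rf()] fit, or any function mapping a numeric matrix
#'   (columns = features) to a probability vector — useful for explaining an
#'   arbitrary black box in the instance's own (already standardized) space.
#' @param instance one-row data frame (raw feature scale, as the model's
#'   training table); for a function black box, a named numeric vector.
#' @param n_samples number of perturbations (>= 100).
#' @param kernel_width proximity kernel width; default \eqn{0.75\sqrt{p}}.
#' @param k number of top-|weight| features to report.
#' @param seed integer seed.
#' @param lambda L2 penalty of the surrogate fit.
#' @return object of class `idh_explanation`: `weights` (all signed surrogate
#'   coefficients), `top` (the k largest by |weight|), `intercept`,
#'   `fidelity` (weighted R² of the surrogate, clipped to [0, 1]),
#'   `prediction` (the model's probability at the instance), `kernel_width`,
#'   `n_samples`, `seed`.
#' @export
explain_instance <- function(model, instance, n_samples = 2000,
                             kernel_width = NULL, k = 10, seed = 1,
                             lambda = 0.01) {
  stop_if_not(inherits(model, "idh_rf") || is.function(model),
              "model must be an idh_rf fit or a prediction function")
  stop_if_not(n_samples >= 100, "n_samples must be >= 100")
  if (is.function(model)) {
    # generic black box: the instance is already in model space
    z0 <- unlist(instance)
    stop_if_not(!is.null(names(z0)), "instance must be named")
    feats <- names(z0)
    p <- length(feats)
    x0s <- matrix(z0, 1, p, dimnames = list(NULL, feats))
    predict_prob <- function(X) as.numeric(model(X[, feats, drop = FALSE]))
    sex_p <- NA
  } else {
    feats <- model$features
    p <- length(feats)
    # standardized instance restricted to the model's features
    nd <- as.data.frame(instance)
    if ("sex" %in% names(nd) && !is.numeric(nd$sex)) {
      nd$sex_M <- as.numeric(nd$sex == "M"); nd$sex <- NULL
    }
    need <- names(model$medians)
    x0 <- matrix(NA_real_, 1, length(need), dimnames = list(NULL, need))
    for (j in intersect(need, names(nd))) x0[, j] <- as.numeric(nd[[j]])
    x0 <- impute_apply(x0, model$medians)
    x0s <- standardize_apply(x0, list(center = model$center, scale = model$scale))
    predict_prob <- function(X) predict(model, X, standardized = TRUE)[, "mutant"]
    sex_p <- model$sex_p_male
  }
  z0 <- x0s[1, feats]
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)

  is_binary <- feats == "sex_M"
  with_seed(seed, {
    Z <- matrix(rnorm(n_samples * p), n_samples, p)
    Z <- sweep(Z, 2, z0, `+`)
    colnames(Z) <- feats
    if (any(is_binary) && inherits(model, "idh_rf") && !is.na(sex_p)) {
      raw <- rbinom(n_samples, 1, sex_p)
      j <- which(is_binary)
      Z[, j] <- (raw - model$center["sex_M"]) / model$scale["sex_M"]
    }
    full <- matrix(rep(x0s, each = n_samples), n_samples, ncol(x0s),
                   dimnames = list(NULL, colnames(x0s)))
    full[, feats] <- Z
    pr <- predict_prob(full)
    d2 <- rowSums(sweep(Z, 2, z0, `-`)^2)
    wts <- exp(-d2 / kernel_width^2)
    # weighted ridge: (X'WX + lambda I)^-1 X'W y, intercept unpenalized
    X <- cbind(1, sweep(Z, 2, z0, `-`))
    A <- crossprod(X * wts, X) + diag(c(0, rep(lambda, p)))
    beta <- solve(A, crossprod(X * wts, pr))
    yhat <- X %*% beta
    wmean <- sum(wts * pr) / sum(wts)
    ss_res <- sum(wts * (pr - yhat)^2)
    ss_tot <- sum(wts * (pr - wmean)^2)
    fidelity <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
    weights <- setNames(as.numeric(beta[-1]), feats)
    top <- weights[order(abs(weights), decreasing = TRUE)][seq_len(min(k, p))]
    structure(list(weights = weights, top = top,
                   intercept = as.numeric(beta[1]), fidelity = fidelity,
                   prediction = as.numeric(predict_prob(x0s)),
                   kernel_width = kernel_width, n_samples = n_samples,
                   seed = seed),
              class = "idh_explanation")
  })
}

#' @export
print.idh_explanation <- function(x, ...) {
  cat(sprintf("Local surrogate explanation (fidelity R2 = %.2f, p(mutant) = %.2f)\n",
              x$fidelity, x$prediction))
  for (nm in names(x$top)) {
    cat(sprintf("  %+0.4f  %s\n", x$top[nm], nm))
  }
  invisible(x)
}

#' @export
plot.idh_explanation <- function(x, ...) {
  w <- rev(x$top)
  cols <- ifelse(w > 0, "#2c7fb8", "#d95f0e")
  op <- par(mar = c(4, 12, 2, 1))
  on.exit(par(op))
  barplot(w, horiz = TRUE, las = 1, col = cols,
          xlab = "surrogate weight",
          main = sprintf("p(mutant) = %.2f", x$prediction), ...)
  abline(v = 0)
  invisible(x)
}

#' Serialize an explanation to JSON
#' @param x an `idh_explanation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_explanation_json <- function(x, path) {
  jsonlite::write_json(list(weights = as.list(x$top), intercept = x$intercept,
                            fidelity = x$fidelity, prediction = x$prediction,
                            kernel_width = x$kernel_width,
                            n_samples = x$n_samples, seed = x$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
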