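#' Reads-per-hundred-thousand classifier features
#'
#' Scales each sample's gene counts to reads per 100,000 (RPK), then takes
#' `log10(rpk + 1)`. The depth scaling makes features comparable across
#' samples of different sequencing depth; the +1 offset maps zero counts to
#' exactly 0 and keeps the transform defined everywhere.
#'
#' @param counts a gene-level [phip_counts()].
#' @return Numeric feature matrix, genes x samples.
#' @export
rpk_transform <- function(counts) {
  stopifnot(inherits(counts, "phip_counts"))
  if (counts$feature_level != "gene") stop("rpk_transform expects gene-level counts")
  tot <- colSums(counts$counts)
  if (any(tot == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts$counts)[tot == 0], collapse = ", "))
  }
  rpk <- sweep(counts$counts, 2, tot, "/") * 1e5
  log10(rpk + 1)
}

# Mann-Whitney AUC of scores for the positive class, average ranks for ties
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_curve <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(positive[ord])
  fp <- cumsum(!positive[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / sum(!positive)),
             tpr = c(0, tp[keep] / sum(positive)))
}

stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' L1 logistic regression with stratified cross-validation
#'
#' Fits an L1-penalized logistic regression of case/control status on the
#' feature matrix, evaluated by pooling out-of-fold predicted probabilities
#' across stratified folds into a single ROC/AUC; coefficients are reported
#' from a final fit on all samples. The penalty is parameterized as an
#' inverse regularization strength C (larger C = weaker penalty), i.e. the
#' minimized objective is `sum_i loss_i + (1/C) * ||w||_1`.
#'
#' @param features numeric matrix, genes x samples (e.g. [rpk_transform()]).
#' @param labels character/factor of `"case"`/`"control"`, one per sample
#'   (column order of `features`).
#' @param n_folds folds for cross-validation (default 5); each class must
#'   have at least `n_folds` samples.
#' @param regularization_strength inverse penalty C (default 1).
#' @param seed seed for the fold shuffle.
#' @return A list of class `phip_classifier`: `auc`, `roc_points`
#'   (`data.frame(fpr, tpr)`), `oof_prob` (pooled out-of-fold case
#'   probabilities), `fold_assignments`, `coefficients` (named per-gene
#'   vector from the full-data fit; sparse under L1), `intercept`,
#'   `regularization_strength`, `n_folds`.
#' @export
fit_logistic_cv <- function(features, labels, n_folds = 5,
                            regularization_strength = 1.0, seed = 1) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  labels <- as.character(labels)
  if (length(labels) != ncol(features)) {
    stop("labels must have one entry per sample (column) of features")
  }
  bad <- setdiff(labels, c("case", "control"))
  if (length(bad) > 0) stop("labels must be 'case' or 'control'")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (min(table(labels)) < n_folds) {
    stop("each class needs at least n_folds samples for stratified folds")
  }

  x <- t(features)                      # samples x genes for glmnet
  y <- as.integer(labels == "case")
  fold <- stratified_folds(labels, n_folds, seed)

  # Fit at the single target lambda via a warm-started descending path
  # (glmnet converges poorly when handed one small lambda directly).
  l1_fit <- function(xtr, ytr) {
    lam <- 1 / (length(ytr) * regularization_strength)
    lam_max <- max(abs(crossprod(xtr, ytr - mean(ytr)))) / length(ytr)
    path <- if (lam_max > lam) {
      exp(seq(log(lam_max), log(lam), length.out = 30))
    } else lam
    fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 1,
                          lambda = path, standardize = FALSE)
    list(fit = fit, lambda = lam)
  }

  oof <- rep(NA_real_, length(y))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    f <- l1_fit(x[tr, , drop = FALSE], y[tr])
    oof[!tr] <- predict(f$fit, x[!tr, , drop = FALSE], type = "response",
                        s = f$lambda)[, 1]
  }
  stopifnot(!anyNA(oof))

  full <- l1_fit(x, y)
  cf <- predict(full$fit, type = "coefficients", s = full$lambda)[, 1]
  beta <- stats::setNames(cf[-1], rownames(features))

  structure(list(
    auc = rank_auc(oof, y == 1),
    roc_points = roc_curve(oof, y == 1),
    oof_prob = stats::setNames(oof, colnames(features)),
    fold_assignments = stats::setNames(fold, colnames(features)),
    coefficients = beta,
    intercept = unname(cf[1]),
    regularization_strength = regularization_strength,
    n_folds = n_folds, seed = as.integer(seed)),
    class = "phip_classifier")
}

#' @export
print.phip_classifier <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("phip_classifier: pooled out-of-fold AUC = %.3f (%d-fold CV), %d nonzero coefficients\n",
              x$auc, x$n_folds, nz))
  top <- sort(abs(x$coefficients), decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) > 0) {
    cat("top coefficients:",
        paste(sprintf("%s=%.2f", names(head(top, 5)),
                      x$coefficients[names(head(top, 5))]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write classifier outputs (JSON summary, ROC TSV, coefficient TSV)
#'
#' @param clf a [fit_logistic_cv()] result.
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
write_classifier_outputs <- function(clf, prefix) {
  stopifnot(inherits(clf, "phip_classifier"))
  json <- paste0(prefix, "_classifier.json")
  jsonlite::write_json(list(auc = clf$auc, n_folds = clf$n_folds,
                            regularization_strength = clf$regularization_strength,
                            n_nonzero_coefficients = sum(clf$coefficients != 0)),
                       json, auto_unbox = TRUE, digits = NA)
  roc <- paste0(prefix, "_roc.tsv")
  write_tsv(clf$roc_points, roc)
  coefs <- paste0(prefix, "_coefficients.tsv")
  cdf <- data.frame(gene = names(clf$coefficients),
                    coefficient = unname(clf$coefficients))
  write_tsv(cdf[order(-abs(cdf$coefficient)), ], coefs)
  invisible(c(json, roc, coefs))
}
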