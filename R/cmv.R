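# Repertoire-based CMV serostatus classification: clone matching against a
# CMV-associated list, a two-feature linear max-margin classifier with
# cross-validated regularization choice, AUROC, and patient-level calling.

#' Count CMV-associated clone matches per sample
#'
#' A repertoire clone matches when its full (CDR3 amino-acid, V gene, J gene)
#' triple equals a list triple; a shared CDR3 with a different V or J does
#' not count. Both features use set semantics, so duplicated clone rows are
#' counted once.
#'
#' @param repertoire A `RepertoireTable` (or equivalent data frame).
#' @param cmv_list Data frame of CMV-associated triples (`cdr3_aa`, `v_gene`,
#'   `j_gene`).
#' @return Data frame with one row per sample: `sample_id`, `patient_id`,
#'   `n_hits` (distinct matching clones), `n_unique` (distinct clones).
#' @export
match_cmv_clones <- function(repertoire, cmv_list) {
  if (!nrow(repertoire)) stop("empty repertoire")
  need <- c("patient_id", "sample_id", "cdr3_aa", "v_gene", "j_gene")
  stopifnot(all(need %in% names(repertoire)),
            all(c("cdr3_aa", "v_gene", "j_gene") %in% names(cmv_list)))
  rep_u <- unique(repertoire[need])
  keys <- clone_key(rep_u)
  list_keys <- unique(clone_key(cmv_list))
  hit <- keys %in% list_keys
  agg <- stats::aggregate(cbind(n_hits = hit, n_unique = rep_len(1L, length(hit))),
                          by = list(sample_id = rep_u$sample_id,
                                    patient_id = rep_u$patient_id),
                          FUN = sum)
  agg <- agg[order(agg$sample_id), c("sample_id", "patient_id",
                                     "n_hits", "n_unique")]
  rownames(agg) <- NULL
  agg
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted half (computed via ranks).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = positive); both classes must occur.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the two-feature linear CMV serostatus classifier
#'
#' Replicates the repertoire serostatus model: the two features (number of
#' detected CMV-associated clones, total distinct clones) are standardized
#' and fed to a linear-kernel support vector machine. The regularization
#' strength is chosen from a logarithmic grid by mean cross-validated AUROC
#' over stratified folds (default 6), ties going to the stronger
#' regularization; the final model is refit on all data at the selected
#' value. The fitted decision function is oriented so larger scores mean
#' CMV-positive.
#'
#' @param features Data frame or matrix with columns `n_hits` and `n_unique`
#'   (exactly these two features).
#' @param labels Binary serostatus labels; both classes required.
#' @param folds Number of cross-validation folds, default 6; requires
#'   `n >= folds`.
#' @param cost_grid Regularization (cost) grid, default `10^(-3:3)`.
#' @param seed Seed for the stratified fold assignment (recorded in the
#'   model metadata).
#' @return Object of class `LinearCMVClassifier`: weights `w`, bias `b`,
#'   feature `center`/`scale`, selected `cost`, the per-cost CV table `cv`,
#'   per-fold AUROCs of the selected cost, `folds` and `seed`.
#' @export
train_cmv_classifier <- function(features, labels, folds = 6,
                                 cost_grid = 10^(-3:3), seed = 1L) {
  X <- as.matrix(as.data.frame(features)[c("n_hits", "n_unique")])
  if (ncol(X) != 2L) stop("exactly two features are required")
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both serostatus classes are required")
  if (nrow(X) < folds) stop("fewer observations than folds")
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(X, center = center, scale = scale_)

  set.seed(seed)
  fold_id <- integer(nrow(X))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }

  fit_svm <- function(x, yy, cost) {
    e1071::svm(x, factor(yy, levels = c(0, 1)), kernel = "linear",
               cost = cost, scale = FALSE)
  }
  decision <- function(model, x) {
    attr(stats::predict(model, x, decision.values = TRUE),
         "decision.values")[, 1]
  }
  cv_auc <- matrix(NA_real_, length(cost_grid), folds)
  for (ci in seq_along(cost_grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) next
      m <- fit_svm(xs[tr, , drop = FALSE], y[tr], cost_grid[ci])
      orient <- if (auroc(decision(m, xs[tr, , drop = FALSE]), y[tr]) < 0.5) -1 else 1
      cv_auc[ci, f] <- auroc(orient * decision(m, xs[!tr, , drop = FALSE]),
                             y[!tr])
    }
  }
  mean_auc <- rowMeans(cv_auc, na.rm = TRUE)
  best <- which(mean_auc == max(mean_auc))
  best <- best[which.min(cost_grid[best])]  # ties -> stronger regularization

  m <- fit_svm(xs, y, cost_grid[best])
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  if (auroc(drop(xs %*% w) + b, y) < 0.5) {
    w <- -w; b <- -b
  }
  structure(list(w = stats::setNames(w, colnames(X)), b = b,
                 center = center, scale = scale_, cost = cost_grid[best],
                 cv = data.frame(cost = cost_grid, mean_auroc = mean_auc),
                 fold_auroc = cv_auc[best, ], folds = folds, seed = seed),
            class = "LinearCMVClassifier")
}

#' @export
print.LinearCMVClassifier <- function(x, ...) {
  cat(sprintf(
    "LinearCMVClassifier: cost = %g (mean CV AUROC %.3f over %d folds)\n",
    x$cost, x$cv$mean_auroc[x$cv$cost == x$cost], x$folds))
  invisible(x)
}

#' Predict CMV serostatus per sample
#'
#' The continuous score is the linear decision value `w . x + b` on the
#' standardized features; the binary label is `score > 0` (a score of exactly
#' 0 is negative).
#'
#' @param classifier A [train_cmv_classifier()] model.
#' @param features Feature table as from [match_cmv_clones()] (columns
#'   `n_hits`, `n_unique`, optionally `sample_id`/`patient_id` which are
#'   carried through).
#' @return Data frame with `score` and binary `label` per sample.
#' @export
predict_cmv <- function(classifier, features) {
  stopifnot(inherits(classifier, "LinearCMVClassifier"))
  fdf <- as.data.frame(features)
  if (!all(c("n_hits", "n_unique") %in% names(fdf))) {
    stop("features must contain n_hits and n_unique")
  }
  X <- as.matrix(fdf[c("n_hits", "n_unique")])
  xs <- scale(X, center = classifier$center, scale = classifier$scale)
  score <- drop(xs %*% classifier$w) + classifier$b
  out <- data.frame(score = score, label = as.integer(score > 0))
  for (v in c("patient_id", "sample_id")) {
    if (v %in% names(fdf)) out[[v]] <- fdf[[v]]
  }
  out[c(intersect(c("sample_id", "patient_id"), names(out)),
        "score", "label")]
}

#' Patient-level CMV status from per-sample predictions
#'
#' A patient is called CMV-positive when any of their samples is predicted
#' positive.
#'
#' @param predictions Data frame with `patient_id` and binary `label` (e.g.
#'   from [predict_cmv()]); every patient must have at least one sample.
#' @return Data frame with `patient_id` and `cmv_positive`.
#' @export
patient_cmv_status <- function(predictions) {
  stopifnot(all(c("patient_id", "label") %in% names(predictions)))
  if (!nrow(predictions)) stop("no samples provided")
  agg <- stats::aggregate(list(cmv_positive = predictions$label),
                          by = list(patient_id = predictions$patient_id),
                          FUN = function(v) as.integer(any(v == 1)))
  agg[order(agg$patient_id), , drop = FALSE]
}
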