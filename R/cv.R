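# Run code with a locally set RNG state, restoring the caller's state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assign pairs to cross-validation folds
#'
#' @param labels Binary label per pair.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Keep the class ratio in every fold (default TRUE); fold
#'   sizes within each stratum differ by at most one.
#' @return Integer fold id (1..k) per pair.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  stopifnot(k >= 2L, n >= k)
  with_local_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

#' Cross-validate the full sequence-to-prediction pipeline
#'
#' For each fold: proteins appearing in training pairs are encoded (440-d raw
#' features), a PCA model is fitted on those training proteins only (unless
#' `global_pca`), all needed proteins are projected to `k_pca` dimensions,
#' training pair vectors form the WSRC dictionary, and held-out pairs are
#' classified. Metrics are computed per fold and averaged.
#'
#' @param proteins Data frame with columns `id`, `sequence`.
#' @param pairs Data frame with columns `id_a`, `id_b`, `label` (1/0).
#' @param folds Number of CV folds (default 5).
#' @param repeats Number of independent CV repetitions averaged together
#'   (default 1; 10 reproduces the common repeated-CV protocol).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param k_pca PCA target dimension per protein (default 30; pair vectors
#'   have twice this length).
#' @param L CT segment count (default 4).
#' @param config A [wsrc_config()].
#' @param global_pca Fit PCA on all proteins instead of training-fold
#'   proteins only (default FALSE; the default avoids information leakage).
#' @param scale_features Unit-variance feature scaling before PCA
#'   (default FALSE).
#' @param stratified Stratify folds by label (default TRUE).
#' @param symmetrize Add each training pair also in reversed orientation
#'   (default FALSE).
#' @return Object of class `metrics_report`: mean `sn`, `sp`, `acc`, `mcc`,
#'   `auc`, a `per_fold` data frame, `predictions` data frame, `n_folds`,
#'   `repeats`, `seed`.
#' @export
cross_validate <- function(proteins, pairs, folds = 5L, repeats = 1L,
                           seed = 1L, k_pca = 30L, L = 4L,
                           config = wsrc_config(), global_pca = FALSE,
                           scale_features = FALSE, stratified = TRUE,
                           symmetrize = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("id_a","id_b","label") %in% names(pairs)))
  unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), proteins$id)
  if (length(unknown) > 0L) {
    stop(sprintf("pairs reference unknown protein id(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  if (length(unique(pairs$label)) < 2L) {
    stop("both pair labels (1 and 0) must be present")
  }

  feats <- encode_proteins(proteins, L = L)  # label-free, safe to precompute
  per_fold <- list()
  predictions <- list()
  for (rep_i in seq_len(repeats)) {
    fold_id <- make_folds(pairs$label, k = folds,
                          seed = seed + 1000L * (rep_i - 1L),
                          stratified = stratified)
    for (f in seq_len(folds)) {
      train <- pairs[fold_id != f, , drop = FALSE]
      test <- pairs[fold_id == f, , drop = FALSE]
      if (symmetrize) {
        train <- rbind(train,
                       data.frame(id_a = train$id_b, id_b = train$id_a,
                                  label = train$label))
      }
      pca_ids <- if (global_pca) proteins$id else
        unique(c(train$id_a, train$id_b))
      kp <- min(k_pca, length(pca_ids) - 1L, ncol(feats))
      pca <- fit_pca(feats[pca_ids, , drop = FALSE], k = kp,
                     scale. = scale_features)
      proj <- project(pca, feats)

      Xtr <- t(cbind(proj[train$id_a, , drop = FALSE],
                     proj[train$id_b, , drop = FALSE]))
      dict <- wsrc_dictionary(Xtr, train$label)
      res <- lapply(seq_len(nrow(test)), function(i) {
        yq <- pair_vector(proj[test$id_a[i], ], proj[test$id_b[i], ])
        wsrc_classify(yq, dict, config)
      })
      pred <- vapply(res, `[[`, integer(1), "label")
      score <- vapply(res, `[[`, numeric(1), "score")
      tp <- sum(pred == 1L & test$label == 1L)
      fp <- sum(pred == 1L & test$label == 0L)
      tn <- sum(pred == 0L & test$label == 0L)
      fn <- sum(pred == 0L & test$label == 1L)
      m <- compute_metrics(tp, fp, tn, fn)
      auc <- if (length(unique(test$label)) == 2L) {
        roc_auc(score, test$label)
      } else NA_real_
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repeat_ = rep_i, fold = f, n = nrow(test),
        tp = tp, fp = fp, tn = tn, fn = fn,
        sn = m[["sn"]], sp = m[["sp"]], acc = m[["acc"]],
        mcc = m[["mcc"]], auc = auc)
      predictions[[length(predictions) + 1L]] <- data.frame(
        repeat_ = rep_i, fold = f, id_a = test$id_a, id_b = test$id_b,
        label = test$label, score = score, predicted = pred)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  predictions <- do.call(rbind, predictions)
  structure(list(
    sn = mean(per_fold$sn), sp = mean(per_fold$sp),
    acc = mean(per_fold$acc), mcc = mean(per_fold$mcc),
    auc = mean(per_fold$auc, na.rm = TRUE),
    per_fold = per_fold, predictions = predictions,
    n_folds = as.integer(folds), repeats = as.integer(repeats),
    seed = as.integer(seed)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (%d repeat%s, seed %d), %d pairs\n",
    x$n_folds, x$repeats, if (x$repeats > 1) "s" else "", x$seed,
    sum(x$per_fold$n) / x$repeats))
  cat(sprintf("  Sn  = %.4f\n  Sp  = %.4f\n  Acc = %.4f\n  Mcc = %.4f\n  AUC = %.4f\n",
              x$sn, x$sp, x$acc, x$mcc, x$auc))
  invisible(x)
}

#' Write a metrics report to JSON (+ predictions TSV)
#'
#' @param report A `metrics_report`.
#' @param json_path Output JSON path.
#' @param predictions_path Optional TSV path for per-pair predictions.
#' @export
write_metrics_report <- function(report, json_path, predictions_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(sn = report$sn, sp = report$sp, acc = report$acc,
              mcc = report$mcc, auc = report$auc,
              n_folds = report$n_folds, repeats = report$repeats,
              seed = report$seed, per_fold = report$per_fold)
  jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  if (!is.null(predictions_path)) {
    utils::write.table(report$predictions, predictions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
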