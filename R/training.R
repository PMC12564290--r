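# Transductive training and stratified cross-validation.

#' Train one fold of the transductive model
#'
#' The whole cohort enters every forward pass (all subjects sit in the
#' population graphs); the cross-entropy and both alignment losses are
#' computed on training-mask nodes only. A stratified slice of the training
#' mask (`train.val_frac`) is held out to monitor the total loss for early
#' stopping, which starts counting at epoch `train.es_start` with patience
#' `train.patience`; the best-checkpoint parameters are returned.
#'
#' @param data A `popconn_data` from [model_data()].
#' @param config A `popconn_config`.
#' @param train_idx,test_idx Disjoint subject index vectors.
#' @param seed Seed controlling initialisation, dropout and the validation
#'   split for this fold (default `config$seed`).
#' @return A `popconn_fit` with elements `params`, `history` (tibble of
#'   per-epoch loss components), `train_idx`, `val_idx`, `test_idx`,
#'   `config`.
#' @export
train_fold <- function(data, config, train_idx, test_idx, seed = config$seed) {
  if (!length(train_idx) || !length(test_idx)) abort("empty train or test mask")
  if (length(intersect(train_idx, test_idx))) abort("masks must be disjoint")
  y <- data$y

  # stratified early-stopping holdout carved out of the training mask
  n_val <- max(2L, ceiling(config$train$val_frac * length(train_idx)))
  take <- function(v, k) v[sample.int(length(v), min(k, length(v)))]
  val_idx <- with_stream(seed, 901, expr = {
    pos <- train_idx[y[train_idx] == 1]
    neg <- train_idx[y[train_idx] == 0]
    c(take(pos, max(1L, round(n_val * length(pos) / length(train_idx)))),
      take(neg, max(1L, round(n_val * length(neg) / length(train_idx)))))
  })
  inner_idx <- setdiff(train_idx, val_idx)

  params <- init_model_params(data, config, seed = seed)
  opt <- adam_new(params, lr = config$train$lr,
                  weight_decay = config$train$weight_decay)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- vector("list", config$train$epochs)

  for (epoch in seq_len(config$train$epochs)) {
    set.seed(derive_seed(seed, 1000, epoch))
    fw <- model_forward(params, data, config, training = TRUE)
    ls <- model_loss(fw, data, config, inner_idx)
    ag_backward(ls$total)
    grads <- lapply(fw$leaves, function(l) l$grad)
    st <- adam_step(opt, params, grads)
    opt <- st$opt; params <- st$params

    val_loss <- NA_real_
    if (epoch >= config$train$es_start || epoch == config$train$epochs) {
      fv <- model_forward(params, data, config, training = FALSE)
      val_loss <- model_loss(fv, data, config, val_idx)$total$value
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ls$total$value, lce = ls$lce, lvc = ls$lvc,
      lcl = ls$lcl, val_loss = val_loss
    )
    if (!is.finite(ls$total$value)) abort("non-finite training loss")
    if (epoch >= config$train$es_start && wait >= config$train$patience) break
  }

  final_params <- if (is.finite(best$loss)) best$params else params
  structure(
    list(params = final_params, history = dplyr::bind_rows(hist),
         train_idx = train_idx, val_idx = val_idx, test_idx = test_idx,
         best_epoch = best$epoch, config = config, atlases = data$atlases),
    class = "popconn_fit"
  )
}

#' @export
print.popconn_fit <- function(x, ...) {
  cat(sprintf("<popconn_fit> %d atlases, %d epochs run (best at %d), final loss %.4f\n",
              length(x$atlases), nrow(x$history), x$best_epoch,
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Predict class probabilities from a trained fold model
#'
#' Deterministic evaluation forward pass over all subjects in the graph.
#'
#' @param object A `popconn_fit`.
#' @param data The `popconn_data` it was trained on (or a perturbed copy).
#' @param ... Unused.
#' @return Tibble with `SUB_ID`, `prob_case`, `pred`.
#' @export
predict.popconn_fit <- function(object, data, ...) {
  pr <- model_probs(object$params, data, object$config)
  tibble::tibble(
    SUB_ID = data$phenotypes$SUB_ID,
    prob_case = pr[, "case"],
    pred = as.integer(pr[, "case"] >= 0.5)
  )
}

#' Stratified fold assignment
#'
#' @param y 0/1 label vector.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer fold label per subject; every fold contains both classes.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  if (length(y) < k) abort("fewer subjects than folds")
  fold <- integer(length(y))
  with_stream(seed, 701, expr = {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      if (length(idx) < k) {
        abort(sprintf("class %s has %d subjects < %d folds; use fewer folds",
                      cls, length(idx), k))
      }
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Classification metrics from probabilities
#'
#' Confusion counts at the given threshold, then accuracy, precision, recall
#' and F1 from the counts, plus the threshold-free AUC computed as the
#' Mann-Whitney rank statistic over positive-class probabilities. Zero
#' denominators (no predicted positives, or no positives) yield 0 with a
#' warning; a single-class truth vector yields `NA` AUC with a warning.
#'
#' @param y_true 0/1 labels.
#' @param y_prob Positive-class probabilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble: `TP`, `TN`, `FP`, `FN`, `ACC`, `PRE`, `RECALL`,
#'   `F1`, `AUC`.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) abort("length mismatch")
  if (any(y_prob < 0 | y_prob > 1)) abort("probabilities outside [0, 1]")
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  acc <- (tp + tn) / length(y_true)
  pre <- if (tp + fp == 0) { warn("no predicted positives: PRE = 0"); 0 } else tp / (tp + fp)
  rec <- if (tp + fn == 0) { warn("no positives: RECALL = 0"); 0 } else tp / (tp + fn)
  f1 <- if (pre + rec == 0) { warn("PRE + RECALL = 0: F1 = 0"); 0 } else 2 * pre * rec / (pre + rec)
  auc <- auc_rank(y_true, y_prob)
  tibble::tibble(TP = tp, TN = tn, FP = fp, FN = fn,
                 ACC = acc, PRE = pre, RECALL = rec, F1 = f1, AUC = auc)
}

auc_rank <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warn("single-class labels: AUC undefined")
    return(NA_real_)
  }
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation of the full model
#'
#' Seeded stratified folds; each fold trains transductively with
#' [train_fold()] and is evaluated on its held-out subjects.
#'
#' @param data A `popconn_data`.
#' @param config A `popconn_config`.
#' @param folds Fold count (default `config$train$folds`).
#' @param seed Master seed (default `config$seed`).
#' @param keep_fits Keep the per-fold models (needed for
#'   [region_importance()]).
#' @return A `popconn_cv` with `metrics` (per-fold tibble), `summary`
#'   (mean/sd per metric), `predictions`, `fold_assign`, `fits`, `config`.
#' @export
cross_validate <- function(data, config = default_config(), folds = NULL,
                           seed = NULL, keep_fits = TRUE) {
  folds <- folds %||% config$train$folds
  seed <- seed %||% config$seed
  y <- data$y
  fold_assign <- stratified_folds(y, folds, seed = seed)
  metrics <- list()
  preds <- list()
  fits <- list()
  for (f in seq_len(folds)) {
    test_idx <- which(fold_assign == f)
    train_idx <- which(fold_assign != f)
    fit <- train_fold(data, config, train_idx, test_idx,
                      seed = derive_seed(seed, 31, f))
    pr <- model_probs(fit$params, data, config)[test_idx, "case"]
    metrics[[f]] <- dplyr::mutate(compute_metrics(y[test_idx], pr), fold = f,
                                  .before = 1)
    preds[[f]] <- tibble::tibble(fold = f, idx = test_idx,
                                 SUB_ID = data$phenotypes$SUB_ID[test_idx],
                                 y = y[test_idx], prob_case = pr)
    fits[[f]] <- if (keep_fits) fit else NULL
  }
  metrics <- dplyr::bind_rows(metrics)
  long <- tidyr::pivot_longer(metrics, c("ACC", "PRE", "RECALL", "F1", "AUC"),
                              names_to = "metric")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  structure(
    list(metrics = metrics, summary = summary,
         predictions = dplyr::bind_rows(preds), fold_assign = fold_assign,
         fits = fits, config = config),
    class = "popconn_cv"
  )
}

#' @export
print.popconn_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<popconn_cv> %d folds\n", max(x$metrics$fold)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s %5.1f%% +/- %.1f\n", s$metric[i], 100 * s$mean[i],
                100 * s$sd[i]))
  }
  invisible(x)
}
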