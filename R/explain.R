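# Perturbation-driven region importance: mask one ROI in both model inputs
# of a trained single-atlas model and measure the accuracy drop.

#' Mask one region in a functional-connectivity matrix
#'
#' Zeroes row `i` and column `i` (including the diagonal entry), leaving all
#' other entries untouched. Masking keeps the dimensionality fixed so a
#' trained model's weights stay applicable; it is idempotent.
#'
#' @param S M x M matrix.
#' @param i 1-based region index.
#' @return Matrix of the same shape.
#' @export
mask_region_fc <- function(S, i) {
  if (!is.matrix(S)) abort("`S` must be a matrix")
  if (i < 1 || i > nrow(S)) abort(sprintf("region index %s out of range", i))
  S[i, ] <- 0
  S[, i] <- 0
  S
}

#' Mask one region in an upper-triangle feature vector
#'
#' Zeroes the `M - 1` positions corresponding to pairs containing region `i`
#' under the fixed row-major pair ordering of [upper_tri_vector()], so the
#' vector mask and the matrix mask address the same entries.
#'
#' @param U Feature vector of length M(M-1)/2.
#' @param i 1-based region index.
#' @param M Region count.
#' @return Masked copy of `U`.
#' @export
mask_region_ut <- function(U, i, M) {
  if (length(U) != M * (M - 1) / 2) {
    abort(sprintf("length(U) = %d inconsistent with M = %d", length(U), M))
  }
  if (i < 1 || i > M) abort(sprintf("region index %s out of range", i))
  others <- setdiff(seq_len(M), i)
  U[pair_index(rep(i, M - 1), others, M)] <- 0
  U
}

#' Perturbation-based region importance for a single-atlas model
#'
#' Computes the baseline accuracy `Acc*` of a trained single-atlas
#' cross-validated model on the union of its held-out folds, then for each
#' region `i` rebuilds both model inputs with region `i` masked (the FC rows
#' fed to the attention aggregator and the upper-triangle node features of
#' the population graph), re-evaluates the frozen fold models, and records
#' `dAcc_i = Acc* - Acc~_i`. Larger drops mark regions the classifier relies
#' on. Graph edges and weights are NOT rebuilt under perturbation by default
#' (only node features change), so structural and feature effects are not
#' conflated; `rebuild_graph = TRUE` switches that behaviour.
#'
#' @param cv A `popconn_cv` trained on a single atlas with `keep_fits =
#'   TRUE`.
#' @param data The `popconn_data` used for training.
#' @param rebuild_graph Recompute the population graph from masked features
#'   for each perturbation.
#' @return A `popconn_importance`: tibble with `roi`, `acc_masked`, `dAcc`,
#'   `rank`, plus attributes `baseline` and `atlas`.
#' @export
region_importance <- function(cv, data, rebuild_graph = FALSE) {
  if (!inherits(cv, "popconn_cv")) abort("`cv` must come from cross_validate()")
  if (length(data$atlases) != 1) {
    abort("multi-atlas data passed: region importance needs a single-atlas model")
  }
  if (!length(cv$fits) || is.null(cv$fits[[1]])) {
    abort("cross_validate() must be run with keep_fits = TRUE")
  }
  M <- ncol(data$tokens[[1]])
  N <- length(data$y)
  config <- cv$config

  pooled_acc <- function(tokens_override = NULL, X_override = NULL,
                         data_eval = data) {
    correct <- 0L; total <- 0L
    for (fit in cv$fits) {
      pr <- model_probs(fit$params, data_eval, config,
                        tokens_override = tokens_override,
                        X_override = X_override)[fit$test_idx, "case"]
      correct <- correct + sum((pr >= 0.5) == (data$y[fit$test_idx] == 1))
      total <- total + length(fit$test_idx)
    }
    correct / total
  }

  baseline <- pooled_acc()
  rows <- purrr::map_dfr(seq_len(M), function(i) {
    tok <- data$tokens[[1]]
    for (b in seq_len(N)) {
      blk <- (b - 1) * M + seq_len(M)
      tok[blk, ] <- mask_region_fc(tok[blk, ], i)
    }
    Xm <- data$graphs[[1]]$X
    masked_cols <- pair_index(rep(i, M - 1), setdiff(seq_len(M), i), M)
    Xm[, masked_cols] <- 0
    data_eval <- data
    if (rebuild_graph) {
      g <- config$graph
      data_eval$graphs[[1]] <- build_population_graph(
        Xm, data$phenotypes, theta1 = g$theta1, theta2 = g$theta2,
        phenotypes = g$phenotypes, seed = config$seed, embed_dim = g$embed_dim)
    }
    acc <- pooled_acc(tokens_override = list(tok), X_override = list(Xm),
                      data_eval = data_eval)
    tibble::tibble(roi = i, acc_masked = acc, dAcc = baseline - acc)
  })
  rows <- dplyr::mutate(
    dplyr::arrange(rows, dplyr::desc(.data$dAcc), .data$roi),
    rank = dplyr::row_number())
  rows <- dplyr::arrange(rows, .data$roi)
  structure(rows, baseline = baseline, atlas = data$atlases[[1]],
            class = c("popconn_importance", class(rows)))
}

#' Top-k regions by importance
#'
#' Descending accuracy drop with ties broken by region index (stable); `k`
#' larger than the region count is clipped with a warning.
#'
#' @param table A `popconn_importance`.
#' @param k Number of regions to keep (default 10).
#' @param labels Optional data frame with columns `index`, `name` mapping
#'   region indices to anatomical labels.
#' @return Tibble of the top regions in rank order.
#' @export
rank_regions <- function(table, k = 10, labels = NULL) {
  M <- nrow(table)
  if (k > M) {
    warn(sprintf("k = %d exceeds region count %d; clipped", k, M))
    k <- M
  }
  out <- dplyr::slice_head(dplyr::arrange(tibble::as_tibble(table),
                                          .data$rank), n = k)
  if (!is.null(labels)) {
    out <- dplyr::left_join(out,
                            dplyr::rename(labels, roi = "index"), by = "roi")
  }
  out
}
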