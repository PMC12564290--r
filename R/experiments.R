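# Experiment harnesses: module ablations and factorial hyperparameter grids,
# run at desk scale on synthetic cohorts.

ablation_variants <- function() {
  list(
    taa_only = function(cfg) {
      cfg$train$use_gcn <- FALSE
      cfg$loss$beta <- 0
      cfg
    },
    gcn_only = function(cfg) {
      cfg$train$use_taa <- FALSE
      cfg$loss$beta <- 0
      cfg
    },
    taa_gcn = function(cfg) {
      cfg$loss$beta <- 0    # graph contrastive learning off
      cfg
    },
    full = function(cfg) cfg
  )
}

#' Module ablation experiment
#'
#' Runs cross-validation for the four model variants -- local branch only,
#' global branch only, both branches without contrastive alignment, and the
#' full model -- over replicate seeds, reporting mean and sd of each metric.
#'
#' @param data A `popconn_data`.
#' @param config Base configuration.
#' @param seeds Replicate seeds.
#' @param folds Fold count per replicate.
#' @return Tibble with one row per variant x metric: `variant`, `metric`,
#'   `mean`, `sd`.
#' @export
run_ablation <- function(data, config = default_config(), seeds = 1:3,
                         folds = 5) {
  variants <- ablation_variants()
  purrr::map_dfr(names(variants), function(vn) {
    cfg <- validate_config(variants[[vn]](config))
    per_seed <- purrr::map_dfr(seeds, function(s) {
      cv <- cross_validate(data, cfg, folds = folds, seed = s,
                           keep_fits = FALSE)
      dplyr::mutate(cv$summary, seed = s)
    })
    out <- dplyr::summarise(
      dplyr::group_by(per_seed, .data$metric),
      mean = mean(.data$mean), sd = stats::sd(.data$mean), .groups = "drop")
    dplyr::mutate(out, variant = vn, .before = 1)
  })
}

#' Full-factorial hyperparameter grid
#'
#' Every cell reruns the identical cross-validation pipeline with only the
#' named factors changed (dotted config paths, e.g. `loss.alpha`), under the
#' same replicate seeds.
#'
#' @param data A `popconn_data`.
#' @param config Base configuration.
#' @param factors Named list of level vectors, names being dotted config
#'   paths.
#' @param seeds Replicate seeds per cell.
#' @param folds Fold count.
#' @return A `popconn_grid` tibble: one row per cell with factor columns and
#'   `ACC_mean`, `ACC_sd`, `AUC_mean`, `AUC_sd`, plus the cell's resolved
#'   config in the list-column `config`.
#' @export
run_grid <- function(data, config = default_config(), factors, seeds = 1,
                     folds = 5) {
  stopifnot(length(factors) >= 1)
  cells <- do.call(tidyr::expand_grid, factors)
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(r) {
    cfg <- config
    for (f in names(factors)) cfg <- config_set(cfg, f, cells[[f]][r])
    accs <- c(); aucs <- c()
    for (s in seeds) {
      cv <- cross_validate(data, cfg, folds = folds, seed = s,
                           keep_fits = FALSE)
      accs <- c(accs, cv$summary$mean[cv$summary$metric == "ACC"])
      aucs <- c(aucs, cv$summary$mean[cv$summary$metric == "AUC"])
    }
    dplyr::mutate(cells[r, ],
                  ACC_mean = mean(accs), ACC_sd = stats::sd(accs),
                  AUC_mean = mean(aucs), AUC_sd = stats::sd(aucs),
                  config = list(cfg))
  })
  structure(out, class = c("popconn_grid", class(out)))
}
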