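# Full model assembly: per-atlas local (TAA) and global (GCN) branches, the
# shared projection head, and the fused linear classifier, run transductively
# on the whole cohort with losses restricted to training nodes.

#' Assemble model-ready data from connectivity views
#'
#' Builds one population graph per atlas (score -> mask -> phenotype
#' embedding -> weights) and the per-subject ROI token tensors (FC rows) the
#' local branch consumes.
#'
#' @param views A `popconn_views` from [build_views()].
#' @param config A `popconn_config`; the `graph` section controls
#'   construction.
#' @return A `popconn_data` list: `graphs`, `tokens` (flattened `(N*M) x M`
#'   matrices), `idx` (attention index structures), `y`, `phenotypes`,
#'   `atlases`.
#' @export
model_data <- function(views, config = default_config()) {
  if (!inherits(views, "popconn_views")) abort("`views` must come from build_views()")
  ph <- views$phenotypes
  y <- ph$DX_GROUP
  if (!all(y %in% c(0, 1))) abort("DX_GROUP must be 0/1")
  g <- config$graph
  graphs <- lapply(views$views, function(v) {
    build_population_graph(v$X, ph, theta1 = g$theta1, theta2 = g$theta2,
                           phenotypes = g$phenotypes, seed = config$seed,
                           embed_dim = g$embed_dim)
  })
  tokens <- lapply(views$views, function(v) do.call(rbind, v$fc))
  idx <- lapply(views$views, function(v) attn_index(nrow(ph), v$M))
  structure(list(graphs = graphs, tokens = tokens, idx = idx, y = y,
                 phenotypes = ph, atlases = names(views$views)),
            class = "popconn_data")
}

pull_prefix <- function(leaves, prefix) {
  keep <- startsWith(names(leaves), prefix)
  setNames(leaves[keep], substring(names(leaves)[keep], nchar(prefix) + 1))
}

init_model_params <- function(data, config, seed = config$seed) {
  p <- list()
  k <- config$gcn$hidden
  for (a in seq_along(data$atlases)) {
    M <- ncol(data$tokens[[a]])
    if (config$train$use_taa) {
      taa <- taa_init(M, embed = config$taa$embed, n_layers = config$taa$layers,
                      heads = config$taa$heads, attn_hidden = config$taa$attn_hidden,
                      seed = derive_seed(seed, 11, a))
      names(taa) <- paste0("v", a, "_", names(taa))
      p <- c(p, taa)
    }
    if (config$train$use_gcn) {
      gcn <- gcn_init(ncol(data$graphs[[a]]$X), hidden = k,
                      n_layers = config$gcn$layers,
                      seed = derive_seed(seed, 13, a),
                      variant = config$gcn$variant, cheb_k = config$gcn$cheb_k)
      names(gcn) <- paste0("v", a, "_", names(gcn))
      p <- c(p, gcn)
    }
  }
  if (config$train$use_taa && config$train$use_gcn) {
    p <- c(p, proj_init(k, p = config$proj$dim, seed = derive_seed(seed, 17)))
  }
  branches <- config$train$use_taa + config$train$use_gcn
  in_dim <- branches * length(data$atlases) *
    ifelse(config$train$use_taa && !config$train$use_gcn, config$taa$embed, k)
  if (config$train$use_taa && config$train$use_gcn) {
    in_dim <- length(data$atlases) * (config$taa$embed + k)
  } else if (config$train$use_taa) {
    in_dim <- length(data$atlases) * config$taa$embed
  } else {
    in_dim <- length(data$atlases) * k
  }
  p$clf_W <- xavier(in_dim, 2, c(seed, 19))
  p$clf_b <- rep(0, 2)
  p
}

# One full forward pass. `training` draws dropout/edge-dropout from the
# caller's RNG state. Token/feature overrides support the perturbation
# analysis. Returns tape nodes.
model_forward <- function(values, data, config, training = FALSE,
                          tokens_override = NULL, X_override = NULL) {
  leaves <- lapply(values, ag_leaf)
  Gs <- vector("list", length(data$atlases))
  Ts <- vector("list", length(data$atlases))
  feats <- list()
  for (a in seq_along(data$atlases)) {
    va <- paste0("v", a, "_")
    if (config$train$use_taa) {
      tok <- tokens_override[[a]] %||% data$tokens[[a]]
      Ts[[a]] <- ag_taa_forward(tok, pull_prefix(leaves, va), data$idx[[a]],
                                config$taa$layers, config$taa$heads)
    }
    if (config$train$use_gcn) {
      X <- X_override[[a]] %||% data$graphs[[a]]$X
      Wd <- drop_edge(data$graphs[[a]]$W, config$gcn$edge_dropout,
                      training = training)
      Gs[[a]] <- ag_gcn_forward(X, norm_adjacency(Wd), pull_prefix(leaves, va),
                                config$gcn$layers, config$gcn$dropout, training,
                                variant = config$gcn$variant,
                                cheb_k = config$gcn$cheb_k)
    }
    feats[[length(feats) + 1]] <-
      if (!is.null(Gs[[a]]) && !is.null(Ts[[a]])) ag_cbind(Gs[[a]], Ts[[a]])
      else Gs[[a]] %||% Ts[[a]]
  }
  fused <- if (length(feats) == 1) feats[[1]] else do.call(ag_cbind, feats)
  logits <- ag_add(ag_matmul(fused, leaves$clf_W), leaves$clf_b)
  list(leaves = leaves, Gs = Gs, Ts = Ts, logits = logits)
}

model_loss <- function(fw, data, config, rows) {
  y <- data$y[rows]
  lce <- ag_ce_logits(ag_rows(fw$logits, rows), y)
  alpha <- config$loss$alpha
  beta <- config$loss$beta
  lvc <- if (alpha > 0) {
    ag_consistency_loss(fw$Gs, fw$Ts, rows = rows)
  } else {
    ag_new(0)
  }
  lcl <- NULL
  if (beta > 0 && config$train$use_taa && config$train$use_gcn) {
    Mp <- positive_mask(length(rows), config$loss$positive_mask, y = y)
    for (a in seq_along(data$atlases)) {
      phi_l <- ag_project(ag_rows(fw$Ts[[a]], rows), fw$leaves)
      phi_g <- ag_project(ag_rows(fw$Gs[[a]], rows), fw$leaves)
      term <- ag_contrastive_loss(phi_l, phi_g, Mp, config$loss$tau,
                                  config$loss$gamma)
      lcl <- if (is.null(lcl)) term else ag_add(lcl, term)
    }
    lcl <- ag_scale(lcl, 1 / length(data$atlases))
  } else {
    lcl <- ag_new(0)
  }
  total <- lce
  if (alpha > 0) total <- ag_add(total, ag_scale(lvc, alpha))
  if (beta > 0) total <- ag_add(total, ag_scale(lcl, beta))
  list(total = total, lce = lce$value, lvc = lvc$value, lcl = lcl$value)
}

# Eval-mode class probabilities for every subject (deterministic).
model_probs <- function(values, data, config, tokens_override = NULL,
                        X_override = NULL) {
  fw <- model_forward(values, data, config, training = FALSE,
                      tokens_override = tokens_override,
                      X_override = X_override)
  z <- fw$logits$value
  zmax <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - zmax); e2 <- exp(z[, 2] - zmax)
  cbind(control = e1 / (e1 + e2), case = e2 / (e1 + e2))
}

#' Fuse per-atlas embeddings and classify
#'
#' Concatenates `[G_v || T_v]` across atlases and applies a linear two-class
#' softmax classifier. Used standalone mainly for inspection; training fits
#' the classifier jointly with the encoders.
#'
#' @param views List per atlas of `list(G =, T =)` embedding matrices.
#' @param W,b Optional classifier parameters; fresh Xavier weights when
#'   omitted.
#' @param seed Initialisation seed.
#' @return N x 2 matrix of class probabilities (rows sum to 1).
#' @export
fuse_and_classify <- function(views, W = NULL, b = NULL, seed = 1) {
  mats <- lapply(views, function(v) {
    parts <- Filter(Negate(is.null), list(v$G, v$T))
    if (!length(parts)) abort("view supplies neither G nor T")
    do.call(cbind, parts)
  })
  nr <- vapply(mats, nrow, integer(1))
  if (length(unique(nr)) != 1) abort("view count mismatch: differing subject counts")
  fused <- do.call(cbind, mats)
  W <- W %||% xavier(ncol(fused), 2, c(seed, 19))
  b <- b %||% rep(0, 2)
  z <- sweep(fused %*% W, 2, b, `+`)
  zmax <- pmax(z[, 1], z[, 2])
  e <- exp(z - zmax)
  e / rowSums(e)
}
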