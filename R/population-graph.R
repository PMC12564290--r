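#' Phenotype similarity kernel
#'
#' Categorical phenotypes match by equality; quantitative phenotypes match
#' when the absolute difference is strictly below `theta2` (the boundary
#' `|p_i - p_j| == theta2` does NOT match).
#'
#' @param p_i,p_j Two phenotype values of the same type.
#' @param kind `"categorical"` or `"quantitative"`.
#' @param theta2 Positive window for quantitative matches (same units as the
#'   phenotype; default 2, i.e. years for age).
#' @return 0 or 1.
#' @export
phenotype_match <- function(p_i, p_j, kind = c("categorical", "quantitative"),
                            theta2 = 2) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.numeric(p_i) != is.numeric(p_j)) abort("mixed-type phenotype comparison")
    return(as.numeric(p_i == p_j))
  }
  if (!is.numeric(p_i) || !is.numeric(p_j)) abort("quantitative comparison on non-numeric values")
  theta2 <- check_number(theta2, "theta2", min = 0, strict_min = TRUE)
  as.numeric(abs(p_i - p_j) < theta2)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Imaging similarity between two subjects' connectivity features
#'
#' Cosine similarity between upper-triangle feature vectors; bounded,
#' symmetric and scale-free. A zero-norm vector yields similarity 0 with a
#' warning.
#'
#' @param u_i,u_j Equal-length finite numeric vectors.
#' @return Scalar in \[-1, 1\].
#' @export
imaging_similarity <- function(u_i, u_j) {
  if (length(u_i) != length(u_j)) abort("feature vectors differ in length")
  if (any(!is.finite(u_i)) || any(!is.finite(u_j))) abort("non-finite feature values")
  if (sum(u_i^2) == 0 || sum(u_j^2) == 0) {
    warn("zero-norm feature vector: imaging similarity set to 0")
    return(0)
  }
  cosine_sim(u_i, u_j)
}

# Split a phenotype data frame into the columns used for edge scoring, with
# inferred kinds (numeric -> quantitative, everything else -> categorical).
phenotype_kinds <- function(P, phenotypes) {
  missing_cols <- setdiff(phenotypes, names(P))
  if (length(missing_cols)) abort(sprintf("phenotype column `%s` not found", missing_cols[1]))
  vapply(phenotypes, function(cl) {
    if (is.numeric(P[[cl]])) "quantitative" else "categorical"
  }, character(1))
}

#' Edge score matrix of the fully connected population graph
#'
#' `A[i, j] = imaging_similarity(u_i, u_j) * sum_m phi(P_im, P_jm)` over the
#' chosen phenotype columns, with the categorical/quantitative kernel of
#' [phenotype_match()]. The raw (unnormalised) sum of kernels is used, and
#' the diagonal is 0.
#'
#' @param X N x d node feature matrix (rows align with `P`).
#' @param P Phenotype data frame.
#' @param theta2 Quantitative kernel window.
#' @param phenotypes Phenotype column names; default site + age, the
#'   recommended combination.
#' @return N x N symmetric score matrix.
#' @export
score_matrix <- function(X, P, theta2 = 2,
                         phenotypes = c("SITE_ID", "AGE_AT_SCAN")) {
  X <- check_matrix(X, "X")
  if (nrow(X) != nrow(P)) abort("`X` rows must align with `P` rows")
  if (length(phenotypes) == 0) abort("need at least one phenotype column (graph would be empty)")
  kinds <- phenotype_kinds(P, phenotypes)
  n <- nrow(X)

  # cosine similarity of all row pairs
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) warn("zero-norm feature row(s): imaging similarity 0 there")
  safe <- ifelse(norms == 0, 1, norms)
  sim <- tcrossprod(X / safe)
  sim[norms == 0, ] <- 0
  sim[, norms == 0] <- 0

  match_sum <- matrix(0, n, n)
  for (cl in phenotypes) {
    v <- P[[cl]]
    if (anyNA(v)) abort(sprintf("missing values in phenotype column `%s`", cl))
    if (kinds[[cl]] == "categorical") {
      match_sum <- match_sum + outer(v, v, `==`)
    } else {
      match_sum <- match_sum + (abs(outer(v, v, `-`)) <
                                  check_number(theta2, "theta2", min = 0, strict_min = TRUE))
    }
  }
  A <- sim * match_sum
  A <- (A + t(A)) / 2
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

#' Binarise the score matrix into the sparse edge mask
#'
#' `F[i, j] = 1` iff `A[i, j] >= theta1` (the threshold itself passes);
#' diagonal 0. Larger `theta1` gives a sparser graph.
#'
#' @param A Symmetric score matrix.
#' @param theta1 Sparsity threshold (default 0.61).
#' @return N x N binary matrix.
#' @export
binarize_scores <- function(A, theta1 = 0.61) {
  A <- check_matrix(A, "A")
  F_mask <- (A >= theta1) * 1
  diag(F_mask) <- 0
  F_mask
}

# Deterministic Xavier-style draw for the fixed phenotype-attention block.
fixed_mat <- function(nr, nc, seed_parts) {
  with_stream(seed_parts, expr = {
    matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  })
}

#' Attention-augmented phenotype embeddings
#'
#' Encodes each phenotype column as a token (one-hot categorical levels or
#' cohort z-scored quantitative values, each mapped through a fixed random
#' token embedding), runs one fixed-seed single-head self-attention block over
#' the tokens of each subject, and flattens the result to `embed_dim`. The
#' block is untrained and computed once: the population graph is static
#' before any model training, and the embedding is a deterministic function
#' of `(P, seed)`.
#'
#' @param P Phenotype data frame.
#' @param phenotypes Columns to embed.
#' @param embed_dim Output embedding dimension e (>= 1).
#' @param token_dim Per-token dimension of the attention block.
#' @param seed Integer seed fixing all random projections.
#' @param return_attention If TRUE, also return the token-attention weights.
#' @return N x `embed_dim` matrix (with attribute `attention` if requested).
#' @export
phenotype_embedding <- function(P, phenotypes = c("SITE_ID", "AGE_AT_SCAN"),
                                embed_dim = 16, token_dim = 8, seed = 1,
                                return_attention = FALSE) {
  embed_dim <- check_count(embed_dim, "embed_dim", min = 1)
  token_dim <- check_count(token_dim, "token_dim", min = 1)
  kinds <- phenotype_kinds(P, phenotypes)
  n <- nrow(P)
  nm <- length(phenotypes)

  # tokens[[m]]: N x token_dim
  tokens <- lapply(seq_along(phenotypes), function(m) {
    cl <- phenotypes[m]
    v <- P[[cl]]
    if (kinds[[cl]] == "categorical") {
      lev <- sort(unique(as.character(v)))
      E <- fixed_mat(length(lev), token_dim, c(seed, 11, m))
      E[match(as.character(v), lev), , drop = FALSE]
    } else {
      s <- stats::sd(v)
      z <- if (s > 0) (v - mean(v)) / s else v * 0
      outer(z, fixed_mat(1, token_dim, c(seed, 13, m))[1, ]) +
        matrix(fixed_mat(1, token_dim, c(seed, 17, m))[1, ], n, token_dim,
               byrow = TRUE)
    }
  })

  Wq <- fixed_mat(token_dim, token_dim, c(seed, 23))
  Wk <- fixed_mat(token_dim, token_dim, c(seed, 29))
  Wv <- fixed_mat(token_dim, token_dim, c(seed, 31))

  out <- matrix(0, n, nm * token_dim)
  attn_store <- if (return_attention) array(0, c(n, nm, nm)) else NULL
  for (i in seq_len(n)) {
    Tok <- do.call(rbind, lapply(tokens, function(tk) tk[i, ]))
    Q <- Tok %*% Wq; K <- Tok %*% Wk; V <- Tok %*% Wv
    scores <- Q %*% t(K) / sqrt(token_dim)
    Aw <- softmax_rows(scores)
    if (return_attention) attn_store[i, , ] <- Aw
    out[i, ] <- as.vector(t(Aw %*% V))
  }

  E <- if (embed_dim == ncol(out)) out else out %*% fixed_mat(ncol(out), embed_dim, c(seed, 37))
  if (return_attention) attr(E, "attention") <- attn_store
  E
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Phenotype-cosine edge weights on the masked graph
#'
#' `W[i, j] = (cos(E_i, E_j) + 1) / 2` where the mask `F` keeps the edge, 0
#' elsewhere; entries lie in \[0, 1\] and the diagonal is 0. Zero-norm
#' embedding rows produce weight 0 with a warning.
#'
#' @param E N x e phenotype embedding matrix.
#' @param F_mask N x N binary mask from [binarize_scores()].
#' @return N x N weighted adjacency.
#' @export
edge_weights <- function(E, F_mask) {
  E <- check_matrix(E, "E")
  if (nrow(E) != nrow(F_mask)) abort("`E` rows must align with `F_mask`")
  norms <- sqrt(rowSums(E^2))
  if (any(norms == 0)) warn("zero-norm phenotype embedding row(s): edge weight 0 there")
  safe <- ifelse(norms == 0, 1, norms)
  cw <- tcrossprod(E / safe)
  cw[norms == 0, ] <- -1
  cw[, norms == 0] <- -1
  W <- (cw + 1) / 2 * (F_mask != 0)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

#' Build one atlas's population graph
#'
#' Orchestrates [score_matrix()] -> [binarize_scores()] ->
#' [phenotype_embedding()] -> [edge_weights()]. Nodes are subjects, node
#' features are the stacked upper-triangle connectivity vectors, and self
#' loops are NOT included here (the graph convolution adds them).
#'
#' @param X N x d node feature matrix for one atlas (or a single view from
#'   [build_views()]).
#' @param P Phenotype data frame with rows aligned to `X`.
#' @param theta1 Edge-filtering threshold on the score matrix (default 0.61).
#' @param theta2 Quantitative phenotype window (default 2).
#' @param phenotypes Phenotype columns used both for scoring and for the
#'   edge-weight embedding.
#' @param seed Seed for the fixed phenotype-attention block.
#' @param embed_dim Phenotype embedding dimension.
#' @return A `popconn_graph` list with `A`, `F`, `W`, `X`, `theta1`,
#'   `theta2`, `phenotypes`.
#' @export
build_population_graph <- function(X, P, theta1 = 0.61, theta2 = 2,
                                   phenotypes = c("SITE_ID", "AGE_AT_SCAN"),
                                   seed = 1, embed_dim = 16) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  A <- score_matrix(X, P, theta2 = theta2, phenotypes = phenotypes)
  F_mask <- binarize_scores(A, theta1 = theta1)
  E <- phenotype_embedding(P, phenotypes = phenotypes, embed_dim = embed_dim,
                           seed = seed)
  W <- edge_weights(E, F_mask)
  structure(
    list(A = A, F = F_mask, W = W, X = X, theta1 = theta1, theta2 = theta2,
         phenotypes = phenotypes),
    class = "popconn_graph"
  )
}

#' @export
print.popconn_graph <- function(x, ...) {
  n <- nrow(x$W)
  ne <- sum(x$F[upper.tri(x$F)])
  cat(sprintf("<popconn_graph> %d subjects, %d edges (density %.3f), theta1=%s theta2=%s\n",
              n, ne, 2 * ne / (n * (n - 1)), format(x$theta1), format(x$theta2)))
  invisible(x)
}

#' Export a population graph as a tidy edge list
#'
#' @param graph A `popconn_graph`.
#' @param keep_all If TRUE include non-edges (F = 0) too.
#' @return Tibble with columns `i`, `j`, `score`, `edge`, `weight`.
#' @export
graph_edge_list <- function(graph, keep_all = FALSE) {
  n <- nrow(graph$A)
  idx <- which(upper.tri(graph$A), arr.ind = TRUE)
  out <- tibble::tibble(
    i = idx[, 1], j = idx[, 2],
    score = graph$A[idx], edge = as.integer(graph$F[idx]),
    weight = graph$W[idx]
  )
  if (!keep_all) out <- dplyr::filter(out, .data$edge == 1L)
  out
}
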