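# Alignment and prediction losses: cross-atlas consistency, local/global
# contrastive alignment, and cross-entropy, combined as
# L = Lce + alpha * Lvc + beta * Lcl.

l2_normalize_rows <- function(x, eps = 1e-12) {
  x / pmax(sqrt(rowSums(x^2)), eps)
}

#' Multi-atlas consistency loss
#'
#' Rewards agreement between the embeddings different atlas views assign to
#' the same subject. Embedding rows are L2-normalised (keeping the sigmoid
#' out of saturation regardless of embedding scale), and for every ordered
#' pair of distinct views the per-subject inner products of global and local
#' embeddings are scored through `-log sigmoid(.)`, averaged over subjects:
#' `Lvc = -sum_{(i,j), i != j} mean_n log sigmoid(<G_in, G_jn> + <T_in, T_jn>)`.
#' A single view yields 0 (no pairs).
#'
#' @param views List with one element per atlas, each `list(G =, T =)` of
#'   N x k embedding matrices (either may be NULL if that branch is absent).
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(views) {
  v <- length(views)
  if (v <= 1) return(0)
  Gs <- lapply(views, function(x) if (!is.null(x$G)) l2_normalize_rows(x$G))
  Ts <- lapply(views, function(x) if (!is.null(x$T)) l2_normalize_rows(x$T))
  total <- 0
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i == j) next
      ip <- 0
      if (!is.null(Gs[[i]])) ip <- ip + rowSums(Gs[[i]] * Gs[[j]])
      if (!is.null(Ts[[i]])) ip <- ip + rowSums(Ts[[i]] * Ts[[j]])
      total <- total - mean(ifelse(ip > 0, -log1p(exp(-ip)), ip - log1p(exp(ip))))
    }
  }
  total
}

ag_consistency_loss <- function(G_list, T_list, rows = NULL) {
  v <- max(length(G_list), length(T_list))
  if (v <= 1) return(ag_new(0))
  pick <- function(x) {
    if (is.null(x)) return(NULL)
    x <- ag_rownorm(if (is.null(rows)) x else ag_rows(x, rows))
    x
  }
  Gn <- lapply(seq_len(v), function(i) pick(G_list[[i]]))
  Tn <- lapply(seq_len(v), function(i) pick(T_list[[i]]))
  total <- NULL
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i == j) next
      ip <- NULL
      if (!is.null(Gn[[i]])) ip <- ag_rowdot(Gn[[i]], Gn[[j]])
      if (!is.null(Tn[[i]])) {
        tp <- ag_rowdot(Tn[[i]], Tn[[j]])
        ip <- if (is.null(ip)) tp else ag_add(ip, tp)
      }
      if (is.null(ip)) next
      term <- ag_scale(ag_mean(ag_logsigmoid(ip)), -1)
      total <- if (is.null(total)) term else ag_add(total, term)
    }
  }
  total %||% ag_new(0)
}

proj_init <- function(k, p = 32, seed = 1) {
  list(proj_W1 = xavier(k, p, c(seed, 301)), proj_b1 = rep(0, p),
       proj_W2 = xavier(p, p, c(seed, 302)), proj_b2 = rep(0, p))
}

ag_project <- function(z, leaves) {
  h <- ag_elu(ag_add(ag_matmul(z, leaves$proj_W1), leaves$proj_b1))
  ag_add(ag_matmul(h, leaves$proj_W2), leaves$proj_b2)
}

#' Shared non-linear projection head
#'
#' Two linear maps around an ELU activation; the SAME parameter set is
#' applied to local and global embeddings so both are mapped into one shared
#' latent space. Weights use Xavier initialisation.
#'
#' @param z N x k embedding matrix.
#' @param params Optional list (`proj_W1`, `proj_b1`, `proj_W2`, `proj_b2`);
#'   default a fresh seeded head.
#' @param dim Output dimension when initialising.
#' @param seed Initialisation seed.
#' @return N x `dim` matrix with the parameters attached as attribute
#'   `params` (pass them to the second call to share the head).
#' @export
project <- function(z, params = NULL, dim = 32, seed = 1) {
  z <- check_matrix(z, "z")
  params <- params %||% proj_init(ncol(z), p = dim, seed = seed)
  out <- ag_project(as_ag(z), lapply(params, as_ag))$value
  attr(out, "params") <- params
  out
}

#' Exponentiated cosine similarity matrix
#'
#' `sim(phi_i, phi_j) = exp(cos(phi_i, phi_j) / tau)`: cosine similarity
#' smoothed by the temperature `tau` and exponentiated, the normalised-
#' temperature form used by the contrastive loss. Entries lie in
#' `[exp(-1/tau), exp(1/tau)]`.
#'
#' @param phi_a,phi_b N x p matrices with nonzero rows.
#' @param tau Positive temperature (default 0.5).
#' @return N x N positive matrix, rows indexing `phi_a`.
#' @export
pairwise_similarity <- function(phi_a, phi_b, tau = 0.5) {
  phi_a <- check_matrix(phi_a, "phi_a"); phi_b <- check_matrix(phi_b, "phi_b")
  if (tau <= 0) abort("`tau` must be > 0")
  if (any(rowSums(phi_a^2) == 0) || any(rowSums(phi_b^2) == 0)) {
    abort("zero-norm projection row")
  }
  exp(tcrossprod(l2_normalize_rows(phi_a), l2_normalize_rows(phi_b)) / tau)
}

#' Local/global contrastive alignment loss
#'
#' The two directions of the masked normalised-temperature objective:
#' `L_lv = -mean_i log( sum_j sim(phi_i_lv, phi_j_gv) Mp_ij /
#' sum_j sim(phi_i_lv, phi_j_gv) )`, symmetrically for `L_gv`, combined as
#' `Lcl = gamma * L_lv + (1 - gamma) * L_gv`. The default positive mask is
#' the identity: the same subject's local and global projections are the
#' positive pair.
#'
#' @param phi_lv,phi_gv N x p projected local and global embeddings.
#' @param Mp Binary positive mask with at least one positive per row;
#'   default `diag(N)`.
#' @param tau Temperature (> 0).
#' @param gamma Balance between the two directions in \[0, 1\] (default 0.4).
#' @return Non-negative scalar.
#' @export
contrastive_loss <- function(phi_lv, phi_gv, Mp = NULL, tau = 0.5,
                             gamma = 0.4) {
  gamma <- check_number(gamma, "gamma", min = 0, max = 1)
  n <- nrow(phi_lv)
  Mp <- Mp %||% diag(n)
  bad <- which(rowSums(Mp) == 0)
  if (length(bad)) abort(sprintf("positive mask row %d has no positive", bad[1]))
  S_lg <- pairwise_similarity(phi_lv, phi_gv, tau)
  S_gl <- pairwise_similarity(phi_gv, phi_lv, tau)
  L_lv <- -mean(log(rowSums(S_lg * Mp) / rowSums(S_lg)))
  L_gv <- -mean(log(rowSums(S_gl * t(Mp)) / rowSums(S_gl)))
  gamma * L_lv + (1 - gamma) * L_gv
}

ag_contrastive_loss <- function(phi_l, phi_g, Mp, tau, gamma) {
  Cn <- ag_matmul(ag_rownorm(phi_l), ag_t(ag_rownorm(phi_g)))
  one_dir <- function(C, M) {
    S <- ag_exp(ag_scale(C, 1 / tau))
    num <- ag_rowsums(ag_mul(S, ag_new(M)))
    den <- ag_rowsums(S)
    ag_scale(ag_mean(ag_sub(ag_log(num), ag_log(den))), -1)
  }
  L_lv <- one_dir(Cn, Mp)
  L_gv <- one_dir(ag_t(Cn), t(Mp))
  ag_add(ag_scale(L_lv, gamma), ag_scale(L_gv, 1 - gamma))
}

#' Binary cross-entropy on predicted probabilities
#'
#' `Lce = -(1/N) sum_n [y log(yhat) + (1 - y) log(1 - yhat)]` with
#' predictions clipped to `[eps, 1 - eps]`, `eps = 1e-7`.
#'
#' @param y_hat Predicted positive-class probabilities in \[0, 1\].
#' @param y Labels in `{0, 1}`.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(y_hat, y) {
  if (length(y_hat) != length(y)) abort("`y_hat` and `y` differ in length")
  if (!all(y %in% c(0, 1))) abort("`y` must be 0/1")
  p <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Combine the loss components
#'
#' `L = Lce + alpha * Lvc + beta * Lcl` with the published defaults
#' `alpha = 0.1`, `beta = 0.01`.
#'
#' @param Lce,Lvc,Lcl Finite scalar components.
#' @param alpha Weight on the consistency term.
#' @param beta Weight on the contrastive term.
#' @return Scalar total loss.
#' @export
total_loss <- function(Lce, Lvc, Lcl, alpha = 0.1, beta = 0.01) {
  stopifnot(is.finite(Lce), is.finite(Lvc), is.finite(Lcl))
  Lce + alpha * Lvc + beta * Lcl
}

positive_mask <- function(n, kind = c("diagonal", "same_label"), y = NULL) {
  kind <- match.arg(kind)
  if (kind == "diagonal") return(diag(n))
  if (is.null(y)) abort("`same_label` mask needs labels")
  outer(y, y, `==`) * 1
}
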