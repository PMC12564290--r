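# Feature extractors: the target-aware attention aggregator (multi-head
# self-attention followed by node-centric attention aggregation over ROI
# tokens) producing local per-subject embeddings, and the population-graph
# convolution producing global embeddings.

check_token_tensor <- function(X) {
  if (length(dim(X)) != 3) abort("`X` must be a B x seq x D array")
  if (any(!is.finite(X))) abort("`X` contains non-finite values")
  if (dim(X)[2] < 2) abort("need seq >= 2 (a region must have a neighbor)")
  X
}

# Neighbor index structures for a B x seq token layout flattened to
# (B*seq) x D row-major by subject. Built once per shape.
attn_index <- function(B, seq) {
  n <- B * seq
  base <- rep((seq_len(B) - 1) * seq, each = seq)
  JIDX_full <- outer(base, seq_len(seq), `+`)          # n x seq, all tokens
  neigh <- matrix(0L, seq, seq - 1)                     # seq x (seq-1)
  for (i in seq_len(seq)) neigh[i, ] <- setdiff(seq_len(seq), i)
  JIDX_n <- matrix(0L, n, seq - 1)
  for (i in seq_len(seq)) {
    rows <- (seq_len(B) - 1) * seq + i
    JIDX_n[rows, ] <- outer((seq_len(B) - 1) * seq, neigh[i, ], `+`)
  }
  pool <- matrix(0, B, n)
  for (b in seq_len(B)) pool[b, (b - 1) * seq + seq_len(seq)] <- 1 / seq
  list(B = B, seq = seq, n = n,
       cidx = seq_len(n), JIDX_full = JIDX_full, JIDX_n = JIDX_n,
       ci_flat = rep(seq_len(n), each = seq - 1),
       j_flat = as.vector(t(JIDX_n)),
       pool = pool)
}

xavier <- function(nr, nc, seed_parts) {
  with_stream(seed_parts, expr = {
    matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  })
}

# Flatten a B x seq x D array to (B*seq) x D, subjects as contiguous blocks.
flatten_tokens <- function(X) {
  d <- dim(X)
  out <- matrix(0, d[1] * d[2], d[3])
  for (b in seq_len(d[1])) {
    out[(b - 1) * d[2] + seq_len(d[2]), ] <- X[b, , ]
  }
  out
}

unflatten_tokens <- function(M, B, seq) {
  X <- array(0, c(B, seq, ncol(M)))
  for (b in seq_len(B)) X[b, , ] <- M[(b - 1) * seq + seq_len(seq), ]
  X
}

# ---- multi-head self-attention ---------------------------------------------

#' Multi-head self-attention over ROI tokens
#'
#' Standard scaled dot-product self-attention applied along the region axis
#' of a `B x seq x D` token tensor, with no positional encoding (output is
#' equivariant to region permutation). With `n_heads = 1` and identity
#' projections this reduces to `softmax(X X' / sqrt(D)) X` per subject.
#'
#' @param X `B x seq x D` array of ROI tokens.
#' @param weights Optional list with `Wq`, `Wk`, `Wv` (D x D) and optional
#'   `Wo` (D x D); `NULL` uses identity projections.
#' @param n_heads Number of attention heads; must divide D.
#' @return A `B x seq x D` array.
#' @export
msa_layer <- function(X, weights = NULL, n_heads = 1) {
  X <- check_token_tensor(X)
  d <- dim(X)
  if (d[3] %% n_heads != 0) {
    abort(sprintf("feature dim %d is not divisible by n_heads = %d", d[3], n_heads))
  }
  idx <- attn_index(d[1], d[2])
  H <- flatten_tokens(X)
  out <- ag_msa(ag_new(H), weights, n_heads, idx)
  unflatten_tokens(out$value, d[1], d[2])
}

ag_msa <- function(H, weights, n_heads, idx) {
  D <- ncol(H$value)
  dk <- D / n_heads
  Q <- if (is.null(weights$Wq)) H else ag_matmul(H, as_ag(weights$Wq))
  K <- if (is.null(weights$Wk)) H else ag_matmul(H, as_ag(weights$Wk))
  V <- if (is.null(weights$Wv)) H else ag_matmul(H, as_ag(weights$Wv))
  heads <- lapply(seq_len(n_heads), function(h) {
    cols <- (h - 1) * dk + seq_len(dk)
    Qh <- if (n_heads == 1) Q else ag_cols(Q, cols)
    Kh <- if (n_heads == 1) K else ag_cols(K, cols)
    Vh <- if (n_heads == 1) V else ag_cols(V, cols)
    S <- ag_pair_scores(Qh, Kh, idx$cidx, idx$JIDX_full, 1 / sqrt(dk))
    A <- ag_softmax_rows(S)
    ag_attention_pool(A, Vh, idx$JIDX_full)
  })
  out <- if (n_heads == 1) heads[[1]] else do.call(ag_cbind, heads)
  if (!is.null(weights$Wo)) out <- ag_matmul(out, as_ag(weights$Wo)) else out
}

# ---- node-centric attention aggregation ------------------------------------

#' Create a shared node-centric attention scorer
#'
#' A two-layer perceptron applied to the concatenation `[h_i || h_j]` of a
#' center token and one neighbor token, producing a scalar score. The same
#' scorer is shared across all centers.
#'
#' @param D Token feature dimension.
#' @param hidden Hidden width of the perceptron.
#' @param seed Seed for the deterministic initialisation.
#' @return List with `W1` (2D x hidden), `b1`, `w2` (hidden x 1), `b2`.
#' @export
ncaa_scorer <- function(D, hidden = 16, seed = 1) {
  list(W1 = xavier(2 * D, hidden, c(seed, 41)),
       b1 = rep(0, hidden),
       w2 = xavier(hidden, 1, c(seed, 43)),
       b2 = 0)
}

#' Node-centric attention weights
#'
#' For each center region i of each subject, scores every other region j
#' through the shared scorer applied to `[h_i || h_j]` and normalises the
#' scores with a softmax over the `seq - 1` neighbors, so each row of the
#' result is a point on the probability simplex. Neighbors are ordered by
#' increasing region index with the center skipped.
#'
#' @param X `B x seq x D` token array.
#' @param scorer Scorer from [ncaa_scorer()]; default a seed-1 scorer.
#' @return `B x seq x (seq-1)` array of attention weights.
#' @export
ncaa_attention <- function(X, scorer = NULL) {
  X <- check_token_tensor(X)
  d <- dim(X)
  scorer <- scorer %||% ncaa_scorer(d[3])
  idx <- attn_index(d[1], d[2])
  A <- ag_ncaa_alpha(ag_new(flatten_tokens(X)), scorer_leaves(scorer), idx)
  out <- array(0, c(d[1], d[2], d[2] - 1))
  for (b in seq_len(d[1])) out[b, , ] <- A$value[(b - 1) * d[2] + seq_len(d[2]), ]
  out
}

scorer_leaves <- function(scorer) lapply(scorer, as_ag)

ag_ncaa_alpha <- function(H, sc, idx) {
  Hc <- ag_rows(H, idx$ci_flat)
  Hj <- ag_rows(H, idx$j_flat)
  Pf <- ag_cbind(Hc, Hj)
  h1 <- ag_relu(ag_add(ag_matmul(Pf, sc$W1), sc$b1))
  s <- ag_add(ag_matmul(h1, sc$w2), sc$b2)
  ag_softmax_rows(ag_reshape_rows(s, idx$n, idx$seq - 1))
}

#' Aggregate neighbors under node-centric attention weights
#'
#' `h~_i = h_i + sum_{j != i} alpha_ij h_j`: the attention-weighted neighbor
#' sum added to the center's own features, reassembled into the token tensor.
#'
#' @param X `B x seq x D` token array.
#' @param alpha `B x seq x (seq-1)` weights from [ncaa_attention()].
#' @return Updated `B x seq x D` array.
#' @export
ncaa_update <- function(X, alpha) {
  X <- check_token_tensor(X)
  d <- dim(X)
  if (!all(dim(alpha) == c(d[1], d[2], d[2] - 1))) {
    abort("`alpha` shape does not match `X`")
  }
  idx <- attn_index(d[1], d[2])
  Af <- matrix(0, idx$n, d[2] - 1)
  for (b in seq_len(d[1])) Af[(b - 1) * d[2] + seq_len(d[2]), ] <- alpha[b, , ]
  H <- ag_new(flatten_tokens(X))
  out <- ag_add(H, ag_attention_pool(ag_new(Af), H, idx$JIDX_n))
  unflatten_tokens(out$value, d[1], d[2])
}

# One NCAA layer on the flat token matrix, composed from tape ops. Used by
# the exported operators; training uses the fused compiled kernel below.
ag_ncaa_layer <- function(H, sc, idx) {
  A <- ag_ncaa_alpha(H, sc, idx)
  ag_add(H, ag_attention_pool(A, H, idx$JIDX_n))
}

# Fused NCAA layer as a single tape node over the compiled kernel.
ag_ncaa_layer_cpp <- function(H, W1, b1, w2, b2, B, seq) {
  H <- as_ag(H); W1 <- as_ag(W1); b1 <- as_ag(b1)
  w2 <- as_ag(w2); b2 <- as_ag(b2)
  D <- ncol(H$value)
  W1t <- W1$value[seq_len(D), , drop = FALSE]
  W1b <- W1$value[D + seq_len(D), , drop = FALSE]
  fwd <- ncaa_forward_cpp(H$value, W1t, W1b, as.numeric(b1$value),
                          as.numeric(w2$value), as.numeric(b2$value), B, seq)
  ag_new(fwd$out, list(H, W1, b1, w2, b2), function(g) {
    bk <- ncaa_backward_cpp(g, H$value, W1t, W1b, as.numeric(b1$value),
                            as.numeric(w2$value), fwd$alpha, B, seq)
    list(bk$dH, rbind(bk$dW1t, bk$dW1b), as.numeric(bk$db1),
         matrix(bk$dw2, ncol = 1), bk$db2)
  })
}

# Fused multi-head self-attention as a single tape node.
ag_msa_cpp <- function(H, Wq, Wk, Wv, Wo, heads, B, seq) {
  H <- as_ag(H); Wq <- as_ag(Wq); Wk <- as_ag(Wk)
  Wv <- as_ag(Wv); Wo <- as_ag(Wo)
  fwd <- msa_forward_cpp(H$value, Wq$value, Wk$value, Wv$value, Wo$value,
                         heads, B, seq)
  ag_new(fwd$out, list(H, Wq, Wk, Wv, Wo), function(g) {
    bk <- msa_backward_cpp(g, H$value, Wq$value, Wk$value, Wv$value, Wo$value,
                           fwd$Q, fwd$K, fwd$V, fwd$Acube, fwd$Oc,
                           heads, B, seq)
    list(bk$dH, bk$dWq, bk$dWk, bk$dWv, bk$dWo)
  })
}

# ---- target-aware attention aggregator -------------------------------------

taa_init <- function(D, embed = 32, n_layers = 3, heads = 2, attn_hidden = 16,
                     seed = 1) {
  p <- list(
    Wq = xavier(D, D, c(seed, 51)), Wk = xavier(D, D, c(seed, 52)),
    Wv = xavier(D, D, c(seed, 53)), Wo = xavier(D, D, c(seed, 54))
  )
  for (l in seq_len(n_layers)) {
    p[[paste0("ncaa", l, "_W1")]] <- xavier(2 * D, attn_hidden, c(seed, 60 + l))
    p[[paste0("ncaa", l, "_b1")]] <- rep(0, attn_hidden)
    p[[paste0("ncaa", l, "_w2")]] <- xavier(attn_hidden, 1, c(seed, 70 + l))
    p[[paste0("ncaa", l, "_b2")]] <- 0
  }
  p$Wl <- xavier(D, embed, c(seed, 81))
  p$bl <- rep(0, embed)
  p
}

ag_taa_forward <- function(tokens, leaves, idx, n_layers, n_heads) {
  H <- ag_msa_cpp(as_ag(tokens), leaves$Wq, leaves$Wk, leaves$Wv, leaves$Wo,
                  n_heads, idx$B, idx$seq)
  for (l in seq_len(n_layers)) {
    H <- ag_ncaa_layer_cpp(H,
                           leaves[[paste0("ncaa", l, "_W1")]],
                           leaves[[paste0("ncaa", l, "_b1")]],
                           leaves[[paste0("ncaa", l, "_w2")]],
                           leaves[[paste0("ncaa", l, "_b2")]],
                           idx$B, idx$seq)
  }
  G <- ag_matmul(ag_new(idx$pool), H)       # mean over ROI tokens
  ag_add(ag_matmul(G, leaves$Wl), leaves$bl)
}

#' Local embeddings from the target-aware attention aggregator
#'
#' Runs one multi-head self-attention block followed by `n_layers` (default
#' 3) node-centric attention aggregation layers over the per-subject ROI
#' token tensor, mean-pools over regions and maps linearly to the embedding
#' dimension. Tokens are the rows of each subject's functional-connectivity
#' matrix (the region's connectivity profile), so `D = seq = M`.
#'
#' @param X `B x seq x D` token array (e.g. stacked FC rows).
#' @param n_layers Number of NCAA layers (>= 1); default 3.
#' @param embed Output embedding dimension.
#' @param n_heads Attention heads for the MSA block (must divide D).
#' @param seed Seed for deterministic weight initialisation.
#' @param params Optional parameter list from a trained model.
#' @return `B x embed` embedding matrix.
#' @export
taa_forward <- function(X, n_layers = 3, embed = 32, n_heads = 2, seed = 1,
                        params = NULL) {
  X <- check_token_tensor(X)
  if (n_layers < 1) abort("`n_layers` must be >= 1")
  d <- dim(X)
  if (d[3] %% n_heads != 0) abort("`n_heads` must divide the token dimension")
  params <- params %||% taa_init(d[3], embed = embed, n_layers = n_layers,
                                 heads = n_heads, seed = seed)
  idx <- attn_index(d[1], d[2])
  out <- ag_taa_forward(flatten_tokens(X), lapply(params, as_ag), idx,
                        n_layers, n_heads)
  out$value
}

# ---- graph convolution ------------------------------------------------------

#' Randomly drop graph edges during training
#'
#' Each undirected edge is removed independently with probability `rate`,
#' zeroing both symmetric entries. In evaluation mode the adjacency is
#' returned untouched, preserving the graph for testing.
#'
#' @param W Symmetric weighted adjacency with zero diagonal.
#' @param rate Removal probability in \[0, 1).
#' @param training Logical; FALSE is a no-op.
#' @param seed Optional seed for a reproducible draw.
#' @return Adjacency of the same shape.
#' @export
drop_edge <- function(W, rate, training = TRUE, seed = NULL) {
  W <- check_matrix(W, "W")
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1)")
  if (!training || rate == 0) return(W)
  if (!is.null(seed)) set.seed(seed)
  up <- upper.tri(W)
  keep <- runif(sum(up)) >= rate
  Wd <- W
  Wd[up][!keep] <- 0
  Wd[lower.tri(Wd)] <- t(Wd)[lower.tri(Wd)]
  Wd
}

# Symmetric renormalised propagation operator D^-1/2 (W + I) D^-1/2.
norm_adjacency <- function(W) {
  At <- W + diag(nrow(W))
  d <- rowSums(At)
  ds <- 1 / sqrt(d)
  At * outer(ds, ds)
}

#' One graph-convolution layer with residual connection
#'
#' `H' = ReLU(D^-1/2 (W + I) D^-1/2 H Theta) + R(H)` where the self-loop is
#' added here (the population graph itself carries none), and the residual
#' `R` is the identity when input and output widths match, a linear
#' projection when a matrix is supplied, or absent when `residual = FALSE`.
#'
#' @param H N x k activation matrix.
#' @param W_adj Symmetric adjacency with zero diagonal.
#' @param Theta k x k' weight matrix.
#' @param residual `TRUE` (identity / projection), `FALSE` (none).
#' @param R Optional k x k' projection matrix for the residual when widths
#'   differ.
#' @return N x k' activation matrix.
#' @export
gcn_layer <- function(H, W_adj, Theta, residual = TRUE, R = NULL) {
  H <- check_matrix(H, "H")
  W_adj <- check_matrix(W_adj, "W_adj")
  L <- norm_adjacency(W_adj)
  out <- pmax(L %*% H %*% Theta, 0)
  if (isTRUE(residual)) {
    if (!is.null(R)) {
      out <- out + H %*% R
    } else if (ncol(H) == ncol(out)) {
      out <- out + H
    } else {
      abort("widths differ: supply a projection matrix `R` for the residual")
    }
  }
  out
}

gcn_init <- function(d_in, hidden = 32, n_layers = 2, seed = 1,
                     variant = "renorm", cheb_k = 2) {
  p <- list()
  din <- d_in
  for (l in seq_len(n_layers)) {
    if (variant == "chebyshev") {
      for (k in seq_len(cheb_k)) {
        p[[paste0("gcn", l, "_T", k)]] <- xavier(din, hidden, c(seed, 200 + 10 * l + k))
      }
    } else {
      p[[paste0("gcn", l, "_W")]] <- xavier(din, hidden, c(seed, 90 + l))
    }
    if (din != hidden) {
      p[[paste0("gcn", l, "_R")]] <- xavier(din, hidden, c(seed, 95 + l))
    }
    din <- hidden
  }
  p
}

ag_gcn_forward <- function(X, L, leaves, n_layers, dropout, training,
                           variant = "renorm", cheb_k = 2) {
  Lc <- ag_new(L)
  Ls <- if (variant == "chebyshev") ag_new(L - diag(nrow(L))) else NULL
  H <- as_ag(X)
  for (l in seq_len(n_layers)) {
    Hin <- ag_dropout(H, dropout, training)
    if (variant == "chebyshev") {
      # T_0(Lhat) = I, T_1(Lhat) = Lhat with Lhat the shifted operator
      acc <- ag_matmul(Hin, leaves[[paste0("gcn", l, "_T", 1)]])
      if (cheb_k >= 2) {
        Tk_prev <- Hin
        Tk <- ag_matmul(Ls, Hin)
        acc <- ag_add(acc, ag_matmul(Tk, leaves[[paste0("gcn", l, "_T", 2)]]))
        if (cheb_k >= 3) {
          for (k in 3:cheb_k) {
            Tk_new <- ag_sub(ag_scale(ag_matmul(Ls, Tk), 2), Tk_prev)
            Tk_prev <- Tk; Tk <- Tk_new
            acc <- ag_add(acc, ag_matmul(Tk, leaves[[paste0("gcn", l, "_T", k)]]))
          }
        }
      }
      conv <- ag_relu(acc)
    } else {
      conv <- ag_relu(ag_matmul(ag_matmul(Lc, Hin),
                                leaves[[paste0("gcn", l, "_W")]]))
    }
    Rw <- leaves[[paste0("gcn", l, "_R")]]
    H <- if (!is.null(Rw)) {
      ag_add(conv, ag_matmul(Hin, Rw))
    } else {
      ag_add(conv, Hin)
    }
  }
  H
}

#' Global embeddings from the population-graph convolution
#'
#' Applies edge dropout (training only), then `n_layers` residual
#' graph-convolution layers with feature dropout, starting from the stacked
#' upper-triangle connectivity features as `H(0)`.
#'
#' @param graph A `popconn_graph` (or a bare adjacency matrix, in which case
#'   `X` must be given).
#' @param X Optional node feature matrix overriding `graph$X`.
#' @param n_layers Number of layers (default 2).
#' @param hidden Hidden width (default 32).
#' @param dropout Feature dropout rate (default 0.2).
#' @param edge_dropout Edge removal rate during training (default 0.3).
#' @param training Logical; controls both dropouts.
#' @param seed Seed for initialisation (and the dropout draw when training).
#' @param params Optional trained parameter list.
#' @param variant `"renorm"` (default) or `"chebyshev"` polynomial
#'   convolution of order `cheb_k`.
#' @param cheb_k Chebyshev order when `variant = "chebyshev"`.
#' @return N x hidden embedding matrix.
#' @export
gcn_forward <- function(graph, X = NULL, n_layers = 2, hidden = 32,
                        dropout = 0.2, edge_dropout = 0.3, training = FALSE,
                        seed = 1, params = NULL, variant = "renorm",
                        cheb_k = 2) {
  W <- if (inherits(graph, "popconn_graph")) graph$W else check_matrix(graph, "graph")
  X <- X %||% graph$X
  X <- check_matrix(X, "X")
  params <- params %||% gcn_init(ncol(X), hidden = hidden, n_layers = n_layers,
                                 seed = seed, variant = variant, cheb_k = cheb_k)
  if (training) set.seed(derive_seed(seed, 7))
  Wd <- drop_edge(W, edge_dropout, training = training)
  L <- norm_adjacency(Wd)
  out <- ag_gcn_forward(X, L, lapply(params, as_ag), n_layers, dropout,
                        training, variant = variant, cheb_k = cheb_k)
  out$value
}
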