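# Minimal reverse-mode automatic differentiation on matrices.
#
# Nodes are environments holding a value, parent links and a backward
# closure. A forward pass builds the graph; ag_backward() topologically sorts
# it and accumulates gradients into leaves. Coarse-grained attention ops keep
# the node count per training step small so the R-level overhead stays
# negligible next to the BLAS calls.

ag_counter <- new.env(parent = emptyenv())
ag_counter$n <- 0L

ag_new <- function(value, parents = list(), backfn = NULL) {
  ag_counter$n <- ag_counter$n + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$id <- ag_counter$n
  class(e) <- "ag_node"
  e
}

is_ag <- function(x) inherits(x, "ag_node")

# Leaf with gradient tracking (a model parameter).
ag_leaf <- function(value) ag_new(value)

# Wrap constants on the fly.
ag_val <- function(x) if (is_ag(x)) x$value else x

as_ag <- function(x) if (is_ag(x)) x else ag_new(x)

#' @export
print.ag_node <- function(x, ...) {
  cat(sprintf("<ag_node #%d> %s\n", x$id,
              paste(dim(as.matrix(x$value)), collapse = "x")))
  invisible(x)
}

# ---- core ops ---------------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_new(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ag_t <- function(a) {
  a <- as_ag(a)
  ag_new(t(a$value), list(a), function(g) list(t(g)))
}

# Elementwise add; `b` may be a length-ncol bias vector broadcast over rows.
ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  if (is.matrix(av) && !is.matrix(bv) && length(bv) == ncol(av)) {
    val <- sweep(av, 2, bv, `+`)
    ag_new(val, list(a, b), function(g) list(g, colSums(g)))
  } else {
    ag_new(av + bv, list(a, b), function(g) list(g, g))
  }
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_new(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {
  a <- as_ag(a)
  ag_new(a$value * s, list(a), function(g) list(g * s))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  m <- a$value > 0
  ag_new(a$value * m, list(a), function(g) list(g * m))
}

ag_elu <- function(a) {
  a <- as_ag(a)
  x <- a$value
  v <- ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  ag_new(v, list(a), function(g) list(g * ifelse(x > 0, 1, v + 1)))
}

ag_exp <- function(a) {
  a <- as_ag(a)
  v <- exp(a$value)
  ag_new(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  a <- as_ag(a)
  x <- a$value
  ag_new(log(x), list(a), function(g) list(g / x))
}

# log(sigmoid(x)), numerically stable.
ag_logsigmoid <- function(a) {
  a <- as_ag(a)
  x <- a$value
  v <- ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
  ag_new(v, list(a), function(g) list(g * stats::plogis(-x)))
}

ag_mean <- function(a) {
  a <- as_ag(a)
  n <- length(a$value)
  ag_new(mean(a$value), list(a), function(g) {
    m <- a$value; m[] <- g / n; list(m)
  })
}

ag_sum <- function(a) {
  a <- as_ag(a)
  ag_new(sum(a$value), list(a), function(g) {
    m <- a$value; m[] <- g; list(m)
  })
}

ag_rowsums <- function(a) {
  a <- as_ag(a)
  av <- a$value
  ag_new(matrix(rowSums(av), ncol = 1), list(a), function(g) {
    list(matrix(g[, 1], nrow(av), ncol(av)))
  })
}

ag_softmax_rows <- function(a) {
  a <- as_ag(a)
  p <- softmax_rows(a$value)
  ag_new(p, list(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# Row-wise L2 normalisation with a floor to keep zero rows finite.
ag_rownorm <- function(a, eps = 1e-12) {
  a <- as_ag(a)
  x <- a$value
  n <- pmax(sqrt(rowSums(x^2)), eps)
  y <- x / n
  ag_new(y, list(a), function(g) {
    list(g / n - y * (rowSums(g * y) / n))
  })
}

ag_rows <- function(a, idx) {
  a <- as_ag(a)
  av <- a$value
  ag_new(av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    acc <- rowsum(g, idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ag_cols <- function(a, idx) {
  a <- as_ag(a)
  av <- a$value
  ag_new(av[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, idx] <- g
    list(out)
  })
}

ag_cbind <- function(...) {
  args <- lapply(list(...), as_ag)
  vals <- lapply(args, `[[`, "value")
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  ag_new(do.call(cbind, vals), args, function(g) {
    lapply(seq_along(args), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ag_rowdot <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_new(matrix(rowSums(av * bv), ncol = 1), list(a, b), function(g) {
    list(g[, 1] * bv, g[, 1] * av)
  })
}

# Reshape an (n*k) x 1 column to an n x k matrix, filling by row.
ag_reshape_rows <- function(a, nr, nc) {
  a <- as_ag(a)
  ag_new(matrix(a$value, nr, nc, byrow = TRUE), list(a), function(g) {
    list(matrix(as.vector(t(g)), ncol = 1))
  })
}

# Dropout as a constant Bernoulli mask drawn at call time (inverted scaling).
ag_dropout <- function(a, rate, training) {
  if (!training || rate <= 0) return(as_ag(a))
  a <- as_ag(a)
  mask <- (matrix(runif(length(a$value)), nrow(a$value)) >= rate) / (1 - rate)
  ag_mul(a, ag_new(mask))
}

# ---- coarse attention ops ---------------------------------------------------

# Scores S[g, s] = scale * <Q[cidx[g], ], K[JIDX[g, s], ]> for every neighbor
# slot s of every center g. cidx must be duplicate-free.
ag_pair_scores <- function(Q, K, cidx, JIDX, scale) {
  Q <- as_ag(Q); K <- as_ag(K)
  Qv <- Q$value; Kv <- K$value
  gs <- ncol(JIDX)
  Qc <- Qv[cidx, , drop = FALSE]
  S <- matrix(0, length(cidx), gs)
  for (s in seq_len(gs)) {
    S[, s] <- rowSums(Qc * Kv[JIDX[, s], , drop = FALSE]) * scale
  }
  ag_new(S, list(Q, K), function(g) {
    dQ <- matrix(0, nrow(Qv), ncol(Qv))
    dK <- matrix(0, nrow(Kv), ncol(Kv))
    dQc <- matrix(0, length(cidx), ncol(Qv))
    for (s in seq_len(gs)) {
      dQc <- dQc + g[, s] * Kv[JIDX[, s], , drop = FALSE] * scale
      acc <- rowsum(g[, s] * Qc * scale, JIDX[, s])
      rows <- as.integer(rownames(acc))
      dK[rows, ] <- dK[rows, ] + acc
    }
    dQ[cidx, ] <- dQc
    list(dQ, dK)
  })
}

# Weighted neighbor aggregation out[g, ] = sum_s alpha[g, s] * V[JIDX[g, s], ].
ag_attention_pool <- function(alpha, V, JIDX) {
  alpha <- as_ag(alpha); V <- as_ag(V)
  Av <- alpha$value; Vv <- V$value
  gs <- ncol(JIDX)
  out <- matrix(0, nrow(Av), ncol(Vv))
  for (s in seq_len(gs)) {
    out <- out + Av[, s] * Vv[JIDX[, s], , drop = FALSE]
  }
  ag_new(out, list(alpha, V), function(g) {
    dA <- matrix(0, nrow(Av), gs)
    dV <- matrix(0, nrow(Vv), ncol(Vv))
    for (s in seq_len(gs)) {
      dA[, s] <- rowSums(g * Vv[JIDX[, s], , drop = FALSE])
      acc <- rowsum(g * Av[, s], JIDX[, s])
      rows <- as.integer(rownames(acc))
      dV[rows, ] <- dV[rows, ] + acc
    }
    list(dA, dV)
  })
}

# Cross-entropy over two-class logits at the given rows, one stable node.
ag_ce_logits <- function(logits, y) {
  logits <- as_ag(logits)
  z <- logits$value
  n <- nrow(z)
  zmax <- pmax(z[, 1], z[, 2])
  lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
  picked <- ifelse(y == 1, z[, 2], z[, 1])
  val <- mean(lse - picked)
  ag_new(val, list(logits), function(g) {
    p <- exp(z - lse)
    oh <- cbind(1 - y, y)
    list(g * (p - oh) / n)
  })
}

# ---- backward ---------------------------------------------------------------

# Reverse-accumulate gradients from a scalar root. Returns invisibly; leaf
# gradients are read off the nodes' $grad fields.
ag_backward <- function(root) {
  order <- vector("list", 256)
  norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  for (k in seq_len(norder)) order[[k]]$grad <- NULL
  root$grad <- 1
  for (k in rev(seq_len(norder))) {
    node <- order[[k]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    grads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      gj <- grads[[j]]
      if (is.null(gj)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
  }
  invisible(root)
}

# ---- optimiser --------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = weight_decay,
       t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$wd > 0) g <- g + opt$wd * params[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
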