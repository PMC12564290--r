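# Alignment and prediction losses.

test_that("consistency loss vanishes for a single view and saturates when aligned", {
  G <- matrix(rnorm(8), 4, 2)
  expect_equal(consistency_loss(list(list(G = G, T = G))), 0)
  # identical, large-inner-product views push -log sigmoid toward 0
  views <- list(list(G = G, T = G), list(G = G, T = G))
  l <- consistency_loss(views)
  expect_gte(l, 0)
  expect_lt(l, 2 * -log(stats::plogis(2)) + 1e-9)  # normalised products <= 2
})

test_that("consistency loss matches a hand-evaluated two-view example", {
  G1 <- rbind(c(1, 0), c(0, 1)); T1 <- rbind(c(1, 1), c(1, -1))
  G2 <- rbind(c(1, 1), c(1, 0)); T2 <- rbind(c(0, 1), c(1, 1))
  l <- consistency_loss(list(list(G = G1, T = T1), list(G = G2, T = T2)))
  n <- function(v) v / sqrt(sum(v^2))
  ip <- function(a, b) sum(n(a) * n(b))
  per_subject <- c(ip(G1[1, ], G2[1, ]) + ip(T1[1, ], T2[1, ]),
                   ip(G1[2, ], G2[2, ]) + ip(T1[2, ], T2[2, ]))
  hand <- -2 * mean(log(stats::plogis(per_subject)))   # both ordered pairs
  expect_equal(l, hand, tolerance = 1e-10)
  # symmetric under swapping views
  l2 <- consistency_loss(list(list(G = G2, T = T2), list(G = G1, T = T1)))
  expect_equal(l, l2, tolerance = 1e-12)
})

test_that("the projection head shares parameters across both inputs", {
  z1 <- matrix(rnorm(12), 4, 3)
  z2 <- matrix(rnorm(12), 4, 3)
  p1 <- project(z1, dim = 5, seed = 3)
  p2 <- project(z2, params = attr(p1, "params"))
  expect_identical(attr(p1, "params"), attr(p2, "params"))
  expect_equal(ncol(p1), 5)
  # identity weights reduce the head to an elementwise ELU
  id <- list(proj_W1 = diag(3), proj_b1 = rep(0, 3),
             proj_W2 = diag(3), proj_b2 = rep(0, 3))
  out <- project(z1, params = id)
  expect_equal(unname(out[, ]), ifelse(z1 > 0, z1, exp(z1) - 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pairwise similarity is exp(cosine over temperature)", {
  phi <- rbind(c(1, 0), c(0, 2), c(1, 1))
  S <- pairwise_similarity(phi, phi, tau = 0.5)
  expect_equal(S[1, 1], exp(2))
  expect_equal(S[1, 2], exp(0))
  set.seed(6)
  a <- matrix(rnorm(6), 3, 2); b <- matrix(rnorm(6), 3, 2)
  S2 <- pairwise_similarity(a, b, tau = 0.7)
  for (i in 1:3) for (j in 1:3) {
    co <- sum(a[i, ] * b[j, ]) / (sqrt(sum(a[i, ]^2)) * sqrt(sum(b[j, ]^2)))
    expect_lt(abs(S2[i, j] - exp(co / 0.7)), 1e-12)
  }
  expect_error(pairwise_similarity(a, b, tau = 0), "tau")
  expect_error(pairwise_similarity(rbind(c(0, 0)), rbind(c(1, 1))), "zero-norm")
})

test_that("contrastive loss endpoints and the two-subject hand expansion hold", {
  set.seed(7)
  pl <- matrix(rnorm(8), 4, 2); pg <- matrix(rnorm(8), 4, 2)
  l1 <- contrastive_loss(pl, pg, gamma = 1)
  l0 <- contrastive_loss(pl, pg, gamma = 0)
  lm <- contrastive_loss(pl, pg, gamma = 0.4)
  expect_equal(lm, 0.4 * l1 + 0.6 * l0, tolerance = 1e-12)

  # N = 2, diagonal mask, fully expanded by hand
  pl2 <- rbind(c(1, 0), c(0, 1)); pg2 <- rbind(c(1, 1), c(-1, 1))
  tau <- 0.5
  s <- function(u, v) exp(sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))) / tau)
  Llv <- -0.5 * (log(s(pl2[1, ], pg2[1, ]) /
                       (s(pl2[1, ], pg2[1, ]) + s(pl2[1, ], pg2[2, ]))) +
                 log(s(pl2[2, ], pg2[2, ]) /
                       (s(pl2[2, ], pg2[1, ]) + s(pl2[2, ], pg2[2, ]))))
  Lgv <- -0.5 * (log(s(pg2[1, ], pl2[1, ]) /
                       (s(pg2[1, ], pl2[1, ]) + s(pg2[1, ], pl2[2, ]))) +
                 log(s(pg2[2, ], pl2[2, ]) /
                       (s(pg2[2, ], pl2[1, ]) + s(pg2[2, ], pl2[2, ]))))
  expect_equal(contrastive_loss(pl2, pg2, tau = tau, gamma = 0.4),
               0.4 * Llv + 0.6 * Lgv, tolerance = 1e-10)
  expect_error(contrastive_loss(pl2, pg2, Mp = matrix(0, 2, 2)), "row 1")
})

test_that("alignment is rewarded relative to permuted pairings", {
  better <- vapply(1:20, function(s) {
    set.seed(500 + s)
    phi <- matrix(rnorm(12 * 3), 12, 3)
    aligned <- contrastive_loss(phi, phi)
    perm <- sample(12)
    permuted <- contrastive_loss(phi, phi[perm, ])
    aligned < permuted
  }, logical(1))
  expect_true(all(better))
})

test_that("contrastive loss falls as the global view approaches the local view", {
  # statistically monotone along the interpolation path, averaged over seeds
  deltas <- vapply(1:20, function(s) {
    set.seed(600 + s)
    pl <- matrix(rnorm(10 * 3), 10, 3)
    pg <- matrix(rnorm(10 * 3), 10, 3)
    ls <- vapply(c(0, 0.5, 1), function(t) {
      contrastive_loss(pl, (1 - t) * pg + t * pl)
    }, numeric(1))
    ls[1] - ls[3]
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.9)
})

test_that("cross-entropy closed forms hold", {
  expect_equal(cross_entropy(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(cross_entropy(c(1, 0), c(1, 0)), 1e-6)
  yh <- c(0.9, 0.2, 0.7); y <- c(1, 0, 1)
  expect_equal(cross_entropy(yh, y),
               -mean(y * log(yh) + (1 - y) * log(1 - yh)), tolerance = 1e-12)
  expect_error(cross_entropy(c(0.5, 0.5), 1), "length")
})

test_that("the total loss is the stated weighted sum with published defaults", {
  expect_equal(total_loss(1, 2, 3, alpha = 0.5, beta = 0.1), 2.3)
  expect_equal(total_loss(1.7, 9, 9, alpha = 0, beta = 0), 1.7)
  cfg <- default_config()
  expect_equal(cfg$loss$alpha, 0.1)
  expect_equal(cfg$loss$beta, 0.01)
  expect_equal(total_loss(1, 1, 1), 1 + 0.1 + 0.01)
})

test_that("tape losses match the plain implementations and their gradients check", {
  set.seed(8)
  G1 <- matrix(rnorm(6), 3, 2); T1 <- matrix(rnorm(6), 3, 2)
  G2 <- matrix(rnorm(6), 3, 2); T2 <- matrix(rnorm(6), 3, 2)
  node <- popconn:::ag_consistency_loss(
    list(popconn:::ag_new(G1), popconn:::ag_new(G2)),
    list(popconn:::ag_new(T1), popconn:::ag_new(T2)))
  expect_equal(node$value,
               consistency_loss(list(list(G = G1, T = T1),
                                     list(G = G2, T = T2))),
               tolerance = 1e-10)
  pl <- matrix(rnorm(6), 3, 2); pg <- matrix(rnorm(6), 3, 2)
  cn <- popconn:::ag_contrastive_loss(popconn:::ag_new(pl),
                                      popconn:::ag_new(pg),
                                      diag(3), 0.5, 0.4)
  expect_equal(cn$value, contrastive_loss(pl, pg, tau = 0.5, gamma = 0.4),
               tolerance = 1e-10)

  # finite-difference gradient sanity on 3 x 2 toys
  for (target in c("consistency", "contrastive")) {
    leafA <- popconn:::ag_leaf(pl)
    root <- if (target == "consistency") {
      popconn:::ag_consistency_loss(list(leafA, popconn:::ag_new(G2)),
                                    list(popconn:::ag_new(T1),
                                         popconn:::ag_new(T2)))
    } else {
      popconn:::ag_contrastive_loss(leafA, popconn:::ag_new(pg),
                                    diag(3), 0.5, 0.4)
    }
    popconn:::ag_backward(root)
    an <- leafA$grad[2, 1]
    f <- function(v) {
      p2 <- pl; p2[2, 1] <- v
      if (target == "consistency") {
        consistency_loss(list(list(G = p2, T = T1), list(G = G2, T = T2)))
      } else {
        contrastive_loss(p2, pg, tau = 0.5, gamma = 0.4)
      }
    }
    num <- fd_grad(f, pl[2, 1])
    expect_lt(abs(an - num) / max(abs(num), 1e-8), 1e-4)
  }
})

test_that("positive masks have the two documented shapes", {
  expect_equal(popconn:::positive_mask(3, "diagonal"), diag(3))
  y <- c(1, 0, 1)
  M <- popconn:::positive_mask(3, "same_label", y = y)
  expect_equal(M[1, 3], 1)
  expect_equal(M[1, 2], 0)
})
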