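# Phenotype-scored population graph construction.

test_that("phenotype kernels follow the strict-inequality window", {
  expect_equal(phenotype_match("NYU", "NYU", "categorical"), 1)
  expect_equal(phenotype_match("NYU", "UM", "categorical"), 0)
  expect_equal(phenotype_match(14.9, 15.7, "quantitative", theta2 = 2), 1)
  # the boundary |diff| == theta2 does NOT match
  expect_equal(phenotype_match(10, 12, "quantitative", theta2 = 2), 0)
  expect_error(phenotype_match("NYU", 3, "categorical"), "mixed-type")
})

test_that("imaging similarity is cosine with a guarded zero-norm case", {
  u <- c(1, 2, -1, 0.5, 3, -2)
  expect_equal(imaging_similarity(u, u), 1)
  expect_equal(imaging_similarity(u, -u), -1)
  set.seed(5)
  a <- rnorm(6); b <- rnorm(6)
  expect_lt(abs(imaging_similarity(a, b) -
                  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))), 1e-12)
  expect_warning(z <- imaging_similarity(rep(0, 6), b), "zero-norm")
  expect_equal(z, 0)
})

test_that("score matrix multiplies imaging similarity by the kernel sum", {
  # cos((1,0), (0.8, 0.6)) = 0.8; both phenotypes match -> A = 1.6
  X <- rbind(c(1, 0), c(0.8, 0.6))
  P <- tibble::tibble(SITE_ID = c("NYU", "NYU"), AGE_AT_SCAN = c(14.9, 15.7))
  A <- score_matrix(X, P, theta2 = 2)
  expect_equal(A[1, 2], 1.6)
  expect_equal(diag(A), c(0, 0))
  # no phenotype match zeroes the score whatever the imaging similarity
  P2 <- tibble::tibble(SITE_ID = c("NYU", "UM"), AGE_AT_SCAN = c(10, 30))
  expect_equal(score_matrix(X, P2, theta2 = 2)[1, 2], 0)
  expect_error(score_matrix(X, P, phenotypes = character(0)), "at least one")
})

test_that("binarisation keeps the threshold itself and zeroes the diagonal", {
  A <- matrix(c(0, 0.61, 0.60, 0.61, 0, 0.8, 0.60, 0.8, 0), 3, 3)
  F_mask <- binarize_scores(A, theta1 = 0.61)
  expect_equal(F_mask[1, 2], 1)   # >= passes at equality
  expect_equal(F_mask[1, 3], 0)
  expect_equal(diag(F_mask), rep(0, 3))
  expect_true(all(binarize_scores(A, theta1 = 1) == 0))
})

test_that("phenotype embedding is deterministic and token attention is a simplex", {
  P <- tibble::tibble(SITE_ID = c("a", "b", "a", "c"),
                      AGE_AT_SCAN = c(10, 20, 10, 30))
  E1 <- phenotype_embedding(P, embed_dim = 12, seed = 5)
  E2 <- phenotype_embedding(P, embed_dim = 12, seed = 5)
  expect_identical(E1, E2)
  expect_equal(dim(E1), c(4, 12))
  # identical phenotype rows get identical embeddings
  expect_equal(E1[1, ], E1[3, ])
  Ea <- phenotype_embedding(P, embed_dim = 12, seed = 5,
                            return_attention = TRUE)
  at <- attr(Ea, "attention")
  expect_true(all(abs(apply(at, c(1, 2), sum) - 1) < 1e-12))
  expect_error(phenotype_embedding(P, embed_dim = 0), "embed_dim")
})

test_that("edge weights are phenotype cosines rescaled onto kept edges", {
  E <- rbind(c(1, 1), c(1, 1), c(-1, -1))
  F_mask <- matrix(1, 3, 3) - diag(3)
  W <- edge_weights(E, F_mask)
  expect_equal(W[1, 2], 1)       # identical embeddings
  expect_equal(W[1, 3], 0)       # antipodal embeddings
  F0 <- matrix(0, 3, 3)
  expect_true(all(edge_weights(E, F0) == 0))
})

test_that("assembled graphs satisfy the structural invariants", {
  spec <- tiny_spec(n = 12, m = 5, seed = 8)
  co <- generate_cohort(spec)
  views <- build_views(co)
  g <- build_population_graph(views$views$A, co$phenotypes)
  expect_symmetric(g$A); expect_symmetric(g$W)
  expect_true(all(g$F %in% 0:1))
  expect_true(all(g$W >= 0 & g$W <= 1))
  expect_true(all(g$W[g$F == 0] == 0))
  expect_equal(diag(g$F), rep(0, 12))
  expect_equal(diag(g$W), rep(0, 12))
})

test_that("two matching subjects above threshold give one weighted edge", {
  spec <- tiny_spec(n = 4, sites = 2, m = 5, seed = 13)
  co <- generate_cohort(spec)
  views <- build_views(co)
  ph <- co$phenotypes[1:2, ]
  ph$SITE_ID <- "SITE01"; ph$AGE_AT_SCAN <- c(15, 15.5)
  g <- build_population_graph(views$views$A$X[1:2, ], ph, theta1 = 0.1)
  expect_equal(g$F[1, 2], 1)
  expect_gt(g$W[1, 2], 0)
  expect_lte(g$W[1, 2], 1)
})

test_that("edge count shrinks with theta1 and grows with theta2", {
  spec <- tiny_spec(n = 24, sites = 3, m = 6, seed = 21)
  co <- generate_cohort(spec)
  views <- build_views(co)
  X <- views$views$A$X
  edges_at <- function(t1, t2) {
    g <- build_population_graph(X, co$phenotypes, theta1 = t1, theta2 = t2)
    sum(g$F) / 2
  }
  e1 <- vapply(c(0.2, 0.4, 0.61, 0.9, 1.3), edges_at, numeric(1), t2 = 2)
  expect_true(all(diff(e1) <= 0))
  e2 <- vapply(c(0.5, 1, 2, 5, 10), function(t2) edges_at(0.61, t2), numeric(1))
  expect_true(all(diff(e2) >= 0))
})

test_that("per-atlas graphs differ only through imaging similarity", {
  spec <- cohort_spec(n_subjects = 10, n_sites = 2,
                      atlas_sizes = c(A = 5, B = 8), n_timepoints = 30,
                      seed = 31)
  co <- generate_cohort(spec)
  views <- build_views(co)
  cfg <- default_config()
  d1 <- build_population_graph(views$views$A$X, co$phenotypes, theta1 = 0.9)
  d2 <- build_population_graph(views$views$B$X, co$phenotypes, theta1 = 0.9)
  # same phenotype factor: where both graphs keep an edge the weight agrees
  both <- d1$F == 1 & d2$F == 1
  expect_equal(d1$W[both], d2$W[both])
  expect_false(isTRUE(all.equal(d1$A, d2$A)))
})

test_that("vectorised construction matches the naive reference exactly", {
  for (s in 1:3) {
    spec <- cohort_spec(n_subjects = 8, n_sites = 2, atlas_sizes = c(A = 5),
                        n_timepoints = 25, seed = 100 + s)
    co <- generate_cohort(spec)
    views <- build_views(co)
    X <- views$views$A$X
    g <- build_population_graph(X, co$phenotypes, theta1 = 0.5, theta2 = 2,
                                seed = 9, embed_dim = 8)
    ref <- naive_population_graph(X, co$phenotypes, theta1 = 0.5, theta2 = 2,
                                  phenotypes = c("SITE_ID", "AGE_AT_SCAN"),
                                  seed = 9, embed_dim = 8)
    expect_equal(g$A, ref$A)
    expect_equal(g$F, ref$F)
    expect_equal(g$W, ref$W)
  }
})

test_that("graph edge lists are tidy and consistent with the mask", {
  spec <- tiny_spec(n = 10, m = 5, seed = 17)
  co <- generate_cohort(spec)
  views <- build_views(co)
  g <- build_population_graph(views$views$A, co$phenotypes)
  el <- graph_edge_list(g)
  expect_equal(nrow(el), sum(g$F) / 2)
  expect_true(all(el$weight > 0 | el$edge == 1))
})
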