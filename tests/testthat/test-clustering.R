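test_that("c = 1 gives the column-mean centroid with full membership", {
  X <- toy_matrix(20L, 5L, seed = 2L)
  fit <- fuzzy_cmeans(X, c = 1L, seed = 1L)
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(X)),
               tolerance = 1e-8)
  expect_true(all(fit$memberships == 1))
})

test_that("two well-separated clouds are recovered with crisp memberships", {
  set.seed(11)
  mu1 <- c(0, 0, 0, 0); mu2 <- c(10, 10, 10, 10)
  X <- rbind(matrix(rnorm(200, 0, 1), 50, 4) + rep(mu1, each = 50),
             matrix(rnorm(200, 0, 1), 50, 4) + rep(mu2, each = 50))
  dimnames(X) <- list(paste0("g", 1:100), paste0("S", 1:4))
  fit <- fuzzy_cmeans(X, c = 2L, m = 1.25, seed = 4L)
  # match centroids to cloud means computed directly from the data
  means <- rbind(colMeans(X[1:50, ]), colMeans(X[51:100, ]))
  ord <- order(fit$centroids[, 1])
  expect_lt(max(abs(fit$centroids[ord, ] - means)), 0.1)
  own <- pmax(fit$memberships[, 1], fit$memberships[, 2])
  expect_true(all(own > 0.99))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  X <- rbind(matrix(rnorm(90, 0, 0.5), 30, 3),
             matrix(rnorm(90, 5, 0.5), 30, 3),
             matrix(rnorm(90, -5, 0.5), 30, 3))
  dimnames(X) <- list(paste0("g", 1:90), paste0("S", 1:3))
  fit <- fuzzy_cmeans(X, c = 3L, m = 1.25, seed = 2L)
  ref <- e1071::cmeans(X, centers = 3, m = 1.25, iter.max = 500)
  # same partition up to label permutation
  perm <- apply(fit$centroids, 1, function(v)
    which.min(colSums((t(ref$centers) - v)^2)))
  expect_setequal(perm, 1:3)
  expect_lt(max(abs(fit$centroids - ref$centers[perm, ])), 0.05)
  mine <- perm[apply(fit$memberships, 1, which.max)]
  expect_equal(unname(mine), unname(ref$cluster))
})

test_that("membership invariants, coincidence rule and input checks hold", {
  X <- toy_matrix(30L, 6L, seed = 7L)
  fit <- fuzzy_cmeans(X, c = 5L, seed = 3L, verify_monotone = TRUE)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # a point exactly at a centroid gets membership 1 there
  Y <- rbind(X, exact = fit$centroids[2, ])
  D2 <- outer(rowSums(Y^2), rowSums(fit$centroids^2), "+") -
    2 * tcrossprod(Y, fit$centroids)
  u <- tempenrich:::.fcm_memberships(pmax(D2, 0), 2 / (1.25 - 1))
  expect_equal(unname(u[nrow(Y), ]), c(0, 1, 0, 0, 0))
  expect_error(fuzzy_cmeans(X, c = 31L, seed = 1L), "exceeds")
  expect_error(fuzzy_cmeans(X, c = 2L, m = 1, seed = 1L), "m must be > 1")
})

test_that("identical seeds reproduce the fit bit-for-bit", {
  X <- toy_matrix(40L, 7L, seed = 12L)
  f1 <- fuzzy_cmeans(X, c = 6L, seed = 99L)
  f2 <- fuzzy_cmeans(X, c = 6L, seed = 99L)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$memberships, f2$memberships)
})

test_that("hardening picks maximal membership with lowest-index ties", {
  fit <- structure(list(memberships = rbind(g1 = c(0.7, 0.3),
                                            g2 = c(0.5, 0.5),
                                            g3 = c(0.2, 0.8))),
                   class = "fuzzy_cmeans")
  a <- harden(fit)
  expect_identical(a, c(g1 = 1L, g2 = 1L, g3 = 2L))
})

test_that("collapsing merges by centroid correlation components", {
  S <- 7L
  base <- c(0, 0.2, 1, 5, 1, 0.2, 0)               # mid-series pulse
  late <- c(0, 0, 0.1, 0.2, 1, 5, 1)               # late pulse
  V <- rbind(A = base, B = base + 0.02 * seq_len(S), C = late)
  colnames(V) <- paste0("S", seq_len(S))
  X <- V[rep(1:3, each = 4), ]
  rownames(X) <- paste0("g", 1:12)
  X <- X + matrix(rnorm(length(X), 0, 1e-3), nrow(X))
  Z <- standardize_profiles(X)
  fit <- structure(list(centroids = V, memberships = NULL),
                   class = "fuzzy_cmeans")
  assign <- setNames(rep(1:3, each = 4), rownames(X))
  stopifnot(cor(V["A", ], V["B", ]) >= 0.95, cor(V["A", ], V["C", ]) < 0.95)
  ps <- collapse_profiles(fit, assign, Z, r_threshold = 0.95)
  expect_length(ps$profile_ids, 2L)             # A+B merged, C alone
  expect_setequal(ps$gene_sets[["C1"]], paste0("g", 1:8))
  # no correlations reach the threshold -> no merging
  ps2 <- collapse_profiles(fit, assign, Z, r_threshold = 1 + 1e-9)
  expect_length(ps2$profile_ids, 3L)
  # identical centroids merge at r = 1
  V2 <- rbind(A = base, B = base, C = late)
  colnames(V2) <- colnames(V)
  fit2 <- structure(list(centroids = V2, memberships = NULL),
                    class = "fuzzy_cmeans")
  ps3 <- collapse_profiles(fit2, assign, Z, r_threshold = 0.95)
  expect_length(ps3$profile_ids, 2L)
})

test_that("chained correlations merge transitively under single linkage", {
  # with standardized A and C at cor rho, B = (A + C)/2 has
  # cor(A, B) = cor(B, C) = sqrt((1 + rho)/2); rho = 0.85 gives 0.962
  S <- 9L
  t <- seq(-1, 1, length.out = S)
  zs <- function(v) (v - mean(v)) / sd(v)
  A <- zs(t)
  q <- zs(residuals(lm(t^2 ~ t)))                  # orthogonal direction
  rho <- 0.85
  C <- zs(rho * A + sqrt(1 - rho^2) * q)
  B <- (A + C) / 2
  V <- rbind(A = A, B = B, C = C)
  colnames(V) <- paste0("S", seq_len(S))
  rAB <- cor(A, B); rBC <- cor(B, C); rAC <- cor(A, C)
  expect_gte(rAB, 0.95); expect_gte(rBC, 0.95); expect_lt(rAC, 0.95)
  genes <- paste0("g", 1:9)
  X <- V[rep(1:3, each = 3), ] + matrix(rnorm(length(V) * 3, 0, 1e-3), 9)
  rownames(X) <- genes
  Z <- standardize_profiles(X)
  fit <- structure(list(centroids = V, memberships = NULL),
                   class = "fuzzy_cmeans")
  assign <- setNames(rep(1:3, each = 3), genes)
  single <- collapse_profiles(fit, assign, Z, r_threshold = 0.95)
  expect_length(single$profile_ids, 1L)
  complete <- collapse_profiles(fit, assign, Z, r_threshold = 0.95,
                                method = "complete")
  expect_gt(length(complete$profile_ids), 1L)
})

test_that("profile sets are disjoint, labelled by size, with provenance", {
  sim <- simulate_expression(G = 400L, S = 7L, noise_sd = 0.2, seed = 5L)
  z <- standardize_profiles(filter_expressed_variance(sim$matrix))
  fit <- fuzzy_cmeans(z, c = 10L, seed = 6L)
  assign <- harden(fit)
  ps <- collapse_profiles(fit, assign, z)
  genes <- unlist(ps$gene_sets, use.names = FALSE)
  expect_identical(anyDuplicated(genes), 0L)
  expect_identical(length(genes), ps$universe_size)
  expect_identical(ps$universe_size, length(assign))
  expect_true(all(diff(unname(ps$sizes)) <= 0))          # C1 largest
  expect_setequal(unname(ps$provenance), ps$profile_ids)
  expect_setequal(names(ps$provenance),
                  as.character(sort(unique(assign))))
  # empty clusters are dropped: profile count <= non-empty cluster count
  expect_lte(length(ps$profile_ids), length(unique(assign)))
  # collapse monotonicity in r
  counts <- vapply(c(1.01, 0.99, 0.95, 0.8, 0.5, -1),
                   function(r) length(collapse_profiles(fit, assign, z,
                                                        r)$profile_ids),
                   integer(1L))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], length(unique(assign)))
})

test_that("degenerate memberships: empty cluster drops from profiles", {
  # 3 clusters, hand-built memberships give cluster 2 no genes
  u <- rbind(g1 = c(0.8, 0.1, 0.1), g2 = c(0.7, 0.2, 0.1),
             g3 = c(0.1, 0.2, 0.7), g4 = c(0.05, 0.15, 0.8))
  V <- rbind(c(1, 0, -1), c(0, 1, 0), c(-1, 0, 1))
  colnames(V) <- paste0("S", 1:3)
  fit <- structure(list(centroids = V, memberships = u),
                   class = "fuzzy_cmeans")
  a <- harden(fit)
  expect_setequal(unique(a), c(1L, 3L))
  raw <- rbind(g1 = c(3, 2, 1), g2 = c(4, 2, 1),
               g3 = c(1, 2, 3), g4 = c(1, 2, 4))
  colnames(raw) <- paste0("S", 1:3)
  Z <- standardize_profiles(raw)
  ps <- collapse_profiles(fit, a, Z, r_threshold = 0.95)
  expect_length(ps$profile_ids, 2L)
})
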