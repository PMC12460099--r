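# Membership-function-value chain: PCA, component selection, scores,
# membership, weights, D value, Ward classification.

random_blue <- function(n, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * 4), n, 4)
  z[, 2] <- z[, 1] * 0.6 + z[, 2] * 0.8
  z[, 3] <- z[, 2] * 0.7 + z[, 3] * 0.5
  m <- 0.55 + 0.08 * z
  colnames(m) <- c("RPH", "RSFW", "RSDW", "RRDW")
  rownames(m) <- sprintf("ACC%03d", seq_len(n))
  m
}

test_that("correlation-matrix PCA has the expected spectral structure", {
  set.seed(10)
  # independent traits, large n: all eigenvalues near 1
  m <- matrix(rnorm(4000 * 4, 0.5, 0.1), 4000, 4,
              dimnames = list(NULL, c("RPH", "RSFW", "RSDW", "RRDW")))
  p <- run_pca(m)
  expect_true(all(abs(p$eigenvalues - 1) < 0.1))
  expect_true(all(abs(p$contribution - 25) < 2.5))
  # generic panel: eigenvalues descending, summing to the trait count,
  # contributions to 100
  b <- random_blue(60, 11)
  p2 <- run_pca(b)
  expect_true(all(diff(p2$eigenvalues) <= 1e-12))
  expect_equal(sum(p2$eigenvalues), 4, tolerance = 1e-10)
  expect_equal(sum(p2$contribution), 100, tolerance = 1e-10)
  # eigenvectors unit norm, largest-magnitude coefficient positive
  for (i in 1:4) {
    expect_equal(sum(p2$loadings[, i]^2), 1, tolerance = 1e-10)
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, i])), i], 0)
  }
  # reconstruction: V diag(lambda) V' recovers the correlation matrix
  rec <- p2$loadings %*% diag(p2$eigenvalues) %*% t(p2$loadings)
  expect_equal(rec, cor(b), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(run_pca(cbind(b[, 1:3], RRDW = rep(1, 60))), "RRDW")
})

test_that("component selection honors the cumulative threshold", {
  expect_equal(select_components(c(66.98, 88.94, 95.47, 100.00), 85), 2L)
  expect_equal(select_components(c(90, 95, 100), 85), 1L)
  expect_equal(select_components(c(40, 70, 90, 100), 100), 4L)
  b <- random_blue(50, 12)
  p <- run_pca(b)
  k <- select_components(p, 85)
  expect_gte(p$cumulative[k], 85)
  if (k > 1) expect_lt(p$cumulative[k - 1], 85)
})

test_that("comprehensive scores equal the explicit loop", {
  b <- random_blue(30, 13)
  p <- run_pca(b)
  F <- comprehensive_scores(p, 2)
  for (a in 1:5) for (i in 1:2)
    expect_equal(F[a, i], sum(p$loadings[, i] * p$x_std[a, ]),
                 tolerance = 1e-12)
  expect_error(comprehensive_scores(p, 9))
})

test_that("membership is min-max scaling with affine invariance", {
  F <- cbind(c(0, 5, 10), c(3, 1, 2))
  mu <- membership(F)
  expect_equal(mu[, 1], c(0, 0.5, 1))
  expect_equal(range(mu[, 2]), c(0, 1))
  # affine transform of a column leaves mu unchanged
  F2 <- F
  F2[, 1] <- 3.7 * F[, 1] - 12
  expect_equal(membership(F2), mu, tolerance = 1e-12)
  expect_error(membership(cbind(c(1, 1, 1))), "constant")
})

test_that("weights renormalize contribution rates of retained PCs", {
  W <- mfv_weights(c(66.98, 21.96))
  expect_equal(W, c(66.98, 21.96) / 88.94, tolerance = 1e-12)
  expect_equal(round(W, 4), c(0.7531, 0.2469))
  expect_equal(mfv_weights(42), 1)
  expect_equal(mfv_weights(c(10, 10, 10)), rep(1 / 3, 3))
  expect_equal(sum(W), 1)
  expect_error(mfv_weights(numeric(0)), "empty")
})

test_that("D value is the weighted membership sum, bounded in [0, 1]", {
  expect_equal(unname(d_value(rbind(c(1, 1)), c(0.6, 0.4))), 1)
  expect_equal(unname(d_value(rbind(c(1, 0)), c(0.75, 0.25))), 0.75)
  b <- random_blue(80, 14)
  m <- mfv_score(b)
  expect_true(all(m$D >= 0 & m$D <= 1))
  expect_true(any(m$mu == 0) && any(m$mu == 1))
})

test_that("D values equal the straight-line oracle and are deterministic", {
  for (seed in c(21, 22, 23)) {
    b <- random_blue(45, seed)
    m <- mfv_score(b)
    expect_equal(unname(m$D), mfv_oracle_d(b), tolerance = 1e-12)
    m2 <- mfv_score(b)
    expect_equal(m$D, m2$D, tolerance = 1e-12)
  }
})

test_that("D survives forced eigenvector sign flips", {
  b <- random_blue(40, 15)
  p <- run_pca(b)
  # flip every eigenvector, re-apply the sign convention, rebuild D
  flipped <- p
  flipped$loadings <- -p$loadings
  for (i in seq_len(ncol(flipped$loadings))) {
    top <- which.max(abs(flipped$loadings[, i]))
    if (flipped$loadings[top, i] < 0)
      flipped$loadings[, i] <- -flipped$loadings[, i]
  }
  expect_equal(flipped$loadings, p$loadings)
  k <- select_components(p, 85)
  D1 <- d_value(membership(comprehensive_scores(p, k)),
                mfv_weights(p$contribution[1:k]))
  D2 <- d_value(membership(comprehensive_scores(flipped, k)),
                mfv_weights(flipped$contribution[1:k]))
  expect_equal(D1, D2, tolerance = 1e-12)
})

test_that("raising one accession's traits never lowers its D under
           non-negative loadings", {
  # strongly positively correlated traits: one retained PC, all loadings
  # positive, so the monotonicity condition holds for every trait
  set.seed(16)
  shared <- rnorm(60)
  b <- 0.55 + 0.08 * (0.93 * shared +
                        0.37 * matrix(rnorm(60 * 4), 60, 4))
  dimnames(b) <- list(sprintf("ACC%03d", 1:60),
                      c("RPH", "RSFW", "RSDW", "RRDW"))
  m <- mfv_score(b)
  keep <- apply(m$pca$loadings[, seq_len(m$k), drop = FALSE] >= 0, 1, all)
  expect_true(any(keep))
  tr <- which(keep)[1]
  b2 <- b
  b2[7, tr] <- b2[7, tr] + 0.05
  # recompute with the original projection (fixed panel standardization)
  F2 <- comprehensive_scores(m$pca, m$k, blue = b2)
  rng <- apply(m$F, 2, range)
  mu2 <- sweep(sweep(F2, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], `/`)
  D2 <- d_value(mu2, m$W)
  expect_gte(D2[7], m$D[7] - 1e-12)
})

test_that("Ward classification matches the exhaustive oracle on tiny panels", {
  D <- c(0.9, 0.88, 0.5, 0.1, 0.12)
  names(D) <- paste0("A", 1:5)
  cl <- classify_tolerance(D, 2)
  expect_equal(canonical_partition(as.integer(cl$class)),
               canonical_partition(ward_oracle(D, 2)))
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    D <- setNames(runif(n), paste0("A", seq_len(n)))
    k <- sample(2:4, 1)
    cl <- classify_tolerance(D, k)
    expect_equal(canonical_partition(as.integer(cl$class[names(D)])),
                 canonical_partition(ward_oracle(D, k)))
  }
})

test_that("well-separated clumps classify exactly, labels ordered by mean D", {
  set.seed(18)
  centers <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  D <- unlist(lapply(centers, function(c0) c0 + runif(6, -0.02, 0.02)))
  names(D) <- sprintf("A%02d", seq_along(D))
  cl <- classify_tolerance(D, 5)
  expect_equal(as.integer(table(cl$class)), rep(6L, 5))
  expect_equal(as.character(cl$class[1:6]), rep("I", 6))
  expect_equal(as.character(cl$class[25:30]), rep("V", 6))
  expect_true(all(diff(cl$summary$mean_d) < 0))
  expect_equal(sum(cl$summary$n), 30L)
})
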