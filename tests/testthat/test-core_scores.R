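test_that("standardize centers, scales, and is idempotent", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 0, 5, 1))
  fm <- standardize(x)
  expect_equal(unname(colMeans(fm$values)), c(0, 0))
  expect_equal(unname(apply(fm$values, 2, sd)), c(1, 1))
  expect_equal(fm$feature_ids, c("a", "b"))
  expect_equal(standardize(fm$values)$values, fm$values, tolerance = 1e-12)
  # simple column: (1,2,3) -> (-1, 0, 1)
  expect_equal(unname(standardize(cbind(1:3, c(0, 1, 0)))$values[, 1]),
               c(-1, 0, 1))
})

test_that("standardize rejects bad input with informative errors", {
  expect_error(standardize(cbind(c(1, 1, 1), 1:3)), "zero variance")
  expect_error(standardize(cbind(cst = rep(2, 5), ok = rnorm(5))), "cst")
  xm <- cbind(1:5, rnorm(5)); xm[3, 2] <- NA
  expect_error(standardize(xm), "row 3, column 2")
  expect_error(standardize(matrix(rnorm(4), 2, 2)), "3 samples")
})

test_that("shrinkage intensity matches the loop oracle and breaks singularity", {
  for (seed in 1:3) {
    fm <- rand_fm(20, 6, seed)
    m <- shrink_correlation(fm)
    expect_equal(m$shrinkage_intensity,
                 oracle_shrinkage_intensity(fm$values), tolerance = 1e-10)
  }
  # duplicated column: off-diagonal shrunk below 1, still PD
  set.seed(4)
  z <- rnorm(30)
  m <- shrink_correlation(cbind(z, z + 0, rnorm(30)))
  expect_lt(m$R[1, 2], 1)
  expect_equal(m$R[1, 2], 1 - m$shrinkage_intensity, tolerance = 1e-10)
  expect_gt(min(m$eigenvalues), 0)
  # single feature
  m1 <- shrink_correlation(matrix(rnorm(10), 10, 1))
  expect_equal(m1$R, matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("shrunk correlation recovers a known compound-symmetry target", {
  # n = 200 draws from 5x5 CS(rho = 0.25); entries near shrunk target
  set.seed(11)
  reps <- replicate(20, {
    fm <- make_block_design(block_design_spec(n = 200, p = 5, n_blocks = 1,
                                              within_rho = 0.25))
    m <- shrink_correlation(fm)
    c(mean(m$R[upper.tri(m$R)]), m$shrinkage_intensity)
  })
  lam <- mean(reps[2, ])
  # E[R_offdiag] ~ (1 - lambda) * 0.25; SE of the mean of 20 x 10 entries
  expect_lt(abs(mean(reps[1, ]) - (1 - lam) * 0.25), 3 * 0.07 / sqrt(20 * 10))
})

test_that("eigendecomposition reconstructs the shrunk matrix", {
  fm <- rand_fm(25, 8, 5)
  m <- shrink_correlation(fm)
  expect_equal(m$eigenvectors %*% diag(m$eigenvalues) %*% t(m$eigenvectors),
               m$R, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 0))
  expect_equal(diag(m$R), rep(1, 8), ignore_attr = TRUE)
})

test_that("matrix_power identities hold", {
  fm <- rand_fm(30, 6, 7)
  m <- shrink_correlation(fm)
  expect_equal(matrix_power(m, 0), diag(6), tolerance = 1e-10)
  expect_equal(matrix_power(m, 1), m$R, tolerance = 1e-10,
               ignore_attr = TRUE)
  # composition over the exponent set
  for (a in c(-1, -0.5, 0, 0.5, 1)) for (b in c(-0.5, 0.5, 1)) {
    expect_equal(matrix_power(m, a) %*% matrix_power(m, b),
                 matrix_power(m, a + b), tolerance = 1e-8)
  }
})

test_that("2x2 compound-symmetry powers match the closed form", {
  # rho = 0.25, exponent -0.5: eigenvalues {1.25, 0.75}, so diagonal
  # (1.25^-0.5 + 0.75^-0.5)/2 and off-diagonal (1.25^-0.5 - 0.75^-0.5)/2
  cs <- oracle_cs2_power(0.25, -0.5)
  expect_equal(cs[1, 1], (1.25^-0.5 + 0.75^-0.5) / 2, tolerance = 1e-10)
  expect_equal(cs[1, 2], (1.25^-0.5 - 0.75^-0.5) / 2, tolerance = 1e-10)
  # build an exact CS(0.25) model via a constructed correlation model
  X <- matrix(c(1, -1, 0, 0.5, -0.5, 0, 1, 0, -1, 0), 5, 2)  # any 2-col design
  m <- shrink_correlation(standardize(X), lambda = 0)
  m$R <- matrix(c(1, 0.25, 0.25, 1), 2, 2)
  e <- eigen(m$R, symmetric = TRUE)
  m$eigenvalues <- e$values; m$eigenvectors <- e$vectors
  for (ex in c(-0.5, 0.5, -1, 2)) {
    expect_equal(matrix_power(m, ex), oracle_cs2_power(0.25, ex),
                 tolerance = 1e-8)
  }
})

test_that("marginal correlations behave as Pearson correlations", {
  fm <- rand_fm(40, 5, 9)
  y <- fm$values[, 3]
  r <- marginal_correlations(fm, y)
  expect_equal(unname(r[3]), 1, tolerance = 1e-12)
  expect_equal(unname(r), unname(cor(fm$values, y)[, 1]), tolerance = 1e-12)
  # orthogonal-in-sample feature has zero correlation
  y2 <- fm$values[, 1] - fm$values[, 2] *
    sum(fm$values[, 1] * fm$values[, 2]) / sum(fm$values[, 2]^2)
  expect_equal(unname(marginal_correlations(fm, y2)[2]), 0, tolerance = 1e-12)
  expect_error(marginal_correlations(fm, rep(1, 40)), "constant")
})

test_that("three-variable chain model ranks as expected at alpha 0 and 1", {
  # X1 ~ N(0,1); X2 = X1 + eps; X3 ~ N(0,1); Y = X2 + 0.5 X3.
  # Marginal ordering |r2| > |r1| > |r3|; at alpha = 1 the score of the
  # non-contributing X1 collapses towards zero.
  set.seed(123)
  n <- 1000
  x1 <- rnorm(n); x2 <- x1 + rnorm(n); x3 <- rnorm(n)
  y <- x2 + 0.5 * x3
  fm <- standardize(cbind(x1, x2, x3))
  s0 <- ecar_scores(fm, y, 0)$score
  expect_true(abs(s0[2]) > abs(s0[1]) && abs(s0[1]) > abs(s0[3]))
  s1 <- ecar_scores(fm, y, 1)$score
  expect_lt(abs(s1[1]), 0.1)
  expect_gt(abs(s1[2]), abs(s0[1]))
})

test_that("ecar_scores equivalences and invariants", {
  fm <- rand_fm(50, 12, 13)
  set.seed(14)
  y <- rnorm(50) + fm$values[, 1]
  # alpha = 0 equals marginal correlations exactly
  expect_equal(ecar_scores(fm, y, 0)$score,
               unname(marginal_correlations(fm, y)), tolerance = 1e-12)
  # alpha = 0.5 is the CAR score
  expect_identical(ecar_scores(fm, y, 0.5)$score, car_scores(fm, y)$score)
  # identity correlation model: scores identical for every alpha
  m <- shrink_correlation(fm)
  m$R <- diag(12); m$eigenvalues <- rep(1, 12); m$eigenvectors <- diag(12)
  for (a in c(0, 0.3, 1)) {
    expect_equal(ecar_scores(fm, y, a, model = m)$score,
                 unname(marginal_correlations(fm, y)), tolerance = 1e-12)
  }
  expect_error(ecar_scores(fm, y, 1.2), "alpha")
  expect_error(ecar_scores(fm, y[-1], 0.5), "length")
})

test_that("isolated feature in its own block is alpha-invariant", {
  fm <- rand_fm(30, 5, 15)
  set.seed(16)
  y <- rnorm(30)
  m <- shrink_correlation(fm)
  # construct exact block-diagonal R: feature 5 isolated
  R <- diag(5)
  R[1:4, 1:4] <- 0.4; diag(R) <- 1
  e <- eigen(R, symmetric = TRUE)
  m$R <- R; m$eigenvalues <- e$values; m$eigenvectors <- e$vectors
  s <- sapply(c(0, 0.25, 0.5, 1), function(a)
    ecar_scores(fm, y, a, model = m)$score[5])
  expect_equal(max(s) - min(s), 0, tolerance = 1e-10)
})

test_that("scores are scale-invariant and sign-flip equivariant", {
  set.seed(17)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  base <- ecar_scores(x, y, 0.7)
  # positive affine rescaling of columns and outcome
  x2 <- sweep(sweep(x, 2, runif(6, 0.5, 4), "*"), 2, rnorm(6), "+")
  expect_equal(ecar_scores(x2, 10 * y - 3, 0.7)$score, base$score,
               tolerance = 1e-10)
  # negating a feature negates its score, ranks unchanged
  x3 <- x; x3[, 2] <- -x3[, 2]
  flip <- ecar_scores(x3, y, 0.7)
  expect_equal(flip$score[2], -base$score[2], tolerance = 1e-10)
  expect_equal(flip$score[-2], base$score[-2], tolerance = 1e-10)
  expect_identical(flip$rank, base$rank)
})

test_that("sum of squared CAR scores equals OLS R-squared without shrinkage", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40; p <- 7
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) + x %*% runif(p, -1, 1)
    fm <- standardize(x)
    m <- shrink_correlation(fm, lambda = 0)
    w <- ecar_scores(fm, y, 0.5, model = m)$score
    r2 <- summary(lm(y ~ x))$r.squared
    expect_equal(sum(w^2), r2, tolerance = 1e-6)
  }
})

test_that("fast grid engine agrees with the dense reference path", {
  fm <- rand_fm(30, 50, 19)   # p > n exercises the null-space branch
  set.seed(20)
  y <- rnorm(30)
  alphas <- c(0, 0.15, 0.5, 1)
  expect_equal(ecar_score_grid(fm, y, alphas, engine = "fast"),
               ecar_score_grid(fm, y, alphas, engine = "dense"),
               tolerance = 1e-8)
  # and in the n > p regime with zero shrinkage
  fm2 <- rand_fm(60, 10, 21)
  set.seed(22); y2 <- rnorm(60)
  expect_equal(ecar_score_grid(fm2, y2, alphas, engine = "fast", lambda = 0),
               ecar_score_grid(fm2, y2, alphas, engine = "dense", lambda = 0),
               tolerance = 1e-8)
})

test_that("rank column is a deterministic permutation by |score|", {
  fm <- rand_fm(25, 9, 23)
  set.seed(24); y <- rnorm(25)
  t <- ecar_scores(fm, y, 0.4)
  expect_setequal(t$rank, 1:9)
  o <- order(t$rank)
  expect_true(all(diff(t$abs_score[o]) <= 1e-15))
})
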