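test_that("QTL counting rule reproduces the reference split exactly", {
  sch <- overlap_scheme(k_traits = 2, w_envs = 2, p = 0, q = 0.7, N = 1001)
  cnt <- overlap_counts(sch)
  expect_identical(cnt$u, 177L)
  expect_identical(cnt$s, 824L)
  expect_identical(cnt$per_trait, 1178L)
  asg <- assign_qtl(sch, 3000L)
  expect_identical(asg$n_qtl, 2356L)
  expect_identical(nrow(asg$X), 2356L)
  # 1,001 QTL per trait-environment: each column of X sums to N
  expect_true(all(colSums(asg$X) == 1001L))
  expect_identical(anyDuplicated(asg$loci), 0L)
})

test_that("overlap boundary cases: no sharing and complete sharing", {
  cnt0 <- overlap_counts(overlap_scheme(k_traits = 1, q = 0, N = 10))
  expect_identical(cnt0$u, 10L)
  expect_identical(cnt0$s, 0L)
  asg0 <- assign_qtl(overlap_scheme(k_traits = 1, q = 0, N = 10), 100L)
  expect_identical(asg0$n_qtl, 20L)
  cnt1 <- overlap_counts(overlap_scheme(k_traits = 2, q = 1, N = 10))
  expect_identical(cnt1$u, 0L)
  expect_identical(cnt1$s, 10L)
  asg1 <- assign_qtl(overlap_scheme(k_traits = 2, q = 1, N = 10), 100L)
  expect_identical(asg1$n_qtl, 20L)
  expect_error(assign_qtl(overlap_scheme(N = 1001), 100L), "host")
})

test_that("Cholesky-sampled effects reproduce the target correlations", {
  set.seed(314)
  w <- effect_covariance()
  # algebraic identity: the factorisation reconstructs w
  L <- chol(w)
  expect_equal(t(L) %*% L, w)
  cors_d <- cors_y <- numeric(20)
  for (i in 1:20) {
    v <- sample_effects(w, 2356)
    cors_d[i] <- cor(v[, "DA"], v[, "DB"])
    cors_y[i] <- cor(v[, "YA"], v[, "YB"])
  }
  expect_lt(abs(mean(cors_d) - 0.8), 0.03)
  expect_lt(abs(mean(cors_y) - 0.4), 0.04)
  # identity covariance: all pairwise correlations near zero
  v0 <- sample_effects(diag(4), 2356)
  cc <- cor(v0)
  expect_true(all(abs(cc[upper.tri(cc)]) < 3 / sqrt(2356) * 3))
})

test_that("non-positive-semi-definite covariance fails loudly", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_effects(bad, 10), "positive semi-definite")
  expect_error(sample_effects(diag(4), 1), ">= 2")
})

test_that("design-matrix masking is the elementwise product", {
  v <- matrix(c(0.5, 0.4, 1.2, -0.3), 1)
  X <- matrix(c(1L, 1L, 0L, 0L), 1)
  expect_equal(drop(mask_effects(v, X)), c(0.5, 0.4, 0, 0),
               ignore_attr = TRUE)
  set.seed(2)
  v6 <- matrix(rnorm(24), 6, 4)
  X6 <- matrix(rbinom(24, 1, 0.5), 6, 4)
  a <- mask_effects(v6, X6)
  for (i in 1:6) for (j in 1:4) {
    expect_identical(a[i, j], X6[i, j] * v6[i, j])
  }
  expect_equal(mask_effects(v6, matrix(1L, 6, 4)), v6, ignore_attr = TRUE)
  expect_error(mask_effects(v6, X), "shape")
})

test_that("major-QTL designation picks the largest effects deterministically", {
  # direct construction: one trait's QTL with known effect magnitudes
  X <- cbind(DA = rep(1L, 6), DB = rep(1L, 6),
             YA = rep(0L, 6), YB = rep(0L, 6))
  a <- cbind(c(5, 4, 3, 2, 1, 0.5), c(5, 4, 3, 2, 1, 0.5),
             rep(0, 6), rep(0, 6))
  expect_identical(designate_major(a, X, rep(1L, 6), n_major = 2L),
                   c(1L, 2L))
  # all-equal effects: ties broken by QTL index
  a_eq <- cbind(rep(1, 6), rep(1, 6), rep(0, 6), rep(0, 6))
  expect_identical(designate_major(a_eq, X, rep(1L, 6), n_major = 3L),
                   1:3)
  # random vector against a sort-based oracle
  set.seed(8)
  arch <- tiny_arch(tiny_map(200, 7), N = 21, n_major = 5)
  drows <- which(arch$trait == 1L)
  score <- rowSums(abs(arch$effects[drows, 1:2])) /
    rowSums(arch$X[drows, 1:2])
  oracle <- sort(drows[order(score, decreasing = TRUE)[1:5]])
  expect_identical(arch$major, oracle)
})

test_that("favourable orientation flips only signs, never rankings", {
  set.seed(12)
  map <- tiny_map(200, 7)
  arch <- tiny_arch(map, N = 21, n_major = 5)
  f <- tiny_founders(arch, map, n_existing = 40, n_external = 10)
  pop <- f$existing
  g_fav <- breeding_values(pop, arch, favourable_coding = TRUE)
  g_raw <- breeding_values(pop, arch, favourable_coding = FALSE)
  # the two codings differ by a per-column constant only
  for (j in 1:4) {
    d <- g_fav[, j] - g_raw[, j]
    expect_lt(diff(range(d)), 1e-10)
  }
  expect_identical(order(g_fav[, 1]), order(g_raw[, 1]))
  # a positive effect means allele 1 is favourable, negative allele 0
  a <- cbind(c(0.3, -0.3), c(0.3, -0.3), 0, 0)
  X <- cbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  expect_identical(orient_favourable(a, X, c(1L, 1L)), c(1L, 0L))
})

test_that("major-QTL rescaling hits the target variance fraction", {
  set.seed(77)
  map <- tiny_map(300, 7)
  arch <- tiny_arch(map, N = 51, n_major = 10)
  f <- tiny_founders(arch, map, n_existing = 400, n_external = 80)
  ref <- reference_pool(f, arch, pct = 0.20, n_parents = 400)
  scaled <- scale_major(arch, ref, target_frac = 0.10)
  expect_lt(abs(major_variance_fraction(scaled, ref) - 0.10), 0.01)
  # scaling constant from the closed-form quadratic equals bisection
  a_bar <- rowMeans(arch$effects[, 1:2])
  drows <- which(arch$trait == 1L)
  minor <- setdiff(drows, arch$major)
  Z <- dosage(ref, arch$loci)
  g1 <- drop(Z[, arch$major] %*% a_bar[arch$major])
  g0 <- drop(Z[, minor] %*% a_bar[minor])
  frac <- function(cc) var(cc * g1) / var(cc * g1 + g0)
  lo <- 1e-6; hi <- 1e3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (frac(mid) < 0.10) lo <- mid else hi <- mid
  }
  expect_lt(abs(scaled$scaling_c - (lo + hi) / 2), 1e-6)
  # idempotence: rescaling an already-scaled architecture is a no-op
  twice <- scale_major(scaled, ref, target_frac = 0.10)
  expect_lt(abs(twice$scaling_c - 1), 1e-8)
  expect_equal(twice$effects, scaled$effects, tolerance = 1e-10)
  # disease-effect vector has standard deviation 1 after rescaling
  act <- scaled$X[drows, 1:2] == 1L
  expect_equal(sd(scaled$effects[drows, 1:2][act]), 1, tolerance = 1e-12)
})

test_that("fixed-point of scaling: target equal to current fraction gives c = 1", {
  set.seed(78)
  map <- tiny_map(300, 7)
  arch <- tiny_arch(map, N = 51, n_major = 10)
  f <- tiny_founders(arch, map, n_existing = 200, n_external = 40)
  ref <- reference_pool(f, arch, pct = 0.20, n_parents = 100)
  cur <- major_variance_fraction(arch, ref)
  scaled <- scale_major(arch, ref, target_frac = cur)
  expect_lt(abs(scaled$scaling_c - 1), 1e-8)
})

test_that("architecture serialisation round-trips", {
  set.seed(3)
  arch <- tiny_arch(tiny_map(200, 7), N = 21, n_major = 5)
  path <- file.path(withr::local_tempdir(), "arch.json")
  write_architecture(arch, path)
  back <- read_architecture(path)
  expect_equal(back$effects, arch$effects)
  expect_identical(back$loci, arch$loci)
  expect_identical(back$major, arch$major)
  expect_identical(back$favourable, arch$favourable)
  expect_equal(back$v, arch$v)
})
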