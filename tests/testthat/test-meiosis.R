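no_mut <- meiosis_params(lambda = 1, mu = 0)

test_that("without recombination or mutation a gamete is one parental haplotype", {
  set.seed(1)
  map <- tiny_map(70, 7)
  h1 <- matrix(0L, 1, 70)
  h2 <- matrix(1L, 1, 70)
  pop <- population(h1, h2)
  p0 <- meiosis_params(lambda = 0, mu = 0)
  for (r in 1:10) {
    g <- sample_gamete(pop, 1, map, p0)
    # per chromosome, the gamete is entirely one haplotype
    for (c in 1:7) {
      expect_true(all(g[map$chr == c] == g[map$chr == c][1]))
    }
  }
})

test_that("no allele creation: every gamete allele is parental", {
  set.seed(2)
  map <- tiny_map(70, 7)
  h1 <- matrix(rbinom(70, 1, 0.5), 1, 70)
  h2 <- matrix(rbinom(70, 1, 0.5), 1, 70)
  pop <- population(h1, h2)
  for (r in 1:20) {
    g <- sample_gamete(pop, 1, map, no_mut)
    expect_true(all(g == h1[1, ] | g == h2[1, ]))
  }
})

test_that("observable haplotype switches reflect a Poisson(1) crossover count", {
  set.seed(3)
  # one 400-locus chromosome with opposite-allele parents: each switch
  # between adjacent loci reveals an odd number of crossovers in the
  # interval; with 400 dense intervals the expected visible switch count
  # is 1 - O(1/400) per gamete
  L <- 400
  map <- make_locus_map(L, 1, 1e6)
  n <- 40000
  h1 <- matrix(0L, n, L)
  h2 <- matrix(1L, n, L)
  pop <- population(h1, h2)
  gam <- gsintro:::gamete_batch(pop$hap1, pop$hap2, map, no_mut)
  switches <- rowSums(gam[, -1] != gam[, -L])
  expect_lt(abs(mean(switches) - 1), 0.02)
  # dispersion consistent with Poisson: variance close to the mean
  expect_lt(abs(var(switches) / mean(switches) - 1), 0.1)
})

test_that("mutation flips alleles at the configured rate", {
  set.seed(4)
  L <- 1000
  map <- make_locus_map(L, 1, 1e6)
  n <- 20000
  h <- matrix(0L, n, L)
  pop <- population(h, h)
  gam <- gsintro:::gamete_batch(pop$hap1, pop$hap2, map,
                                meiosis_params(lambda = 0, mu = 0.001))
  flips <- rowSums(gam)
  expect_lt(abs(mean(flips) - 1), 0.03)  # mu * L = 1 expected flip
})

test_that("crossing homozygous inbreds gives heterozygous F1 exactly where parents differ", {
  set.seed(5)
  map <- tiny_map(70, 7)
  a <- matrix(rbinom(70, 1, 0.5), 1, 70)
  b <- matrix(rbinom(70, 1, 0.5), 1, 70)
  pop <- bind_pops(population(a, a, id = "A"), population(b, b, id = "B"))
  f1 <- cross(pop, 1, 2, n_progeny = 10, map, no_mut)
  expect_equal(n_ind(f1), 10)
  expect_true(all(f1$family == 1L))
  het <- f1$hap1 != f1$hap2
  differs <- a[1, ] != b[1, ]
  for (i in 1:10) expect_identical(unname(het[i, ]), unname(differs))
})

test_that("F1 allele frequency equals the parental mean in expectation", {
  set.seed(6)
  map <- tiny_map(70, 7)
  a <- matrix(rbinom(70, 1, 0.5), 1, 70)
  b <- matrix(rbinom(70, 1, 0.5), 1, 70)
  pop <- bind_pops(population(a, a), population(b, b))
  f1 <- cross(pop, rep(1, 500), rep(2, 500), n_progeny = 1, map, no_mut)
  freq <- colMeans(dosage(f1)) / 2
  parental <- (a[1, ] + b[1, ]) / 2
  expect_identical(unname(freq), unname(parental))
})

test_that("selfing a homozygous line reproduces it; a heterozygote segregates 1:2:1", {
  set.seed(7)
  map <- tiny_map(70, 7)
  h <- matrix(rbinom(70, 1, 0.5), 1, 70)
  pop <- population(h, h)
  kids <- self_progeny(pop, 5, map, no_mut)
  expect_equal(n_ind(kids), 5)
  for (i in 1:5) {
    expect_identical(unname(kids$hap1[i, ]), unname(h[1, ]))
    expect_identical(unname(kids$hap2[i, ]), unname(h[1, ]))
  }
  # single-locus heterozygote
  map1 <- make_locus_map(1, 1, 1e6)
  hetp <- population(matrix(0L, 1, 1), matrix(1L, 1, 1))
  kids2 <- self_progeny(hetp, 4000, map1, no_mut)
  counts <- table(factor(dosage(kids2), levels = 0:2))
  props <- counts / 4000
  expect_lt(abs(props[["0"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  expect_lt(abs(props[["1"]] - 0.50), 3 * sqrt(0.5 * 0.5 / 4000))
  expect_lt(abs(props[["2"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("single seed descent halves heterozygosity per generation", {
  set.seed(8)
  map <- tiny_map(70, 7)
  n <- 2000
  h1 <- matrix(0L, n, 70)
  h2 <- matrix(1L, n, 70)
  pop <- population(h1, h2)  # fully heterozygous F1-like cohort
  expect_identical(single_seed_descent(pop, 0, map, no_mut), pop)
  adv <- single_seed_descent(pop, 2, map, no_mut)
  expect_equal(n_ind(adv), n)
  H <- mean(heterozygosity(adv))
  expect_lt(abs(H - 0.25), 0.02)  # H0 = 1, two selfing steps -> 1/4
})

test_that("meiosis is deterministic under a fixed seed", {
  map <- tiny_map(70, 7)
  h <- matrix(rbinom(140, 1, 0.5), 2, 70)
  pop <- population(h, 1L - h)
  set.seed(123)
  g1 <- cross(pop, 1, 2, 5, map, meiosis_params())
  set.seed(123)
  g2 <- cross(pop, 1, 2, 5, map, meiosis_params())
  expect_identical(g1$hap1, g2$hap1)
  expect_identical(g1$hap2, g2$hap2)
})
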