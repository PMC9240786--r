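test_that("the full-scale planner reproduces the programme's cohort trace", {
  plan <- plan_cohorts(programme_config())
  expect_identical(plan, c(crosses = 350L, f1 = 3500L, f2 = 7000L,
                           f2_selected = 3500L, f3 = 35000L,
                           stage1 = 800L, parents = 400L))
  # the scaled profile preserves every structural ratio
  sp <- plan_cohorts(scaled_programme_config())
  expect_equal(unname(plan / sp),
               rep(10, 7), tolerance = 1e-12)
})

test_that("configuration inconsistencies are rejected", {
  expect_error(programme_config(n_parents = 10, n_primary = 4),
               "n_parents / 2")
  expect_error(programme_config(n_topcross = 100), "n_best_primary")
  expect_error(programme_config(introgression_pct = 1.5), "\\[0,1\\]")
})

test_that("make_crosses uses each parent once and builds all cross types", {
  set.seed(30)
  sc <- mini_scenario()
  fdn <- build_foundation(sc)
  parents <- subset_pop(fdn$founders$existing, 1:8)
  f1type <- make_crosses(parents, rep(0, 8), sc$programme, fdn$arch,
                         fdn$map, meiosis_params(mu = 0))
  expect_equal(n_ind(f1type), 14)  # 7 crosses x 2 progeny
  expect_equal(sort(unique(f1type$family)), 1:7)
  # primary crosses (families 1-4): each parent appears exactly once
  prim <- f1type$family <= 4
  used <- c(f1type$mother[prim], f1type$father[prim])
  expect_identical(sort(unique(used)), sort(parents$id))
  expect_true(all(table(used) == 2))  # 2 progeny per cross
  expect_setequal(unique(f1type$generation),
                  c("F1", "TC1F1", "BC1F1"))
  expect_equal(sum(f1type$generation == "TC1F1"), 4)
  expect_equal(sum(f1type$generation == "BC1F1"), 2)
})

test_that("introgression arithmetic and identity preservation", {
  set.seed(31)
  sc <- mini_scenario()
  fdn <- build_foundation(sc)
  parents <- subset_pop(fdn$founders$existing, 1:8)
  scores <- c(3, 1, 4, 1, 5, 9, 2, 6)
  # pct = 0: nothing changes
  out0 <- introgress_parents(parents, scores, fdn$founders$external,
                             0, fdn$arch)
  expect_identical(out0$parents$hap1, parents$hap1)
  expect_identical(out0$n_introduced, 0L)
  # pct = 0.25 of 8 parents: two external lines replace the two
  # lowest-scoring parents; kept genotypes are untouched
  out <- introgress_parents(parents, scores, fdn$founders$external,
                            0.25, fdn$arch)
  expect_identical(out$n_introduced, 2L)
  expect_equal(n_ind(out$parents), 8)
  kept_ids <- setdiff(parents$id, parents$id[order(scores)[1:2]])
  expect_true(all(kept_ids %in% out$parents$id))
  for (id in kept_ids) {
    expect_identical(out$parents$hap1[out$parents$id == id, ],
                     parents$hap1[parents$id == id, ])
  }
  # 1% of a 400-parent pool is 4 lines
  expect_identical(as.integer(ceiling(0.01 * 400)), 4L)
  expect_error(introgress_parents(parents, scores,
                                  fdn$founders$external, 1, fdn$arch),
               "external pool")
})

test_that("one cycle realizes exactly the planned cohort sizes", {
  set.seed(32)
  sc <- mini_scenario()
  fdn <- build_foundation(sc)
  state <- init_programme(fdn$founders, sc$programme, fdn$arch)
  state2 <- run_cycle(state, sc$programme, fdn$arch, fdn$map,
                      meiosis_params())
  expect_equal(n_ind(state2$parents), 8)
  expect_equal(state2$cycle, 2L)
  expect_equal(length(state2$training), 1L)
  m <- state2$metrics
  expect_setequal(unique(m$metric),
                  c("genetic_gain", "accuracy", "freq_major",
                    "freq_minor", "freq_yield"))
  # phenotypic cycle: no accuracy yet
  expect_true(all(is.na(m$value[m$metric == "accuracy"])))
  expect_true(all(m$value[grepl("freq", m$metric)] >= 0 &
                    m$value[grepl("freq", m$metric)] <= 1))
})

test_that("a replicated mini programme is deterministic under a fixed seed", {
  sc <- mini_scenario()
  r1 <- run_programme(sc, n_replicates = 1, seed = 42)
  r2 <- run_programme(sc, n_replicates = 1, seed = 42)
  expect_identical(r1$raw, r2$raw)
  expect_equal(length(r1$failed), 0L)
  # the introgression event is recorded once, at its configured cycle
  intr <- subset(r1$raw, stage == "intr")
  expect_true(all(intr$cycle == sc$programme$introgression_cycle))
  # GS cycles report a finite accuracy
  acc <- subset(r1$raw, metric == "accuracy" & stage == "cycle" &
                  cycle >= sc$programme$gs_start_cycle)
  expect_true(all(is.finite(acc$value)))
})

test_that("training window never exceeds its configured depth", {
  set.seed(34)
  sc <- mini_scenario()
  fdn <- build_foundation(sc)
  state <- init_programme(fdn$founders, sc$programme, fdn$arch)
  for (i in 1:5) {
    if (state$cycle == sc$programme$introgression_cycle) {
      out <- introgress_parents(state$parents, state$parent_scores,
                                fdn$founders$external,
                                sc$programme$introgression_pct, fdn$arch)
      state$parents <- out$parents
      state$parent_scores <- out$scores
    }
    state <- run_cycle(state, sc$programme, fdn$arch, fdn$map,
                       meiosis_params())
    expect_lte(length(state$training), sc$programme$training_cycles)
  }
})
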