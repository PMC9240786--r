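#' Breeding programme configuration
#'
#' Cohort sizes and scenario switches of the recurrent genomic-selection
#' programme. One cycle runs: 200 primary crosses from 400 parents (each
#' used once), the best 150 primary crosses (by the parents' summed major
#' favourable-allele count) spawning 90 top crosses and 60 backcrosses,
#' 10 progeny per cross (3,500 F1-type plants), 2 selfed seeds per plant
#' (7,000 F2), half the F2 selected, 10 F3 seeds per selected F2 (35,000),
#' single seed descent to F5, 800 family-balanced Stage-1 lines phenotyped
#' in two environments, and 400 lines selected as next-cycle parents.
#' Phenotypic selection runs in cycles 1-3 and genomic selection from
#' `gs_start_cycle` on; external germplasm is introgressed once, at the
#' start of `introgression_cycle`.
#'
#' @param n_parents parents per cycle.
#' @param n_primary primary (bi-parental) crosses; must be `n_parents / 2`.
#' @param n_best_primary primary crosses eligible to spawn top/backcrosses.
#' @param n_topcross,n_backcross top crosses and backcrosses (their sum must
#'   equal `n_best_primary`); ranks 1..n_topcross of the best primary
#'   crosses spawn top crosses, the rest backcrosses.
#' @param n_progeny progeny per cross.
#' @param n_self_per_f1 selfed seeds per F1-type plant.
#' @param n_f3_per_f2 F3 seeds per selected F2 plant.
#' @param ssd_generations selfing generations of single seed descent
#'   (F3 to F5 = 2).
#' @param n_stage1 Stage-1 lines selected (family-balanced).
#' @param n_cycles breeding cycles.
#' @param gs_start_cycle first genomic-selection cycle (phenotypic
#'   selection before).
#' @param introgression_cycle cycle at whose start external lines replace
#'   part of the parent pool.
#' @param introgression_pct fraction of the parent pool replaced (0
#'   disables).
#' @param training_cycles training window (number of latest cycles kept).
#' @param index an [index_spec()].
#' @param h2 named heritabilities `c(disease, yield)`.
#' @param prediction_method "fast" (closed-form ridge) or "gibbs".
#' @param marker_loci optional panel subset used as markers (default: all
#'   loci, QTL included).
#' @return list of class `programme_config`.
#' @export
programme_config <- function(n_parents = 400, n_primary = 200,
                             n_best_primary = 150, n_topcross = 90,
                             n_backcross = 60, n_progeny = 10,
                             n_self_per_f1 = 2, n_f3_per_f2 = 10,
                             ssd_generations = 2, n_stage1 = 800,
                             n_cycles = 8, gs_start_cycle = 4,
                             introgression_cycle = 4,
                             introgression_pct = 0.20,
                             training_cycles = 3,
                             index = index_spec(0.5, 0.5, 0),
                             h2 = c(disease = 0.5, yield = 0.25),
                             prediction_method = c("fast", "gibbs"),
                             marker_loci = NULL) {
  prediction_method <- match.arg(prediction_method)
  if (n_primary * 2 != n_parents) {
    stop("n_primary must be n_parents / 2 (each parent used once)")
  }
  if (n_topcross + n_backcross != n_best_primary) {
    stop("n_topcross + n_backcross must equal n_best_primary")
  }
  if (n_best_primary > n_primary) stop("n_best_primary exceeds n_primary")
  if (introgression_pct < 0 || introgression_pct > 1) {
    stop("introgression_pct must lie in [0,1]")
  }
  n_crosses <- n_primary + n_topcross + n_backcross
  n_f2 <- n_crosses * n_progeny * n_self_per_f1
  if (n_f2 %% 2 != 0) stop("F2 cohort must be even (half are selected)")
  structure(list(
    n_parents = n_parents, n_primary = n_primary,
    n_best_primary = n_best_primary, n_topcross = n_topcross,
    n_backcross = n_backcross, n_progeny = n_progeny,
    n_self_per_f1 = n_self_per_f1, n_f3_per_f2 = n_f3_per_f2,
    ssd_generations = ssd_generations, n_stage1 = n_stage1,
    n_cycles = n_cycles, gs_start_cycle = gs_start_cycle,
    introgression_cycle = introgression_cycle,
    introgression_pct = introgression_pct,
    training_cycles = training_cycles, index = index, h2 = h2,
    prediction_method = prediction_method, marker_loci = marker_loci),
    class = "programme_config")
}

#' Scaled-down programme profile
#'
#' A structurally identical programme at one tenth the parent numbers
#' (40 parents, 20 primary crosses, 15 best spawning 9 top + 6 backcrosses,
#' 700 F2, 3,500 F3, 80 Stage-1 lines) preserving every ratio of the full
#' design. Used for fast replicated runs.
#'
#' @param ... overrides passed to [programme_config()].
#' @export
scaled_programme_config <- function(...) {
  defaults <- list(n_parents = 40, n_primary = 20, n_best_primary = 15,
                   n_topcross = 9, n_backcross = 6, n_progeny = 10,
                   n_self_per_f1 = 2, n_f3_per_f2 = 10, n_stage1 = 80)
  args <- utils::modifyList(defaults, list(...))
  do.call(programme_config, args)
}

#' Expected cohort sizes for a configuration
#'
#' Dry-run planner: the exact integer cohort trace one cycle must produce.
#'
#' @param config a `programme_config`.
#' @return named integer vector: crosses, f1, f2, f2_selected, f3, stage1,
#'   parents.
#' @export
plan_cohorts <- function(config) {
  n_crosses <- config$n_primary + config$n_topcross + config$n_backcross
  n_f1 <- n_crosses * config$n_progeny
  n_f2 <- n_f1 * config$n_self_per_f1
  n_f2_sel <- n_f2 %/% 2L
  c(crosses = as.integer(n_crosses), f1 = as.integer(n_f1),
    f2 = as.integer(n_f2), f2_selected = as.integer(n_f2_sel),
    f3 = as.integer(n_f2_sel * config$n_f3_per_f2),
    stage1 = as.integer(config$n_stage1),
    parents = as.integer(config$n_parents))
}

#' Make one cycle's crosses
#'
#' Randomly pairs the parents into primary crosses (each parent used once),
#' ranks the primary crosses by the parents' summed favourable-allele count
#' at the major disease QTL, and lets the best `n_best_primary` spawn top
#' crosses (ranks 1..n_topcross: the cross's first F1 crossed to the
#' highest-scoring parent outside the cross) and backcrosses (remaining
#' ranks: first F1 crossed back to the cross parent carrying more major
#' favourable alleles, ties to the mother). Every cross yields `n_progeny`
#' progeny; families are numbered primary crosses first, then top crosses,
#' then backcrosses.
#'
#' @param parents a `population` of the cycle's parents.
#' @param scores per-parent index scores used to pick top-cross parents.
#' @param config a `programme_config`.
#' @param arch a `trait_architecture`.
#' @param map a `locus_map`.
#' @param params `meiosis_params`.
#' @return A `population` of all F1-type plants (F1, TC1F1, BC1F1).
#' @export
make_crosses <- function(parents, scores, config, arch, map,
                         params = meiosis_params()) {
  np <- n_ind(parents)
  if (np < config$n_parents) stop("insufficient parents")
  perm <- sample.int(np)
  mothers <- perm[seq_len(config$n_primary)]
  fathers <- perm[config$n_primary + seq_len(config$n_primary)]
  f1 <- cross(parents, mothers, fathers, config$n_progeny, map, params,
              family = seq_len(config$n_primary), generation = "F1")
  mc <- major_allele_counts(parents, arch)
  cross_score <- mc[mothers] + mc[fathers]
  best <- order(-cross_score, seq_along(cross_score))[
    seq_len(config$n_best_primary)]
  tc_crosses <- best[seq_len(config$n_topcross)]
  bc_crosses <- best[config$n_topcross + seq_len(config$n_backcross)]
  # one F1 plant per selected cross acts as the TC/BC parent
  f1_rep <- (seq_len(config$n_primary) - 1L) * config$n_progeny + 1L
  pool <- bind_pops(parents, f1)
  f1_off <- np
  # top crosses: third parent = highest-scoring parent not in the cross
  ord_score <- order(-scores, seq_len(np))
  third <- vapply(tc_crosses, function(ci) {
    excl <- c(mothers[ci], fathers[ci])
    ord_score[which(!(ord_score %in% excl))[1L]]
  }, integer(1))
  tc <- cross(pool, f1_off + f1_rep[tc_crosses], third, config$n_progeny,
              map, params,
              family = config$n_primary + seq_len(config$n_topcross),
              generation = "TC1F1")
  # backcrosses: recurrent parent = cross parent with more major alleles
  recurrent <- ifelse(mc[mothers[bc_crosses]] >= mc[fathers[bc_crosses]],
                      mothers[bc_crosses], fathers[bc_crosses])
  bc <- cross(pool, f1_off + f1_rep[bc_crosses], recurrent,
              config$n_progeny, map, params,
              family = config$n_primary + config$n_topcross +
                seq_len(config$n_backcross),
              generation = "BC1F1")
  bind_pops(f1, tc, bc)
}

#' Introgress external lines into the parent pool
#'
#' Replaces `ceiling(pct * n_parents)` of the lowest-scoring parents with
#' the external lines carrying the most favourable alleles at the major
#' disease QTL. Only parent identities change; no genotypes are edited.
#'
#' @param parents parent `population`.
#' @param scores per-parent index scores (lowest are replaced).
#' @param external external `population`.
#' @param pct fraction of the pool to replace, in \[0,1\].
#' @param arch a `trait_architecture`.
#' @return list with the new `parents` population, updated `scores`
#'   (introduced lines carry NA until next scored) and `n_introduced`.
#' @export
introgress_parents <- function(parents, scores, external, pct, arch) {
  np <- n_ind(parents)
  n_intro <- as.integer(ceiling(pct * np))
  if (n_intro == 0) {
    return(list(parents = parents, scores = scores, n_introduced = 0L))
  }
  if (n_intro > n_ind(external)) {
    stop("external pool has only ", n_ind(external), " lines; ",
         n_intro, " requested")
  }
  mc_ext <- major_allele_counts(external, arch)
  take <- order(-mc_ext, seq_along(mc_ext))[seq_len(n_intro)]
  drop_idx <- order(scores, seq_len(np))[seq_len(n_intro)]
  keep <- setdiff(seq_len(np), drop_idx)
  new_parents <- bind_pops(subset_pop(parents, keep),
                           subset_pop(external, take))
  new_scores <- c(scores[keep], rep(NA_real_, n_intro))
  list(parents = new_parents, scores = new_scores, n_introduced = n_intro)
}

# fit the four trait-environment marker models on a training window
fit_models <- function(training, config) {
  Z <- do.call(rbind, lapply(training, `[[`, "Z"))
  Y <- do.call(rbind, lapply(training, `[[`, "y"))
  trait_of_col <- c("disease", "disease", "yield", "yield")
  lapply(seq_len(4L), function(j) {
    fit_marker_effects(Y[, j], Z, method = config$prediction_method,
                       h2 = config$h2[[trait_of_col[j]]])
  })
}

# per-trait GEBVs: mean of the two environment-model predictions
predict_traits <- function(Z, models) {
  u <- vapply(models, function(m) gebv(Z, m), numeric(nrow(Z)))
  cbind(disease = rowMeans(u[, 1:2, drop = FALSE]),
        yield = rowMeans(u[, 3:4, drop = FALSE]))
}

marker_matrix <- function(pop, config) {
  if (is.null(config$marker_loci)) dosage(pop) else
    dosage(pop, config$marker_loci)
}

index_scores <- function(uD, uY, config, pop, arch) {
  counts <- if (config$index$k > 0) major_allele_counts(pop, arch) else NULL
  selection_index(uD, uY, config$index, counts)
}

#' Run one breeding cycle
#'
#' Executes crossing, selfing, F2 selection (GEBV index in
#' genomic-selection cycles, random in phenotypic cycles), F3 expansion,
#' single seed descent, family-balanced Stage-1 selection, Stage-1
#' phenotyping in two environments, model refitting and parent selection,
#' and updates the training window. Cohort sizes are checked against the
#' planner at every stage.
#'
#' @param state programme state list (see [init_programme()]).
#' @param config a `programme_config`.
#' @param arch a `trait_architecture`.
#' @param map a `locus_map`.
#' @param params `meiosis_params`.
#' @return Updated state; the cycle's metrics are appended to
#'   `state$metrics`.
#' @export
run_cycle <- function(state, config, arch, map, params = meiosis_params()) {
  plan <- plan_cohorts(config)
  cyc <- state$cycle
  gs <- cyc >= config$gs_start_cycle
  check <- function(what, got) {
    if (got != plan[[what]]) {
      stop("cohort mismatch at ", what, ": expected ", plan[[what]],
           ", got ", got)
    }
  }
  models_lagged <- NULL
  parent_scores <- state$parent_scores
  if (gs) {
    if (!length(state$training)) stop("no training records before GS cycle")
    models_lagged <- fit_models(state$training, config)
    up <- predict_traits(marker_matrix(state$parents, config), models_lagged)
    parent_scores <- index_scores(up[, "disease"], up[, "yield"], config,
                                  state$parents, arch)
  }
  parent_scores[is.na(parent_scores)] <- min(parent_scores, na.rm = TRUE)
  f1type <- make_crosses(state$parents, parent_scores, config, arch, map,
                         params)
  check("f1", n_ind(f1type))
  f2 <- self_progeny(f1type, config$n_self_per_f1, map, params,
                     generation = "F2")
  check("f2", n_ind(f2))
  n_sel_f2 <- plan[["f2_selected"]]
  if (gs) {
    uf2 <- predict_traits(marker_matrix(f2, config), models_lagged)
    sc_f2 <- index_scores(uf2[, "disease"], uf2[, "yield"], config, f2, arch)
    sel_f2 <- truncation_select(sc_f2, n_sel_f2)
  } else {
    sel_f2 <- sort(sample.int(n_ind(f2), n_sel_f2))
  }
  f3 <- self_progeny(subset_pop(f2, sel_f2), config$n_f3_per_f2, map,
                     params, generation = "F3")
  check("f3", n_ind(f3))
  f5 <- single_seed_descent(f3, config$ssd_generations, map, params,
                            generation = "F5")
  if (gs) {
    uf5 <- predict_traits(marker_matrix(f5, config), models_lagged)
    sc_f5 <- index_scores(uf5[, "disease"], uf5[, "yield"], config, f5, arch)
  } else {
    sc_f5 <- stats::runif(n_ind(f5))
  }
  sel_f5 <- truncation_select(sc_f5, config$n_stage1, family = f5$family,
                              balance = "equal")
  stage1 <- subset_pop(f5, sel_f5)
  check("stage1", n_ind(stage1))
  g1 <- breeding_values(stage1, arch)
  y1 <- simulate_phenotypes(g1, config$h2)
  tb <- trait_means(g1)
  acc <- c(disease = NA_real_, yield = NA_real_)
  if (gs) {
    u_lag <- predict_traits(marker_matrix(stage1, config), models_lagged)
    acc["disease"] <- prediction_accuracy(u_lag[, "disease"], tb[, "disease"])
    acc["yield"] <- prediction_accuracy(u_lag[, "yield"], tb[, "yield"])
  }
  Z1 <- marker_matrix(stage1, config)
  if (gs) {
    current <- list(list(Z = Z1, y = y1, cycle = cyc))
    models_now <- fit_models(c(state$training, current), config)
    u_now <- predict_traits(Z1, models_now)
    sc_parents <- index_scores(u_now[, "disease"], u_now[, "yield"],
                               config, stage1, arch)
  } else {
    sc_parents <- index_scores(rowMeans(y1[, 1:2]), rowMeans(y1[, 3:4]),
                               config, stage1, arch)
  }
  sel_p <- truncation_select(sc_parents, config$n_parents)
  new_parents <- subset_pop(stage1, sel_p)
  check("parents", n_ind(new_parents))
  state$training <- c(state$training,
                      list(list(Z = Z1[sel_p, , drop = FALSE],
                                y = y1[sel_p, , drop = FALSE], cycle = cyc)))
  if (length(state$training) > config$training_cycles) {
    state$training <- state$training[
      seq.int(length(state$training) - config$training_cycles + 1L,
              length(state$training))]
  }
  gain <- c(
    disease = genetic_gain(tb[sel_p, "disease"],
                           state$base$mean["disease"],
                           state$base$sd["disease"]),
    yield = genetic_gain(tb[sel_p, "yield"],
                         state$base$mean["yield"], state$base$sd["yield"]))
  freqs <- track_frequencies(new_parents, arch)
  state$metrics <- rbind(state$metrics,
                         metric_rows(cyc, "cycle", gain, acc, freqs))
  state$parents <- new_parents
  state$parent_scores <- sc_parents[sel_p]
  state$cycle <- cyc + 1L
  state
}

metric_rows <- function(cycle, stage, gain, acc, freqs) {
  rbind(
    data.frame(cycle = cycle, stage = stage, metric = "genetic_gain",
               trait = names(gain), value = as.numeric(gain)),
    data.frame(cycle = cycle, stage = stage, metric = "accuracy",
               trait = names(acc), value = as.numeric(acc)),
    data.frame(cycle = cycle, stage = stage, metric = names(freqs),
               trait = NA_character_, value = as.numeric(freqs)))
}

#' Initialise programme state
#'
#' Draws the cycle-1 parents at random from the existing founder
#' population and fixes the base additive mean and standard deviation per
#' trait (the unit of genetic gain) from that pool.
#'
#' @param founders a `founder_set`.
#' @param config a `programme_config`.
#' @param arch a `trait_architecture`.
#' @return state list with elements `cycle`, `parents`, `parent_scores`,
#'   `training`, `base`, `metrics`.
#' @export
init_programme <- function(founders, config, arch) {
  ne <- n_ind(founders$existing)
  if (ne < config$n_parents) stop("existing population smaller than n_parents")
  idx <- sort(sample.int(ne, config$n_parents))
  parents <- subset_pop(founders$existing, idx)
  tb <- trait_means(breeding_values(parents, arch))
  base <- list(mean = c(disease = mean(tb[, "disease"]),
                        yield = mean(tb[, "yield"])),
               sd = c(disease = stats::sd(tb[, "disease"]),
                      yield = stats::sd(tb[, "yield"])))
  list(cycle = 1L, parents = parents,
       parent_scores = rep(0, config$n_parents),
       training = list(), base = base, metrics = NULL)
}

#' Run a full breeding programme once
#'
#' Runs `config$n_cycles` cycles from a given foundation, applying the
#' introgression event at the start of its configured cycle and recording
#' the post-introgression parent pool as stage "intr".
#'
#' @param founders a `founder_set`.
#' @param config a `programme_config`.
#' @param arch a `trait_architecture`.
#' @param params `meiosis_params`.
#' @return data.frame of per-cycle metrics (cycle, stage, metric, trait,
#'   value).
#' @export
run_programme_once <- function(founders, config, arch,
                               params = meiosis_params()) {
  state <- init_programme(founders, config, arch)
  for (cyc in seq_len(config$n_cycles)) {
    if (cyc == config$introgression_cycle && config$introgression_pct > 0) {
      intro <- introgress_parents(state$parents, state$parent_scores,
                                  founders$external,
                                  config$introgression_pct, arch)
      state$parents <- intro$parents
      state$parent_scores <- intro$scores
      tb <- trait_means(breeding_values(state$parents, arch))
      gain <- c(disease = genetic_gain(tb[, "disease"],
                                       state$base$mean["disease"],
                                       state$base$sd["disease"]),
                yield = genetic_gain(tb[, "yield"],
                                     state$base$mean["yield"],
                                     state$base$sd["yield"]))
      state$metrics <- rbind(
        state$metrics,
        metric_rows(cyc, "intr", gain,
                    c(disease = NA_real_, yield = NA_real_),
                    track_frequencies(state$parents, arch)))
    }
    state <- run_cycle(state, config, arch, founders$map, params)
  }
  state$metrics
}

#' Run a replicated breeding programme
#'
#' Per replicate: fresh founder sampling, fresh QTL architecture (same
#' scheme), major-QTL rescaling against the configured reference pool,
#' then the full multi-cycle programme. Replicate failures are caught,
#' reported and excluded rather than silently dropped.
#'
#' @param scenario a [scenario_config()].
#' @param n_replicates number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it. For a
#'   paired comparison across scenarios, share the master seed.
#' @return list of class `programme_results` with `raw` (long data.frame
#'   including a `replicate` column), `summary` (via
#'   [summarize_replicates()]) and `failed` (replicate ids that errored,
#'   with messages).
#' @export
run_programme <- function(scenario, n_replicates = 50, seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  raw <- NULL
  failed <- list()
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      set.seed(rep_seeds[r])
      fdn <- build_foundation(scenario)
      m <- run_programme_once(fdn$founders, scenario$programme, fdn$arch,
                              scenario$meiosis)
      m$replicate <- r
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[as.character(r)]] <- conditionMessage(res)
    } else {
      raw <- rbind(raw, res)
    }
  }
  if (length(failed)) {
    warning(length(failed), " replicate(s) failed: ",
            paste(names(failed), collapse = ", "))
  }
  structure(list(raw = raw, summary = summarize_replicates(raw),
                 failed = failed),
            class = "programme_results")
}

#' @export
print.programme_results <- function(x, ...) {
  nr <- if (is.null(x$raw)) 0L else length(unique(x$raw$replicate))
  cat("programme_results:", nr, "replicates,",
      length(x$failed), "failed\n")
  invisible(x)
}
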