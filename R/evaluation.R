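#' Genetic gain in base additive standard deviations
#'
#' Mean true breeding value of the selected individuals relative to the
#' base population mean, expressed in units of the base population's
#' additive standard deviation (fixed at the start of cycle 1).
#'
#' @param tbv TBV vector of the selected individuals (one trait,
#'   environment-averaged).
#' @param base_mean,base_sd base-population TBV mean and SD for that trait.
#' @return numeric gain.
#' @export
genetic_gain <- function(tbv, base_mean, base_sd) {
  if (!length(tbv)) stop("empty selection")
  if (base_sd <= 0) stop("base additive SD must be positive")
  unname((mean(tbv) - base_mean) / base_sd)
}

#' Summarise replicate results
#'
#' Across-replicate mean and standard error (SD / sqrt(n)) per cycle,
#' stage, metric and trait. A single replicate yields SE 0 by convention.
#' Invariant to replicate ordering.
#'
#' @param raw long data.frame with columns replicate, cycle, stage,
#'   metric, trait, value.
#' @return data.frame with columns cycle, stage, metric, trait, n, mean,
#'   se.
#' @export
summarize_replicates <- function(raw) {
  if (is.null(raw) || !nrow(raw)) stop("need at least one replicate")
  key <- interaction(raw$cycle, raw$stage, raw$metric, raw$trait,
                     drop = TRUE, lex.order = TRUE)
  parts <- split(raw, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    v <- d$value[!is.na(d$value)]
    n <- length(v)
    data.frame(cycle = d$cycle[1], stage = d$stage[1],
               metric = d$metric[1], trait = d$trait[1], n = n,
               mean = if (n) mean(v) else NA_real_,
               se = if (n > 1) stats::sd(v) / sqrt(n) else
                 if (n == 1) 0 else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$cycle, out$stage, out$metric, out$trait), ]
}

#' Write raw and summary results to CSV
#'
#' @param results a `programme_results` (from [run_programme()]).
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw_path <- file.path(dir, "results_raw.csv")
  sum_path <- file.path(dir, "results_summary.csv")
  utils::write.csv(results$raw, raw_path, row.names = FALSE)
  utils::write.csv(results$summary, sum_path, row.names = FALSE)
  invisible(c(raw = raw_path, summary = sum_path))
}
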