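#' Selection index specification
#'
#' Two-trait index `I = wD uD / sd(uD) + wY uY / sd(uY) + k N` where `uD`,
#' `uY` are disease and yield scores (GEBVs in genomic-selection cycles,
#' phenotypes in phenotypic-selection cycles), standardised by the
#' candidate cohort's standard deviations, and `N` is the candidate's total
#' favourable-allele count over the major disease QTL (0..20 with 10 major
#' loci). With equal weights the first two terms have expected variance 0.5
#' for independent components; `k = 0` disables the marker-assisted term.
#'
#' @param wD,wY non-negative index weights summing to 1.
#' @param k weight on the major favourable-allele count (default 0; the
#'   marker-assisted scenario uses 0.01).
#' @return list of class `index_spec`.
#' @export
index_spec <- function(wD = 0.5, wY = 0.5, k = 0) {
  if (wD < 0 || wY < 0 || k < 0) stop("weights must be non-negative")
  if (abs(wD + wY - 1) > 1e-8) stop("wD + wY must equal 1")
  structure(list(wD = wD, wY = wY, k = k), class = "index_spec")
}

#' Major favourable-allele counts
#'
#' @param pop a `population`.
#' @param arch a `trait_architecture`.
#' @return integer vector per individual: total favourable alleles over the
#'   major disease QTL (0 .. 2 * n_major).
#' @export
major_allele_counts <- function(pop, arch) {
  loci <- arch$loci[arch$major]
  fav <- arch$favourable[arch$major]
  Z <- dosage(pop, loci)
  flip <- fav == 0L
  Z[, flip] <- 2L - Z[, flip]
  as.integer(rowSums(Z))
}

#' Compute the selection index
#'
#' @param uD,uY per-candidate disease and yield scores.
#' @param spec an `index_spec`.
#' @param major_counts per-candidate major favourable-allele counts
#'   (required when `spec$k > 0`).
#' @return numeric index per candidate.
#' @export
selection_index <- function(uD, uY, spec = index_spec(),
                            major_counts = NULL) {
  if (length(uD) != length(uY)) stop("uD and uY length mismatch")
  sD <- stats::sd(uD)
  sY <- stats::sd(uY)
  if (is.na(sD) || sD == 0 || is.na(sY) || sY == 0) {
    stop("candidate cohort has zero score variance; cannot standardise")
  }
  I <- spec$wD * uD / sD + spec$wY * uY / sY
  if (spec$k > 0) {
    if (is.null(major_counts)) {
      stop("major_counts required when the index weight k > 0")
    }
    I <- I + spec$k * major_counts
  }
  I
}

#' Truncation selection with optional family balancing
#'
#' Selects `n_select` candidates by score. With `balance = "none"` the top
#' scores win (ties broken by candidate position, lowest first). With
#' `balance = "equal"` each family first receives a quota of
#' `floor(n_select / n_families)` of its best candidates (capped at family
#' size); remaining slots are then awarded one at a time to the family
#' whose best not-yet-selected candidate scores highest.
#'
#' @param scores numeric score per candidate.
#' @param n_select number to select (<= number of candidates).
#' @param family family id per candidate (required for balancing).
#' @param balance "none" or "equal".
#' @return integer indices of the selected candidates (ascending).
#' @export
truncation_select <- function(scores, n_select, family = NULL,
                              balance = c("none", "equal")) {
  balance <- match.arg(balance)
  n <- length(scores)
  if (n_select > n) stop("n_select exceeds number of candidates")
  if (n_select == n) return(seq_len(n))
  if (balance == "none") {
    return(sort(order(-scores, seq_len(n))[seq_len(n_select)]))
  }
  if (is.null(family)) stop("family ids required for balanced selection")
  fam <- as.character(family)
  fams <- unique(fam)
  quota <- n_select %/% length(fams)
  by_fam <- split(order(-scores, seq_len(n)), fam[order(-scores, seq_len(n))])
  taken <- integer(0)
  n_taken_fam <- stats::setNames(integer(length(fams)), fams)
  for (f in fams) {
    k <- min(quota, length(by_fam[[f]]))
    if (k > 0) {
      taken <- c(taken, by_fam[[f]][seq_len(k)])
      n_taken_fam[f] <- k
    }
  }
  # remainder: one extra slot per family per round, awarded to the
  # families whose next-best candidate scores highest
  while (length(taken) < n_select) {
    next_best <- vapply(fams, function(f) {
      cand <- by_fam[[f]]
      if (n_taken_fam[f] < length(cand)) scores[cand[n_taken_fam[f] + 1L]]
      else -Inf
    }, numeric(1))
    elig <- fams[is.finite(next_best)]
    if (!length(elig)) break
    r <- min(n_select - length(taken), length(elig))
    winners <- elig[order(-next_best[elig])][seq_len(r)]
    for (f in winners) {
      n_taken_fam[f] <- n_taken_fam[f] + 1L
      taken <- c(taken, by_fam[[f]][n_taken_fam[f]])
    }
  }
  sort(taken)
}
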