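#' Meiosis parameters
#'
#' @param lambda mean number of crossovers per chromosome per meiosis
#'   (Poisson; default 1).
#' @param mu per-locus per-gamete allele-flip (mutation) probability
#'   (default 0.001).
#' @return list of class `meiosis_params`.
#' @export
meiosis_params <- function(lambda = 1, mu = 0.001) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (mu < 0 || mu > 1) stop("mu must lie in [0,1]")
  structure(list(lambda = lambda, mu = mu), class = "meiosis_params")
}

# One gamete per individual for a whole cohort (individuals x loci).
# Per chromosome: a Poisson(lambda) number of crossover points is placed
# uniformly along the chromosome (bp), the source haplotype alternates
# between segments from a fair random start, then each locus mutates
# (allele flip) independently with probability mu.
gamete_batch <- function(hap1, hap2, map, params) {
  n <- nrow(hap1)
  out <- matrix(0L, n, ncol(hap1))
  for (c in seq_len(map$n_chr)) {
    cols <- which(map$chr == c)
    pos <- map$pos[cols]
    len <- map$chr_lengths[c]
    k <- stats::rpois(n, params$lambda)
    start <- sample.int(2L, n, replace = TRUE) - 1L  # 0 -> hap1 first
    src <- matrix(start, n, length(cols))            # column-recycled
    hot <- which(k > 0L)
    if (length(hot)) {
      # count crossover points below each locus for all individuals at
      # once; parity of the count plus the starting haplotype gives the
      # source. Chunked to bound the (crossovers x loci) work matrix.
      chunk <- max(1L, ceiling(2e6 / length(cols)))
      grp <- ceiling(seq_along(hot) / chunk)
      for (ch in split(hot, grp)) {
        kc <- k[ch]
        iv <- rep.int(seq_along(ch), kc)
        nk <- sum(kc)
        pv <- stats::runif(nk, 0, len)
        below <- matrix(rep(pv, times = length(pos)) <
                          rep(pos, each = nk), nk)
        segs <- rowsum(below + 0L, iv, reorder = TRUE)
        src[ch, ] <- (start[ch] + segs) %% 2L
      }
    }
    g <- hap1[, cols, drop = FALSE]
    take2 <- src == 1L
    h2 <- hap2[, cols, drop = FALSE]
    g[take2] <- h2[take2]
    out[, cols] <- g
  }
  if (params$mu > 0) {
    n_mut <- stats::rbinom(1L, length(out), params$mu)
    if (n_mut > 0L) {
      idx <- sample.int(length(out), n_mut)
      out[idx] <- 1L - out[idx]
    }
  }
  out
}

#' Sample a gamete from one individual
#'
#' @param pop a `population`.
#' @param i individual index (default 1).
#' @param map a `locus_map`.
#' @param params `meiosis_params`.
#' @return integer haplotype vector (one allele per locus).
#' @export
sample_gamete <- function(pop, i = 1L, map, params = meiosis_params()) {
  drop(gamete_batch(pop$hap1[i, , drop = FALSE],
                    pop$hap2[i, , drop = FALSE], map, params))
}

#' Cross pairs of individuals
#'
#' Generates `n_progeny` offspring for each (mother, father) pair; each
#' offspring receives one independent gamete from each parent. Selfing
#' (mother == father) is allowed and is how selfed generations are made.
#'
#' @param pop a `population` holding the parents.
#' @param mother,father parallel vectors of parent indices into `pop`, one
#'   entry per cross.
#' @param n_progeny progeny per cross (>= 1).
#' @param map a `locus_map`.
#' @param params `meiosis_params`.
#' @param family family id per cross (default: cross number).
#' @param generation generation tag for the progeny.
#' @return A `population` with `length(mother) * n_progeny` individuals,
#'   ordered cross-major (all progeny of cross 1, then cross 2, ...).
#' @export
cross <- function(pop, mother, father, n_progeny = 1L, map,
                  params = meiosis_params(), family = NULL,
                  generation = "F1") {
  if (length(mother) != length(father)) stop("mother/father length mismatch")
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  if (is.null(family)) family <- seq_along(mother)
  mi <- rep(mother, each = n_progeny)
  fi <- rep(father, each = n_progeny)
  g_m <- gamete_batch(pop$hap1[mi, , drop = FALSE],
                      pop$hap2[mi, , drop = FALSE], map, params)
  g_f <- gamete_batch(pop$hap1[fi, , drop = FALSE],
                      pop$hap2[fi, , drop = FALSE], map, params)
  new_population(g_m, g_f,
                 id = paste0(generation, "_", seq_along(mi)),
                 family = rep(as.integer(family), each = n_progeny),
                 generation = rep_len(generation, length(mi)),
                 mother = pop$id[mi], father = pop$id[fi])
}

#' Self every individual of a cohort
#'
#' @param pop a `population`.
#' @param n_progeny selfed progeny per individual.
#' @param map a `locus_map`.
#' @param params `meiosis_params`.
#' @param generation generation tag for the progeny.
#' @return A `population` with `n_ind(pop) * n_progeny` individuals;
#'   family ids are inherited from the parents.
#' @export
self_progeny <- function(pop, n_progeny = 1L, map,
                         params = meiosis_params(), generation = "self") {
  idx <- seq_len(n_ind(pop))
  out <- cross(pop, idx, idx, n_progeny = n_progeny, map = map,
               params = params, family = pop$family,
               generation = generation)
  out
}

#' Single seed descent
#'
#' Advances every line by one selfed seed per generation for
#' `n_generations` generations (population size unchanged). Expected
#' heterozygosity halves each generation (without mutation).
#'
#' @param pop a `population`.
#' @param n_generations number of selfing steps (>= 0).
#' @param map a `locus_map`.
#' @param params `meiosis_params`.
#' @param generation generation tag for the final cohort (default keeps a
#'   running "SSD" tag).
#' @return A `population` of the same size.
#' @export
single_seed_descent <- function(pop, n_generations, map,
                                params = meiosis_params(),
                                generation = "SSD") {
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (n_generations == 0) return(pop)
  for (g in seq_len(n_generations)) {
    pop <- self_progeny(pop, 1L, map, params, generation = generation)
  }
  pop
}
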