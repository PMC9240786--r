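#' Founder allele-frequency profile
#'
#' Per-locus-class favourable-allele frequency settings used to construct
#' the two founder populations. The existing population carries the major
#' disease QTL at favourable frequency 0 (absent) while the external
#' population segregates them around `major_external`; minor disease QTL
#' frequencies centre on the scenario mean (high/medium/low) in the
#' existing population and are lower in the external one by a per-locus
#' difference drawn from `minor_diff`; yield QTL favourable frequencies are
#' drawn from the band `yield_band` in the existing population and are
#' lower in the external population by a per-locus difference drawn from
#' `yield_diff` (external germplasm is agronomically inferior, which is
#' what creates linkage drag); neutral markers are uniform in each
#' population independently.
#'
#' @param scenario minor-QTL frequency level: "high" (0.85), "medium"
#'   (0.52) or "low" (0.27).
#' @param major_existing favourable frequency of major QTL in the existing
#'   population (default 0).
#' @param major_external favourable frequency of major QTL in the external
#'   population (default 0.65).
#' @param minor_mean override of the scenario's minor-QTL mean.
#' @param minor_jitter half-width of the per-locus uniform jitter around
#'   the minor mean (default 0.12).
#' @param minor_diff range of the per-locus existing-minus-external
#'   favourable-frequency difference at minor QTL (default c(0.03, 0.19)).
#' @param yield_band favourable-frequency band for yield QTL in the
#'   existing population (default c(0.3, 0.7)).
#' @param yield_diff range of the existing-minus-external
#'   favourable-frequency difference at yield QTL (default
#'   c(0.05, 0.13)).
#' @param neutral_band frequency band for non-QTL markers
#'   (default c(0.05, 0.95)).
#' @return list of class `freq_profile`.
#' @export
freq_profile <- function(scenario = c("high", "medium", "low"),
                         major_existing = 0, major_external = 0.65,
                         minor_mean = NULL, minor_jitter = 0.12,
                         minor_diff = c(0.03, 0.19),
                         yield_band = c(0.3, 0.7),
                         yield_diff = c(0.05, 0.13),
                         neutral_band = c(0.05, 0.95)) {
  scenario <- match.arg(scenario)
  if (is.null(minor_mean)) {
    minor_mean <- c(high = 0.85, medium = 0.52, low = 0.27)[[scenario]]
  }
  vals <- c(major_existing, major_external, minor_mean, minor_diff,
            yield_band, yield_diff, neutral_band)
  if (any(vals < 0 | vals > 1)) stop("frequency targets must lie in [0,1]")
  structure(list(scenario = scenario, major_existing = major_existing,
                 major_external = major_external, minor_mean = minor_mean,
                 minor_jitter = minor_jitter, minor_diff = minor_diff,
                 yield_band = yield_band, yield_diff = yield_diff,
                 neutral_band = neutral_band),
            class = "freq_profile")
}

clip01 <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

#' Per-locus target favourable frequencies for both populations
#'
#' Draws the per-locus favourable-allele frequency targets implied by a
#' profile, for every locus of the panel (QTL classes from the
#' architecture; remaining loci are neutral markers).
#'
#' @param profile a `freq_profile`.
#' @param arch a `trait_architecture` (defines QTL loci and classes).
#' @param n_loci panel size.
#' @return list with numeric vectors `existing` and `external` (favourable
#'   frequency per panel locus; for neutral loci "favourable" is allele 1).
#' @export
sample_freq_targets <- function(profile, arch, n_loci) {
  exist <- stats::runif(n_loci, profile$neutral_band[1], profile$neutral_band[2])
  exter <- stats::runif(n_loci, profile$neutral_band[1], profile$neutral_band[2])
  cls <- qtl_classes(arch)
  qloci <- arch$loci
  i_major <- qloci[cls == "major"]
  i_minor <- qloci[cls == "minor"]
  i_yield <- qloci[cls == "yield"]
  exist[i_major] <- profile$major_existing
  exter[i_major] <- profile$major_external
  f_min <- clip01(stats::runif(length(i_minor),
                               profile$minor_mean - profile$minor_jitter,
                               profile$minor_mean + profile$minor_jitter))
  exist[i_minor] <- f_min
  exter[i_minor] <- clip01(f_min - stats::runif(length(i_minor),
                                                profile$minor_diff[1],
                                                profile$minor_diff[2]))
  f_yld <- stats::runif(length(i_yield), profile$yield_band[1],
                        profile$yield_band[2])
  exist[i_yield] <- f_yld
  exter[i_yield] <- clip01(f_yld - stats::runif(length(i_yield),
                                                profile$yield_diff[1],
                                                profile$yield_diff[2]))
  list(existing = exist, external = exter)
}

#' Generate synthetic founder populations
#'
#' Builds two fully homozygous (inbred-line) founder populations, existing
#' and external, by sampling each line's genotype at each locus as a
#' Bernoulli draw at that population's target favourable-allele frequency
#' (both haplotypes set equal). Targets are expressed on the favourable
#' allele as oriented by the architecture and converted to allele-1
#' frequencies internally. Loci are sampled independently (no founder LD);
#' linkage enters later through simulated meiosis.
#'
#' @param n_existing,n_external numbers of lines (>= 2 each).
#' @param map a `locus_map`.
#' @param arch a `trait_architecture`.
#' @param profile a `freq_profile`.
#' @return An object of class `founder_set`: list with `existing` and
#'   `external` (`population`s), `map`, `targets` (per-locus favourable
#'   targets) and `favourable` (favourable allele per panel locus; allele 1
#'   at non-QTL loci).
#' @export
generate_founders <- function(n_existing, n_external, map, arch, profile) {
  if (n_existing < 2 || n_external < 2) stop("population sizes must be >= 2")
  n_loci <- map$n_loci
  targets <- sample_freq_targets(profile, arch, n_loci)
  fav <- rep(1L, n_loci)
  fav[arch$loci] <- arch$favourable
  # convert favourable-allele frequency to allele-1 frequency
  p1_exist <- ifelse(fav == 1L, targets$existing, 1 - targets$existing)
  p1_exter <- ifelse(fav == 1L, targets$external, 1 - targets$external)
  draw <- function(n, p1, id_prefix) {
    h <- matrix(stats::rbinom(n * n_loci, 1L, rep(p1, each = n)), n, n_loci)
    storage.mode(h) <- "integer"
    population(h, h, id = paste0(id_prefix, seq_len(n)),
               generation = "founder")
  }
  structure(
    list(existing = draw(n_existing, p1_exist, "EX"),
         external = draw(n_external, p1_exter, "XT"),
         map = map, targets = targets, favourable = fav,
         profile = profile),
    class = "founder_set"
  )
}

#' @export
print.founder_set <- function(x, ...) {
  cat("founder_set:", n_ind(x$existing), "existing +", n_ind(x$external),
      "external lines,", x$map$n_loci, "loci\n")
  invisible(x)
}

#' Realized favourable-allele frequencies
#'
#' Counts favourable alleles at the requested loci over all individuals of
#' a population and returns per-locus frequencies and their mean.
#'
#' @param pop a `population`.
#' @param loci panel locus indices (non-empty).
#' @param favourable favourable allele (0/1) per requested locus, or a
#'   panel-length vector indexed by `loci`.
#' @return list with `freq` (per-locus favourable frequency) and `mean`.
#' @export
realized_allele_freqs <- function(pop, loci, favourable) {
  if (!length(loci)) stop("empty locus set")
  if (length(favourable) == ncol(pop$hap1)) favourable <- favourable[loci]
  if (length(favourable) != length(loci)) {
    stop("favourable-allele orientation missing for some loci")
  }
  d1 <- colMeans(dosage(pop, loci)) / 2  # allele-1 frequency
  f <- ifelse(favourable == 1L, d1, 1 - d1)
  list(freq = f, mean = mean(f))
}

#' Mean favourable frequency per QTL group
#'
#' @param pop a `population`.
#' @param arch a `trait_architecture`.
#' @return named numeric vector with mean favourable frequency for the
#'   major-disease, minor-disease and yield QTL groups.
#' @export
track_frequencies <- function(pop, arch) {
  cls <- qtl_classes(arch)
  out <- vapply(levels(cls), function(g) {
    idx <- which(cls == g)
    realized_allele_freqs(pop, arch$loci[idx], arch$favourable[idx])$mean
  }, numeric(1))
  names(out) <- c("freq_major", "freq_minor", "freq_yield")
  out
}
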