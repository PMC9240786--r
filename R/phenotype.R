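#' True breeding values
#'
#' Computes the additive genetic value of every individual for every
#' trait-environment column: the incidence of favourable alleles (0/1/2)
#' at the QTL times the additive effects, `g = M a`. Effects are stored in
#' allele-1 coding; breeding values are computed in that coding and then
#' shifted to favourable coding (the two differ by a per-column constant,
#' so variances, correlations and selection rankings are unaffected).
#'
#' @param pop a `population`.
#' @param arch a `trait_architecture`.
#' @param favourable_coding if TRUE (default) report values as
#'   favourable-allele incidence x non-negative-oriented effects; FALSE
#'   gives raw allele-1 coding.
#' @return numeric matrix (individuals x trait-env columns DA, DB, YA, YB).
#' @export
breeding_values <- function(pop, arch, favourable_coding = TRUE) {
  if (max(arch$loci) > ncol(pop$hap1)) {
    stop("architecture loci outside the population's locus panel")
  }
  Z <- dosage(pop, arch$loci)
  g <- Z %*% arch$effects
  if (favourable_coding) {
    # M_fav = 2 - Z at loci where allele 0 is favourable; with effects
    # sign-flipped there, g_fav = g_raw + 2 * sum(effects at flipped loci)
    flip <- arch$favourable == 0L
    if (any(flip)) {
      shift <- 2 * colSums(arch$effects[flip, , drop = FALSE])
      g <- sweep(g, 2L, shift)  # g_fav = g_raw - 2 * sum(flipped effects)
    }
  }
  colnames(g) <- colnames(arch$effects)
  g
}

#' Environment-averaged breeding values per trait
#'
#' @param g matrix from [breeding_values()] with columns DA, DB, YA, YB.
#' @return matrix with columns `disease`, `yield`.
#' @export
trait_means <- function(g) {
  cbind(disease = rowMeans(g[, 1:2, drop = FALSE]),
        yield = rowMeans(g[, 3:4, drop = FALSE]))
}

#' Simulate phenotypes
#'
#' Adds independent normal residuals to true breeding values. The residual
#' standard deviation per column is `sqrt((1 - h2) / h2 * sigma_a2)` where
#' `h2` is the trait's narrow-sense heritability and `sigma_a2` the
#' additive (TBV) variance; by default `sigma_a2` is the realized TBV
#' variance of the cohort being phenotyped, so the realized heritability of
#' the cohort matches the target.
#'
#' @param g TBV matrix (individuals x trait-env columns).
#' @param h2 named heritabilities per trait, `c(disease = 0.5,
#'   yield = 0.25)`.
#' @param trait_of_col trait name per column of `g` (default
#'   disease, disease, yield, yield).
#' @param sigma_a2 optional per-column additive variances overriding the
#'   cohort-realized values.
#' @return phenotype matrix `y` of the same shape as `g`.
#' @export
simulate_phenotypes <- function(g, h2 = c(disease = 0.5, yield = 0.25),
                                trait_of_col = c("disease", "disease",
                                                 "yield", "yield"),
                                sigma_a2 = NULL) {
  if (any(h2 <= 0) || any(h2 > 1)) stop("heritabilities must lie in (0, 1]")
  if (is.null(sigma_a2)) sigma_a2 <- apply(g, 2, stats::var)
  h2c <- h2[trait_of_col]
  sd_e <- sqrt((1 - h2c) / h2c * sigma_a2)
  e <- matrix(stats::rnorm(length(g)), nrow(g), ncol(g))
  y <- g + sweep(e, 2L, sd_e, FUN = "*")
  colnames(y) <- colnames(g)
  y
}
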