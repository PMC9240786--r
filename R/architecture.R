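#' Multi-trait multi-environment QTL overlap scheme
#'
#' Describes how QTL are shared between traits and environments: `k_traits`
#' traits observed in `w_envs` environments, with a trait-overlap rate `p`
#' (0 = fully disjoint trait QTL sets) and an environment-overlap rate `q`
#' (fraction of a trait's QTL shared between its two environments), and `N`
#' QTL per trait per environment.
#'
#' @param k_traits number of traits (>= 1).
#' @param w_envs number of environments (currently 2).
#' @param p trait-overlap rate in \[0,1\]; only `p = 0` is supported.
#' @param q environment-overlap rate in \[0,1\].
#' @param N QTL per trait per environment (>= 1).
#' @return An object of class `overlap_scheme`.
#' @export
overlap_scheme <- function(k_traits = 2, w_envs = 2, p = 0, q = 0.7, N = 1001) {
  if (p < 0 || p > 1 || q < 0 || q > 1) stop("p and q must lie in [0,1]")
  if (p != 0) stop("trait-overlap p > 0 (pleiotropy) is not supported")
  if (w_envs != 2) stop("only w_envs = 2 is supported")
  if (N < 1 || k_traits < 1) stop("N and k_traits must be >= 1")
  structure(list(k_traits = as.integer(k_traits), w_envs = as.integer(w_envs),
                 p = p, q = q, N = as.integer(N)),
            class = "overlap_scheme")
}

#' Per-trait environment-overlap counts
#'
#' For two environments, each trait's `N` QTL per environment split into `s`
#' QTL shared between environments and `u` unique to each environment, with
#' `s + u = N` and the shared fraction of the trait's distinct QTL,
#' `s / (s + 2u)`, as close as possible to `q`. Solving gives
#' `u = round(N (1 - q) / (1 + q))`. At `q = 0.7`, `N = 1001` this yields
#' `u = 177`, `s = 824` and `2u + s = 1178` distinct QTL per trait.
#'
#' @param scheme an `overlap_scheme`.
#' @return list with integers `u` (unique per environment), `s` (shared) and
#'   `per_trait` (distinct QTL per trait).
#' @export
overlap_counts <- function(scheme) {
  N <- scheme$N
  q <- scheme$q
  u <- as.integer(round(N * (1 - q) / (1 + q)))
  s <- N - u
  list(u = u, s = s, per_trait = 2L * u + s)
}

#' Assign QTL loci to traits and environments
#'
#' Samples the distinct QTL loci of all traits without replacement from the
#' locus panel and builds the 0/1 design matrix `X` (QTL x trait-environment
#' columns) whose rows encode which trait-environment combinations each QTL
#' affects. With `p = 0` trait blocks are disjoint. Column order is
#' trait-major: (trait1 envA, trait1 envB, trait2 envA, trait2 envB, ...);
#' for the two-trait disease/yield case the columns are DA, DB, YA, YB.
#'
#' @param scheme an `overlap_scheme`.
#' @param map a `locus_map` (or an integer giving the panel size).
#' @return list with `loci` (panel indices of the distinct QTL), `X` (design
#'   matrix), `trait` (trait index per QTL), `counts` (from
#'   [overlap_counts()]), and `n_qtl`.
#' @export
assign_qtl <- function(scheme, map) {
  n_panel <- if (inherits(map, "locus_map")) map$n_loci else as.integer(map)
  cnt <- overlap_counts(scheme)
  k <- scheme$k_traits
  n_qtl <- k * cnt$per_trait
  if (n_qtl > n_panel) {
    stop("panel of ", n_panel, " loci cannot host ", n_qtl, " distinct QTL")
  }
  loci <- sort(sample.int(n_panel, n_qtl))
  X <- matrix(0L, n_qtl, 2L * k)
  trait <- rep(seq_len(k), each = cnt$per_trait)
  # per trait: u rows env A only, u rows env B only, s rows shared
  pat <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  rows_per_pat <- c(cnt$u, cnt$u, cnt$s)
  for (t in seq_len(k)) {
    off_row <- (t - 1L) * cnt$per_trait
    off_col <- (t - 1L) * 2L
    r <- off_row
    for (pi in 1:3) {
      if (rows_per_pat[pi] == 0L) next
      idx <- r + seq_len(rows_per_pat[pi])
      X[idx, off_col + 1L] <- pat[pi, 1L]
      X[idx, off_col + 2L] <- pat[pi, 2L]
      r <- r + rows_per_pat[pi]
    }
  }
  if (k == 2L) colnames(X) <- c("DA", "DB", "YA", "YB")
  list(loci = loci, X = X, trait = trait, counts = cnt, n_qtl = n_qtl)
}

#' Trait-environment effect covariance matrix
#'
#' The 4x4 correlation matrix over (disease envA, disease envB, yield envA,
#' yield envB) with a between-environment genetic correlation of
#' `r_disease` for disease resistance and `r_yield` for grain yield, and no
#' cross-trait correlation.
#'
#' @param r_disease between-environment correlation for disease (default 0.8).
#' @param r_yield between-environment correlation for yield (default 0.4).
#' @export
effect_covariance <- function(r_disease = 0.8, r_yield = 0.4) {
  w <- diag(4)
  w[1, 2] <- w[2, 1] <- r_disease
  w[3, 4] <- w[4, 3] <- r_yield
  dimnames(w) <- list(c("DA", "DB", "YA", "YB"), c("DA", "DB", "YA", "YB"))
  w
}

#' Sample correlated QTL effects via Cholesky factorisation
#'
#' Draws `u0`, an `n_qtl` x ncol(cov) matrix of independent standard
#' normals, and returns `v = u0 L` where `cov = L'L` (upper-triangular
#' Cholesky factor), so that the columns of `v` are marginally standard
#' normal with cross-correlations converging to `cov`.
#'
#' @param cov symmetric positive semi-definite covariance (correlation)
#'   matrix.
#' @param n_qtl number of rows to sample (>= 2).
#' @return numeric matrix `v` with `n_qtl` rows.
#' @export
sample_effects <- function(cov, n_qtl) {
  if (n_qtl < 2) stop("n_qtl must be >= 2")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("covariance is not positive semi-definite (eigenvalue ",
         format(min(ev)), ")")
  }
  L <- chol(cov)  # upper triangular, cov = t(L) %*% L
  u0 <- matrix(stats::rnorm(n_qtl * ncol(cov)), n_qtl, ncol(cov))
  v <- u0 %*% L
  colnames(v) <- colnames(cov)
  v
}

#' Mask effects with the design matrix
#'
#' Hadamard (element-wise) product `a = X * v`: a QTL's effect on a
#' trait-environment combination is zeroed unless the design matrix says the
#' QTL affects it.
#'
#' @param v sampled effect matrix.
#' @param X 0/1 design matrix of the same shape.
#' @export
mask_effects <- function(v, X) {
  if (!identical(dim(v), dim(X))) stop("shape mismatch between v and X")
  a <- X * v
  colnames(a) <- colnames(v)
  a
}

#' Designate major disease QTL
#'
#' Picks the `n_major` disease QTL with the largest effects, ranking each
#' QTL by the mean absolute effect over the environments it affects
#' (environment-unique QTL are eligible through their single effect). Ties
#' are broken by QTL index (lowest first), so the result is deterministic
#' given the effects.
#'
#' @param a masked effect matrix.
#' @param X design matrix.
#' @param trait trait index per QTL row.
#' @param disease_trait which trait index is disease (default 1).
#' @param n_major number of major QTL (default 10).
#' @return integer vector of QTL row indices (into `a`) of the major QTL.
#' @export
designate_major <- function(a, X, trait, disease_trait = 1L, n_major = 10L) {
  dcols <- (disease_trait - 1L) * 2L + 1:2
  cand <- which(trait == disease_trait)
  if (length(cand) < n_major) stop("fewer disease QTL than n_major")
  score <- rowSums(abs(a[cand, dcols, drop = FALSE])) /
    rowSums(X[cand, dcols, drop = FALSE])
  ord <- cand[order(-score, cand)]
  sort(ord[seq_len(n_major)])
}

#' Orient favourable alleles
#'
#' For each QTL the favourable allele is the one whose substitution
#' increases the trait's merit: allele 1 if the QTL's mean raw effect over
#' its environments is positive, allele 0 if negative. Zero-effect QTL
#' default to allele 1.
#'
#' @param a masked effect matrix (raw allele-1 coding).
#' @param X design matrix.
#' @param trait trait index per QTL row.
#' @return integer vector (per QTL) of the favourable allele, 0 or 1.
#' @export
orient_favourable <- function(a, X, trait) {
  k <- max(trait)
  n <- nrow(a)
  fav <- rep(1L, n)
  for (t in seq_len(k)) {
    cols <- (t - 1L) * 2L + 1:2
    rows <- which(trait == t)
    m <- rowSums(a[rows, cols, drop = FALSE]) /
      rowSums(X[rows, cols, drop = FALSE])
    fav[rows] <- ifelse(m < 0, 0L, 1L)
  }
  fav
}

#' Assemble a trait architecture
#'
#' Bundles the QTL assignment, sampled effects, major-QTL designation and
#' favourable-allele orientation into one object. Convenience constructor;
#' the usual entry point is [simulate_architecture()].
#'
#' @param assignment result of [assign_qtl()].
#' @param v pre-mask effect matrix.
#' @param n_major number of major disease QTL.
#' @param disease_trait trait index of disease (default 1).
#' @return An object of class `trait_architecture` with elements `loci`,
#'   `X`, `v`, `effects` (masked, possibly rescaled), `trait`, `major`
#'   (QTL row indices), `favourable` (allele per QTL), `scaling_c`.
#' @export
trait_architecture <- function(assignment, v, n_major = 10L,
                               disease_trait = 1L) {
  if (is.null(colnames(v)) && ncol(v) == 4L) {
    colnames(v) <- c("DA", "DB", "YA", "YB")
  }
  a <- mask_effects(v, assignment$X)
  major <- designate_major(a, assignment$X, assignment$trait,
                           disease_trait, n_major)
  fav <- orient_favourable(a, assignment$X, assignment$trait)
  structure(
    list(loci = assignment$loci, X = assignment$X, v = v, effects = a,
         trait = assignment$trait, counts = assignment$counts,
         n_qtl = assignment$n_qtl, major = major, favourable = fav,
         disease_trait = disease_trait, scaling_c = NA_real_),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("trait_architecture:", x$n_qtl, "QTL (",
      length(x$major), "major disease ), scaling_c =",
      format(x$scaling_c, digits = 4), "\n")
  invisible(x)
}

#' QTL class labels
#'
#' @param arch a `trait_architecture`.
#' @return factor per QTL with levels major/minor/yield (minor = non-major
#'   disease QTL).
#' @export
qtl_classes <- function(arch) {
  cls <- ifelse(arch$trait == arch$disease_trait, "minor", "yield")
  cls[arch$major] <- "major"
  factor(cls, levels = c("major", "minor", "yield"))
}

disease_cols <- function(arch) (arch$disease_trait - 1L) * 2L + 1:2

#' Environment-averaged effects per QTL for one trait
#'
#' Mean of the masked effects over the environments the QTL affects is not
#' used for breeding values (those are per-environment); this helper returns
#' the simple mean of the two environment columns, which is the disease
#' merit direction used for scaling and orientation.
#' @noRd
env_mean_effects <- function(arch, trait_idx) {
  cols <- (trait_idx - 1L) * 2L + 1:2
  rowMeans(arch$effects[, cols, drop = FALSE])
}

#' Rescale major disease QTL effects
#'
#' Multiplies the major disease QTL effects by a constant `c` chosen so that
#' the major loci explain `target_frac` of the total disease genetic
#' variance in a reference population (the parent pool containing the
#' configured share of external lines), then rescales the full disease
#' effect vector to standard deviation 1. Variance is computed on the
#' environment-averaged disease breeding values of the reference lines;
#' `c` solves the quadratic
#' `c^2 A (1 - f) - 2 f c C - f B = 0` with `A = Var(major component)`,
#' `B = Var(minor component)`, `C = Cov(major, minor)` and `f` the target
#' fraction (positive root).
#'
#' Alternatively, when `major_effect_mean` is supplied (the effect-size
#' scenario switch) the constant is chosen so the mean absolute
#' environment-averaged major effect equals that value, before the same
#' SD-1 rescaling.
#'
#' @param arch a `trait_architecture`.
#' @param reference a `population` of reference lines (e.g. 320 existing +
#'   80 external founders).
#' @param target_frac target variance fraction for the major QTL
#'   (default 0.10).
#' @param major_effect_mean optional mean absolute major effect size
#'   overriding the variance-fraction criterion.
#' @return The architecture with rescaled disease effects and `scaling_c`
#'   set.
#' @export
scale_major <- function(arch, reference, target_frac = 0.10,
                        major_effect_mean = NULL) {
  dcols <- disease_cols(arch)
  drows <- which(arch$trait == arch$disease_trait)
  minor_rows <- setdiff(drows, arch$major)
  a_bar <- env_mean_effects(arch, arch$disease_trait)
  if (is.null(major_effect_mean)) {
    Z <- dosage(reference, arch$loci)
    g_major <- as.numeric(Z[, arch$major, drop = FALSE] %*% a_bar[arch$major])
    g_minor <- as.numeric(Z[, minor_rows, drop = FALSE] %*% a_bar[minor_rows])
    A <- stats::var(g_major)
    B <- stats::var(g_minor)
    C <- stats::cov(g_major, g_minor)
    f <- target_frac
    if (A <= 0) {
      stop("major QTL are monomorphic in the reference population; ",
           "target variance fraction unattainable")
    }
    disc <- f^2 * C^2 + f * (1 - f) * A * B
    if (disc < 0) stop("target variance fraction unattainable")
    den <- A * (1 - f)
    roots <- if (abs(den) < 1e-12) {
      -f * B / (2 * f * C)
    } else {
      (f * C + c(1, -1) * sqrt(disc)) / den
    }
    roots <- roots[is.finite(roots) & roots > 0]
    if (!length(roots)) {
      stop("no positive scaling constant attains the target fraction")
    }
    # if both roots are admissible take the smaller adjustment
    c_const <- roots[which.min(abs(log(roots)))]
  } else {
    cur <- mean(abs(a_bar[arch$major]))
    c_const <- major_effect_mean / cur
  }
  arch$effects[arch$major, dcols] <- arch$effects[arch$major, dcols] * c_const
  # rescale the full disease-effect vector (active entries) to SD 1
  act <- arch$X[drows, dcols, drop = FALSE] == 1L
  vals <- arch$effects[drows, dcols, drop = FALSE][act]
  s <- stats::sd(vals)
  arch$effects[, dcols] <- arch$effects[, dcols] / s
  arch$scaling_c <- c_const
  arch
}

#' Variance fraction explained by the major disease QTL
#'
#' Share of the variance of the environment-averaged disease breeding value
#' attributable to the major loci (including their covariance-free ratio
#' Var(major)/Var(total)) in a given population.
#'
#' @param arch a `trait_architecture`.
#' @param pop a `population`.
#' @return numeric scalar in \[0, 1\] (can exceed 1 only if major and minor
#'   components are strongly negatively correlated).
#' @export
major_variance_fraction <- function(arch, pop) {
  a_bar <- env_mean_effects(arch, arch$disease_trait)
  drows <- which(arch$trait == arch$disease_trait)
  Z <- dosage(pop, arch$loci)
  g_major <- as.numeric(Z[, arch$major, drop = FALSE] %*% a_bar[arch$major])
  g_total <- as.numeric(Z[, drows, drop = FALSE] %*% a_bar[drows])
  stats::var(g_major) / stats::var(g_total)
}

#' Simulate a complete trait architecture
#'
#' Runs the full construction: QTL assignment, Cholesky effect sampling,
#' masking, major-QTL designation and favourable-allele orientation.
#' Rescaling against a reference population ([scale_major()]) is a separate
#' step because it needs founder genotypes.
#'
#' @param scheme an `overlap_scheme`.
#' @param map a `locus_map`.
#' @param cov effect covariance (default [effect_covariance()]).
#' @param n_major number of major disease QTL (default 10).
#' @return A `trait_architecture`.
#' @export
simulate_architecture <- function(scheme, map, cov = effect_covariance(),
                                  n_major = 10L) {
  asg <- assign_qtl(scheme, map)
  v <- sample_effects(cov, asg$n_qtl)
  trait_architecture(asg, v, n_major = n_major)
}

#' Serialise / restore a trait architecture
#'
#' Writes the architecture (QTL loci, design matrix, effects, major flags,
#' orientation, scaling constant) to a single JSON file so that a run is
#' fully reproducible from disk.
#'
#' @param arch a `trait_architecture`.
#' @param path file path.
#' @export
write_architecture <- function(arch, path) {
  obj <- list(loci = arch$loci, X = arch$X, v = arch$v,
              effects = arch$effects, trait = arch$trait,
              major = arch$major, favourable = arch$favourable,
              disease_trait = arch$disease_trait,
              scaling_c = arch$scaling_c,
              counts = arch$counts, n_qtl = arch$n_qtl)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- c("DA", "DB", "YA", "YB")
  for (m in c("X", "v", "effects")) {
    obj[[m]] <- as.matrix(obj[[m]])
    if (ncol(obj[[m]]) == 4) colnames(obj[[m]]) <- cn
  }
  structure(
    list(loci = as.integer(obj$loci), X = obj$X, v = obj$v,
         effects = obj$effects, trait = as.integer(obj$trait),
         counts = obj$counts, n_qtl = as.integer(obj$n_qtl),
         major = as.integer(obj$major),
         favourable = as.integer(obj$favourable),
         disease_trait = as.integer(obj$disease_trait),
         scaling_c = if (is.null(obj$scaling_c)) NA_real_ else
           as.numeric(obj$scaling_c)),
    class = "trait_architecture"
  )
}
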