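#' Construct a locus map
#'
#' A locus map places every SNP of the panel on a chromosome at a physical
#' (bp) position. Loci are globally ordered by chromosome then position;
#' their 1-based row index is the locus index used everywhere else in the
#' package.
#'
#' @param chr integer vector, chromosome id (1..n_chr) per locus.
#' @param pos integer vector, bp position per locus; strictly increasing
#'   within each chromosome.
#' @param chr_lengths numeric vector of chromosome lengths in bp, one per
#'   chromosome; must be at least the largest position on that chromosome.
#' @return An object of class `locus_map`: a list with elements `chr`,
#'   `pos`, `chr_lengths`, `n_loci`, `n_chr`.
#' @export
locus_map <- function(chr, pos, chr_lengths) {
  chr <- as.integer(chr)
  pos <- as.numeric(pos)
  if (length(chr) != length(pos)) stop("chr and pos must have equal length")
  n_chr <- length(chr_lengths)
  if (n_chr < 1L) stop("need at least one chromosome")
  if (any(chr < 1L | chr > n_chr)) stop("chromosome id outside 1..n_chr")
  ord <- order(chr, pos)
  if (any(ord != seq_along(chr))) {
    chr <- chr[ord]
    pos <- pos[ord]
  }
  for (c in unique(chr)) {
    p <- pos[chr == c]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", c)
    }
    if (max(p) > chr_lengths[c]) {
      stop("position beyond length of chromosome ", c)
    }
  }
  structure(
    list(chr = chr, pos = pos, chr_lengths = as.numeric(chr_lengths),
         n_loci = length(chr), n_chr = n_chr),
    class = "locus_map"
  )
}

#' Build a regular synthetic locus map
#'
#' Distributes `n_loci` loci as evenly as possible across `n_chr`
#' chromosomes at uniformly spaced positions. Defaults mirror a barley-like
#' panel: 7 chromosomes of 655 Mb.
#'
#' @param n_loci total number of loci.
#' @param n_chr number of chromosomes.
#' @param chr_length length of each chromosome in bp (recycled to `n_chr`).
#' @return A `locus_map`.
#' @export
make_locus_map <- function(n_loci, n_chr = 7, chr_length = 655e6) {
  chr_lengths <- rep_len(chr_length, n_chr)
  per_chr <- rep(n_loci %/% n_chr, n_chr)
  extra <- n_loci %% n_chr
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chr <- rep(seq_len(n_chr), per_chr)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    round(seq(1, chr_lengths[c], length.out = per_chr[c] + 1L)[-1])
  }), use.names = FALSE)
  locus_map(chr, pos, chr_lengths)
}

#' @export
print.locus_map <- function(x, ...) {
  cat("locus_map:", x$n_loci, "loci on", x$n_chr, "chromosomes\n")
  invisible(x)
}
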