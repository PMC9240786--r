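#' Write founder genotypes to VCF with sidecar files
#'
#' Emits a VCF v4.2 file (one sample per inbred line, homozygous GT
#' records), a TSV locus map (`<path>.map.tsv`: chrom, pos, locus_id plus a
#' header line of chromosome lengths) and a TSV population-label file
#' (`<path>.pops.tsv`: sample, population). Favourable-allele orientation
#' and frequency targets are not part of the genotype files; serialise the
#' architecture separately with [write_architecture()].
#'
#' @param f a `founder_set`.
#' @param path path of the VCF file to create (e.g. "founders.vcf").
#' @return Invisibly, the three file paths.
#' @export
write_founders <- function(f, path) {
  all_pop <- bind_pops(f$existing, f$external)
  if (!is_inbred(all_pop)) {
    stop("founders must be fully homozygous inbred lines")
  }
  map <- f$map
  n <- n_ind(all_pop)
  ids <- all_pop$id
  gt <- t(all_pop$hap1)  # loci x individuals, 0/1
  gt_str <- matrix(c("0/0", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsintro",
    paste0("##contig=<ID=", seq_len(map$n_chr), ",length=",
           format(map$chr_lengths, scientific = FALSE, trim = TRUE), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- paste(map$chr,
                format(map$pos, scientific = FALSE, trim = TRUE),
                paste0("L", seq_len(map$n_loci)),
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  map_path <- paste0(path, ".map.tsv")
  utils::write.table(
    data.frame(chrom = map$chr, pos = map$pos,
               locus_id = paste0("L", seq_len(map$n_loci)),
               chrom_length = map$chr_lengths[map$chr]),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pop_path <- paste0(path, ".pops.tsv")
  utils::write.table(
    data.frame(sample = ids,
               population = rep(c("existing", "external"),
                                c(n_ind(f$existing), n_ind(f$external)))),
    pop_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = path, map = map_path, pops = pop_path))
}

#' Read founder genotypes from VCF
#'
#' Inverse of [write_founders()]. Heterozygous genotype records are
#' rejected: founders are inbred lines and a het call indicates a corrupt
#' or foreign file.
#'
#' @param path path of the VCF written by [write_founders()] (the sidecar
#'   `.map.tsv` and `.pops.tsv` files must sit next to it).
#' @return A `founder_set` (without frequency targets, which are a property
#'   of generation, not of the genotypes).
#' @export
read_founders <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ok <- gt %in% c("0/0", "1/1", "0|0", "1|1")
  if (!all(ok)) {
    bad <- gt[!ok][1]
    stop("founder VCF contains non-homozygous or missing genotype '",
         bad, "'; founders must be inbred lines")
  }
  allele <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
  h <- t(allele)  # individuals x loci
  map_df <- utils::read.table(paste0(path, ".map.tsv"), header = TRUE,
                              sep = "\t")
  chr_lengths <- tapply(map_df$chrom_length, map_df$chrom, `[`, 1)
  map <- locus_map(map_df$chrom, map_df$pos, as.numeric(chr_lengths))
  pops <- utils::read.table(paste0(path, ".pops.tsv"), header = TRUE,
                            sep = "\t")
  ids <- colnames(gt)
  lab <- pops$population[match(ids, pops$sample)]
  mk <- function(which_pop) {
    i <- which(lab == which_pop)
    population(h[i, , drop = FALSE], h[i, , drop = FALSE],
               id = ids[i], generation = "founder")
  }
  structure(list(existing = mk("existing"), external = mk("external"),
                 map = map, targets = NULL, favourable = NULL,
                 profile = NULL),
            class = "founder_set")
}
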