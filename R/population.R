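#' Population container
#'
#' A cohort of individuals carrying two haplotypes per locus (alleles coded
#' 0/1). Haplotypes are stored as two integer matrices (individuals x loci).
#'
#' @param hap1,hap2 integer matrices (n individuals x n loci), entries 0/1.
#' @param id character or integer individual ids (unique within the cohort).
#' @param family integer family label (the original cross); recycled.
#' @param generation character generation tag (e.g. "founder", "F1", "F2").
#' @param mother,father parent ids (NA for founders); recycled.
#' @return An object of class `population`.
#' @export
population <- function(hap1, hap2, id = NULL, family = NA_integer_,
                       generation = "founder",
                       mother = NA_character_, father = NA_character_) {
  hap1 <- as_hap_matrix(hap1)
  hap2 <- as_hap_matrix(hap2)
  if (!identical(dim(hap1), dim(hap2))) stop("haplotype matrices differ in shape")
  n <- nrow(hap1)
  if (is.null(id)) id <- as.character(seq_len(n))
  id <- as.character(id)
  if (length(id) != n) stop("id length must equal number of individuals")
  structure(
    list(hap1 = hap1, hap2 = hap2, id = id,
         family = rep_len(as.integer(family), n),
         generation = rep_len(as.character(generation), n),
         mother = rep_len(as.character(mother), n),
         father = rep_len(as.character(father), n)),
    class = "population"
  )
}

# internal fast constructor: trusts its inputs (already-validated integer
# 0/1 matrices and full-length metadata vectors)
new_population <- function(hap1, hap2, id, family, generation,
                           mother, father) {
  structure(list(hap1 = hap1, hap2 = hap2, id = id, family = family,
                 generation = generation, mother = mother,
                 father = father),
            class = "population")
}

as_hap_matrix <- function(h) {
  h <- as.matrix(h)
  storage.mode(h) <- "integer"
  if (length(h) && any(h != 0L & h != 1L)) stop("alleles must be coded 0/1")
  h
}

#' Number of individuals in a population
#' @param pop a `population`.
#' @export
n_ind <- function(pop) nrow(pop$hap1)

#' @export
print.population <- function(x, ...) {
  cat("population:", n_ind(x), "individuals x", ncol(x$hap1), "loci (",
      paste(unique(x$generation), collapse = "/"), ")\n")
  invisible(x)
}

#' Allele-1 dosage matrix
#'
#' @param pop a `population`.
#' @param loci optional locus indices (columns) to extract.
#' @return integer matrix (individuals x loci) with entries 0/1/2 counting
#'   copies of allele 1.
#' @export
dosage <- function(pop, loci = NULL) {
  if (is.null(loci)) return(pop$hap1 + pop$hap2)
  pop$hap1[, loci, drop = FALSE] + pop$hap2[, loci, drop = FALSE]
}

#' Subset a population by individual
#'
#' @param pop a `population`.
#' @param i individual indices (or logical vector).
#' @return A `population` with the selected individuals.
#' @export
subset_pop <- function(pop, i) {
  new_population(pop$hap1[i, , drop = FALSE], pop$hap2[i, , drop = FALSE],
                 id = pop$id[i], family = pop$family[i],
                 generation = pop$generation[i],
                 mother = pop$mother[i], father = pop$father[i])
}

#' Concatenate populations over individuals
#'
#' @param ... `population` objects with identical locus dimension.
#' @return A single `population`.
#' @export
bind_pops <- function(...) {
  pops <- list(...)
  pops <- pops[!vapply(pops, is.null, logical(1))]
  if (!length(pops)) stop("nothing to bind")
  new_population(do.call(rbind, lapply(pops, `[[`, "hap1")),
                 do.call(rbind, lapply(pops, `[[`, "hap2")),
                 id = unlist(lapply(pops, `[[`, "id")),
                 family = unlist(lapply(pops, `[[`, "family")),
                 generation = unlist(lapply(pops, `[[`, "generation")),
                 mother = unlist(lapply(pops, `[[`, "mother")),
                 father = unlist(lapply(pops, `[[`, "father")))
}

#' Per-individual heterozygosity
#'
#' Fraction of loci at which the two haplotypes differ, per individual.
#' @param pop a `population`.
#' @export
heterozygosity <- function(pop) rowMeans(pop$hap1 != pop$hap2)

#' Is every individual fully homozygous?
#' @param pop a `population`.
#' @export
is_inbred <- function(pop) all(pop$hap1 == pop$hap2)
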