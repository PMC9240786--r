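# Shared fixtures, built in code at test time.

# a small panel: 70 loci on 7 chromosomes
tiny_map <- function(n_loci = 70, n_chr = 7) {
  make_locus_map(n_loci, n_chr, chr_length = 1e6)
}

# a small two-trait architecture on a given panel
tiny_arch <- function(map = tiny_map(200, 7), N = 21, q = 0.7,
                      n_major = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_architecture(overlap_scheme(N = N, q = q), map,
                        n_major = n_major)
}

# a founder set matched to tiny_arch
tiny_founders <- function(arch, map, n_existing = 100, n_external = 20,
                          scenario = "high", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  generate_founders(n_existing, n_external, map, arch,
                    freq_profile(scenario))
}

# a population built directly from a haplotype matrix (inbred if hap2
# omitted)
pop_from <- function(hap1, hap2 = hap1, ...) {
  population(hap1, hap2, ...)
}

# a miniature programme (8 parents, 7 crosses) for fast cycle tests
mini_config <- function(...) {
  programme_config(n_parents = 8, n_primary = 4, n_best_primary = 3,
                   n_topcross = 2, n_backcross = 1, n_progeny = 2,
                   n_self_per_f1 = 2, n_f3_per_f2 = 2,
                   ssd_generations = 1, n_stage1 = 14, n_cycles = 3,
                   gs_start_cycle = 2, introgression_cycle = 2,
                   introgression_pct = 0.25, ...)
}

mini_scenario <- function(...) {
  scenario_config(n_existing = 30, n_external = 4, n_loci = 120,
                  n_chr = 7, scheme = overlap_scheme(N = 11),
                  n_major = 5, programme = mini_config(), ...)
}
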