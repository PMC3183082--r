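# Shared fixtures. Everything heavy is memoized and only computed when a
# test first asks for it, so light test files stay fast.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small standard population: 5 chromosomes x 90 cM, 5 cM framework map,
# 200 RILs — the simulated analogue of a biparental RIL mapping panel.
std_map <- function() memo("std_map", simulate_genetic_map(5, 90, 5))

std_geno <- function() {
  memo("std_geno", simulate_ril_genotypes(std_map(), 200, seed = 42))
}

std_grid <- function() {
  memo("std_grid", build_scan_grid(std_geno(), std_map(), step_cM = 1))
}

# Marker name nearest a (chrom, pos) — independent of the package's
# internal lookup.
nearest_marker_for_test <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, ]
  sub$marker[which.min(abs(sub$pos - pos))]
}

# Null trait specs: no planted QTL anywhere.
null_specs <- function(n, baseline_mean = 100, baseline_cv = 0.1) {
  lapply(seq_len(n), function(j) {
    trait_spec(sprintf("null%04d", j), baseline_mean, baseline_cv)
  })
}

# Genome-wide permutation threshold on the standard population, estimated
# from 100 null phenotypes x 300 permutations. Shared by the calibration and
# recovery tests (it is the expensive fixture).
std_threshold <- function() {
  memo("std_threshold", {
    tr <- simulate_replicated_traits(std_geno(), std_map(), null_specs(100),
                                     seed = 101)
    cvp <- cv_phenotypes(tr)
    permutation_threshold(cvp$cv_mean, std_grid(), n_traits = 100,
                          n_perm = 300, alpha = 0.05, seed = 202)
  })
}
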