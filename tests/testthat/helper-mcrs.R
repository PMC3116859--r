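# Shared fixtures: small parameter sets and hand-built lattices.

tiny_params <- function(...) {
  mcrs_params(L = 5L, generations = 0L, seed = 1L, ...)
}

# lattice holding the given phenotypes at explicit coordinates
lattice_with <- function(params, ...) {
  ph <- tibble::tibble(...)
  mcrs_lattice(params, ph)
}

# random feasible phenotype tibble at given coordinates (helper for oracles)
random_lattice <- function(params, occupancy = 0.5, seed = 1) {
  set.seed(seed)
  n <- round(occupancy * params$L^2)
  sites <- sample.int(params$L^2, n)
  ph <- sample_mutant(n, params)
  ph$row <- (sites - 1L) %% params$L + 1L
  ph$col <- (sites - 1L) %/% params$L + 1L
  mcrs_lattice(params, ph)
}

# run the compiled kernel directly from a prepared lattice (no re-init)
run_engine_from <- function(lat, params, generations, seed = 1,
                            record_at = generations,
                            regions = class_regions()) {
  mcrs:::.run_engine_cpp(
    occ = as.integer(lat$occ), e1 = as.numeric(lat$e1),
    e2 = as.numeric(lat$e2), k = as.numeric(lat$k),
    conf = as.integer(lat$conf), L = lat$L, par = unclass(params),
    generations = as.integer(generations), start_generation = 0L,
    record_at = as.integer(record_at),
    regions = c(regions$parasite_sum_max, regions$specialist_minor_max,
                regions$generalist_s_max),
    seed = as.double(seed)
  )
}

# independent evaluation of the replication-rate cap (kept separate from the
# package's own algebra on purpose: tests compare against this)
oracle_cap <- function(e1, e2, b, g, E_max = 10, k_min = 2, k_max = 2.5) {
  u <- (e1^b + e2^b)^(1 / b) / E_max
  ifelse(u > 1, NA_real_, k_min + (k_max - k_min) * (1 - u)^(1 / g))
}
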