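# Shared simulated datasets, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# measurement-noise-free dataset with no signature switching: exact truth
# recovery, zero switching fractions
clean_sim <- function() {
  cached("clean_sim", function() {
    simulate_regulome_evolution(
      sim_config(n_regions = 400, peak_jitter_sd = 0, replicate_dropout = 0,
                 noise_peak_rate = 0, switch_matrix = diag(3)),
      seed = 5
    )
  })
}

clean_regulome <- function() {
  cached("clean_regulome", function() build_regulome(clean_sim()$peaks))
}

# measurement-noise-free dataset under the default switching/loss dynamics
evolved_sim <- function() {
  cached("evolved_sim", function() {
    simulate_regulome_evolution(
      sim_config(n_regions = 600, peak_jitter_sd = 0, replicate_dropout = 0,
                 noise_peak_rate = 0),
      seed = 9
    )
  })
}

evolved_regulome <- function() {
  cached("evolved_regulome", function() build_regulome(evolved_sim()$peaks))
}

sim_map <- function(sim, a, b) {
  m <- sim$maps[sim$maps$species_a == a & sim$maps$species_b == b, ]
  if (nrow(m) > 0) return(m)
  regevo:::flip_alignment_map(
    sim$maps[sim$maps$species_a == b & sim$maps$species_b == a, ]
  )
}

species_regulome <- function(reg, s) reg[reg$species == s, ]

# bare interval tibble constructor for hand-built cases
iv <- function(start, end, seq_id = "chr1") {
  tibble::tibble(seq_id = seq_id, start = start, end = end)
}

# minimal regulome rows for hand-built evolution/triad cases
mk_regulome <- function(start, end, signature, species, tissue = "liver",
                        seq_id = "chr1", intra_dynamic = "none",
                        specificity = "tissue_specific") {
  tibble::tibble(
    seq_id = seq_id, start = start, end = end, signature = signature,
    species = species, tissue = tissue,
    region_id = paste(species, tissue, signature, seq_along(start), start, sep = "."),
    intra_dynamic = intra_dynamic, specificity = specificity
  )
}

# identity alignment map covering [0, len) of one sequence
identity_map <- function(sp_a, sp_b, len = 1e6, seq_id = "chr1") {
  tibble::tibble(species_a = sp_a, seq_a = seq_id, start_a = 0L, end_a = len,
                 species_b = sp_b, seq_b = seq_id, start_b = 0L, end_b = len)
}
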