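# small simulation used across module tests (fast; full-scale defaults are
# exercised in the acceptance suite)
tiny_config <- function(...) {
  base <- list(n_chromosomes = 4, chromosome_length_bp = 30000,
               fsr_length_bp = 6000, fsr_chromosome = 4, fsr_position = 0.7,
               n_fsr_genes = 3, marker_spacing_bp = 3000,
               scaffold_n50_target_bp = 8000, f1_size = 60,
               missing_rate = 0, genotyping_error_rate = 0)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

tiny_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_zw_genome(tiny_config())
    cache
  }
})
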