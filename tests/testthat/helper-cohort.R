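# Small cohort configurations used across test files. Group sizes keep the
# coupled group a realistic minority of the array so percentile
# normalization is not distorted by the coupled signal.

small_config <- function(seed = 1L, ...) {
  cohort_config(
    n_genes = 120,
    group_sizes = c(RP = 15, AA_biosynthesis = 20, PPP = 10),
    seed = seed,
    ...
  )
}

# Noise-free configuration: probes read the true expression exactly.
# Overrides in `...` win over the clean defaults.
clean_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, bias_amplitude = 0, replicate_noise_sd = 0,
         probe_noise_sd = 0, od_noise_cv = 0),
    list(...)
  )
  do.call(small_config, args)
}

# Hand-built probe table: one sample, `genes` genes, intensities given on
# the log2 scale as true value + linear bias slope * dx.
toy_probe_table <- function(truth, dx_list, bias_slope = 0,
                            sample_id = "s1") {
  rows <- purrr::map_dfr(names(truth), function(g) {
    dx <- dx_list[[g]]
    tibble::tibble(
      sample_id = sample_id,
      strain_id = "strainA",
      condition = "glucose",
      gene_id = g,
      probe_id = paste0(g, "_p", seq_along(dx)),
      placement_index = 1L,
      dx = as.integer(dx),
      intensity = truth[[g]] + bias_slope * dx,
      scale = "log2"
    )
  })
  rows
}
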