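test_that("array design satisfies the probe-layout invariants", {
  cfg <- small_config(seed = 2)
  design <- simulate_array_design(cfg)
  per_gene <- dplyr::count(design, gene_id)
  expect_true(all(per_gene$n %in% 3:4))
  expect_gte(mean(per_gene$n), 3)
  expect_lte(mean(per_gene$n), 4)
  expect_true(all(design$n_placements %in% 3:4))
  # every gene has exactly one probe at dx = 0, all dx distinct, nonnegative
  by_gene <- split(design$dx, design$gene_id)
  expect_true(all(vapply(by_gene, function(d) sum(d == 0) == 1L, logical(1))))
  expect_true(all(vapply(by_gene, anyDuplicated, integer(1)) == 0L))
  expect_true(all(design$dx >= 0))
})

test_that("a one-gene design is valid and generation is deterministic", {
  cfg <- cohort_config(n_genes = 1, group_sizes = c(AA_biosynthesis = 1),
                       seed = 0)
  design <- simulate_array_design(cfg)
  expect_true(nrow(design) %in% 3:4)
  expect_identical(sum(design$dx == 0), 1L)
  expect_identical(design, simulate_array_design(cfg))
  expect_error(cohort_config(n_genes = 0), class = "gx_config_error")
})

test_that("phenotypes respect the doubling-time identity and zero-CV case", {
  cfg <- small_config(seed = 3, growth_rate_cv = c(glucose = 0,
                                                   xylulose = 0.29))
  phen <- simulate_phenotypes(cfg)
  expect_equal(phen$doubling_time, log(2) / phen$growth_rate,
               tolerance = 1e-9)
  expect_true(all(phen$growth_rate > 0))
  expect_true(all(phen$ethanol >= 0))
  glc <- phen$growth_rate[phen$condition == "glucose"]
  expect_true(all(glc == glc[1]))  # cv = 0: identical rates
  expect_identical(table(phen$species[phen$condition == "glucose"]),
                   table(rep(c("cerevisiae", "paradoxus"), each = 12)))
  expect_error(cohort_config(growth_rate_cv = c(glucose = -0.1,
                                                xylulose = 0.2)),
               class = "gx_config_error")
})

test_that("large-cohort growth-rate dispersion matches the configured CV", {
  cfg <- cohort_config(
    n_strains_per_species = 2500,  # 5000 strains
    n_genes = 1, group_sizes = c(AA_biosynthesis = 1),
    growth_rate_cv = c(glucose = 0.13, xylulose = 0.29),
    coupling = tibble::tibble(group = character(), phenotype = character(),
                              condition = character(), rho = numeric()),
    seed = 1
  )
  phen <- simulate_phenotypes(cfg)
  glc <- phen$growth_rate[phen$condition == "glucose"]
  xyl <- phen$growth_rate[phen$condition == "xylulose"]
  expect_equal(sd(glc) / mean(glc), 0.13, tolerance = 0.01 / 0.13)
  expect_equal(sd(xyl) / mean(xyl), 0.29, tolerance = 0.02 / 0.29)
})

test_that("expression coupling construction hits the target correlation", {
  # degenerate couplings first: rho = 1 with no gene noise is exact
  cfg1 <- small_config(
    seed = 5, gene_noise_sd = 0,
    coupling = tibble::tibble(group = "AA_biosynthesis",
                              phenotype = "growth_rate",
                              condition = "xylulose", rho = 1)
  )
  co <- simulate_cohort(cfg1)
  lr <- compute_log_ratios(true_expression(co, "xylulose"),
                           true_expression(co, "glucose"))
  prof <- group_mean_profile(lr, co$groups, group = "AA_biosynthesis")
  res <- correlate_group_phenotype(prof, co$phenotypes,
                                   condition = "xylulose")
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_true(res$significant)

  # null coupling: group mean is uncorrelated noise
  r_null <- vapply(1:100, function(s) {
    cfg <- small_config(
      seed = s,
      coupling = tibble::tibble(group = character(), phenotype = character(),
                                condition = character(), rho = numeric())
    )
    phen <- simulate_phenotypes(cfg)
    expr <- simulate_expression(cfg, phen)
    prof <- group_mean_profile(true_expression(expr, "xylulose"),
                               cohort_groups(cfg), group = "AA_biosynthesis")
    correlate_group_phenotype(prof, phen, condition = "xylulose")$r
  }, numeric(1))
  expect_lt(abs(median(r_null)), 0.2)

  # Monte-Carlo recovery of rho = -0.79 at n = 24 strains
  r_rec <- vapply(1:200, function(s) {
    cfg <- small_config(seed = s)
    phen <- simulate_phenotypes(cfg)
    expr <- simulate_expression(cfg, phen)
    prof <- group_mean_profile(true_expression(expr, "xylulose"),
                               cohort_groups(cfg), group = "AA_biosynthesis")
    correlate_group_phenotype(prof, phen, condition = "xylulose")$r
  }, numeric(1))
  expect_equal(median(r_rec), -0.79, tolerance = 0.1 / 0.79)
})

test_that("unknown coupling group or phenotype is a configuration error", {
  expect_error(
    small_config(coupling = tibble::tibble(
      group = "nonexistent", phenotype = "growth_rate",
      condition = "xylulose", rho = 0.5)),
    class = "gx_config_error"
  )
  cfg <- small_config(coupling = tibble::tibble(
    group = "AA_biosynthesis", phenotype = "not_a_phenotype",
    condition = "xylulose", rho = 0.5))
  expect_error(simulate_expression(cfg), class = "gx_config_error")
})

test_that("probe intensities encode expression, 3' bias and determinism", {
  # no bias, no noise: every placement equals the true gene value
  cfg0 <- clean_config(seed = 6)
  phen <- simulate_phenotypes(cfg0)
  expr <- simulate_expression(cfg0, phen)
  design <- simulate_array_design(cfg0)
  probes <- simulate_probe_intensities(expr, design, cfg0)
  joined <- dplyr::inner_join(
    probes, expr, by = c("gene_id", "strain_id", "condition"))
  expect_equal(log2(joined$intensity), joined$expr, tolerance = 1e-12)

  # bias 1.0, no noise: probe at max dx reads exactly 1 log2 below P_last
  cfg1 <- clean_config(seed = 6, bias_amplitude = 1)
  probes1 <- simulate_probe_intensities(expr, design, cfg1)
  max_dx <- max(design$dx)
  far <- probes1[probes1$dx == max_dx, ][1, ]
  plast <- probes1[probes1$sample_id == far$sample_id &
                     probes1$gene_id == far$gene_id & probes1$dx == 0, ][1, ]
  expect_equal(log2(far$intensity), log2(plast$intensity) - 1,
               tolerance = 1e-12)

  # full noise, fixed seed: byte-identical rerun
  cfgn <- small_config(seed = 7)
  co1 <- simulate_cohort(cfgn)
  co2 <- simulate_cohort(cfgn)
  expect_identical(co1$probes, co2$probes)
  expect_identical(co1$curves, co2$curves)

  # genes missing from the design are a data error
  bad_design <- design[design$gene_id != "g0001", ]
  expect_error(simulate_probe_intensities(expr, bad_design, cfg0),
               class = "gx_data_error")
})

test_that("growth curves follow lag/exponential/saturation with OD > 0", {
  cfg <- clean_config(seed = 8)
  phen <- simulate_phenotypes(cfg)
  curves <- simulate_growth_curves(phen, cfg)
  expect_true(all(curves$od > 0))
  one <- curves[curves$strain_id == phen$strain_id[1] &
                  curves$condition == phen$condition[1], ]
  rate <- phen$growth_rate[1]
  # noiseless: log OD exactly linear inside the exponential window
  inwin <- one$time_h >= cfg$lag_h & one$od < cfg$od_max
  seg <- one[inwin, ]
  slopes <- diff(log(seg$od)) / diff(seg$time_h)
  expect_equal(slopes, rep(rate, length(slopes)), tolerance = 1e-9)
  # lag phase flat at the inoculum OD
  expect_true(all(one$od[one$time_h < cfg$lag_h] == cfg$od_start))
})

test_that("condition-set generator recovers the configured coupling", {
  r <- vapply(1:50, function(s) {
    cs <- simulate_condition_set(n_conditions = 100, rho = -0.36, seed = s)
    prof <- group_mean_profile(cs$expression, cs$groups,
                               group = "AA_biosynthesis")
    correlate_group_phenotype(prof, cs$phenotypes)$r
  }, numeric(1))
  expect_equal(median(r), -0.36, tolerance = 0.1 / 0.36)
  cs <- simulate_condition_set(n_conditions = 100, seed = 1)
  expect_identical(nrow(cs$phenotypes), 100L)
})
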