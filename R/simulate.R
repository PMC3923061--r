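#' Configure a synthetic strain cohort
#'
#' Builds the parameter object consumed by all `simulate_*()` generators.
#' Defaults mirror the study design the package targets: two species
#' (*S. cerevisiae* and *S. paradoxus*) with 12 strains each, grown on
#' glucose and on the pentose xylulose; inter-strain growth-rate dispersion
#' (std/mean) of 0.13 on glucose and 0.29 on xylulose; and a single built-in
#' coupling tying the amino-acid-biosynthesis (GCN4 regulon) group's mean
#' expression to growth rate on xylulose with target Pearson correlation
#' -0.79. All other group/phenotype couplings default to zero.
#'
#' Phenotypes and multiplicative noise are log-normal so that all rates,
#' intensities and OD values stay positive. The 3'-positional probe bias is
#' linear in `dx` (distance to the gene's 3'-most probe) with total amplitude
#' `bias_amplitude` log2 units over the widest `dx` on the array.
#'
#' @param n_strains_per_species strains per species (two species).
#' @param n_genes genes on the array; must cover `sum(group_sizes)`.
#' @param group_sizes named integer vector, genes per predefined group.
#' @param growth_rate_mean,growth_rate_cv named per-condition mean (1/h) and
#'   coefficient of variation of the true strain growth rates.
#' @param ethanol_mean,ethanol_cv named per-condition ethanol production
#'   mean (g/L) and CV.
#' @param coupling tibble with columns `group`, `phenotype`, `condition`,
#'   `rho`: target Pearson correlation between the group's per-strain mean
#'   expression and the phenotype in that condition.
#' @param bias_amplitude total 3' signal attenuation, log2 units over max dx.
#' @param replicate_noise_sd sd of per-placement noise, log2 units.
#' @param probe_noise_sd sd of the fixed per-probe sequence offset, log2.
#' @param expression_noise_sd sd of the coupled group-mean signal, log2.
#' @param gene_noise_sd sd of per-gene, per-strain biological noise, log2.
#' @param od_noise_cv CV of the multiplicative OD measurement noise.
#' @param lag_h,od_start,od_max growth-curve lag (h), inoculum OD and
#'   saturation OD.
#' @param sampling_interval_h OD sampling interval, hours (0.5 = 30 min).
#' @param duration_h total culture time simulated, hours.
#' @param max_dx widest probe-to-3'-probe distance drawn, base pairs.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression.
#' @param seed integer seed; fixes every generated artifact.
#' @return an object of class `cohort_config` (a named list).
#' @examples
#' cfg <- cohort_config(n_genes = 50, group_sizes = c(AA_biosynthesis = 10))
#' cohort <- simulate_cohort(cfg)
#' names(cohort)
#' @export
cohort_config <- function(n_strains_per_species = 12,
                          n_genes = 2000,
                          group_sizes = c(
                            RP = 120, Ribi = 150, ESR_induced = 180,
                            ESR_repressed = 180, proteasome = 90,
                            AA_biosynthesis = 120, GF = 40, PPP = 25,
                            TCA = 35, RC = 60
                          ),
                          growth_rate_mean = c(glucose = 0.45, xylulose = 0.15),
                          growth_rate_cv = c(glucose = 0.13, xylulose = 0.29),
                          ethanol_mean = c(glucose = 8, xylulose = 1),
                          ethanol_cv = c(glucose = 0.05, xylulose = 0.8),
                          coupling = tibble(
                            group = "AA_biosynthesis",
                            phenotype = "growth_rate",
                            condition = "xylulose",
                            rho = -0.79
                          ),
                          bias_amplitude = 1,
                          replicate_noise_sd = 0.1,
                          probe_noise_sd = 0.15,
                          expression_noise_sd = 0.5,
                          gene_noise_sd = 0.25,
                          od_noise_cv = 0.02,
                          lag_h = 2,
                          od_start = 0.05,
                          od_max = 1.5,
                          sampling_interval_h = 0.5,
                          duration_h = 30,
                          max_dx = 1200,
                          baseline_mean = 8,
                          baseline_sd = 1.5,
                          seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    abort("`n_genes` must be a positive integer", class = "gx_config_error")
  }
  if (n_strains_per_species < 1) {
    abort("`n_strains_per_species` must be >= 1", class = "gx_config_error")
  }
  if (any(growth_rate_mean <= 0)) {
    abort("`growth_rate_mean` must be positive", class = "gx_config_error")
  }
  cvs <- c(growth_rate_cv, ethanol_cv, od_noise_cv)
  if (any(cvs < 0)) {
    abort("coefficients of variation must be >= 0", class = "gx_config_error")
  }
  sds <- c(replicate_noise_sd, probe_noise_sd, expression_noise_sd,
           gene_noise_sd, bias_amplitude)
  if (any(sds < 0)) {
    abort("noise and bias amplitudes must be >= 0", class = "gx_config_error")
  }
  if (sum(group_sizes) > n_genes) {
    abort("`sum(group_sizes)` exceeds `n_genes`", class = "gx_config_error")
  }
  coupling <- as_tibble(coupling)
  if (nrow(coupling) > 0) {
    needed <- c("group", "phenotype", "condition", "rho")
    if (!all(needed %in% names(coupling))) {
      abort("`coupling` needs columns group, phenotype, condition, rho",
            class = "gx_config_error")
    }
    if (any(abs(coupling$rho) > 1)) {
      abort("coupling `rho` must lie in [-1, 1]", class = "gx_config_error")
    }
    unknown <- setdiff(coupling$group, names(group_sizes))
    if (length(unknown) > 0) {
      abort(paste0("coupling references unknown group(s): ",
                   paste(unknown, collapse = ", ")),
            class = "gx_config_error")
    }
  }
  conditions <- names(growth_rate_mean)
  if (is.null(conditions) || !setequal(conditions, names(growth_rate_cv))) {
    abort("growth-rate mean and cv must be named by the same conditions",
          class = "gx_config_error")
  }
  structure(
    list(
      n_strains_per_species = as.integer(n_strains_per_species),
      n_genes = as.integer(n_genes),
      group_sizes = group_sizes,
      conditions = conditions,
      growth_rate_mean = growth_rate_mean,
      growth_rate_cv = growth_rate_cv,
      ethanol_mean = ethanol_mean,
      ethanol_cv = ethanol_cv,
      coupling = coupling,
      bias_amplitude = bias_amplitude,
      replicate_noise_sd = replicate_noise_sd,
      probe_noise_sd = probe_noise_sd,
      expression_noise_sd = expression_noise_sd,
      gene_noise_sd = gene_noise_sd,
      od_noise_cv = od_noise_cv,
      lag_h = lag_h,
      od_start = od_start,
      od_max = od_max,
      sampling_interval_h = sampling_interval_h,
      duration_h = duration_h,
      max_dx = as.integer(max_dx),
      baseline_mean = baseline_mean,
      baseline_sd = baseline_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  strains:", 2L * x$n_strains_per_species,
      sprintf("(%d per species)", x$n_strains_per_species), "\n")
  cat("  genes:", x$n_genes, "in", length(x$group_sizes), "groups\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  if (nrow(x$coupling) > 0) {
    cat("  couplings:\n")
    for (i in seq_len(nrow(x$coupling))) {
      cat(sprintf("    %s ~ %s [%s]: rho = %.2f\n",
                  x$coupling$group[i], x$coupling$phenotype[i],
                  x$coupling$condition[i], x$coupling$rho[i]))
    }
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate the probe layout of a custom expression array
#'
#' Each gene receives 3 or 4 distinct probes (uniformly), one of which is the
#' gene's 3'-most probe (`dx = 0`); the remaining probes sit at distinct
#' distances `dx` drawn without replacement from `1:max_dx` base pairs. Each
#' probe is printed in 3 or 4 places on the array.
#'
#' @param config a [cohort_config()].
#' @return tibble with columns `gene_id`, `probe_id`, `dx`, `n_placements`.
#' @export
simulate_array_design <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed + 101L, {
    n <- config$n_genes
    ids <- gene_ids(n)
    n_probes <- sample(3:4, n, replace = TRUE)
    dx <- unlist(lapply(n_probes, function(np) {
      c(0L, sort(sample.int(config$max_dx, np - 1L)))
    }), use.names = FALSE)
    gene <- rep(ids, n_probes)
    design <- tibble(
      gene_id = gene,
      probe_id = paste0(gene, "_p", sequence(n_probes)),
      dx = as.integer(dx),
      n_placements = sample(3:4, sum(n_probes), replace = TRUE)
    )
    design
  })
}

#' Simulate per-strain growth phenotypes
#'
#' Draws each strain's true growth rate and ethanol production per condition
#' from log-normal distributions with the configured mean and CV. Doubling
#' time is `log(2) / growth_rate`.
#'
#' @param config a [cohort_config()].
#' @return tibble with `strain_id`, `species`, `condition`, `growth_rate`
#'   (1/h), `doubling_time` (h), `ethanol` (g/L).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed + 202L, {
    nsp <- config$n_strains_per_species
    strains <- tibble(
      strain_id = c(sprintf("cer_%02d", seq_len(nsp)),
                    sprintf("par_%02d", seq_len(nsp))),
      species = rep(c("cerevisiae", "paradoxus"), each = nsp)
    )
    out <- purrr::map_dfr(config$conditions, function(cond) {
      n <- nrow(strains)
      rate <- rlnorm_cv(n, config$growth_rate_mean[[cond]],
                        config$growth_rate_cv[[cond]])
      eth <- rlnorm_cv(n, config$ethanol_mean[[cond]],
                       config$ethanol_cv[[cond]])
      mutate(strains,
             condition = cond,
             growth_rate = rate,
             doubling_time = log(2) / rate,
             ethanol = eth)
    })
    out
  })
}

#' Simulate true gene expression with configured phenotype couplings
#'
#' Generates the ground-truth log2 expression of every gene in every strain
#' and condition. For each configured coupling `(group, phenotype, condition,
#' rho)` the group's per-strain mean expression shift is constructed as
#' `s * (rho * z + sqrt(1 - rho^2) * eps)` with `z` the standardized
#' phenotype, `eps` independent standard normal and `s = expression_noise_sd`,
#' so that the expected Pearson correlation between group mean expression and
#' phenotype equals `rho`. Genes outside coupled groups carry independent
#' noise only.
#'
#' @param config a [cohort_config()].
#' @param phenotypes output of [simulate_phenotypes()] (regenerated when
#'   omitted).
#' @return long tibble with `gene_id`, `strain_id`, `condition`, `expr`
#'   (true log2 expression).
#' @export
simulate_expression <- function(config, phenotypes = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(phenotypes)) phenotypes <- simulate_phenotypes(config)
  groups <- cohort_groups(config)
  withr::with_seed(config$seed + 303L, {
    ids <- gene_ids(config$n_genes)
    baseline <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    names(baseline) <- ids
    out <- purrr::map_dfr(config$conditions, function(cond) {
      phen_c <- filter(phenotypes, .data$condition == cond)
      strains <- phen_c$strain_id
      ns <- length(strains)
      # gene x strain noise around the per-gene baseline
      e <- matrix(rnorm(config$n_genes * ns, 0, config$gene_noise_sd),
                  nrow = config$n_genes)
      e <- e + baseline
      rownames(e) <- ids
      colnames(e) <- strains
      cpl <- filter(config$coupling, .data$condition == cond)
      for (i in seq_len(nrow(cpl))) {
        ph <- phen_c[[cpl$phenotype[i]]]
        if (is.null(ph)) {
          abort(paste0("coupling references unknown phenotype: ",
                       cpl$phenotype[i]), class = "gx_config_error")
        }
        z <- as.numeric(scale(ph))
        eps <- rnorm(ns)
        rho <- cpl$rho[i]
        shift <- config$expression_noise_sd *
          (rho * z + sqrt(1 - rho^2) * eps)
        members <- groups$gene_id[groups$group == cpl$group[i]]
        e[members, ] <- e[members, , drop = FALSE] +
          rep(shift, each = length(members))
      }
      tibble(
        gene_id = rep(ids, ns),
        strain_id = rep(strains, each = config$n_genes),
        condition = cond,
        expr = as.vector(e)
      )
    })
    out
  })
}

#' Gene-group membership implied by a cohort configuration
#'
#' Genes are assigned to the configured groups in order: the first
#' `group_sizes[1]` gene ids form the first group, and so on; remaining genes
#' belong to no group.
#'
#' @param config a [cohort_config()].
#' @return tibble with columns `group`, `gene_id`.
#' @export
cohort_groups <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sizes <- config$group_sizes
  ids <- gene_ids(config$n_genes)
  tibble(
    group = rep(names(sizes), sizes),
    gene_id = ids[seq_len(sum(sizes))]
  )
}

#' Simulate probe-level array intensities
#'
#' Expands true expression to one record per probe placement. On the log2
#' scale each placement reads
#' `expr - bias_amplitude * dx / max(dx) + probe offset + replicate noise`:
#' signal attenuates linearly with distance from the gene's 3'-most probe
#' (mimicking reverse-transcription fall-off), each probe carries a fixed
#' sequence offset, and each placement adds independent noise. Intensities
#' are returned on the linear scale.
#'
#' @param expr long true-expression tibble from [simulate_expression()].
#' @param design array layout from [simulate_array_design()].
#' @param config a [cohort_config()].
#' @return probe-level tibble with columns `sample_id`, `strain_id`,
#'   `condition`, `gene_id`, `probe_id`, `placement_index`, `dx`,
#'   `intensity`, `scale` (`"linear"`).
#' @export
simulate_probe_intensities <- function(expr, design, config) {
  stopifnot(inherits(config, "cohort_config"))
  missing_genes <- setdiff(unique(expr$gene_id), design$gene_id)
  if (length(missing_genes) > 0) {
    abort(paste0("genes absent from the array design: ",
                 paste(head(missing_genes, 5), collapse = ", ")),
          class = "gx_data_error")
  }
  withr::with_seed(config$seed + 404L, {
    probe_offset <- setNames(
      rnorm(nrow(design), 0, config$probe_noise_sd), design$probe_id)
    max_dx <- max(design$dx)
    bias <- if (max_dx > 0) -config$bias_amplitude * design$dx / max_dx
            else rep(0, nrow(design))
    placements <- design[rep(seq_len(nrow(design)), design$n_placements),
                         c("gene_id", "probe_id", "dx")]
    placements$placement_index <- sequence(design$n_placements)
    placements$bias <- rep(bias, design$n_placements)
    placements$offset <- unname(probe_offset[placements$probe_id])

    samples <- distinct(expr, .data$strain_id, .data$condition)
    long <- tidyr::expand_grid(samples, placements)
    long <- inner_join(long, expr,
                       by = c("strain_id", "condition", "gene_id"))
    log2i <- long$expr + long$bias + long$offset +
      rnorm(nrow(long), 0, config$replicate_noise_sd)
    tibble(
      sample_id = paste(long$strain_id, long$condition, sep = "."),
      strain_id = long$strain_id,
      condition = long$condition,
      gene_id = long$gene_id,
      probe_id = long$probe_id,
      placement_index = long$placement_index,
      dx = long$dx,
      intensity = 2^log2i,
      scale = "linear"
    )
  })
}

#' Simulate optical-density growth curves
#'
#' Three-phase deterministic kernel — flat lag, exponential growth at the
#' strain's true rate, saturation at `od_max` — sampled every
#' `sampling_interval_h` hours and multiplied by log-normal noise with CV
#' `od_noise_cv` (unit mean, so OD stays positive and unbiased).
#'
#' @param phenotypes tibble from [simulate_phenotypes()].
#' @param config a [cohort_config()].
#' @return long tibble with `strain_id`, `condition`, `time_h`, `od`.
#' @export
simulate_growth_curves <- function(phenotypes, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(phenotypes$growth_rate <= 0)) {
    abort("growth rates must be positive", class = "gx_data_error")
  }
  withr::with_seed(config$seed + 505L, {
    tt <- seq(0, config$duration_h, by = config$sampling_interval_h)
    purrr::pmap_dfr(
      phenotypes[c("strain_id", "condition", "growth_rate")],
      function(strain_id, condition, growth_rate) {
        od <- growth_curve_kernel(tt, growth_rate, config$lag_h,
                                  config$od_start, config$od_max)
        noise <- rlnorm_cv(length(tt), 1, config$od_noise_cv)
        tibble(strain_id = strain_id, condition = condition,
               time_h = tt, od = od * noise)
      }
    )
  })
}

growth_curve_kernel <- function(t, rate, lag, od0, od_max) {
  od <- ifelse(t < lag, od0, od0 * exp(rate * (t - lag)))
  pmin(od, od_max)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator under one configuration: array design, strain
#' phenotypes, ground-truth expression, probe-level intensities and growth
#' curves, together with the group membership and a `truth` record of the
#' quantities the analysis pipeline should recover. Fixing `config$seed`
#' reproduces every artifact exactly.
#'
#' @param config a [cohort_config()].
#' @return object of class `yeast_cohort`: list with elements `config`,
#'   `design`, `phenotypes`, `groups`, `expression`, `probes`, `curves`,
#'   `truth`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_genes = 60, group_sizes = c(AA_biosynthesis = 20), seed = 7
#' ))
#' cohort$phenotypes
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  design <- simulate_array_design(config)
  phenotypes <- simulate_phenotypes(config)
  expression <- simulate_expression(config, phenotypes)
  probes <- simulate_probe_intensities(expression, design, config)
  curves <- simulate_growth_curves(phenotypes, config)
  truth <- list(
    coupling = config$coupling,
    growth_rate_cv = as.list(config$growth_rate_cv),
    growth_rate_mean = as.list(config$growth_rate_mean),
    bias_amplitude = config$bias_amplitude,
    seed = config$seed
  )
  structure(
    list(config = config, design = design, phenotypes = phenotypes,
         groups = cohort_groups(config), expression = expression,
         probes = probes, curves = curves, truth = truth),
    class = "yeast_cohort"
  )
}

#' @export
print.yeast_cohort <- function(x, ...) {
  cat("<yeast_cohort>\n")
  cat(sprintf("  %d strains x %d conditions, %d genes, %d probe placements\n",
              length(unique(x$phenotypes$strain_id)),
              length(x$config$conditions), x$config$n_genes, nrow(x$probes)))
  cat(sprintf("  seed %d\n", x$config$seed))
  invisible(x)
}

#' True expression of one condition as a wide matrix tibble
#'
#' @param cohort a `yeast_cohort` or the long expression tibble.
#' @param condition condition name to extract.
#' @return wide tibble: `gene_id` plus one column per strain.
#' @export
true_expression <- function(cohort, condition) {
  expr <- if (inherits(cohort, "yeast_cohort")) cohort$expression else cohort
  cond <- condition
  wide <- expr %>%
    filter(.data$condition == cond) %>%
    select("gene_id", "strain_id", "expr") %>%
    tidyr::pivot_wider(names_from = "strain_id", values_from = "expr")
  if (ncol(wide) == 1L) {
    abort(paste0("no expression data for condition: ", condition),
          class = "gx_data_error")
  }
  wide
}

#' Simulate a deletion-mutant-style condition panel
#'
#' Emulates a compendium of `n_conditions` perturbations (gene deletions or
#' drug treatments) in which a single gene group's induction is coupled to
#' the measured growth rate with target Pearson correlation `rho`, using the
#' same coupling construction as [simulate_expression()]. Useful for testing
#' correlation recovery on condition sets rather than strain panels.
#'
#' @param n_conditions number of perturbation conditions.
#' @param rho target Pearson correlation between the group mean induction
#'   and growth rate.
#' @param group_size genes in the coupled group.
#' @param n_genes total genes (the rest are uncoupled noise).
#' @param phenotype_mean,phenotype_cv log-normal growth-rate distribution of
#'   the mutants (relative to wild type).
#' @param expression_noise_sd,gene_noise_sd signal and per-gene noise, log2.
#' @param seed integer seed.
#' @return list with `phenotypes` (tibble: `strain_id`, `condition`,
#'   `growth_rate`), `expression` (wide tibble, log2 induction values),
#'   `groups` (tibble: `group`, `gene_id`).
#' @export
simulate_condition_set <- function(n_conditions = 100,
                                   rho = -0.36,
                                   group_size = 100,
                                   n_genes = 300,
                                   phenotype_mean = 0.85,
                                   phenotype_cv = 0.25,
                                   expression_noise_sd = 0.5,
                                   gene_noise_sd = 0.25,
                                   seed = 1L) {
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1]", class = "gx_config_error")
  cfg <- cohort_config(
    n_strains_per_species = ceiling(n_conditions / 2),
    n_genes = n_genes,
    group_sizes = c(AA_biosynthesis = group_size),
    growth_rate_mean = c(perturbation = phenotype_mean),
    growth_rate_cv = c(perturbation = phenotype_cv),
    ethanol_mean = c(perturbation = 1),
    ethanol_cv = c(perturbation = 0),
    coupling = tibble(group = "AA_biosynthesis", phenotype = "growth_rate",
                      condition = "perturbation", rho = rho),
    expression_noise_sd = expression_noise_sd,
    gene_noise_sd = gene_noise_sd,
    baseline_mean = 0,  # induction scale: log-ratios around zero
    baseline_sd = 0.5,
    seed = seed
  )
  phen <- simulate_phenotypes(cfg)
  # trim to exactly n_conditions pseudo-strains and relabel as conditions
  keep <- phen$strain_id[seq_len(n_conditions)]
  phen <- phen %>%
    filter(.data$strain_id %in% keep) %>%
    mutate(strain_id = sprintf("cond_%03d", match(.data$strain_id, keep)))
  expr <- simulate_expression(cfg, phenotypes = phen)
  wide <- true_expression(expr, "perturbation")
  list(
    phenotypes = select(phen, "strain_id", "condition", "growth_rate"),
    expression = wide,
    groups = cohort_groups(cfg)
  )
}
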