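#' Pearson correlation with pairwise-complete observations
#'
#' Standard Pearson r over the pairs where both values are observed, with a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; missing values are dropped
#'   pairwise.
#' @return one-row tibble with `r`, `p_value`, `n`.
#' @export
cor_pearson <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` lengths differ", class = "gx_data_error")
  }
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    abort("need >= 3 complete pairs", class = "gx_data_error")
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "gx_data_error")
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(r = r, p_value = p, n = n)
}

#' Correlate group expression profiles with a strain phenotype
#'
#' Joins per-strain group mean-expression profiles to a phenotype table and
#' computes one Pearson correlation per group, flagged as significant at
#' `alpha` (two-sided t test).
#'
#' @param profiles long tibble from [group_mean_profile()] (`group`,
#'   `strain_id`, `mean_expr`).
#' @param phenotypes tibble with `strain_id`, the phenotype column, and
#'   optionally `condition`.
#' @param phenotype name of the phenotype column (e.g. `"growth_rate"`,
#'   `"ethanol"`).
#' @param condition if given, `phenotypes` is filtered to this condition
#'   first.
#' @param alpha significance threshold on the p-value.
#' @return tibble with `group`, `phenotype`, `r`, `n`, `p_value`,
#'   `significant`.
#' @export
correlate_group_phenotype <- function(profiles, phenotypes,
                                      phenotype = "growth_rate",
                                      condition = NULL, alpha = 0.01) {
  if (!phenotype %in% names(phenotypes)) {
    abort(paste0("phenotype column not found: ", phenotype),
          class = "gx_data_error")
  }
  if (!is.null(condition)) {
    cond <- condition
    phenotypes <- filter(phenotypes, .data$condition == cond)
  }
  if (anyDuplicated(phenotypes$strain_id)) {
    abort("phenotype table has duplicate strains; pass `condition`",
          class = "gx_data_error")
  }
  joined <- inner_join(profiles,
                       phenotypes[c("strain_id", phenotype)],
                       by = "strain_id")
  purrr::map_dfr(unique(joined$group), function(g) {
    d <- joined[joined$group == g, ]
    res <- cor_pearson(d$mean_expr, d[[phenotype]])
    tibble(group = g, phenotype = phenotype, r = res$r, n = res$n,
           p_value = res$p_value, significant = res$p_value < alpha)
  })
}

#' Systematic scan of gene groups against a phenotype
#'
#' Correlates every group profile with the phenotype, ranks the results by
#' descending `|r|` (ties broken by group name) and flags the single
#' strongest significantly anti-correlated group. A Bonferroni-adjusted
#' p-value column is included for transparency; significance itself is
#' called at the unadjusted `alpha`.
#'
#' @inheritParams correlate_group_phenotype
#' @return tibble of class `group_scan`: `group`, `phenotype`, `r`, `n`,
#'   `p_value`, `p_bonferroni`, `significant`, `top_anticorrelated`.
#' @export
scan_groups <- function(profiles, phenotypes, phenotype = "growth_rate",
                        condition = NULL, alpha = 0.01) {
  res <- correlate_group_phenotype(profiles, phenotypes,
                                   phenotype = phenotype,
                                   condition = condition, alpha = alpha)
  res <- res %>%
    mutate(p_bonferroni = pmin(1, .data$p_value * dplyr::n())) %>%
    arrange(desc(abs(.data$r)), .data$group)
  anti <- res$significant & res$r < 0
  res$top_anticorrelated <- FALSE
  if (any(anti)) {
    res$top_anticorrelated[which(anti)[1]] <- TRUE  # rows sorted by |r|
  }
  class(res) <- c("group_scan", class(res))
  res
}

#' Classify pathway genes by phenotype correlation and induction
#'
#' Mirrors the two-way labelling used for pentose-phosphate-pathway genes:
#' each gene gets a correlation class (`positive` if `r > c_thresh`,
#' `negative` if `r < -c_thresh`, else `none`) and an induction class (`+`
#' if the mean log-difference exceeds `d_thresh`, `-` below `-d_thresh`,
#' else `0`). Values exactly at a threshold classify as `none`/`0`.
#'
#' @param data tibble with columns `gene_id`, `r` (Pearson correlation with
#'   the phenotype, in `[-1, 1]`) and `mean_log_diff` (mean log2 difference
#'   between conditions).
#' @param c_thresh correlation threshold (default 0.3).
#' @param d_thresh log-difference threshold (default 0.2).
#' @return the input tibble with `correlation_class` and `induction_class`
#'   columns added.
#' @export
classify_ppp_genes <- function(data, c_thresh = 0.3, d_thresh = 0.2) {
  if (!all(c("r", "mean_log_diff") %in% names(data))) {
    abort("`data` needs columns r and mean_log_diff", class = "gx_data_error")
  }
  if (any(abs(data$r) > 1, na.rm = TRUE)) {
    abort("correlations must lie in [-1, 1]", class = "gx_data_error")
  }
  data %>%
    mutate(
      correlation_class = case_when(
        .data$r > c_thresh ~ "positive",
        .data$r < -c_thresh ~ "negative",
        TRUE ~ "none"
      ),
      induction_class = case_when(
        .data$mean_log_diff > d_thresh ~ "+",
        .data$mean_log_diff < -d_thresh ~ "-",
        TRUE ~ "0"
      )
    )
}

#' Correlate sample expression profiles with reference condition profiles
#'
#' Pearson correlation between each sample's gene profile and each
#' reference condition's profile over their shared genes
#' (pairwise-complete), e.g. to ask which reference carbon source each
#' strain's transcriptome resembles most.
#'
#' @param expr wide expression tibble (`gene_id` + sample columns).
#' @param references wide tibble (`gene_id` + one column per reference
#'   condition).
#' @return long tibble with `sample`, `reference`, `r`, `n`.
#' @export
profile_similarity <- function(expr, references) {
  me <- expr_to_matrix(expr)
  mr <- expr_to_matrix(references)
  genes <- intersect(rownames(me), rownames(mr))
  if (length(genes) < 3) {
    abort("fewer than 3 shared genes between matrix and references",
          class = "gx_data_error")
  }
  me <- me[genes, , drop = FALSE]
  mr <- mr[genes, , drop = FALSE]
  out <- tidyr::expand_grid(sample = colnames(me), reference = colnames(mr))
  purrr::pmap_dfr(out, function(sample, reference) {
    x <- me[, sample]; y <- mr[, reference]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      abort(paste0("fewer than 3 shared observed genes for pair ", sample,
                   " / ", reference), class = "gx_data_error")
    }
    res <- cor_pearson(x, y)
    tibble(sample = sample, reference = reference, r = res$r, n = res$n)
  })
}

#' Classify conditions by ribosomal-protein versus amino-acid modulation
#'
#' Conditions fall into a bimodal pattern: some modulate ribosomal-protein
#' (RP) expression while leaving amino-acid-biosynthesis (AA) genes
#' unchanged, others the reverse. The quadrant rule labels each condition
#' by whether `|delta_rp|` and/or `|delta_aa|` exceed `theta` (log2 units).
#'
#' @param data tibble with columns `delta_rp` and `delta_aa` (mean log2
#'   expression changes of the two groups).
#' @param theta modulation threshold, log2 units.
#' @return the input tibble with a `class` column:
#'   `"RP-modulated"`, `"AA-modulated"`, `"both"` or `"neither"`.
#' @export
classify_condition_bimodal <- function(data, theta = 0.5) {
  if (!all(c("delta_rp", "delta_aa") %in% names(data))) {
    abort("`data` needs columns delta_rp and delta_aa",
          class = "gx_data_error")
  }
  if (any(!is.finite(data$delta_rp)) || any(!is.finite(data$delta_aa))) {
    abort("delta values must be finite", class = "gx_data_error")
  }
  data %>%
    mutate(class = case_when(
      abs(.data$delta_rp) > theta & abs(.data$delta_aa) > theta ~ "both",
      abs(.data$delta_rp) > theta ~ "RP-modulated",
      abs(.data$delta_aa) > theta ~ "AA-modulated",
      TRUE ~ "neither"
    ))
}
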