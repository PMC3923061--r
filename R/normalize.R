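#' Median intensity over replicate probe placements
#'
#' Each probe is printed several times on the array; this collapses the
#' placements to one record per sample and probe by taking the median
#' intensity (midpoint of the two central values for even counts).
#'
#' @param probes probe-level tibble (see [simulate_probe_intensities()] for
#'   the column contract).
#' @return tibble with one row per sample x probe; `placement_index` is
#'   dropped.
#' @export
median_over_replicates <- function(probes) {
  if (!is.data.frame(probes) || nrow(probes) == 0) {
    abort("probe table is empty", class = "gx_data_error")
  }
  keys <- intersect(
    c("sample_id", "strain_id", "condition", "gene_id", "probe_id", "dx",
      "scale"),
    names(probes)
  )
  probes %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(intensity = median(.data$intensity), .groups = "drop")
}

# Put probe intensities on the log2 scale if they are not already.
probes_to_log2 <- function(probes) {
  if (!"scale" %in% names(probes)) {
    abort("probe table needs a `scale` column (linear or log2)",
          class = "gx_data_error")
  }
  lin <- probes$scale == "linear"
  if (any(lin)) {
    if (any(probes$intensity[lin] <= 0)) {
      abort("linear-scale intensities must be positive",
            class = "gx_data_error")
    }
    probes$intensity[lin] <- log2(probes$intensity[lin])
    probes$scale[lin] <- "log2"
  }
  probes
}

#' Positional-bias coordinates: probe distance vs log-ratio to the 3' probe
#'
#' For every sample and gene, the probe closest to the gene's 3' end
#' (`dx = 0`, "P_last") is the reference: each probe contributes the pair
#' `(dx, dy)` with `dy = log2(intensity) - log2(intensity of P_last)`.
#' P_last itself contributes `(0, 0)`. Genes lacking a `dx = 0` probe in a
#' sample are skipped with a warning.
#'
#' @param probes one-row-per-probe tibble (after
#'   [median_over_replicates()]); converted to log2 if on the linear scale.
#' @return tibble with `sample_id`, `gene_id`, `probe_id`, `dx`, `dy`.
#' @export
compute_dx_dy <- function(probes) {
  probes <- probes_to_log2(median_like(probes))
  plast <- probes %>%
    filter(.data$dx == 0) %>%
    select("sample_id", "gene_id", plast_intensity = "intensity")
  joined <- left_join(probes, plast, by = c("sample_id", "gene_id"))
  orphan <- is.na(joined$plast_intensity)
  if (any(orphan)) {
    skipped <- unique(joined$gene_id[orphan])
    warn(paste0(length(skipped),
                " gene(s) lack a dx = 0 probe in some sample and were ",
                "skipped (e.g. ", head(skipped, 1), ")"))
    joined <- joined[!orphan, ]
  }
  joined %>%
    mutate(dy = .data$intensity - .data$plast_intensity) %>%
    select("sample_id", "gene_id", "probe_id", "dx", "dy")
}

# Guard that the table looks like one row per sample x probe.
median_like <- function(probes) {
  if (!all(c("sample_id", "gene_id", "probe_id", "dx", "intensity")
           %in% names(probes))) {
    abort("probe table is missing required columns", class = "gx_data_error")
  }
  probes
}

#' Fit the 3'-positional bias trend by Lowess
#'
#' Locally weighted regression (`stats::lowess`, 3 robustifying iterations)
#' of `dy` on `dx`, evaluated on the sorted unique `dx` grid and anchored so
#' that the offset at `dx = 0` is exactly zero (P_last is its own
#' reference). Between grid points the curve interpolates linearly; beyond
#' the grid it is constant.
#'
#' @param pairs tibble of `(dx, dy)` pairs from [compute_dx_dy()]; pool
#'   across genes within a sample (or across samples) for a stable fit.
#' @param span Lowess smoother span (fraction of points), in (0, 1].
#' @return object of class `bias_curve` with fields `dx`, `offset`, `span`
#'   and the training pairs.
#' @export
fit_positional_bias <- function(pairs, span = 0.3) {
  if (!all(c("dx", "dy") %in% names(pairs))) {
    abort("`pairs` needs columns dx and dy", class = "gx_data_error")
  }
  pairs <- pairs[is.finite(pairs$dx) & is.finite(pairs$dy), ]
  if (nrow(pairs) < 10) {
    abort(paste0("need >= 10 (dx, dy) pairs to fit the positional bias; ",
                 "pool pairs across samples and retry"),
          class = "gx_fit_error")
  }
  if (span <= 0 || span > 1) {
    abort("`span` must lie in (0, 1]", class = "gx_config_error")
  }
  lw <- lowess(pairs$dx, pairs$dy, f = span, iter = 3)
  # lowess returns fits at every (sorted) x; average duplicates per unique dx
  fit <- tapply(lw$y, lw$x, mean)
  grid <- as.numeric(names(fit))
  offset <- as.numeric(fit)
  at0 <- approx(grid, offset, xout = 0, rule = 2, ties = "ordered")$y
  structure(
    list(dx = grid, offset = offset - at0, span = span,
         pairs = as_tibble(pairs[c("dx", "dy")])),
    class = "bias_curve"
  )
}

#' @export
print.bias_curve <- function(x, ...) {
  cat("<bias_curve>\n")
  cat(sprintf("  %d grid points, dx in [%g, %g], span %.2f\n",
              length(x$dx), min(x$dx), max(x$dx), x$span))
  cat(sprintf("  offset range [%.3f, %.3f] log2\n",
              min(x$offset), max(x$offset)))
  invisible(x)
}

#' Evaluate a fitted bias curve at new probe distances
#'
#' @param object a `bias_curve`.
#' @param dx numeric distances (bp).
#' @param ... unused.
#' @return log2 offsets; linear interpolation inside the fitted grid,
#'   constant extrapolation outside.
#' @export
predict.bias_curve <- function(object, dx, ...) {
  if (length(object$dx) == 1L) {
    return(rep(object$offset, length(dx)))
  }
  approx(object$dx, object$offset, xout = dx, rule = 2, ties = "ordered")$y
}

#' Remove the fitted 3'-positional trend from probe intensities
#'
#' Subtracts the bias-curve offset at each probe's `dx` from its log2
#' intensity, so that corrected intensities of a gene's probes no longer
#' depend on their distance from the 3' end. Probes at `dx = 0` are
#' unchanged.
#'
#' @param probes one-row-per-probe tibble; converted to log2 if linear.
#' @param curve a [fit_positional_bias()] result, or a named list of curves
#'   keyed by `sample_id` for per-sample correction.
#' @return the probe tibble with corrected log2 intensities.
#' @export
apply_bias_correction <- function(probes, curve) {
  probes <- probes_to_log2(median_like(probes))
  if (inherits(curve, "bias_curve")) {
    probes$intensity <- probes$intensity - predict(curve, probes$dx)
    return(probes)
  }
  if (!is.list(curve) || is.null(names(curve))) {
    abort("`curve` must be a bias_curve or a named list of them",
          class = "gx_data_error")
  }
  missing_s <- setdiff(unique(probes$sample_id), names(curve))
  if (length(missing_s) > 0) {
    abort(paste0("no bias curve for sample(s): ",
                 paste(head(missing_s, 3), collapse = ", ")),
          class = "gx_data_error")
  }
  probes %>%
    group_by(.data$sample_id) %>%
    dplyr::group_modify(function(d, key) {
      cv <- curve[[key$sample_id]]
      mutate(d, intensity = .data$intensity - predict(cv, .data$dx))
    }) %>%
    ungroup()
}

#' Summarize corrected probes to one value per gene and sample
#'
#' Per-gene intensity is the median of the gene's corrected probe log2
#' intensities in each sample. Genes with no probes in a sample come out
#' missing.
#'
#' @param probes corrected probe tibble (log2 scale).
#' @return wide expression tibble: `gene_id` plus one column per sample.
#' @export
summarize_gene_intensity <- function(probes) {
  probes <- probes_to_log2(median_like(probes))
  long <- probes %>%
    group_by(.data$sample_id, .data$gene_id) %>%
    summarise(value = median(.data$intensity), .groups = "drop")
  tidyr::pivot_wider(long, names_from = "sample_id", values_from = "value") %>%
    arrange(.data$gene_id)
}

#' Percentile (quantile) normalization across samples
#'
#' Gives every sample the same value distribution: each column's
#' rank-ordered values are replaced by the across-column mean of the sorted
#' values at that rank. Missing entries are excluded from ranking and stay
#' missing; ties receive the mean of the reference values their ranks span.
#' Columns with different numbers of observed values are matched by linear
#' interpolation of the reference distribution on fractional ranks.
#'
#' @param expr wide expression tibble (`gene_id` + sample columns).
#' @return wide tibble of the same shape with normalized values.
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                     s1 = c(1, 2, 3), s2 = c(10, 20, 30))
#' percentile_normalize(m)  # both columns become 5.5, 11, 16.5
#' @export
percentile_normalize <- function(expr) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) {
    abort("percentile normalization needs >= 2 samples",
          class = "gx_data_error")
  }
  nobs <- colSums(!is.na(m))
  if (any(nobs < 2)) {
    bad <- colnames(m)[nobs < 2][1]
    abort(paste0("sample has fewer than 2 observed values: ", bad),
          class = "gx_data_error")
  }
  nmax <- max(nobs)
  grid <- if (nmax == 1) 0 else (seq_len(nmax) - 1) / (nmax - 1)
  sorted <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[, j])
    if (length(v) == nmax) v
    else approx((seq_along(v) - 1) / (length(v) - 1), v, xout = grid,
                ties = "ordered")$y
  }, numeric(nmax))
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    idx <- which(!is.na(m[, j]))
    nj <- length(idx)
    refj <- if (nj == nmax) ref
            else approx(grid, ref, xout = (seq_len(nj) - 1) / (nj - 1),
                        ties = "ordered")$y
    ord <- order(m[idx, j])
    vals_sorted <- m[idx, j][ord]
    # ties: average the reference values the tied ranks span
    assigned <- stats::ave(refj, match(vals_sorted, vals_sorted))
    out[idx[ord], j] <- assigned
  }
  matrix_to_expr(out) %>% mutate(gene_id = expr$gene_id)
}

#' Full probe-to-gene normalization pipeline
#'
#' Composes the stages of the custom two-colour normalization:
#' replicate medians ([median_over_replicates()]), positional-bias
#' coordinates ([compute_dx_dy()]), Lowess trend fit pooled across genes
#' ([fit_positional_bias()]), bias correction
#' ([apply_bias_correction()]), per-gene median summarization
#' ([summarize_gene_intensity()]) and percentile normalization
#' ([percentile_normalize()]).
#'
#' @param probes probe-level tibble (linear or log2 intensities).
#' @param span Lowess span for the trend fit.
#' @param pool `"sample"` fits one bias curve per sample (default);
#'   `"batch"` pools (dx, dy) pairs across all samples into a single curve.
#' @return normalized wide expression tibble (`gene_id` + sample columns).
#' @export
normalize_experiment <- function(probes, span = 0.3,
                                 pool = c("sample", "batch")) {
  pool <- match.arg(pool)
  med <- probes_to_log2(median_over_replicates(probes))
  pairs <- compute_dx_dy(med)
  if (pool == "batch") {
    curve <- fit_positional_bias(pairs, span = span)
  } else {
    curve <- lapply(split(pairs, pairs$sample_id), fit_positional_bias,
                    span = span)
  }
  corrected <- apply_bias_correction(med, curve)
  expr <- summarize_gene_intensity(corrected)
  percentile_normalize(expr)
}

#' Expression log-ratios between two conditions
#'
#' Per gene and strain, the log2 difference between expression on the test
#' condition (e.g. xylulose) and the reference condition (e.g. glucose) —
#' division on the linear intensity scale. Strains are matched by column
#' name; genes by `gene_id`. A value missing in either input is missing in
#' the ratio.
#'
#' @param numerator,denominator wide expression tibbles whose sample columns
#'   are strain ids.
#' @return wide tibble of log2 ratios over the shared genes and strains.
#' @export
compute_log_ratios <- function(numerator, denominator) {
  mx <- expr_to_matrix(numerator)
  mg <- expr_to_matrix(denominator)
  strains <- intersect(colnames(mx), colnames(mg))
  if (length(strains) == 0) {
    abort("no shared strains between the two matrices",
          class = "gx_data_error")
  }
  genes <- intersect(rownames(mx), rownames(mg))
  if (length(genes) == 0) {
    abort("no shared genes between the two matrices",
          class = "gx_data_error")
  }
  matrix_to_expr(mx[genes, strains, drop = FALSE] -
                   mg[genes, strains, drop = FALSE])
}

#' Split a normalized experiment into per-condition strain matrices
#'
#' Normalization returns columns keyed by `sample_id`
#' (`<strain_id>.<condition>`); this splits them into one wide tibble per
#' condition with plain strain-id columns, ready for
#' [compute_log_ratios()].
#'
#' @param expr wide tibble from [normalize_experiment()].
#' @param samples tibble with `sample_id`, `strain_id`, `condition`.
#' @return named list of wide tibbles, one per condition.
#' @export
split_by_condition <- function(expr, samples) {
  samples <- distinct(samples, .data$sample_id, .data$strain_id,
                      .data$condition)
  missing_s <- setdiff(setdiff(names(expr), "gene_id"), samples$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("samples absent from the sample table: ",
                 paste(head(missing_s, 3), collapse = ", ")),
          class = "gx_data_error")
  }
  out <- lapply(split(samples, samples$condition), function(s) {
    cols <- intersect(s$sample_id, names(expr))
    wide <- expr[c("gene_id", cols)]
    names(wide) <- c("gene_id", s$strain_id[match(cols, s$sample_id)])
    wide
  })
  out
}
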