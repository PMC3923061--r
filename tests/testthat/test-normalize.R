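test_that("replicate medians use the midpoint rule and reject empty input", {
  probes <- tibble::tibble(
    sample_id = "s1", strain_id = "a", condition = "glucose",
    gene_id = "g1",
    probe_id = rep(c("p1", "p2", "p3"), c(3, 4, 1)),
    placement_index = c(1:3, 1:4, 1L),
    dx = rep(c(0L, 100L, 400L), c(3, 4, 1)),
    intensity = c(100, 200, 300, 100, 200, 300, 400, 7.5),
    scale = "linear"
  )
  med <- median_over_replicates(probes)
  med <- med[order(med$probe_id), ]
  expect_equal(med$intensity, c(200, 250, 7.5))
  expect_error(median_over_replicates(probes[0, ]), class = "gx_data_error")
})

test_that("dx/dy pairs are log2 ratios to the gene's 3'-most probe", {
  probes <- toy_probe_table(
    truth = c(g1 = 10, g2 = 5),
    dx_list = list(g1 = c(0, 300), g2 = c(0, 100, 500))
  )
  # probe at dx=300 reads 512 when P_last reads 1024
  probes$intensity[probes$gene_id == "g1"] <- c(log2(1024), log2(512))
  pairs <- compute_dx_dy(probes)
  g1 <- pairs[pairs$gene_id == "g1", ]
  expect_equal(g1$dy[g1$dx == 300], -1)
  expect_equal(g1$dy[g1$dx == 0], 0)
  # equal intensities: dy = 0 at every dx
  g2 <- pairs[pairs$gene_id == "g2", ]
  expect_equal(sort(g2$dx), c(0, 100, 500))
  expect_equal(g2$dy, rep(0, 3))
  # gene without a dx=0 probe is skipped with a warning
  broken <- probes[!(probes$gene_id == "g2" & probes$dx == 0), ]
  expect_warning(p2 <- compute_dx_dy(broken), "skipped")
  expect_false("g2" %in% p2$gene_id)
})

test_that("lowess bias fit reproduces a noiseless linear trend", {
  set.seed(41)
  # P_last pairs sit at (0, 0); the rest spread over the dx range
  dx <- sort(c(rep(0, 40), sample(1:1000, 360, replace = TRUE)))
  pairs <- tibble::tibble(dx = dx, dy = -0.002 * dx)
  curve <- fit_positional_bias(pairs, span = 0.3)
  expect_s3_class(curve, "bias_curve")
  # anchored at zero by construction
  expect_equal(predict(curve, 0), 0, tolerance = 1e-12)
  # interior of the range matches the generating line and a least-squares
  # oracle to 1e-3
  interior <- seq(100, 900, by = 50)
  expect_equal(predict(curve, interior), -0.002 * interior, tolerance = 1e-3,
               ignore_attr = TRUE)
  ls_fit <- lm(dy ~ dx, data = pairs)
  oracle <- unname(predict(ls_fit, tibble::tibble(dx = interior)) -
                     coef(ls_fit)[1])
  expect_equal(predict(curve, interior), oracle, tolerance = 1e-3)

  # flat data: offsets all zero
  flat <- tibble::tibble(dx = dx, dy = 0)
  curve0 <- fit_positional_bias(flat)
  expect_equal(curve0$offset, rep(0, length(curve0$offset)),
               tolerance = 1e-9)

  # symmetric noise around zero: max offset shrinks with n
  amp_at <- function(n, seed) {
    set.seed(seed)
    p <- tibble::tibble(dx = sample(0:1000, n, replace = TRUE),
                        dy = sample(c(-0.5, 0.5), n, replace = TRUE))
    max(abs(fit_positional_bias(p)$offset))
  }
  small_amp <- mean(vapply(1:5, function(s) amp_at(50, s), numeric(1)))
  big_amp <- mean(vapply(1:5, function(s) amp_at(5000, s), numeric(1)))
  expect_lt(big_amp, small_amp)
  expect_lt(big_amp, 0.1)

  expect_error(fit_positional_bias(pairs[1:5, ]), class = "gx_fit_error")
  expect_error(fit_positional_bias(pairs, span = 0), class = "gx_config_error")
})

test_that("bias correction subtracts the fitted trend", {
  curve <- structure(
    list(dx = c(0, 500), offset = c(0, -1), span = 0.3,
         pairs = tibble::tibble(dx = numeric(), dy = numeric())),
    class = "bias_curve"
  )
  probes <- toy_probe_table(truth = c(g1 = 9), dx_list = list(g1 = c(0, 500)))
  corrected <- apply_bias_correction(probes, curve)
  # offset(500) = -1: log2 intensity 9 becomes 10; dx = 0 probe unchanged
  expect_equal(corrected$intensity[corrected$dx == 500], 10)
  expect_equal(corrected$intensity[corrected$dx == 0], 9)

  # end-to-end: known linear bias, no noise -> probes of a gene collapse
  truth <- c(g1 = 8, g2 = 10, g3 = 12, g4 = 9.5)
  dx_list <- list(g1 = c(0, 200, 800), g2 = c(0, 150, 650),
                  g3 = c(0, 300, 900), g4 = c(0, 450, 1000))
  probes <- toy_probe_table(truth, dx_list, bias_slope = -0.001)
  pairs <- compute_dx_dy(probes)
  fitted <- fit_positional_bias(pairs, span = 0.5)
  corr <- apply_bias_correction(probes, fitted)
  spread <- tapply(corr$intensity, corr$gene_id, function(v) diff(range(v)))
  expect_true(all(spread < 1e-3))
})

test_that("gene summarization takes the median over probes", {
  probes <- toy_probe_table(truth = c(g1 = 0, g2 = 0),
                            dx_list = list(g1 = c(0, 100, 300),
                                           g2 = c(0, 50)))
  probes$intensity <- c(10, 11, 12, 7.5, 7.5)
  expr <- summarize_gene_intensity(probes)
  expect_equal(expr$s1, c(11, 7.5))
  # permutation invariance
  shuffled <- probes[sample(nrow(probes)), ]
  expect_equal(summarize_gene_intensity(shuffled), expr)
})

test_that("percentile normalization equalizes distributions", {
  m <- tibble::tibble(gene_id = c("a", "b", "c"),
                      s1 = c(1, 2, 3), s2 = c(10, 20, 30))
  out <- percentile_normalize(m)
  expect_equal(out$s1, c(5.5, 11, 16.5))
  expect_equal(out$s2, c(5.5, 11, 16.5))

  # identical columns are a fixed point
  ident <- tibble::tibble(gene_id = letters[1:4], s1 = c(4, 1, 3, 2),
                          s2 = c(4, 1, 3, 2))
  expect_equal(percentile_normalize(ident), ident)

  # arbitrary input: equal-length columns share the sorted value multiset,
  # rank order within columns is preserved, missing entries stay missing
  set.seed(99)
  big <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:50),
    s1 = rnorm(50), s2 = rnorm(50, 2, 3), s3 = rnorm(50, -1, 0.5)
  )
  big$s2[c(3, 7)] <- NA
  big$s3[c(3, 11)] <- NA
  norm <- percentile_normalize(big)
  expect_identical(is.na(norm$s2), is.na(big$s2))
  expect_equal(sort(norm$s2[!is.na(norm$s2)]),
               sort(norm$s3[!is.na(norm$s3)]))  # equal non-missing counts
  for (col in c("s1", "s2", "s3")) {
    expect_identical(order(norm[[col]]), order(big[[col]]))
  }
  expect_error(
    percentile_normalize(tibble::tibble(gene_id = c("a", "b"),
                                        s1 = c(1, 2), s2 = c(NA, 3))),
    "s2"
  )
})

test_that("percentile normalization matches limma on complete matrices", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(200), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  ours <- expr_to_matrix(percentile_normalize(matrix_to_expr(m)))
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("the full normalization pipeline recovers the generator truth", {
  cfg <- small_config(seed = 21, replicate_noise_sd = 0.05,
                      probe_noise_sd = 0.1)
  co <- simulate_cohort(cfg)
  expr <- normalize_experiment(co$probes, span = 0.3)
  samples <- dplyr::distinct(co$probes, sample_id, strain_id, condition)
  by_cond <- split_by_condition(expr, samples)
  for (cond in names(by_cond)) {
    mt <- expr_to_matrix(true_expression(co, cond))
    mn <- expr_to_matrix(by_cond[[cond]])
    genes <- intersect(rownames(mt), rownames(mn))
    cors <- vapply(colnames(mt), function(s) {
      cor(mt[genes, s], mn[genes, s])
    }, numeric(1))
    expect_gt(min(cors), 0.99)
  }
  # determinism: same probes, same matrix
  expect_equal(normalize_experiment(co$probes, span = 0.3), expr)
})

test_that("log ratios subtract matched glucose from xylulose values", {
  xyl <- tibble::tibble(gene_id = c("g1", "g2"), a = c(5, 2), b = c(4, NA))
  glc <- tibble::tibble(gene_id = c("g1", "g2"), a = c(3, 2), b = c(NA, 1))
  lr <- compute_log_ratios(xyl, glc)
  expect_equal(lr$a, c(2, 0))
  expect_true(all(is.na(lr$b)))
  expect_error(
    compute_log_ratios(xyl, dplyr::rename(glc, c = a, d = b)),
    class = "gx_data_error"
  )
})
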