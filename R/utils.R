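# Internal helpers shared across modules.

# Wide expression tibble (gene_id + one column per sample) -> numeric matrix.
expr_to_matrix <- function(x) {
  if (!is.data.frame(x) || !"gene_id" %in% names(x)) {
    abort("expected a wide expression tibble with a `gene_id` column",
          class = "gx_data_error")
  }
  cols <- setdiff(names(x), "gene_id")
  m <- as.matrix(x[cols])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

matrix_to_expr <- function(m) {
  as_tibble(m, rownames = "gene_id")
}

# Log-normal parameters giving a prescribed arithmetic mean and CV (sd/mean).
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  p <- lnorm_pars(mean, cv)
  rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}

# Accept gene groups as a named list of gene-id vectors or as a long tibble
# (columns group, gene_id); normalize to the long-tibble form, deduplicated
# within group, order preserved.
as_group_tbl <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "gene_id") %in% names(groups))) {
      abort("gene groups need columns `group` and `gene_id`",
            class = "gx_data_error")
    }
    out <- as_tibble(groups[c("group", "gene_id")])
  } else if (is.list(groups)) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      abort("gene-group list must be named", class = "gx_config_error")
    }
    out <- tibble(
      group = rep(names(groups), lengths(groups)),
      gene_id = unlist(groups, use.names = FALSE)
    )
  } else {
    abort("unsupported gene-group representation", class = "gx_data_error")
  }
  distinct(out, .data$group, .data$gene_id)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"),
          class = "gx_config_error")
  }
}
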