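#' Read gene groups from a GMT file
#'
#' Standard GMT: one group per line, tab-separated fields `name`,
#' `description`, then gene ids. Duplicate genes within a group are
#' collapsed; group and gene order is preserved.
#'
#' @param path path to a GMT file.
#' @return tibble with columns `group`, `description`, `gene_id` (one row
#'   per gene).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste0("GMT file is empty: ", path))
    return(tibble(group = character(), description = character(),
                  gene_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(paste0("malformed GMT line ", bad[1], " (needs name, description ",
                 "and >= 1 gene): ", path),
          class = "gx_data_error")
  }
  purrr::map_dfr(fields, function(f) {
    tibble(group = f[1], description = f[2], gene_id = unique(f[-(1:2)]))
  })
}

#' Write gene groups to a GMT file
#'
#' @param groups tibble with columns `group`, `gene_id` and optionally
#'   `description`, or a named list of gene-id vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(groups, path) {
  tbl <- as_group_tbl(groups)
  desc <- if (is.data.frame(groups) && "description" %in% names(groups)) {
    distinct(groups, .data$group, .data$description)
  } else {
    tibble(group = unique(tbl$group), description = "synthetic")
  }
  lines <- vapply(unique(tbl$group), function(g) {
    genes <- tbl$gene_id[tbl$group == g]
    d <- desc$description[match(g, desc$group)]
    paste(c(g, d, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Drop genes observed in too few strains
#'
#' Keeps only genes with at least `k` non-missing values across the sample
#' columns — the missing-strain filter applied before group profiling
#' (default: data from at least 14 of the 24 strains).
#'
#' @param expr wide expression tibble (`gene_id` + sample columns).
#' @param k minimum number of non-missing strain values.
#' @return the filtered wide tibble.
#' @export
filter_min_strains <- function(expr, k = 14) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    abort("`k` must be a positive integer", class = "gx_config_error")
  }
  m <- expr_to_matrix(expr)
  keep <- rowSums(!is.na(m)) >= k
  expr[keep, , drop = FALSE]
}

#' Per-strain mean expression of gene groups
#'
#' For each group, the unweighted arithmetic mean over the group's genes
#' present in the matrix, computed per strain with missing entries excluded.
#' Strains with no observed group gene come out missing.
#'
#' @param expr wide expression tibble (`gene_id` + strain columns); apply
#'   [filter_min_strains()] first if desired.
#' @param groups gene groups: long tibble (`group`, `gene_id`) or named
#'   list; see [read_gmt()].
#' @param group optional character vector restricting which groups to
#'   profile.
#' @return long tibble with `group`, `strain_id`, `mean_expr`.
#' @export
group_mean_profile <- function(expr, groups, group = NULL) {
  tbl <- as_group_tbl(groups)
  if (!is.null(group)) tbl <- filter(tbl, .data$group %in% !!group)
  m <- expr_to_matrix(expr)
  purrr::map_dfr(unique(tbl$group), function(g) {
    genes <- intersect(tbl$gene_id[tbl$group == g], rownames(m))
    if (length(genes) == 0) {
      abort(paste0("no genes of group '", g, "' are present in the matrix"),
            class = "gx_data_error")
    }
    sub <- m[genes, , drop = FALSE]
    means <- colMeans(sub, na.rm = TRUE)
    means[colSums(!is.na(sub)) == 0] <- NA_real_
    tibble(group = g, strain_id = colnames(m), mean_expr = unname(means))
  })
}
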