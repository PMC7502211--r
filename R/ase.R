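#' Annotate SNPs with gene identifiers
#'
#' Assigns each SNP to every gene whose span contains it (1-based inclusive
#' coordinates, strand ignored). SNPs falling in overlapping genes are
#' duplicated, one row per gene; SNPs in no gene get `NA` and SNPs on
#' chromosomes absent from the annotation trigger a warning.
#'
#' @param snps Tibble of SNP counts with at least `chrom` and `pos`.
#' @param genes Tibble of gene models with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), e.g. from [read_gff()] or
#'   [simulate_ase_counts()].
#' @return `snps` with a `gene_id` column (possibly more rows than input
#'   because of overlapping genes).
#' @export
annotate_snps <- function(snps, genes) {
  check_columns(snps, c("chrom", "pos"), "`snps`")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "`genes`")
  missing_chrom <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(missing_chrom) > 0) {
    warn(sprintf("%d SNP chromosome(s) absent from the gene annotation: %s",
                 length(missing_chrom),
                 paste(head(missing_chrom, 5), collapse = ", ")))
  }
  snps$gene_id <- NULL
  left_join(
    snps,
    genes |> select("gene_id", "chrom", "start", "end"),
    by = join_by("chrom", between("pos", "start", "end"))
  ) |>
    select(-"start", -"end")
}

#' Filter SNPs for coverage and heterozygosity
#'
#' Removes SNPs with total coverage below `min_coverage` (default 10 reads)
#' and SNPs with a zero count for either allele - a zero suggests the site
#' was mis-called as heterozygous when it is actually homozygous. SNPs not
#' assigned to any gene are also dropped, since all downstream testing is
#' per gene.
#'
#' @param snps Annotated SNP tibble with `ref_count`, `alt_count`,
#'   `gene_id`.
#' @param min_coverage Minimum `ref_count + alt_count` to retain (default
#'   10).
#' @return Filtered tibble; attribute `"filter_log"` records rows removed
#'   per reason.
#' @export
filter_snps <- function(snps, min_coverage = 10) {
  check_columns(snps, c("ref_count", "alt_count", "gene_id"), "`snps`")
  check_count(min_coverage, "min_coverage")
  total <- snps$ref_count + snps$alt_count
  keep_cov <- total >= min_coverage
  keep_het <- snps$ref_count > 0 & snps$alt_count > 0
  keep_gene <- !is.na(snps$gene_id)
  out <- snps[keep_cov & keep_het & keep_gene, ]
  attr(out, "filter_log") <- tibble(
    reason = c("input", "low_coverage", "zero_allele", "no_gene", "retained"),
    n = c(nrow(snps), sum(!keep_cov), sum(keep_cov & !keep_het),
          sum(keep_cov & keep_het & !keep_gene), nrow(out))
  )
  if (nrow(out) == 0) inform("filter_snps: no SNPs retained")
  out
}

#' Pool replicate samples per SNP within colony and status
#'
#' Sums ref/alt counts of a SNP over the replicate individuals of each
#' colony-by-status group before any allele allocation. Pooling first means
#' the allocation rule sees each SNP's aggregate evidence once per group,
#' rather than rectifying sampling noise independently in every replicate -
#' which would inflate the apparent allelic proportion of unbiased genes
#' well beyond what the proportion threshold can absorb.
#'
#' @param snps Filtered SNP tibble with `sample_id`, `chrom`, `pos`,
#'   `gene_id`, `ref_count`, `alt_count`.
#' @param samples Sample sheet tibble (`sample_id`, `colony`, `status`).
#'   Samples missing from the sheet are an error.
#' @return Tibble with one row per (gene, SNP, colony, status):
#'   `ref_count`/`alt_count` summed over replicates, plus `n_samples`.
#' @export
pool_replicates <- function(snps, samples) {
  check_columns(snps, c("sample_id", "chrom", "pos", "gene_id",
                        "ref_count", "alt_count"), "`snps`")
  check_columns(samples, c("sample_id", "colony", "status"), "`samples`")
  unknown <- setdiff(unique(snps$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("sample(s) absent from the sample sheet: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  snps |>
    select(-dplyr::any_of(c("colony", "status"))) |>
    inner_join(samples |> select("sample_id", "colony", "status"),
               by = "sample_id") |>
    group_by(.data$gene_id, .data$chrom, .data$pos, .data$colony,
             .data$status) |>
    summarise(
      ref_count = sum(.data$ref_count),
      alt_count = sum(.data$alt_count),
      n_samples = n(),
      .groups = "drop"
    )
}

#' Allocate per-SNP counts to allele 1 and allele 2
#'
#' Without parental genomes the physical phase of ref/alt bases across SNPs
#' is unknown, so per SNP the larger count is assigned to "allele 1" and
#' the smaller to "allele 2" (ties keep the reference count on allele 1).
#' This makes downstream proportions invariant to ref/alt labelling but
#' inflates null proportions above 0.5 by construction - the reason the
#' ASE call requires a mean proportion above 0.65, not just a significant
#' test.
#'
#' @param snps Filtered SNP tibble with `ref_count`, `alt_count`.
#' @return `snps` with `allele1_count` and `allele2_count` columns.
#' @export
allocate_alleles <- function(snps) {
  check_columns(snps, c("ref_count", "alt_count"), "`snps`")
  snps |>
    mutate(
      allele1_count = pmax(.data$ref_count, .data$alt_count),
      allele2_count = pmin(.data$ref_count, .data$alt_count)
    )
}

#' Aggregate allocated counts per gene, colony and status
#'
#' Sums allele-1 and allele-2 counts over all SNPs and replicate samples of
#' each gene within each colony-by-status group, creating one representative
#' observation per reproductive status per colony. Testing at the gene level
#' (rather than per SNP) reduces false positives from residual reference
#' mapping bias.
#'
#' @param snps Allocated SNP tibble with `gene_id`, `allele1_count`,
#'   `allele2_count`, plus either `colony`/`status` columns (e.g. from
#'   [pool_replicates()]) or a `sample_id` column resolved through
#'   `samples`.
#' @param samples Sample sheet tibble with `sample_id`, `colony`, `status`;
#'   only needed when `snps` lacks `colony`/`status`. Samples missing from
#'   the sheet are an error.
#' @return Tibble with one row per (gene_id, colony, status):
#'   `allele1_total`, `allele2_total`, `n_snps`, `proportion`.
#' @export
aggregate_alleles <- function(snps, samples = NULL) {
  check_columns(snps, c("gene_id", "allele1_count", "allele2_count", "pos"),
                "`snps`")
  if (!all(c("colony", "status") %in% names(snps))) {
    if (is.null(samples)) {
      abort("`snps` lacks colony/status columns; supply a `samples` sheet")
    }
    check_columns(samples, c("sample_id", "colony", "status"), "`samples`")
    unknown <- setdiff(unique(snps$sample_id), samples$sample_id)
    if (length(unknown) > 0) {
      abort(sprintf("sample(s) absent from the sample sheet: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
    snps <- snps |>
      inner_join(samples |> select("sample_id", "colony", "status"),
                 by = "sample_id")
  }
  snps |>
    group_by(.data$gene_id, .data$colony, .data$status) |>
    summarise(
      allele1_total = sum(.data$allele1_count),
      allele2_total = sum(.data$allele2_count),
      n_snps = n_distinct(.data$chrom, .data$pos),
      .groups = "drop"
    ) |>
    mutate(proportion = .data$allele1_total /
             (.data$allele1_total + .data$allele2_total))
}

#' Genes eligible for ASE testing
#'
#' A gene is testable if, for at least one reproductive status, it has
#' aggregated counts in at least `min_colonies` colonies (default 2 of 3).
#'
#' @param gene_table Output of [aggregate_alleles()].
#' @param min_colonies Minimum colonies per status (default 2).
#' @return Character vector of eligible gene ids.
#' @export
eligible_genes <- function(gene_table, min_colonies = 2) {
  check_columns(gene_table, c("gene_id", "colony", "status"), "`gene_table`")
  check_count(min_colonies, "min_colonies")
  gene_table |>
    group_by(.data$gene_id, .data$status) |>
    summarise(n_col = n_distinct(.data$colony), .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(ok = any(.data$n_col >= min_colonies), .groups = "drop") |>
    filter(.data$ok) |>
    pull("gene_id")
}

#' Quasibinomial test of allelic imbalance for one gene
#'
#' Fits a logistic regression of allele-1 successes out of total allelic
#' reads on reproductive status and colony, with a quasibinomial dispersion
#' correction, and tests the intercept against 0 on the logit scale
#' (H0: allelic proportion = 0.5). Sum-to-zero contrasts are used for the
#' covariates so the intercept is the grand-mean logit proportion rather
#' than a reference-cell mean. The dispersion is estimated as Pearson
#' chi-square over residual degrees of freedom and floored at 1 (no
#' under-dispersion credit); the p-value uses a t reference with the
#' residual df. Degenerate designs fall back gracefully: zero residual df
#' triggers an intercept-only refit, and a single observation (or complete
#' separation, where every row is pure allele 1) falls back to an exact
#' two-sided binomial test of the pooled counts against 0.5.
#'
#' @param gene_rows Tibble of aggregated rows for one gene: `allele1_total`,
#'   `allele2_total`, plus `status` and `colony` where available.
#' @return An object of class `ase_fit`: list with `p_value`, `estimate`
#'   (intercept, logit scale), `dispersion`, `df_residual`, `method`
#'   (`"glm"`, `"glm_intercept_only"` or `"binomial_exact"`), `n_groups`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
#' @examples
#' rows <- tibble::tibble(
#'   status = rep(c("reproductive", "sterile"), each = 3),
#'   colony = rep(c("A", "B", "C"), 2),
#'   allele1_total = c(30, 28, 31, 29, 33, 30),
#'   allele2_total = c(10, 12, 11, 13, 9, 12)
#' )
#' fit_ase_glm(rows)
fit_ase_glm <- function(gene_rows) {
  check_columns(gene_rows, c("allele1_total", "allele2_total"), "`gene_rows`")
  a1 <- gene_rows$allele1_total
  a2 <- gene_rows$allele2_total
  if (any(a1 + a2 <= 0)) abort("every row needs allele1_total + allele2_total > 0")
  n <- nrow(gene_rows)

  exact_fallback <- function(method) {
    bt <- binom.test(sum(a1), sum(a1) + sum(a2), p = 0.5)
    new_ase_fit(
      p_value = bt$p.value,
      estimate = stats::qlogis(min(max(bt$estimate, 1e-12), 1 - 1e-12)),
      std_error = NA_real_, statistic = NA_real_,
      dispersion = NA_real_, df_residual = 0L,
      method = method, n_groups = n
    )
  }

  if (n < 2 || all(a2 == 0) || all(a1 == 0)) {
    return(exact_fallback("binomial_exact"))
  }

  covars <- c("status", "colony")
  covars <- covars[covars %in% names(gene_rows)]
  covars <- covars[vapply(covars,
                          function(v) n_distinct(gene_rows[[v]]) > 1,
                          logical(1))]
  fit_with <- function(covars) {
    rhs <- if (length(covars) == 0) "1" else paste(covars, collapse = " + ")
    dat <- gene_rows
    for (v in covars) dat[[v]] <- factor(dat[[v]])
    ctr <- lapply(setNames(covars, covars), function(v) "contr.sum")
    glm(as.formula(paste("cbind(allele1_total, allele2_total) ~", rhs)),
        family = binomial(), data = dat,
        contrasts = if (length(covars) > 0) ctr else NULL)
  }

  method <- "glm"
  fit <- fit_with(covars)
  if (df.residual(fit) == 0 && length(covars) > 0) {
    fit <- fit_with(character(0))
    method <- "glm_intercept_only"
  }
  df_res <- df.residual(fit)
  if (df_res == 0) return(exact_fallback("binomial_exact"))

  phi <- max(1, sum(residuals(fit, type = "pearson")^2) / df_res)
  est <- coef(fit)[["(Intercept)"]]
  se <- sqrt(diag(vcov(fit))[["(Intercept)"]] * phi)
  tval <- est / se
  new_ase_fit(
    p_value = 2 * pt(-abs(tval), df_res),
    estimate = est, std_error = se, statistic = tval,
    dispersion = phi, df_residual = df_res,
    method = method, n_groups = n
  )
}

new_ase_fit <- function(p_value, estimate, std_error, statistic, dispersion,
                        df_residual, method, n_groups) {
  structure(
    list(p_value = p_value, estimate = estimate, std_error = std_error,
         statistic = statistic, dispersion = dispersion,
         df_residual = df_residual, method = method, n_groups = n_groups),
    class = "ase_fit"
  )
}

#' @export
print.ase_fit <- function(x, ...) {
  cat(sprintf(
    "<ase_fit> method=%s  intercept(logit)=%.4f  dispersion=%s  p=%.4g\n",
    x$method, x$estimate,
    if (is.na(x$dispersion)) "NA" else sprintf("%.3f", x$dispersion),
    x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ase_fit
#' @export
tidy.ase_fit <- function(x, ...) {
  tibble(term = "(Intercept)", estimate = x$estimate,
         std.error = x$std_error, statistic = x$statistic,
         p.value = x$p_value)
}

#' @method glance ase_fit
#' @export
glance.ase_fit <- function(x, ...) {
  tibble(dispersion = x$dispersion, df.residual = x$df_residual,
         method = x$method, n.groups = x$n_groups, p.value = x$p_value)
}

#' Test all eligible genes for allelic imbalance
#'
#' Runs [fit_ase_glm()] on every eligible gene and collects per-gene
#' p-values together with the mean allelic proportion per status (mean of
#' per-colony proportions).
#'
#' @param gene_table Output of [aggregate_alleles()].
#' @param genes Character vector of genes to test; defaults to
#'   [eligible_genes()] at `min_colonies`.
#' @param min_colonies Passed to [eligible_genes()] when `genes` is NULL.
#' @return Tibble with one row per tested gene: `gene_id`, `p_value`,
#'   `dispersion`, `method`, `n_groups`, and `mean_prop_<status>` columns.
#' @export
test_ase <- function(gene_table, genes = NULL, min_colonies = 2) {
  if (is.null(genes)) genes <- eligible_genes(gene_table, min_colonies)
  if (length(genes) == 0) {
    inform("test_ase: no eligible genes")
    return(tibble(gene_id = character(), p_value = numeric()))
  }
  tab <- gene_table |> filter(.data$gene_id %in% genes)

  props <- tab |>
    group_by(.data$gene_id, .data$status) |>
    summarise(mean_prop = mean(.data$proportion), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "status", values_from = "mean_prop",
                       names_prefix = "mean_prop_")

  fits <- tab |>
    tidyr::nest(data = -"gene_id") |>
    mutate(fit = purrr::map(.data$data, fit_ase_glm)) |>
    mutate(
      p_value = purrr::map_dbl(.data$fit, "p_value"),
      dispersion = purrr::map_dbl(.data$fit, "dispersion"),
      method = purrr::map_chr(.data$fit, "method"),
      n_groups = purrr::map_int(.data$fit, "n_groups")
    ) |>
    select(-"data", -"fit")

  left_join(fits, props, by = "gene_id") |> arrange(.data$gene_id)
}

#' Classify genes as showing allele-specific expression
#'
#' Applies Benjamini-Hochberg correction across the tested genes and calls
#' a gene ASE in a reproductive status when `q < q_threshold` and its mean
#' allelic proportion across that status's colonies exceeds
#' `prop_threshold`. The proportion cut-off guards against mis-allocation
#' of SNPs to alleles: even a perfectly balanced gene shows an allocated
#' proportion above 0.5.
#'
#' @param tests Output of [test_ase()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param prop_threshold Mean-proportion threshold (default 0.65).
#' @param statuses The two status labels; defaults to those found in the
#'   `mean_prop_*` columns.
#' @return `tests` with `q_value`, per-status `ase_<status>` booleans and a
#'   `class` column (`"none"`, `"shared"`, or `"<status>_only"`).
#' @export
call_ase <- function(tests, q_threshold = 0.05, prop_threshold = 0.65,
                     statuses = NULL) {
  check_prob(q_threshold, "q_threshold", open_left = TRUE, open_right = TRUE)
  check_prob(prop_threshold, "prop_threshold", open_left = TRUE,
             open_right = TRUE)
  if (nrow(tests) == 0) return(tests)
  if (is.null(statuses)) {
    statuses <- sub("^mean_prop_", "",
                    grep("^mean_prop_", names(tests), value = TRUE))
  }
  if (length(statuses) == 0) abort("no mean_prop_* columns found in `tests`")
  out <- tests |> mutate(q_value = bh_adjust(.data$p_value))
  for (s in statuses) {
    prop <- out[[paste0("mean_prop_", s)]]
    out[[paste0("ase_", s)]] <- !is.na(prop) &
      out$q_value < q_threshold & prop > prop_threshold
  }
  flags <- as.matrix(out[paste0("ase_", statuses)])
  n_on <- rowSums(flags)
  cls <- rep("none", nrow(out))
  cls[n_on == length(statuses)] <- "shared"
  if (length(statuses) > 1) {
    for (s in statuses) {
      only <- n_on == 1 & flags[, paste0("ase_", s)]
      cls[only] <- paste0(s, "_only")
    }
  }
  out$class <- cls
  out
}

#' Run the full ASE pipeline
#'
#' Convenience wrapper chaining [annotate_snps()], [filter_snps()],
#' [pool_replicates()], [allocate_alleles()], [aggregate_alleles()],
#' [test_ase()] and [call_ase()].
#'
#' @param counts Per-SNP count tibble (`chrom`, `pos`, `ref_count`,
#'   `alt_count`, `sample_id`).
#' @param samples Sample sheet (`sample_id`, `colony`, `status`).
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`).
#' @param min_coverage,min_colonies,q_threshold,prop_threshold Pipeline
#'   thresholds; see the individual steps.
#' @return List with `results` (the called gene table), `gene_table`
#'   (aggregated counts) and `log` (filter accounting).
#' @export
ase_pipeline <- function(counts, samples, genes,
                         min_coverage = 10, min_colonies = 2,
                         q_threshold = 0.05, prop_threshold = 0.65) {
  filtered <- counts |>
    annotate_snps(genes) |>
    filter_snps(min_coverage = min_coverage)
  flog <- attr(filtered, "filter_log")
  gene_table <- filtered |>
    pool_replicates(samples) |>
    allocate_alleles() |>
    aggregate_alleles()
  results <- gene_table |>
    test_ase(min_colonies = min_colonies) |>
    call_ase(q_threshold = q_threshold, prop_threshold = prop_threshold)
  list(results = results, gene_table = gene_table, log = flog)
}
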