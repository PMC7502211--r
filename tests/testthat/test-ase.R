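test_that("gene annotation uses inclusive bounds and duplicates overlaps", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "LG1",
                          start = c(100L, 180L), end = c(200L, 300L))
  snps <- snp_row("s1", pos = c(99L, 100L, 150L, 190L, 301L),
                  ref = 5L, alt = 5L)
  ann <- annotate_snps(snps, genes)
  expect_equal(ann$gene_id[ann$pos == 99], NA_character_)
  expect_equal(ann$gene_id[ann$pos == 100], "g1")
  expect_equal(ann$gene_id[ann$pos == 301], NA_character_)
  # pos 190 sits in both genes: duplicated, one row per gene
  expect_setequal(ann$gene_id[ann$pos == 190], c("g1", "g2"))
  expect_equal(nrow(ann), 6)
})

test_that("annotation agrees with brute-force interval containment", {
  set.seed(31)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:6), chrom = sample(c("LG1", "LG2"), 6, TRUE),
    start = sample(1:500, 6)
  )
  genes$end <- genes$start + sample(50:200, 6)
  snps <- snp_row("s1", pos = sample(1:700, 40), ref = 5L, alt = 5L,
                  chrom = sample(c("LG1", "LG2"), 40, TRUE))
  ann <- annotate_snps(snps, genes)
  brute <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    hit <- genes$chrom == snps$chrom[i] & genes$start <= snps$pos[i] &
      genes$end >= snps$pos[i]
    data.frame(pos = snps$pos[i], chrom = snps$chrom[i],
               gene_id = if (any(hit)) genes$gene_id[hit] else NA_character_)
  }))
  got <- ann[order(ann$chrom, ann$pos, ann$gene_id),
             c("pos", "chrom", "gene_id")]
  want <- brute[order(brute$chrom, brute$pos, brute$gene_id), ]
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
})

test_that("annotation warns on chromosomes missing from the gene models", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "LG1",
                          start = 1L, end = 100L)
  snps <- snp_row("s1", pos = 50L, ref = 5L, alt = 5L, chrom = "scaffold_9")
  expect_warning(ann <- annotate_snps(snps, genes), "scaffold_9")
  expect_true(is.na(ann$gene_id))
})

test_that("SNP filter enforces coverage, heterozygosity and gene assignment", {
  snps <- dplyr::bind_rows(
    snp_row("s1", 1L, 5L, 4L, gene_id = "g1"),   # coverage 9 < 10
    snp_row("s1", 2L, 10L, 0L, gene_id = "g1"),  # homozygous-looking
    snp_row("s1", 3L, 0L, 12L, gene_id = "g1"),  # homozygous-looking
    snp_row("s1", 4L, 6L, 4L, gene_id = "g1"),   # retained
    snp_row("s1", 5L, 8L, 8L, gene_id = NA)      # no gene
  )
  out <- filter_snps(snps)
  expect_equal(out$pos, 4L)
  log <- attr(out, "filter_log")
  expect_equal(log$n[log$reason == "input"], 5)
  expect_equal(log$n[log$reason == "retained"], 1)
  # accounting reconciles
  expect_equal(sum(log$n[!log$reason %in% c("input", "retained")]) +
                 log$n[log$reason == "retained"],
               log$n[log$reason == "input"])
})

test_that("allocation assigns the larger count to allele 1, ties to ref", {
  snps <- dplyr::bind_rows(
    snp_row("s1", 1L, 3L, 7L, gene_id = "g1"),
    snp_row("s1", 2L, 7L, 3L, gene_id = "g1"),
    snp_row("s1", 3L, 5L, 5L, gene_id = "g1")
  )
  out <- allocate_alleles(snps)
  expect_equal(out$allele1_count, c(7L, 7L, 5L))
  expect_equal(out$allele2_count, c(3L, 3L, 5L))
  expect_true(all(out$allele1_count >= out$allele2_count))
})

test_that("aggregation sums SNPs within groups and conserves reads", {
  samples <- toy_samples(colonies = "A", replicates = 1)
  snps <- dplyr::bind_rows(
    snp_row("A_reproductive_r1", 10L, 8L, 2L, gene_id = "g1"),
    snp_row("A_reproductive_r1", 20L, 3L, 7L, gene_id = "g1"),
    snp_row("A_sterile_r1", 10L, 6L, 4L, gene_id = "g1")
  )
  tab <- snps |>
    pool_replicates(samples) |>
    allocate_alleles() |>
    aggregate_alleles()
  repro <- tab[tab$status == "reproductive", ]
  expect_equal(repro$allele1_total, 15)
  expect_equal(repro$allele2_total, 5)
  expect_equal(repro$proportion, 0.75)
  expect_equal(repro$n_snps, 2)
  sterile <- tab[tab$status == "sterile", ]
  expect_equal(sterile$proportion, 0.6)
  # read conservation through pooling + allocation + aggregation
  expect_equal(sum(tab$allele1_total + tab$allele2_total),
               sum(snps$ref_count + snps$alt_count))
})

test_that("replicate pooling sums counts per SNP before allocation", {
  samples <- toy_samples(colonies = "A", statuses = "reproductive",
                         replicates = 2)
  # same SNP, opposite imbalance in the two replicates: pooled first, the
  # allocation sees 10 vs 10 and reports a balanced SNP
  snps <- dplyr::bind_rows(
    snp_row("A_reproductive_r1", 10L, 8L, 2L, gene_id = "g1"),
    snp_row("A_reproductive_r2", 10L, 2L, 8L, gene_id = "g1")
  )
  pooled <- pool_replicates(snps, samples)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$ref_count, 10L)
  expect_equal(pooled$n_samples, 2L)
  tab <- pooled |> allocate_alleles() |> aggregate_alleles()
  expect_equal(tab$proportion, 0.5)
  expect_error(pool_replicates(snps, samples[0, ]), "absent")
})

test_that("eligibility requires two colonies in at least one status", {
  tab <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2"),
    colony = c("A", "B", "A", "B"),
    status = c("sterile", "sterile", "reproductive", "sterile"),
    allele1_total = 10, allele2_total = 5, n_snps = 1,
    proportion = 2 / 3
  )
  expect_equal(eligible_genes(tab), "g1")
  # with dropout disabled every simulated gene is eligible
  sim <- simulate_ase_counts(n_genes = 12, snps_per_gene = 2, seed = 2)
  samples <- dplyr::distinct(sim$counts, sample_id, colony, status)
  gt <- sim$counts |>
    annotate_snps(sim$genes) |>
    filter_snps() |>
    pool_replicates(samples) |>
    allocate_alleles() |>
    aggregate_alleles()
  expect_setequal(eligible_genes(gt), sim$truth$gene_id)
})

test_that("perfectly balanced genes give a zero intercept and p = 1", {
  rows <- tibble::tibble(
    status = rep(c("reproductive", "sterile"), 3),
    colony = rep(c("A", "B", "C"), each = 2),
    allele1_total = 12, allele2_total = 12
  )
  fit <- fit_ase_glm(rows)
  expect_equal(fit$estimate, 0, tolerance = 1e-8)
  expect_equal(fit$p_value, 1, tolerance = 1e-6)
  expect_equal(fit$method, "glm")
  expect_equal(fit$dispersion, 1)  # floored
})

test_that("a single observation falls back to the exact binomial test", {
  fit <- fit_ase_glm(tibble::tibble(allele1_total = 15, allele2_total = 5))
  # two-sided binomial enumeration oracle for 15/20 successes at 0.5
  d <- dbinom(0:20, 20, 0.5)
  oracle <- sum(d[d <= d[16] * (1 + 1e-7)])
  expect_equal(oracle, 0.04138946533, tolerance = 1e-8)
  expect_equal(fit$p_value, oracle, tolerance = 1e-8)
  expect_equal(fit$method, "binomial_exact")
})

test_that("complete separation falls back with a finite p-value", {
  rows <- tibble::tibble(
    status = rep(c("reproductive", "sterile"), 2),
    colony = rep(c("A", "B"), each = 2),
    allele1_total = c(20, 18, 25, 22), allele2_total = 0
  )
  fit <- fit_ase_glm(rows)
  expect_equal(fit$method, "binomial_exact")
  expect_lt(fit$p_value, 1e-6)
})

test_that("saturated designs refit intercept-only and are flagged", {
  rows <- tibble::tibble(
    status = c("reproductive", "sterile"),
    colony = c("A", "A"),
    allele1_total = c(14, 16), allele2_total = c(6, 5)
  )
  fit <- fit_ase_glm(rows)
  expect_equal(fit$method, "glm_intercept_only")
  expect_equal(fit$df_residual, 1)
})

test_that("tidy and glance expose the fit in broom shape", {
  rows <- tibble::tibble(
    status = rep(c("reproductive", "sterile"), 3),
    colony = rep(c("A", "B", "C"), each = 2),
    allele1_total = c(30, 28, 31, 29, 33, 30),
    allele2_total = c(10, 12, 11, 13, 9, 12)
  )
  fit <- fit_ase_glm(rows)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- generics::glance(fit)
  expect_equal(gl$p.value, fit$p_value)
  expect_equal(gl$method, "glm")
})

test_that("the quasibinomial intercept test is not anti-conservative at the null", {
  # gene tables generated directly (no allocation), pi = 0.5, rho = 0.1,
  # 6 colony-by-status groups; 2000 replicate genes
  set.seed(2024)
  n_rep <- 2000
  shape <- (1 - 0.1) / 0.1
  p_vals <- vapply(seq_len(n_rep), function(i) {
    pr <- rbeta(6, 0.5 * shape, 0.5 * shape)
    tot <- rpois(6, 60) + 1
    a1 <- rbinom(6, tot, pr)
    a1 <- pmin(pmax(a1, 1), tot - 1)  # keep both alleles observed
    rows <- tibble::tibble(
      status = rep(c("reproductive", "sterile"), 3),
      colony = rep(c("A", "B", "C"), each = 2),
      allele1_total = a1, allele2_total = tot - a1
    )
    fit_ase_glm(rows)$p_value
  }, numeric(1))
  rate <- mean(p_vals < 0.05)
  mcse <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, 0.05 + 2 * mcse)
  expect_gt(rate, 0.001)  # the test does reject sometimes
})

test_that("BH q-values match the step-up definition", {
  expect_equal(q_values(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(q_values(p), bh_oracle(p))
    q <- q_values(p)
    expect_true(all(q >= p - 1e-12 & q <= 1))
    # monotone in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("ASE classification applies both the q and proportion rules", {
  tests <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    p_value = c(0.0001, 0.0001, 0.5, 0.0001),
    mean_prop_reproductive = c(0.70, 0.90, 0.90, 0.70),
    mean_prop_sterile = c(0.60, 0.90, 0.90, 0.70)
  )
  out <- call_ase(tests)
  expect_equal(out$class[out$gene_id == "g1"], "reproductive_only")
  expect_equal(out$class[out$gene_id == "g2"], "shared")
  expect_equal(out$class[out$gene_id == "g3"], "none")  # q too large
  expect_equal(out$class[out$gene_id == "g4"], "shared")
  expect_true(all(out$q_value >= out$p_value))
})

test_that("downstream results are invariant to ref/alt orientation", {
  sim <- simulate_ase_counts(n_genes = 20, snps_per_gene = 2,
                             true_prop = 0.75, seed = 10)
  samples <- dplyr::distinct(sim$counts, sample_id, colony, status)
  flipped <- sim$counts
  set.seed(1)
  # a SNP's ref/alt labelling is a property of the site: flip whole SNPs
  snp_keys <- unique(flipped[c("chrom", "pos")])
  snp_keys <- snp_keys[runif(nrow(snp_keys)) < 0.5, ]
  swap <- paste(flipped$chrom, flipped$pos) %in%
    paste(snp_keys$chrom, snp_keys$pos)
  tmp <- flipped$ref_count[swap]
  flipped$ref_count[swap] <- flipped$alt_count[swap]
  flipped$alt_count[swap] <- tmp
  res_a <- ase_pipeline(sim$counts, samples, sim$genes)$results
  res_b <- ase_pipeline(flipped, samples, sim$genes)$results
  expect_equal(res_a, res_b)
})
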