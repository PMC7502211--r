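#' Simulate per-SNP allelic read counts with known truth
#'
#' Generates a synthetic table of heterozygous-SNP allelic read counts with
#' the structure the ASE pipeline consumes: several genetically distinct
#' colonies, two worker reproductive statuses, replicate individuals per
#' colony-by-status group, and one or more heterozygous SNPs per gene.
#' Per-SNP counts are drawn beta-binomially so that overdispersion relative
#' to a plain binomial (the reason a quasibinomial fit is used downstream)
#' can be switched on. The reference/alternative orientation of each SNP is
#' randomized independently of the true allele, so that only the allele
#' allocation rule - not the ref/alt labelling - can recover the simulated
#' bias. This reproduces the central ambiguity of an experiment without
#' parental genomes: a reference base at one SNP may sit on either physical
#' allele.
#'
#' @param n_genes Number of genes to simulate.
#' @param snps_per_gene Number of heterozygous SNPs per gene; either a single
#'   count or a length-2 range `c(min, max)` sampled uniformly per gene.
#' @param n_colonies Number of genetically distinct colonies (default 3).
#' @param statuses Character vector of the two reproductive statuses.
#' @param replicates_per_group Individuals sequenced per colony-by-status
#'   group (default 3).
#' @param coverage_mean Mean read coverage per SNP per sample. Coverage is
#'   Poisson-distributed (truncated at 1) unless `fixed_coverage = TRUE`.
#' @param true_prop True proportion of expression from the favoured allele,
#'   per gene (scalar recycled, or length `n_genes`). Must lie in (0, 1);
#'   0.5 means no allelic bias.
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   `[0, 1)` (scalar recycled, or length `n_genes`). 0 gives plain
#'   binomial counts.
#' @param missing_colony_rate Probability that a gene is unobserved in a
#'   given colony (all its SNP rows dropped there), emulating genes without
#'   callable heterozygous SNPs in some families.
#' @param fixed_coverage If `TRUE` every SNP has exactly `coverage_mean`
#'   reads.
#' @param seed Integer seed; the output is a deterministic function of the
#'   configuration and this seed.
#'
#' @return A list with three tibbles:
#' \describe{
#'   \item{counts}{one row per SNP per sample: `sample_id`, `colony`,
#'     `status`, `chrom`, `pos`, `gene_id`, `ref_count`, `alt_count`.}
#'   \item{genes}{gene models (`gene_id`, `chrom`, `start`, `end`) usable
#'     for annotation.}
#'   \item{truth}{`gene_id`, `true_prop`.}
#' }
#' @export
#' @examples
#' sim <- simulate_ase_counts(n_genes = 5, snps_per_gene = 2,
#'                            coverage_mean = 20, true_prop = 0.85, seed = 1)
#' sim$counts
simulate_ase_counts <- function(n_genes,
                                snps_per_gene = 3,
                                n_colonies = 3,
                                statuses = c("reproductive", "sterile"),
                                replicates_per_group = 3,
                                coverage_mean = 30,
                                true_prop = 0.5,
                                overdispersion_rho = 0,
                                missing_colony_rate = 0,
                                fixed_coverage = FALSE,
                                seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  n_colonies <- check_count(n_colonies, "n_colonies")
  replicates_per_group <- check_count(replicates_per_group, "replicates_per_group")
  if (length(statuses) != 2 || anyDuplicated(statuses)) {
    abort("`statuses` must be two distinct labels")
  }
  if (!is.numeric(coverage_mean) || coverage_mean < 1) {
    abort("`coverage_mean` must be >= 1")
  }
  if (!all(is.finite(true_prop)) || any(true_prop <= 0) || any(true_prop >= 1)) {
    abort("`true_prop` values must lie strictly in (0, 1)")
  }
  if (!(length(true_prop) %in% c(1L, n_genes))) {
    abort("`true_prop` must have length 1 or n_genes")
  }
  if (!all(is.finite(overdispersion_rho)) || any(overdispersion_rho < 0) ||
      any(overdispersion_rho >= 1)) {
    abort("`overdispersion_rho` values must lie in [0, 1)")
  }
  if (!(length(overdispersion_rho) %in% c(1L, n_genes))) {
    abort("`overdispersion_rho` must have length 1 or n_genes")
  }
  check_prob(missing_colony_rate, "missing_colony_rate")
  if (length(snps_per_gene) == 1) snps_per_gene <- rep(snps_per_gene, 2)
  if (length(snps_per_gene) != 2 || any(snps_per_gene < 1)) {
    abort("`snps_per_gene` must be a count or a c(min, max) range, all >= 1")
  }
  seed <- check_count(seed, "seed", min = 0)

  withr::with_seed(seed, {
    pi_g <- rep_len(true_prop, n_genes)
    rho_g <- rep_len(overdispersion_rho, n_genes)
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    n_snps_g <- sample(seq(snps_per_gene[1], snps_per_gene[2]),
                       n_genes, replace = TRUE)

    # Lay genes out head-to-tail on one chromosome, 1 kb apart, SNPs spread
    # evenly inside each gene body.
    gene_len <- pmax(1000L, n_snps_g * 100L)
    starts <- cumsum(c(1L, head(gene_len + 1000L, -1L)))
    genes <- tibble(
      gene_id = gene_ids, chrom = "LG1",
      start = starts, end = starts + gene_len - 1L
    )

    snp_tbl <- tibble(
      gene_id = rep(gene_ids, n_snps_g),
      true_prop = rep(pi_g, n_snps_g),
      rho = rep(rho_g, n_snps_g),
      chrom = "LG1",
      pos = unlist(purrr::map2(seq_len(n_genes), n_snps_g, function(g, k) {
        starts[g] + round(seq(50, gene_len[g] - 50, length.out = k))
      })),
      # TRUE: the reference base sits on the favoured allele at this SNP.
      ref_is_allele_a = runif(sum(n_snps_g)) < 0.5
    )

    samples <- tidyr::expand_grid(
      colony = sprintf("colony_%s", LETTERS[seq_len(n_colonies)]),
      status = statuses,
      replicate = seq_len(replicates_per_group)
    )
    samples$sample_id <- sprintf("%s_%s_r%d", samples$colony,
                                 samples$status, samples$replicate)

    counts <- tidyr::crossing(snp_tbl, samples)

    if (missing_colony_rate > 0) {
      drop <- tidyr::expand_grid(gene_id = gene_ids,
                                 colony = unique(samples$colony))
      drop <- drop[runif(nrow(drop)) < missing_colony_rate, ]
      counts <- anti_join(counts, drop, by = c("gene_id", "colony"))
    }

    m <- nrow(counts)
    cov <- if (fixed_coverage) rep(as.integer(coverage_mean), m)
           else pmax(1L, rpois(m, coverage_mean))
    p_draw <- counts$true_prop
    od <- counts$rho > 0
    if (any(od)) {
      shape <- (1 - counts$rho[od]) / counts$rho[od]
      p_draw[od] <- rbeta(sum(od), counts$true_prop[od] * shape,
                          (1 - counts$true_prop[od]) * shape)
    }
    allele_a <- rbinom(m, cov, p_draw)
    counts$ref_count <- ifelse(counts$ref_is_allele_a, allele_a, cov - allele_a)
    counts$alt_count <- cov - counts$ref_count

    counts <- counts |>
      select("sample_id", "colony", "status", "chrom", "pos",
             "gene_id", "ref_count", "alt_count") |>
      arrange(.data$gene_id, .data$pos, .data$sample_id)

    list(counts = counts,
         genes = genes,
         truth = tibble(gene_id = gene_ids, true_prop = pi_g,
                        overdispersion_rho = rho_g))
  })
}
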