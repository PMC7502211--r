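#' Slide CpG windows over epireads
#'
#' Scans each allowed chromosome with a window of `window` consecutive CpGs
#' (step 1 CpG) and collects, per window, the methylation-state matrix of
#' the epireads overlapping it. Windows where any CpG has fewer than
#' `min_coverage` observing reads are skipped and counted. Reads partially
#' covering a window contribute only the CpGs they observe (`NA`
#' elsewhere).
#'
#' @param epireads Tibble with `chrom`, `cpg_index` (0-based index of the
#'   read's first CpG in the chromosome's ordered CpG list) and `states`
#'   (string over C = methylated, T = unmethylated).
#' @param cpg_positions Tibble with `chrom`, `pos` (1-based genomic
#'   position), sorted within chromosome; defines the CpG index space.
#' @param window Number of CpGs per window (default 3).
#' @param min_coverage Minimum reads observing each window CpG (default 10).
#' @param chroms Optional chromosome allow-list (e.g. the assembly's placed
#'   linkage groups); unlisted chromosomes are not scanned.
#' @return Tibble of tested windows: `chrom`, `start_index` (0-based CpG
#'   index), `pos_start`, `pos_end` (1-based genomic positions of the first
#'   and last window CpG) and a list-column `reads` of 0/1/NA matrices
#'   (reads x window CpGs). Attribute `"scan_log"` counts windows formed,
#'   skipped for coverage, and tested.
#' @export
scan_windows <- function(epireads, cpg_positions, window = 3,
                         min_coverage = 10, chroms = NULL) {
  check_columns(epireads, c("chrom", "cpg_index", "states"), "`epireads`")
  check_columns(cpg_positions, c("chrom", "pos"), "`cpg_positions`")
  window <- check_count(window, "window")
  min_coverage <- check_count(min_coverage, "min_coverage")
  use_chroms <- unique(cpg_positions$chrom)
  if (!is.null(chroms)) use_chroms <- intersect(use_chroms, chroms)

  n_formed <- 0L
  n_skipped <- 0L
  out <- purrr::map(use_chroms, function(ch) {
    pos <- sort(cpg_positions$pos[cpg_positions$chrom == ch])
    n_cpg <- length(pos)
    if (n_cpg < window) {
      warn(sprintf("chromosome %s has fewer than %d CpGs; no windows", ch,
                   window))
      return(NULL)
    }
    reads <- epireads |> filter(.data$chrom == ch)
    lens <- nchar(reads$states)
    # Read i observes CpG indices first..last (0-based).
    first <- reads$cpg_index
    last <- first + lens - 1L
    if (nrow(reads) > 0 && max(last) >= n_cpg) {
      abort(sprintf("epiread on %s extends past its CpG list", ch))
    }
    cov <- integer(n_cpg)
    for (i in seq_along(first)) {
      idx <- (first[i] + 1L):(last[i] + 1L)
      cov[idx] <- cov[idx] + 1L
    }
    starts <- 0:(n_cpg - window)
    n_formed <<- n_formed + length(starts)
    win_ok <- vapply(starts, function(s) {
      all(cov[(s + 1L):(s + window)] >= min_coverage)
    }, logical(1))
    n_skipped <<- n_skipped + sum(!win_ok)
    starts <- starts[win_ok]
    if (length(starts) == 0) return(NULL)

    state_mat <- function(s) {
      w_idx <- s:(s + window - 1L)
      keep <- which(first <= w_idx[window] & last >= w_idx[1])
      m <- matrix(NA_integer_, length(keep), window)
      for (k in seq_along(keep)) {
        i <- keep[k]
        js <- max(first[i], w_idx[1]):min(last[i], w_idx[window])
        chars <- substring(reads$states[i],
                           js - first[i] + 1L, js - first[i] + 1L)
        m[k, js - s + 1L] <- as.integer(chars == "C")
      }
      m
    }
    tibble(
      chrom = ch,
      start_index = starts,
      pos_start = pos[starts + 1L],
      pos_end = pos[starts + window],
      reads = purrr::map(starts, state_mat)
    )
  })
  out <- bind_rows(out)
  attr(out, "scan_log") <- tibble(
    windows_formed = n_formed, windows_skipped = n_skipped,
    windows_tested = nrow(out)
  )
  out
}

# Clamp per-CpG rates away from 0/1 so log-likelihoods stay finite.
clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Per-read log-likelihood under one per-CpG Bernoulli profile.
# x: reads x w matrix of 0/1/NA; returns a length-nrow(x) vector.
read_loglik <- function(x, profile) {
  lp <- log(profile)
  lq <- log1p(-profile)
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0L)
  drop(x0 %*% lp + (obs - x0) %*% lq)
}

#' Single-profile likelihood of a CpG window
#'
#' Maximum-likelihood fit of the model in which both alleles share one
#' per-CpG methylation profile: the rate at CpG j is the observed
#' methylated fraction (clamped to `[1e-6, 1 - 1e-6]`), and the
#' log-likelihood sums independent Bernoulli terms over all observed states.
#'
#' @param reads Matrix of 0/1/NA states, reads x window CpGs.
#' @return List with `loglik` and `profile` (per-CpG rates).
#' @export
fit_single_profile <- function(reads) {
  stopifnot(is.matrix(reads))
  m <- colSums(reads, na.rm = TRUE)
  n <- colSums(!is.na(reads))
  if (any(n == 0)) abort("window CpG with zero coverage; filter windows first")
  profile <- clamp_prob(m / n)
  list(loglik = sum(read_loglik(reads, profile)), profile = profile)
}

#' Two-epiallele mixture likelihood of a CpG window
#'
#' Fits the model in which the two alleles carry different per-CpG
#' methylation profiles: a 50:50 mixture of two Bernoulli profiles over
#' reads, fit by expectation-maximisation (E-step: per-read allele
#' responsibilities; M-step: responsibility-weighted per-CpG rates).
#' Several restarts are used and the best log-likelihood kept: a split
#' initialisation (reads partitioned by mean methylation), the
#' single-profile point (guaranteeing the mixture never scores below the
#' nested single-profile model), and seeded random profiles. The
#' likelihood-ratio statistic `2 * (ll_two - ll_single)` is referred to a
#' chi-square with `ncol(reads)` degrees of freedom (the added profile
#' parameters); this reference is conservative for mixtures, which is the
#' safe direction for calling.
#'
#' @param reads Matrix of 0/1/NA states, reads x window CpGs.
#' @param restarts Number of EM initialisations (default 5).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` (default 1e-8) or after `max_iter` (500) iterations.
#' @param seed Integer seed for the random restarts.
#' @param mixing Allele-A mixture weight; fixed at 0.5 (diploid) by
#'   default. Supplying `NA` estimates it by EM as well.
#' @return Object of class `amr_fit`: list with `ll_single`, `ll_two`,
#'   `lr_stat`, `p_value`, `profile_single`, `profile_a`, `profile_b`,
#'   `mixing`, `em_iterations`, `converged`.
#' @export
fit_two_profile <- function(reads, restarts = 5, max_iter = 500, tol = 1e-8,
                            seed = 1, mixing = 0.5) {
  stopifnot(is.matrix(reads))
  restarts <- check_count(restarts, "restarts")
  single <- fit_single_profile(reads)
  w <- ncol(reads)
  n_reads <- nrow(reads)
  free_mixing <- is.na(mixing)
  if (!free_mixing) check_prob(mixing, "mixing", open_left = TRUE,
                               open_right = TRUE)

  # Precompute observation masks once; the E/M loop only does small
  # matrix-vector products per iteration.
  obs <- !is.na(reads)
  x0 <- ifelse(obs, reads, 0L)
  y0 <- obs - x0
  ll_by_read <- function(p) drop(x0 %*% log(p) + y0 %*% log1p(-p))

  run_em <- function(pa, pb) {
    lam <- if (free_mixing) 0.5 else mixing
    ll_old <- -Inf
    iters <- 0L
    converged <- FALSE
    repeat {
      la <- ll_by_read(pa) + log(lam)
      lb <- ll_by_read(pb) + log1p(-lam)
      mx <- pmax(la, lb)
      ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
      if (ll - ll_old < tol) {
        converged <- ll - ll_old > -tol
        break
      }
      if (iters >= max_iter) break
      ll_old <- ll
      iters <- iters + 1L
      ra <- 1 / (1 + exp(lb - la))
      wa <- colSums(ra * obs)
      wb <- colSums((1 - ra) * obs)
      pa <- clamp_prob(colSums(ra * x0) / pmax(wa, 1e-12))
      pb <- clamp_prob(colSums((1 - ra) * x0) / pmax(wb, 1e-12))
      if (free_mixing) lam <- min(max(mean(ra), 1e-6), 1 - 1e-6)
    }
    list(ll = ll, pa = pa, pb = pb, lam = lam, iters = iters,
         converged = converged)
  }

  inits <- vector("list", restarts)
  # 1: split reads at the overall mean methylation.
  read_mean <- rowMeans(reads, na.rm = TRUE)
  hi <- read_mean >= mean(read_mean, na.rm = TRUE)
  prof_from <- function(sel) {
    if (sum(sel) == 0) return(clamp_prob(runif(w)))
    m <- colSums(reads[sel, , drop = FALSE], na.rm = TRUE)
    n <- colSums(!is.na(reads[sel, , drop = FALSE]))
    clamp_prob(ifelse(n > 0, m / n, 0.5))
  }
  inits[[1]] <- withr::with_seed(seed, list(prof_from(hi), prof_from(!hi)))
  # 2: the single-profile point (nested null; EM cannot go below it).
  if (restarts >= 2) inits[[2]] <- list(single$profile, single$profile)
  if (restarts >= 3) {
    for (r in 3:restarts) {
      inits[[r]] <- withr::with_seed(seed + r, list(clamp_prob(runif(w)),
                                                    clamp_prob(runif(w))))
    }
  }

  best <- NULL
  for (init in inits) {
    res <- run_em(init[[1]], init[[2]])
    if (is.null(best) || res$ll > best$ll) best <- res
  }

  lr <- max(0, 2 * (best$ll - single$loglik))
  structure(
    list(
      ll_single = single$loglik, ll_two = best$ll,
      lr_stat = lr, p_value = pchisq(lr, df = w, lower.tail = FALSE),
      profile_single = single$profile,
      profile_a = best$pa, profile_b = best$pb, mixing = best$lam,
      em_iterations = best$iters, converged = best$converged,
      n_reads = n_reads, window = w
    ),
    class = "amr_fit"
  )
}

#' @export
print.amr_fit <- function(x, ...) {
  cat(sprintf("<amr_fit> lr=%.3f  p=%.3g  ll_single=%.3f  ll_two=%.3f\n",
              x$lr_stat, x$p_value, x$ll_single, x$ll_two))
  invisible(x)
}

#' @method tidy amr_fit
#' @export
tidy.amr_fit <- function(x, ...) {
  tibble(cpg = seq_len(x$window), profile_single = x$profile_single,
         profile_a = x$profile_a, profile_b = x$profile_b)
}

#' @method glance amr_fit
#' @export
glance.amr_fit <- function(x, ...) {
  tibble(ll_single = x$ll_single, ll_two = x$ll_two, lr_stat = x$lr_stat,
         p.value = x$p_value, mixing = x$mixing,
         em_iterations = x$em_iterations, converged = x$converged,
         n_reads = x$n_reads)
}

#' Fit the two-model comparison on every tested window
#'
#' @param windows Output of [scan_windows()].
#' @param restarts,seed Passed to [fit_two_profile()]; each window gets a
#'   distinct seed derived from `seed` so results are reproducible but
#'   windows are independent.
#' @return `windows` (without the `reads` list-column) plus `ll_single`,
#'   `ll_two`, `lr_stat`, `p_value`, `converged`.
#' @export
test_amr_windows <- function(windows, restarts = 5, seed = 1) {
  if (nrow(windows) == 0) {
    return(tibble(chrom = character(), start_index = integer(),
                  pos_start = integer(), pos_end = integer(),
                  lr_stat = numeric(), p_value = numeric()))
  }
  fits <- purrr::imap(windows$reads, function(m, i) {
    fit_two_profile(m, restarts = restarts, seed = seed + i)
  })
  windows |>
    select(-"reads") |>
    mutate(
      ll_single = purrr::map_dbl(fits, "ll_single"),
      ll_two = purrr::map_dbl(fits, "ll_two"),
      lr_stat = purrr::map_dbl(fits, "lr_stat"),
      p_value = purrr::map_dbl(fits, "p_value"),
      converged = purrr::map_lgl(fits, "converged")
    )
}

#' Call allelically methylated regions from window fits
#'
#' Benjamini-Hochberg correction is applied across all tested windows;
#' significant windows (`q < q_threshold`) that overlap or abut in CpG
#' index space on the same chromosome are merged into regions. A region's
#' interval spans the first to last CpG of its member windows, reported
#' BED-style (0-based half-open). The region carries the minimum member
#' p and q values; q is not recomputed at region level.
#'
#' @param window_fits Output of [test_amr_windows()].
#' @param q_threshold Window-level FDR threshold (default 0.05).
#' @param window Window width in CpGs used when scanning (default 3).
#' @return Tibble of regions: `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_windows`, `p_value`, `q_value`.
#' @export
call_amrs <- function(window_fits, q_threshold = 0.05, window = 3) {
  check_prob(q_threshold, "q_threshold", open_left = TRUE, open_right = TRUE)
  empty <- tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_windows = integer(),
                  p_value = numeric(), q_value = numeric())
  if (nrow(window_fits) == 0) return(empty)
  fits <- window_fits |> mutate(q_value = bh_adjust(.data$p_value))
  sig <- fits |> filter(.data$q_value < q_threshold) |>
    arrange(.data$chrom, .data$start_index)
  if (nrow(sig) == 0) return(empty)

  sig <- sig |>
    group_by(.data$chrom) |>
    mutate(
      # New region when this window neither overlaps nor abuts the previous
      # one's CpG range [start_index, start_index + window - 1].
      new_run = c(TRUE, diff(.data$start_index) > window),
      run = cumsum(.data$new_run)
    ) |>
    ungroup()

  sig |>
    group_by(.data$chrom, .data$run) |>
    summarise(
      start = min(.data$pos_start) - 1L,  # 0-based half-open output
      end = max(.data$pos_end),
      n_windows = n(),
      p_value = min(.data$p_value),
      q_value = min(.data$q_value),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("amr_%03d", row_number())) |>
    select("region_id", "chrom", "start", "end", "n_windows",
           "p_value", "q_value")
}

#' Annotate AMRs with genes and exon/intron features
#'
#' Intersects regions (0-based half-open) with gene models (1-based
#' inclusive). A region overlapping several genes lists them all. The
#' feature is `"exon"` if the region intersects any exon of an assigned
#' gene, `"intron"` if it lies in a gene body without touching an exon,
#' and `"no_annotation"` outside genes.
#'
#' @param regions Output of [call_amrs()].
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`).
#' @param exons Optional exon tibble (`gene_id`, `chrom`, `start`, `end`);
#'   without it gene-overlapping regions are all labelled `"intron"`.
#' @return `regions` plus `gene_ids` (semicolon-joined), `n_genes`,
#'   `feature`.
#' @export
annotate_amrs <- function(regions, genes, exons = NULL) {
  check_columns(regions, c("region_id", "chrom", "start", "end"),
                "`regions`")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "`genes`")
  if (nrow(regions) == 0) {
    return(regions |> mutate(gene_ids = character(0), n_genes = integer(0),
                             feature = character(0)))
  }
  # Convert regions to 1-based inclusive for interval intersection.
  reg1 <- regions |> mutate(r_start = .data$start + 1L, r_end = .data$end)
  hit <- function(feats) {
    inner_join(
      reg1 |> select("region_id", "chrom", "r_start", "r_end"),
      feats |> select("gene_id", "chrom", f_start = "start", f_end = "end"),
      by = join_by("chrom", "r_start" <= "f_end", "r_end" >= "f_start")
    )
  }
  gene_hits <- hit(genes)
  gene_sum <- gene_hits |>
    group_by(.data$region_id) |>
    summarise(gene_ids = paste(sort(unique(.data$gene_id)), collapse = ";"),
              n_genes = n_distinct(.data$gene_id), .groups = "drop")
  exon_regions <- if (!is.null(exons) && nrow(exons) > 0) {
    unique(hit(exons)$region_id)
  } else character(0)

  regions |>
    left_join(gene_sum, by = "region_id") |>
    mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      gene_ids = dplyr::coalesce(.data$gene_ids, ""),
      feature = dplyr::case_when(
        n_genes == 0 ~ "no_annotation",
        region_id %in% exon_regions ~ "exon",
        TRUE ~ "intron"
      )
    )
}

#' Gene-level weighted methylation
#'
#' The weighted methylation level of a gene is the sum of methylated read
#' counts over all its CpGs divided by the sum of total read counts - a
#' coverage-weighted mean. A gene is called methylated when its level
#' exceeds the bisulfite conversion error rate (strictly greater than
#' `error_rate`, default 0.05).
#'
#' @param cytosine Cytosine report tibble: `chrom`, `pos`,
#'   `count_methylated`, `count_unmethylated`.
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param error_rate Conversion error rate (default 0.05).
#' @return Tibble: `gene_id`, `n_cpgs`, `weighted_level`, `is_methylated`.
#'   Genes with no covered CpG are omitted.
#' @export
weighted_methylation <- function(cytosine, genes, error_rate = 0.05) {
  check_columns(cytosine, c("chrom", "pos", "count_methylated",
                            "count_unmethylated"), "`cytosine`")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "`genes`")
  check_prob(error_rate, "error_rate")
  inner_join(
    cytosine,
    genes |> select("gene_id", "chrom", "start", "end"),
    by = join_by("chrom", between("pos", "start", "end"))
  ) |>
    group_by(.data$gene_id) |>
    summarise(
      n_cpgs = n(),
      weighted_level = sum(.data$count_methylated) /
        sum(.data$count_methylated + .data$count_unmethylated),
      .groups = "drop"
    ) |>
    mutate(is_methylated = .data$weighted_level > error_rate)
}

#' Run the full AMR pipeline
#'
#' Chains [scan_windows()], [test_amr_windows()], [call_amrs()] and
#' optionally [annotate_amrs()].
#'
#' @param epireads,cpg_positions,chroms See [scan_windows()].
#' @param genes,exons Optional annotation; see [annotate_amrs()].
#' @param window,min_coverage,q_threshold,restarts,seed Caller parameters.
#' @return List with `regions`, `window_fits` and `log` (scan accounting).
#' @export
amr_pipeline <- function(epireads, cpg_positions, genes = NULL, exons = NULL,
                         chroms = NULL, window = 3, min_coverage = 10,
                         q_threshold = 0.05, restarts = 5, seed = 1) {
  windows <- scan_windows(epireads, cpg_positions, window = window,
                          min_coverage = min_coverage, chroms = chroms)
  slog <- attr(windows, "scan_log")
  fits <- test_amr_windows(windows, restarts = restarts, seed = seed)
  regions <- call_amrs(fits, q_threshold = q_threshold, window = window)
  if (!is.null(genes)) regions <- annotate_amrs(regions, genes, exons)
  list(regions = regions, window_fits = fits, log = slog)
}
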