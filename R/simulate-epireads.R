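#' Simulate bisulfite epireads from one- or two-epiallele regions
#'
#' Generates epiread records (the methylation states of consecutive CpGs on
#' single reads) and the matching per-CpG cytosine report for a set of
#' regions with known truth. Regions flagged as allelically methylated draw
#' each read from epiallele profile A with probability `mixing` and from
#' profile B otherwise - the 50:50 diploid mixture the window caller models.
#' Non-AMR regions draw every read from one shared profile (by default the
#' midpoint of the two profiles, an intermediate-methylation null). Every
#' sampled state is then flipped with probability `conversion_error`,
#' emulating incomplete/over-conversion noise in bisulfite data.
#'
#' Each region is placed on its own chromosome so that the sliding window of
#' the caller never straddles two simulated regions; reads cover every CpG
#' of their region unless `partial_read_rate` trims read ends.
#'
#' @param n_regions Number of regions.
#' @param cpgs_per_region CpGs per region (must be >= the caller's window).
#' @param cpg_spacing Distance in bp between consecutive CpGs.
#' @param reads_per_cpg Number of reads per region (full-length reads, so
#'   this is also the per-CpG coverage).
#' @param profile_a,profile_b Per-CpG methylation probabilities of the two
#'   epialleles; scalars are recycled to `cpgs_per_region`.
#' @param is_amr Logical vector (recycled) flagging which regions carry two
#'   distinct epialleles.
#' @param null_profile Per-CpG methylation probabilities used for non-AMR
#'   regions; default `(profile_a + profile_b) / 2`.
#' @param mixing Probability a read from an AMR region comes from profile A
#'   (default 0.5, the diploid expectation).
#' @param conversion_error Per-state flip probability (default 0.05, the
#'   conversion error floor assumed downstream).
#' @param partial_read_rate Probability that a read is trimmed; a trimmed
#'   read loses a uniform number of CpGs from one end (default 0, full
#'   reads).
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A list of tibbles:
#' \describe{
#'   \item{epireads}{`chrom`, `cpg_index` (0-based index of the read's first
#'     CpG within the chromosome's ordered CpG list), `states` (string over
#'     C = methylated, T = unmethylated).}
#'   \item{cytosine}{per-CpG report: `chrom`, `pos` (1-based), `strand`,
#'     `count_methylated`, `count_unmethylated`; equals the column sums of
#'     the epireads.}
#'   \item{cpg_positions}{`chrom`, `pos` for every simulated CpG.}
#'   \item{truth}{`region_id`, `chrom`, `start`, `end`, `is_amr`.}
#' }
#' @export
#' @examples
#' sim <- simulate_epireads(n_regions = 2, cpgs_per_region = 5,
#'                          reads_per_cpg = 10, is_amr = c(TRUE, FALSE),
#'                          seed = 1)
#' head(sim$epireads)
simulate_epireads <- function(n_regions,
                              cpgs_per_region = 12,
                              cpg_spacing = 50,
                              reads_per_cpg = 15,
                              profile_a = 0.9,
                              profile_b = 0.1,
                              is_amr = FALSE,
                              null_profile = NULL,
                              mixing = 0.5,
                              conversion_error = 0.05,
                              partial_read_rate = 0,
                              seed = 1) {
  n_regions <- check_count(n_regions, "n_regions")
  cpgs_per_region <- check_count(cpgs_per_region, "cpgs_per_region")
  reads_per_cpg <- check_count(reads_per_cpg, "reads_per_cpg")
  check_prob(mixing, "mixing")
  check_prob(conversion_error, "conversion_error")
  check_prob(partial_read_rate, "partial_read_rate")
  w <- cpgs_per_region
  expand_profile <- function(p, name) {
    if (length(p) == 1) p <- rep(p, w)
    if (length(p) != w) {
      abort(sprintf("`%s` must have length 1 or cpgs_per_region (%d)", name, w))
    }
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      abort(sprintf("`%s` probabilities must lie in [0, 1]", name))
    }
    p
  }
  profile_a <- expand_profile(profile_a, "profile_a")
  profile_b <- expand_profile(profile_b, "profile_b")
  null_profile <- expand_profile(null_profile %||% ((profile_a + profile_b) / 2),
                                 "null_profile")
  is_amr <- rep_len(as.logical(is_amr), n_regions)
  seed <- check_count(seed, "seed", min = 0)

  withr::with_seed(seed, {
    region_id <- sprintf("region_%03d", seq_len(n_regions))
    chroms <- sprintf("LG%d", seq_len(n_regions))
    pos <- 100L + cpg_spacing * (seq_len(w) - 1L)

    per_region <- purrr::map(seq_len(n_regions), function(r) {
      n_reads <- reads_per_cpg
      if (is_amr[r]) {
        from_a <- runif(n_reads) < mixing
        probs <- rbind(profile_a, profile_b)[2 - from_a, , drop = FALSE]
      } else {
        probs <- matrix(null_profile, n_reads, w, byrow = TRUE)
      }
      states <- matrix(runif(n_reads * w) < probs, n_reads, w)
      flip <- matrix(runif(n_reads * w) < conversion_error, n_reads, w)
      states <- xor(states, flip)

      first <- rep(0L, n_reads)
      last <- rep(w - 1L, n_reads)
      if (partial_read_rate > 0) {
        trim <- runif(n_reads) < partial_read_rate
        n_trim <- sum(trim)
        if (n_trim > 0) {
          # Trim 1..(w-1) CpGs off one end, keeping >= 1 CpG.
          k <- sample(w - 1L, n_trim, replace = TRUE)
          from_start <- runif(n_trim) < 0.5
          first[trim] <- ifelse(from_start, k, 0L)
          last[trim] <- ifelse(from_start, w - 1L, w - 1L - k)
        }
      }
      state_str <- vapply(seq_len(n_reads), function(i) {
        paste(ifelse(states[i, (first[i] + 1):(last[i] + 1)], "C", "T"),
              collapse = "")
      }, character(1))

      meth <- integer(w)
      tot <- integer(w)
      for (i in seq_len(n_reads)) {
        idx <- (first[i] + 1):(last[i] + 1)
        meth[idx] <- meth[idx] + states[i, idx]
        tot[idx] <- tot[idx] + 1L
      }
      list(
        epireads = tibble(chrom = chroms[r], cpg_index = first,
                          states = state_str),
        cytosine = tibble(chrom = chroms[r], pos = pos, strand = "+",
                          count_methylated = meth,
                          count_unmethylated = tot - meth),
        cpg_positions = tibble(chrom = chroms[r], pos = pos)
      )
    })

    list(
      epireads = bind_rows(purrr::map(per_region, "epireads")),
      cytosine = bind_rows(purrr::map(per_region, "cytosine")),
      cpg_positions = bind_rows(purrr::map(per_region, "cpg_positions")),
      truth = tibble(region_id = region_id, chrom = chroms,
                     start = pos[1], end = pos[w], is_amr = is_amr)
    )
  })
}
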