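#' Default pipeline configuration
#'
#' Collects every tunable threshold of the ASE and AMR callers in one
#' validated list. Values are the defaults used throughout: minimum SNP
#' coverage 10, gene testable in >= 2 colonies for a status, ASE call at
#' q < 0.05 and mean proportion > 0.65, AMR windows of 3 CpGs at >= 10
#' reads per CpG, window q < 0.05, 5 EM restarts, methylated-gene cut-off
#' at the 0.05 conversion error rate.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `beeallele_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_coverage = 10, min_colonies = 2,
    ase_q_threshold = 0.05, prop_threshold = 0.65,
    window = 3, min_cpg_coverage = 10, amr_q_threshold = 0.05,
    restarts = 5, error_rate = 0.05, chroms = NULL, seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  for (f in c("ase_q_threshold", "prop_threshold", "amr_q_threshold",
              "error_rate")) {
    check_prob(cfg[[f]], f, open_left = f != "error_rate",
               open_right = f != "error_rate")
  }
  for (f in c("min_coverage", "min_colonies", "window", "min_cpg_coverage",
              "restarts")) {
    check_count(cfg[[f]], f)
  }
  check_count(cfg$seed, "seed", min = 0)
  structure(cfg, class = "beeallele_config")
}

#' Run the integrated ASE + AMR + overlap pipeline
#'
#' Orchestrates the whole analysis on in-memory inputs: per-SNP allelic
#' counts through the ASE caller, epireads through the AMR caller,
#' gene-level weighted methylation, and the overlap statistics tying the
#' two gene lists together. Every stage's row accounting is collected in a
#' run log, and the run is fully deterministic given `cfg$seed`.
#'
#' @param counts Per-SNP count tibble (see [read_counts_table()] /
#'   [simulate_ase_counts()]).
#' @param samples Sample sheet tibble.
#' @param genes Gene models tibble; `exons` optional.
#' @param epireads,cpg_positions Epiread inputs (see [scan_windows()]);
#'   optional - without them the methylation arm is skipped.
#' @param cytosine Optional cytosine report for [weighted_methylation()].
#' @param exons Optional exon models.
#' @param cfg Configuration from [pipeline_config()].
#' @return List with `ase` (results + gene table), `amr` (regions + window
#'   fits), `methylation`, `overlap` (ASE x AMR hypergeometric test, when
#'   both arms ran) and `log`.
#' @export
run_pipeline <- function(counts, samples, genes,
                         epireads = NULL, cpg_positions = NULL,
                         cytosine = NULL, exons = NULL,
                         cfg = pipeline_config()) {
  if (!inherits(cfg, "beeallele_config")) {
    abort("`cfg` must come from pipeline_config()")
  }
  logs <- list()

  ase <- ase_pipeline(counts, samples, genes,
                      min_coverage = cfg$min_coverage,
                      min_colonies = cfg$min_colonies,
                      q_threshold = cfg$ase_q_threshold,
                      prop_threshold = cfg$prop_threshold)
  logs$ase_filter <- ase$log

  amr <- NULL
  meth <- NULL
  if (!is.null(epireads)) {
    if (is.null(cpg_positions)) abort("epireads require `cpg_positions`")
    amr <- amr_pipeline(epireads, cpg_positions, genes = genes,
                        exons = exons, chroms = cfg$chroms,
                        window = cfg$window,
                        min_coverage = cfg$min_cpg_coverage,
                        q_threshold = cfg$amr_q_threshold,
                        restarts = cfg$restarts, seed = cfg$seed)
    logs$amr_scan <- amr$log
  }
  if (!is.null(cytosine)) {
    meth <- weighted_methylation(cytosine, genes,
                                 error_rate = cfg$error_rate)
  }

  overlap <- NULL
  if (!is.null(amr) && nrow(ase$results) > 0) {
    ase_genes <- ase$results$gene_id[ase$results$class != "none"]
    amr_genes <- if (nrow(amr$regions) > 0 && "gene_ids" %in% names(amr$regions)) {
      unique(unlist(strsplit(amr$regions$gene_ids, ";")))
    } else character(0)
    amr_genes <- setdiff(amr_genes, "")
    universe <- union(ase$results$gene_id, amr_genes)
    if (length(universe) > 0) {
      overlap <- hypergeom_overlap(intersect(ase_genes, universe),
                                   intersect(amr_genes, universe), universe)
    }
  }

  list(ase = ase, amr = amr, methylation = meth, overlap = overlap,
       log = logs, config = cfg)
}
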