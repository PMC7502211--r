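#' Read a per-SNP allelic count table
#'
#' Reads the tab-separated output shape of GATK ASEReadCounter: columns
#' `contig`, `position`, `refCount`, `altCount` plus a `sample` column
#' (other columns such as `variantID` or `totalCount` are ignored). Rows
#' with missing or negative counts are rejected with their line numbers.
#'
#' @param path Path to a TSV file.
#' @return Tibble with `sample_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`.
#' @export
read_counts_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("contig", "position", "refCount", "altCount", "sample")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(sprintf("counts file %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(df$position) | is.na(df$refCount) | is.na(df$altCount) |
                 df$refCount < 0 | df$altCount < 0 | df$position < 1)
  if (length(bad) > 0) {
    abort(sprintf("malformed count row(s) at line(s): %s",
                  paste(head(bad + 1L, 10), collapse = ", ")))
  }
  tibble(
    sample_id = as.character(df$sample), chrom = as.character(df$contig),
    pos = as.integer(df$position), ref_count = as.integer(df$refCount),
    alt_count = as.integer(df$altCount)
  )
}

#' Write a per-SNP allelic count table
#'
#' Inverse of [read_counts_table()]; writes the ASEReadCounter-style
#' header.
#'
#' @param counts Tibble with `sample_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  check_columns(counts, c("sample_id", "chrom", "pos", "ref_count",
                          "alt_count"), "`counts`")
  readr::write_tsv(
    tibble(contig = counts$chrom, position = counts$pos,
           refCount = counts$ref_count, altCount = counts$alt_count,
           sample = counts$sample_id),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `colony`, `status`.
#' @return Tibble with `sample_id`, `colony`, `status`.
#' @export
read_samples <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("sample", "colony", "status"),
                sprintf("sample sheet %s", path))
  tibble(sample_id = as.character(df$sample),
         colony = as.character(df$colony),
         status = as.character(df$status))
}

#' Read gene and exon models from GFF3
#'
#' Parses a GFF3 file (via [rtracklayer::readGFF()]) and returns gene and
#' exon intervals with 1-based inclusive coordinates preserved. Exons are
#' attached to their gene by walking `Parent` attributes (so exons nested
#' under mRNA features resolve to the grandparent gene). Exons extending
#' outside their gene's span are a validation error.
#'
#' @param path Path to a GFF3 file.
#' @return List of tibbles `genes` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`) and `exons` (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gff <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  ids <- as.character(g$ID)
  parents <- vapply(g$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  is_gene <- g$type == "gene"
  gene_of <- function(i) {
    # Walk Parent links up to a gene feature (bounded walk).
    cur <- i
    for (step in 1:5) {
      p <- parents[cur]
      if (is.na(p)) return(NA_character_)
      j <- match(p, ids)
      if (is.na(j)) return(NA_character_)
      if (is_gene[j]) return(gene_label(g, j))
      cur <- j
    }
    NA_character_
  }
  gene_label <- function(g, i) {
    lbl <- g$ID[i]
    if (is.na(lbl) || lbl == "") lbl <- paste0("gene_row_", i)
    as.character(lbl)
  }
  genes <- tibble(
    gene_id = vapply(which(is_gene), function(i) gene_label(g, i),
                     character(1)),
    chrom = as.character(g$seqid[is_gene]),
    start = as.integer(g$start[is_gene]),
    end = as.integer(g$end[is_gene]),
    strand = as.character(g$strand[is_gene])
  )
  exon_rows <- which(g$type == "exon")
  exons <- tibble(
    gene_id = vapply(exon_rows, gene_of, character(1)),
    chrom = as.character(g$seqid[exon_rows]),
    start = as.integer(g$start[exon_rows]),
    end = as.integer(g$end[exon_rows])
  ) |> filter(!is.na(.data$gene_id))
  chk <- inner_join(exons, genes, by = "gene_id", suffix = c("", ".gene"))
  bad <- chk$start < chk$start.gene | chk$end > chk$end.gene
  if (any(bad)) {
    abort(sprintf("%d exon(s) extend outside their gene span in %s",
                  sum(bad), path))
  }
  list(genes = genes, exons = exons)
}

#' Read an epiread file
#'
#' One record per line: `chrom TAB first-CpG-index TAB state-string`, the
#' state string over C (methylated) / T (unmethylated) and the index
#' 0-based within the chromosome's ordered CpG list.
#'
#' @param path Path to the epiread text file.
#' @return Tibble with `chrom`, `cpg_index`, `states`.
#' @export
read_epireads <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "cpg_index", "states"),
                        col_types = "cic", progress = FALSE)
  bad <- which(is.na(df$cpg_index) | df$cpg_index < 0 |
                 !grepl("^[CT]+$", df$states))
  if (length(bad) > 0) {
    abort(sprintf("malformed epiread(s) at line(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  df
}

#' Write an epiread file
#'
#' @param epireads Tibble with `chrom`, `cpg_index`, `states`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epireads <- function(epireads, path) {
  check_columns(epireads, c("chrom", "cpg_index", "states"), "`epireads`")
  readr::write_tsv(epireads[c("chrom", "cpg_index", "states")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a per-CpG cytosine report
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `strand`,
#'   `count_methylated`, `count_unmethylated`.
#' @return Tibble of the same columns.
#' @export
read_cytosine_report <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("chrom", "pos", "strand", "count_methylated",
                      "count_unmethylated"),
                sprintf("cytosine report %s", path))
  if (any(df$count_methylated < 0 | df$count_unmethylated < 0, na.rm = TRUE)) {
    abort("negative counts in cytosine report")
  }
  as_tibble(df)
}

#' Read a gene-to-GO-term map
#'
#' Expects a TSV with two columns: gene id and a `;`-separated list of GO
#' terms. Returned in long form, one row per (gene, term).
#'
#' @param path Path to the map file.
#' @return Tibble with `gene_id`, `term`.
#' @export
read_go_map <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene_id", "terms"),
                        col_types = "cc", progress = FALSE)
  if (tolower(df$gene_id[1]) %in% c("gene_id", "gene")) df <- df[-1, ]
  df |>
    mutate(term = stringr::str_split(.data$terms, ";")) |>
    tidyr::unnest("term") |>
    mutate(term = stringr::str_trim(.data$term)) |>
    filter(.data$term != "") |>
    select("gene_id", "term") |>
    distinct()
}

#' Write called AMRs as BED6+
#'
#' Chrom, 0-based half-open interval, region id, a score of
#' `-10 * log10(q)` capped at 1000, `.` strand, then p, q, genes and
#' feature columns.
#'
#' @param regions Annotated region tibble from [annotate_amrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amr_bed <- function(regions, path) {
  check_columns(regions, c("chrom", "start", "end", "region_id", "p_value",
                           "q_value"), "`regions`")
  bed <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$region_id,
    score = round(pmin(1000, -10 * log10(pmax(regions$q_value, 1e-100)))),
    strand = ".",
    p = regions$p_value, q = regions$q_value,
    genes = regions$gene_ids %||% "", feature = regions$feature %||% ""
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
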