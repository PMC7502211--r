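# Small in-code fixtures shared across test files.

# A minimal sample sheet for hand-built count tables.
toy_samples <- function(colonies = c("A", "B", "C"),
                        statuses = c("reproductive", "sterile"),
                        replicates = 1) {
  grid <- expand.grid(colony = colonies, status = statuses,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%s_r%d", grid$colony, grid$status,
                        grid$replicate),
    colony = grid$colony, status = grid$status
  )
}

# One hand-built SNP count row.
snp_row <- function(sample_id, pos, ref, alt, chrom = "LG1",
                    gene_id = NA_character_) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = pos,
                 gene_id = gene_id, ref_count = ref, alt_count = alt)
}

# Read matrix with n_a copies of pattern a and n_b of pattern b (0/1
# vectors).
read_matrix <- function(pattern_a, n_a, pattern_b = NULL, n_b = 0) {
  m <- matrix(rep(pattern_a, each = n_a), n_a)
  if (n_b > 0) m <- rbind(m, matrix(rep(pattern_b, each = n_b), n_b))
  storage.mode(m) <- "integer"
  m
}

# Mixture log-likelihood of a read matrix under two given profiles at
# 50:50 mixing; independent of the EM code path.
mixture_loglik <- function(reads, pa, pb) {
  per_read <- function(x, p) {
    obs <- !is.na(x)
    sum(x[obs] * log(p[obs]) + (1 - x[obs]) * log(1 - p[obs]))
  }
  sum(apply(reads, 1, function(x) {
    la <- per_read(x, pa) + log(0.5)
    lb <- per_read(x, pb) + log(0.5)
    m <- max(la, lb)
    m + log(exp(la - m) + exp(lb - m))
  }))
}

# Exhaustive-enumeration oracle for the upper-tail overlap probability:
# all ways of drawing |A| elements from the universe, counting those with
# overlap >= k against the fixed set B.
enumerate_overlap_p <- function(n_universe, n_a, n_b, k) {
  draws <- utils::combn(n_universe, n_a)
  hits <- colSums(draws <= n_b)  # B is elements 1..n_b
  mean(hits >= k)
}

# Step-up BH oracle, straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}
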