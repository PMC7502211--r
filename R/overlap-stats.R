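#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two gene sets when `|A|` genes are drawn without replacement from a
#' universe containing `|B|` "successes". The p-value is meaningless
#' without a declared universe, so the universe is a required argument and
#' both sets must be contained in it.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @return Tibble with `overlap`, `size_a`, `size_b`, `universe_size`,
#'   `expected`, `p_value`.
#' @export
#' @examples
#' hypergeom_overlap(letters[1:5], letters[1:5], letters[1:10])
hypergeom_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of `universe`")
  }
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b); n_u <- length(universe)
  tibble(
    overlap = k, size_a = n_a, size_b = n_b, universe_size = n_u,
    expected = n_a * n_b / n_u,
    p_value = phyper(k - 1, n_b, n_u - n_b, n_a, lower.tail = FALSE)
  )
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic for observed counts against expected proportions
#' (equal by default), with `length(observed) - 1` degrees of freedom.
#'
#' @param observed Vector of category counts.
#' @param expected_prop Expected proportions (default equal); recycled and
#'   normalised to sum to 1.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi2_gof(c(303, 201))
chi2_gof <- function(observed, expected_prop = NULL) {
  if (length(observed) < 2 || any(observed < 0)) {
    abort("`observed` needs >= 2 non-negative counts")
  }
  expected_prop <- expected_prop %||% rep(1, length(observed))
  expected_prop <- rep_len(expected_prop, length(observed))
  expected_prop <- expected_prop / sum(expected_prop)
  expected <- sum(observed) * expected_prop
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the t
#' approximation (via [stats::cor.test()] with `exact = FALSE`).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tibble with `rho`, `s_statistic`, `n`, `p_value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                  exact = FALSE))
  tibble(rho = unname(ct$estimate), s_statistic = unname(ct$statistic),
         n = sum(ok), p_value = ct$p.value)
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Kruskal-Wallis H (with tie correction, via [stats::kruskal.test()])
#' across groups, followed by pairwise Dunn Z tests using the tie-corrected
#' pooled rank variance, two-sided, with Benjamini-Hochberg adjustment over
#' the pairwise family.
#'
#' @param values Numeric vector of observations (e.g. allelic proportions).
#' @param groups Factor or character vector of group labels, same length.
#' @return List with `kruskal` (tibble: `statistic`, `df`, `p_value`) and
#'   `dunn` (tibble: `group1`, `group2`, `z`, `p_value`, `q_value`).
#' @export
#' @examples
#' kruskal_dunn(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_dunn <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length")
  }
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  if (n_distinct(groups) < 2) abort("need at least two groups")
  kw <- kruskal.test(values, factor(groups))

  r <- rank(values)
  big_n <- length(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (big_n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2)
  z <- apply(pairs, 2, function(pr) {
    num <- mean_rank[[pr[1]]] - mean_rank[[pr[2]]]
    den <- sqrt((big_n * (big_n + 1) / 12 - tie_corr) *
                  (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    num / den
  })
  p <- 2 * stats::pnorm(-abs(z))
  list(
    kruskal = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p_value = kw$p.value),
    dunn = tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                  p_value = p, q_value = bh_adjust(p))
  )
}

#' Interaction-versus-main-effects ANOVA
#'
#' Compares the least-squares fit of `response ~ a + b` with
#' `response ~ a * b` and reports the F test of the interaction terms.
#'
#' @param data Data frame.
#' @param response,a,b Column names (strings) of the response and the two
#'   factors.
#' @return Tibble with `f_statistic`, `df1`, `df2`, `p_value`, `rss_main`,
#'   `rss_interaction`.
#' @export
interaction_anova <- function(data, response, a, b) {
  check_columns(data, c(response, a, b), "`data`")
  dat <- data.frame(y = data[[response]],
                    a = factor(data[[a]]), b = factor(data[[b]]))
  main <- lm(y ~ a + b, data = dat)
  inter <- lm(y ~ a * b, data = dat)
  cmp <- anova(main, inter)
  tibble(
    f_statistic = cmp$F[2], df1 = cmp$Df[2], df2 = inter$df.residual,
    p_value = cmp$`Pr(>F)`[2],
    rss_main = cmp$RSS[1], rss_interaction = cmp$RSS[2]
  )
}

#' GO term enrichment by hypergeometric test
#'
#' For each term annotated to at least one study gene, tests whether the
#' term's genes are over-represented in the study set relative to a
#' caller-supplied background (upper-tail hypergeometric), with
#' Benjamini-Hochberg correction across terms. Terms are used exactly as
#' annotated - no ancestor propagation - matching a flat custom-database
#' workflow. The background should reflect the detection universe:
#' expressed genes for ASE lists, methylated genes for ASM lists, the whole
#' annotation for joint lists.
#'
#' @param study Character vector of study gene ids (must be within
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param go_map Tibble with `gene_id`, `term` (one row per annotation), as
#'   from [read_go_map()].
#' @param q_threshold Optional; when non-NULL only terms with
#'   `q_value < q_threshold` are returned.
#' @return Tibble per term: `term`, `k` (study hits), `big_k` (background
#'   hits), `n` (study size), `big_n` (background size), `p_value`,
#'   `q_value`, sorted by p.
#' @export
go_enrichment <- function(study, background, go_map, q_threshold = NULL) {
  check_columns(go_map, c("gene_id", "term"), "`go_map`")
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background)) {
    abort("`study` must be a subset of `background`")
  }
  if (length(study) == 0) {
    return(tibble(term = character(), k = integer(), big_k = integer(),
                  n = integer(), big_n = integer(), p_value = numeric(),
                  q_value = numeric()))
  }
  ann <- go_map |> filter(.data$gene_id %in% background) |> distinct()
  n <- length(study)
  big_n <- length(background)
  res <- ann |>
    group_by(.data$term) |>
    summarise(
      k = sum(unique(.data$gene_id) %in% study),
      big_k = n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    filter(.data$k > 0) |>
    mutate(
      n = n, big_n = big_n,
      p_value = phyper(.data$k - 1, .data$big_k, big_n - .data$big_k, n,
                       lower.tail = FALSE)
    ) |>
    mutate(q_value = bh_adjust(.data$p_value)) |>
    arrange(.data$p_value)
  if (!is.null(q_threshold)) res <- res |> filter(.data$q_value < q_threshold)
  res
}

#' Partition two gene sets into shared and unique members
#'
#' @param set_a,set_b Character vectors.
#' @param names Labels for the two sets, used in the summary tibble.
#' @return List with `shared`, `a_only`, `b_only` (character vectors) and
#'   `summary` (tibble of the three counts).
#' @export
#' @examples
#' classify_shared(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
classify_shared <- function(set_a, set_b, names = c("a", "b")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  list(
    shared = shared, a_only = a_only, b_only = b_only,
    summary = tibble(
      subset = c("shared", paste0(names[1], "_only"), paste0(names[2], "_only")),
      n = c(length(shared), length(a_only), length(b_only))
    )
  )
}
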