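# The geNorm algorithm: pairwise log-ratio variation, average expression
# stability M, iterative exclusion ranking, geometric-mean normalization
# factors, and the pairwise variation V(n/n+1) used to choose how many
# reference genes to combine.
#
# All logarithms are base 2 (the field's convention for expression ratios).
# M, V_jk and V(n/n+1) are standard deviations of log2 ratios, so changing
# the base would rescale them jointly with the customary 0.15 V-threshold.
# Sample standard deviation (n - 1 denominator) is used throughout.

#' Pairwise variation matrix of a quantity matrix
#'
#' For genes j and k, `V_jk` is the standard deviation over samples of
#' `log2(Q_j / Q_k)`: 0 when two genes are perfectly proportional, growing
#' as their profiles diverge. The diagonal is `NA` (a gene has no variation
#' against itself).
#'
#' @param q Genes x samples matrix of positive relative quantities,
#'   at least 2 genes and 3 samples.
#' @return Symmetric genes x genes matrix of pairwise variations, `NA`
#'   diagonal.
#' @export
pairwise_variation_matrix <- function(q) {
  check_quantity_matrix(q, min_genes = 2)
  if (ncol(q) < 3) stop("at least 3 samples are required (sd over samples is ill-conditioned)")
  y <- log2(q)
  n <- nrow(y)
  v <- matrix(NA_real_, n, n, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      v_jk <- sd(y[j, ] - y[k, ])
      v[j, k] <- v_jk
      v[k, j] <- v_jk
    }
  }
  v
}

#' geNorm expression stability values M
#'
#' `M_j` is the mean of gene j's pairwise variations against every other
#' gene. The gene with the highest M is the least stable. M is invariant to
#' rescaling any gene or any sample by a positive constant (both are shifts
#' on the log-ratio scale).
#'
#' @inheritParams pairwise_variation_matrix
#' @return Named numeric vector of M values.
#' @export
m_values <- function(q) {
  v <- pairwise_variation_matrix(q)
  rowMeans(v, na.rm = TRUE)
}

#' geNorm iterative exclusion ranking
#'
#' Repeatedly computes M on the remaining genes and removes the gene with
#' the highest M, until two genes remain. The final two genes cannot be
#' ranked against each other (their M values are identical by construction)
#' and are reported as an unordered pair sharing ranks 1-2. An exact tie in
#' the argmax is broken deterministically by excluding the gene that sorts
#' later lexicographically, and the round is recorded.
#'
#' @inheritParams pairwise_variation_matrix
#' @param q Matrix with at least 3 genes.
#' @return A list with `order` (genes from most to least stable; the first
#'   two form the unordered final pair, stored sorted), `final_pair`,
#'   `exclusion` (tibble: `round`, `gene`, `m_value`, `n_remaining` for each
#'   excluded gene), `m_by_round` (list of named M vectors, round 1 = all
#'   genes), and `tie_rounds`.
#' @export
rank_genes_genorm <- function(q) {
  check_quantity_matrix(q, min_genes = 3)
  remaining <- rownames(q)
  exclusion <- list()
  m_by_round <- list()
  tie_rounds <- integer(0)
  round <- 1L
  while (length(remaining) > 2) {
    m <- m_values(q[remaining, , drop = FALSE])
    m_by_round[[round]] <- m
    worst_m <- max(m)
    candidates <- names(m)[m >= worst_m - 1e-12]
    if (length(candidates) > 1) tie_rounds <- c(tie_rounds, round)
    drop_gene <- sort(candidates)[length(candidates)]  # later lexicographic
    exclusion[[round]] <- tibble::tibble(
      round = round, gene = drop_gene, m_value = m[[drop_gene]],
      n_remaining = length(remaining) - 1L
    )
    remaining <- setdiff(remaining, drop_gene)
    round <- round + 1L
  }
  m_final <- m_values(q[remaining, , drop = FALSE])
  m_by_round[[round]] <- m_final
  final_pair <- sort(remaining)
  excl_tbl <- dplyr::bind_rows(exclusion)
  list(
    order = c(final_pair, rev(excl_tbl$gene)),
    final_pair = final_pair,
    exclusion = excl_tbl,
    m_by_round = m_by_round,
    tie_rounds = tie_rounds
  )
}

#' Geometric-mean normalization factor
#'
#' The per-sample normalization factor is the geometric mean of the selected
#' reference genes' relative quantities; target genes are normalized by
#' dividing by it.
#'
#' @inheritParams pairwise_variation_matrix
#' @param genes Non-empty subset of `rownames(q)`.
#' @return Named numeric vector, one NF per sample.
#' @export
normalization_factor <- function(q, genes) {
  check_quantity_matrix(q, min_genes = 1)
  if (length(genes) == 0) stop("gene set for the normalization factor is empty")
  missing <- setdiff(genes, rownames(q))
  if (length(missing) > 0) stop("gene(s) not in quantity matrix: ", paste(missing, collapse = ", "))
  2^colMeans(log2(q[genes, , drop = FALSE]))
}

#' Pairwise variation V(n/n+1) and the recommended number of reference genes
#'
#' For n = 2..N-1, builds normalization factors from the top n and top n+1
#' genes of the exclusion ranking and computes the standard deviation over
#' samples of their log2 ratio. A small V(n/n+1) means the (n+1)-th gene
#' adds nothing; the recommended n is the smallest with V below the
#' threshold (customarily 0.15, a guideline rather than a hard rule).
#'
#' @inheritParams pairwise_variation_matrix
#' @param ranking Gene ordering, most stable first (e.g.
#'   `rank_genes_genorm(q)$order`).
#' @param threshold Decision threshold on V; default 0.15.
#' @return List with `v_curve` (tibble `n`, `v`, `below_threshold`),
#'   `recommended_n`, and `threshold_met` (`FALSE` when no n satisfies the
#'   threshold, in which case `recommended_n` = N).
#' @export
pairwise_variation_v <- function(q, ranking, threshold = 0.15) {
  check_quantity_matrix(q, min_genes = 3)
  if (!setequal(ranking, rownames(q))) stop("ranking must be a permutation of the gene set")
  n_genes <- nrow(q)
  ns <- 2:(n_genes - 1)
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(q, ranking[1:n])
    nf_n1 <- normalization_factor(q, ranking[1:(n + 1)])
    sd(log2(nf_n / nf_n1))
  }, numeric(1))
  below <- v < threshold
  list(
    v_curve = tibble::tibble(n = ns, v = v, below_threshold = below),
    recommended_n = if (any(below)) ns[which(below)[1]] else n_genes,
    threshold_met = any(below)
  )
}

#' Run the full geNorm analysis
#'
#' Convenience wrapper: pairwise variation matrix, M values on the full gene
#' set, exclusion ranking, and the V(n/n+1) curve.
#'
#' @inheritParams pairwise_variation_v
#' @return Object of class `genorm_result`: `m_values` (full gene set),
#'   `pairwise_v`, `order`, `final_pair`, `exclusion`, `m_by_round`,
#'   `tie_rounds`, `v_curve`, `recommended_n`, `threshold_met`, `threshold`.
#' @examples
#' study <- simulate_study(default_sim_config(), seed = 1)
#' agg <- aggregate_technical_replicates(study$cq)
#' part <- partition_datasets(study$meta)
#' m <- complete_cq_matrix(agg, dataset_samples(part, "A"))
#' q <- relative_quantities(m, study$efficiency)
#' genorm(q[setdiff(rownames(q), "Dbp"), ])
#' @export
genorm <- function(q, threshold = 0.15) {
  ranking <- rank_genes_genorm(q)
  v <- pairwise_variation_v(q, ranking$order, threshold = threshold)
  structure(
    c(
      list(
        m_values = m_values(q),
        pairwise_v = pairwise_variation_matrix(q)
      ),
      ranking,
      v,
      list(threshold = threshold)
    ),
    class = "genorm_result"
  )
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability analysis\n")
  cat(sprintf("  %d genes\n", length(x$m_values)))
  cat("  ranking (most -> least stable): ", paste(x$order, collapse = ", "), "\n", sep = "")
  cat(sprintf("  final pair (unordered): %s\n", paste(x$final_pair, collapse = " / ")))
  cat(sprintf("  recommended n = %d (V threshold %.2f%s)\n",
              x$recommended_n, x$threshold,
              if (x$threshold_met) "" else ", not met by any n"))
  invisible(x)
}

check_quantity_matrix <- function(q, min_genes = 2) {
  if (!is.matrix(q) || !is.numeric(q)) stop("q must be a numeric genes x samples matrix")
  if (is.null(rownames(q))) stop("q must have gene rownames")
  if (nrow(q) < min_genes) stop("at least ", min_genes, " genes are required")
  if (anyNA(q) || any(q <= 0)) stop("all relative quantities must be positive and non-missing")
  invisible(q)
}
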