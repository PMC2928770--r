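# NormFinder: a model-based decomposition of reference-gene variation into
# intragroup variance and intergroup deviation, with samples divided into
# subgroups (here, by default, the seven circadian sacrifice times).
#
# The model for log2 quantities is
#   y_igj = alpha_i + beta_gj + d_ig + eps_igj,   eps ~ N(0, sigma2_ig)
# where i indexes genes, g subgroups, j samples within a subgroup; alpha_i is
# the gene level, beta_gj the sample loading, d_ig a gene-by-group
# interaction (a gene whose level shifts systematically in some subgroup is
# a poor reference), and eps the residual intragroup noise. Neither sigma2
# nor d is identifiable per cell without bias corrections, which are applied
# below and enforced by Monte-Carlo unbiasedness tests.

#' Assemble a NormFinder input from a quantity matrix
#'
#' Takes log2 of the relative quantities and attaches a subgroup label per
#' sample. The intragroup estimator divides by I - 2, so at least 3 genes
#' are required; every subgroup needs at least 2 samples for a variance.
#'
#' @param q Genes x samples matrix of positive relative quantities.
#' @param groups Subgroup label per sample: either a vector aligned with
#'   `colnames(q)` (named or positional), or a sample-metadata tibble from
#'   which the `group_by` column is taken for the matching sample ids.
#' @param group_by Metadata column used when `groups` is a tibble; default
#'   `"time_ct"`, the circadian sacrifice time.
#' @return List of class `normfinder_input`: `y` (log2 quantities),
#'   `group` (factor per sample), `I`, `G`, `n_g`.
#' @export
normfinder_input <- function(q, groups, group_by = "time_ct") {
  check_quantity_matrix(q, min_genes = 3)
  if (is.data.frame(groups)) {
    idx <- match(colnames(q), groups$sample_id)
    if (anyNA(idx)) {
      stop("metadata missing for sample(s): ",
           paste(colnames(q)[is.na(idx)], collapse = ", "))
    }
    groups <- groups[[group_by]][idx]
  } else if (!is.null(names(groups))) {
    if (!all(colnames(q) %in% names(groups))) stop("named groups must cover all samples")
    groups <- groups[colnames(q)]
  } else if (length(groups) != ncol(q)) {
    stop("groups must have one label per sample")
  }
  group <- factor(groups)
  n_g <- table(group)
  small <- names(n_g)[n_g < 2]
  if (length(small) > 0) {
    stop("subgroup(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }
  structure(
    list(y = log2(q), group = group, I = nrow(q), G = nlevels(group),
         n_g = as.numeric(n_g)),
    class = "normfinder_input"
  )
}

#' Fit the NormFinder variance model
#'
#' Estimates, per gene i and subgroup g: the intragroup variance
#' `sigma2[i, g]` and the intergroup deviation `d_hat[i, g]`, plus the
#' between-group deviation variance `gamma2` and the shrunken deviations
#' `d_tilde`.
#'
#' @details Within each subgroup the two-way (gene + sample) residuals
#' `r_igj = y_igj - ybar_ig. - ybar_.gj + ybar_..g` give raw variances
#' `v_ig = sum_j r^2 / (n_g - 1)`, which under the model have expectation
#' `sigma2_ig (1 - 2/I) + sigmabar2_g / I`; the bias-corrected estimate is
#' `sigma2_ig = I/(I-2) * (v_ig - vbar_g/(I-1))`, floored at zero. Group
#' deviations are `d_hat_ig = z_ig - sum_g n_g z_ig / sum_g n_g` with
#' `z_ig = ybar_ig. - mean_i(ybar_ig.)`; their dispersion
#' `gamma2 = max(0, sum(d_hat^2)/((I-1)(G-1)) - mean(sigma2_ig/n_g))`
#' drives the shrinkage `d_tilde = d_hat * gamma2/(gamma2 + sigma2_ig/n_g)`.
#' With a single subgroup all d terms are zero and only `sigma2` is
#' estimated (from the same two-way residuals, correction unchanged).
#'
#' @param input A `normfinder_input`.
#' @return List of class `normfinder_fit`: matrices `v`, `sigma2`, `d_hat`,
#'   `d_tilde` (genes x groups), `gamma2`, `n_g`, `n_floored` (count of
#'   negative variance cells floored at 0), and the input's dimensions.
#' @export
normfinder_fit <- function(input) {
  stopifnot(inherits(input, "normfinder_input"))
  y <- input$y
  I <- input$I
  G <- input$G
  levels_g <- levels(input$group)
  genes <- rownames(y)
  v <- sigma2 <- z <- matrix(NA_real_, I, G, dimnames = list(genes, levels_g))
  for (g in seq_len(G)) {
    yg <- y[, input$group == levels_g[g], drop = FALSE]
    n_g <- ncol(yg)
    gene_means <- rowMeans(yg)
    sample_means <- colMeans(yg)
    grand <- mean(yg)
    r <- yg - outer(gene_means, rep(1, n_g)) - outer(rep(1, I), sample_means) + grand
    v[, g] <- rowSums(r^2) / (n_g - 1)
    sigma2[, g] <- (I / (I - 2)) * (v[, g] - mean(v[, g]) / (I - 1))
    z[, g] <- gene_means - mean(gene_means)
  }
  n_floored <- sum(sigma2 < 0)
  if (n_floored > 0) sigma2 <- pmax(sigma2, 0)
  n_g <- input$n_g
  if (G > 1) {
    grand_z <- as.vector(z %*% n_g) / sum(n_g)        # per-gene weighted mean
    d_hat <- z - outer(grand_z, rep(1, G))
    sigma2_over_n <- sweep(sigma2, 2, n_g, "/")
    gamma2 <- max(0, sum(d_hat^2) / ((I - 1) * (G - 1)) - mean(sigma2_over_n))
    d_tilde <- d_hat * shrink_factor(gamma2, sigma2_over_n)
  } else {
    d_hat <- d_tilde <- matrix(0, I, 1, dimnames = list(genes, levels_g))
    gamma2 <- 0
  }
  degenerate_gamma <- G > 1 && gamma2 == 0
  if (degenerate_gamma) {
    warning("estimated between-group deviation variance gamma^2 is 0; ",
            "intergroup stability components are unresolvable and all ",
            "multigroup stability values collapse to 0 (ranking falls back ",
            "to the intragroup tie-break)")
  }
  structure(
    list(v = v, sigma2 = sigma2, d_hat = d_hat, d_tilde = d_tilde,
         gamma2 = gamma2, n_g = n_g, I = I, G = G, n_floored = n_floored,
         degenerate_gamma = degenerate_gamma),
    class = "normfinder_fit"
  )
}

# Empirical-Bayes shrinkage weight gamma2 / (gamma2 + sigma2/n), with the
# 0/0 limit (gamma2 = 0 and a zero-variance cell) resolved to 0: a zero
# prior variance pins the deviation at exactly 0.
shrink_factor <- function(gamma2, sigma2_over_n) {
  denom <- gamma2 + sigma2_over_n
  out <- ifelse(denom == 0, 0, gamma2 / denom)
  if (is.matrix(sigma2_over_n)) dimnames(out) <- dimnames(sigma2_over_n)
  out
}

#' NormFinder stability values
#'
#' The stability value combines, per subgroup, the magnitude of the shrunken
#' intergroup deviation with the uncertainty of the group mean:
#' \deqn{\rho_i = \frac{1}{G}\sum_g \left[\,|\tilde d_{ig}| +
#'   \sqrt{\frac{\gamma^2}{\gamma^2 + \sigma^2_{ig}/n_g}\cdot
#'         \frac{\sigma^2_{ig}}{n_g}}\,\right]}
#' Lower is more stable. With a single subgroup the value reduces to the
#' intragroup standard deviation `sqrt(sigma2_i)`.
#'
#' @param fit A `normfinder_fit`.
#' @return Tibble with `gene`, `stability`, `rank` (1 = most stable),
#'   sorted ascending by stability.
#' @export
normfinder_stability <- function(fit) {
  stopifnot(inherits(fit, "normfinder_fit"))
  sigma2_over_n <- sweep(fit$sigma2, 2, fit$n_g, "/")
  if (fit$G > 1) {
    shrink <- shrink_factor(fit$gamma2, sigma2_over_n)
    per_group <- abs(fit$d_tilde) + sqrt(shrink * sigma2_over_n)
    rho <- rowMeans(per_group)
  } else {
    rho <- sqrt(fit$sigma2[, 1])
  }
  # Secondary key used only to break exact stability ties (e.g. the
  # degenerate gamma^2 = 0 collapse, where every rho is 0): the mean
  # standard error of the subgroup means, a pure intragroup quantity.
  intragroup_se <- rowMeans(sqrt(sigma2_over_n))
  out <- tibble::tibble(gene = names(rho), stability = unname(rho),
                        intragroup_se = unname(intragroup_se))
  out <- out[order(out$stability, out$intragroup_se, out$gene), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Best two-gene combination
#'
#' For every unordered pair of genes, replaces the pair by the pseudo-gene
#' `(y_a + y_b)/2` (the log2 of their geometric mean), refits the variance
#' model on the reduced gene set, and scores the pseudo-gene's stability.
#' Returns the pair minimizing that score and whether it beats the best
#' single gene -- averaging halves independent intragroup variance, so it
#' usually (but not always) does.
#'
#' @param input A `normfinder_input` with at least 4 genes (the refit needs
#'   3 genes after the pair collapses into one).
#' @param stability Optional precomputed single-gene stability table.
#' @return List: `gene_a`, `gene_b`, `combined_stability`, `best_single`
#'   (gene and value), `combined_lt_single`, and `pair_table` (all pairs,
#'   sorted).
#' @export
normfinder_best_pair <- function(input, stability = NULL) {
  stopifnot(inherits(input, "normfinder_input"))
  if (input$I < 4) {
    stop("best-pair search needs at least 4 genes (the refit after pairing needs 3)")
  }
  if (is.null(stability)) stability <- normfinder_stability(normfinder_fit(input))
  genes <- rownames(input$y)
  pairs <- combn(genes, 2)
  pseudo_rho <- pseudo_se <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    y2 <- input$y[setdiff(genes, c(a, b)), , drop = FALSE]
    pseudo <- (input$y[a, ] + input$y[b, ]) / 2
    y2 <- rbind(y2, ..pair.. = pseudo)
    input2 <- structure(
      list(y = y2, group = input$group, I = nrow(y2), G = input$G, n_g = input$n_g),
      class = "normfinder_input"
    )
    st2 <- suppressWarnings(normfinder_stability(normfinder_fit(input2)))
    pseudo_rho[p] <- st2$stability[st2$gene == "..pair.."]
    pseudo_se[p] <- st2$intragroup_se[st2$gene == "..pair.."]
  }
  # ties on the stability value (possible under the gamma^2 = 0 collapse)
  # break on the pair's intragroup standard error, then on gene names
  ord <- order(pseudo_rho, pseudo_se, pairs[1, ], pairs[2, ])
  best <- ord[1]
  list(
    gene_a = pairs[1, best],
    gene_b = pairs[2, best],
    combined_stability = pseudo_rho[best],
    best_single = list(gene = stability$gene[1], stability = stability$stability[1]),
    combined_lt_single = pseudo_rho[best] < stability$stability[1],
    pair_table = tibble::tibble(
      gene_a = pairs[1, ord], gene_b = pairs[2, ord],
      combined_stability = pseudo_rho[ord]
    )
  )
}

#' Run the full NormFinder analysis
#'
#' @inheritParams normfinder_input
#' @param best_pair Whether to run the exhaustive best-pair search (needs
#'   at least 4 genes). Default `TRUE`.
#' @return Object of class `normfinder_result`: the fit (`sigma2`, `d_hat`,
#'   `d_tilde`, `gamma2`, ...), `stability` table, and `best_pair`.
#' @examples
#' study <- simulate_study(default_sim_config(), seed = 1)
#' agg <- aggregate_technical_replicates(study$cq)
#' part <- partition_datasets(study$meta)
#' m <- complete_cq_matrix(agg, dataset_samples(part, "A"))
#' q <- relative_quantities(m, study$efficiency)
#' normfinder(q[setdiff(rownames(q), "Dbp"), ], study$meta)
#' @export
normfinder <- function(q, groups, group_by = "time_ct", best_pair = TRUE) {
  input <- normfinder_input(q, groups, group_by = group_by)
  fit <- normfinder_fit(input)
  stab <- normfinder_stability(fit)
  bp <- if (best_pair && input$I >= 4) normfinder_best_pair(input, stab) else NULL
  structure(
    list(fit = fit, stability = stab, best_pair = bp,
         group_by = if (is.data.frame(groups)) group_by else NA_character_),
    class = "normfinder_result"
  )
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability analysis\n")
  cat(sprintf("  %d genes, %d subgroup(s)%s\n", x$fit$I, x$fit$G,
              if (x$fit$n_floored > 0) sprintf(" [%d variance cell(s) floored at 0]", x$fit$n_floored) else ""))
  top <- utils::head(x$stability, 3)
  cat("  most stable: ",
      paste(sprintf("%s (%.4f)", top$gene, top$stability), collapse = ", "), "\n", sep = "")
  if (!is.null(x$best_pair)) {
    cat(sprintf("  best pair: %s + %s (%.4f%s)\n",
                x$best_pair$gene_a, x$best_pair$gene_b,
                x$best_pair$combined_stability,
                if (x$best_pair$combined_lt_single) ", below best single" else ""))
  }
  invisible(x)
}
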