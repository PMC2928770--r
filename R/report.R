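# Pipeline wrappers, deterministic result writers, a run manifest, and
# human-readable report tables (per-dataset rankings and the V-curve table).

#' Run the full stability pipeline on one analysis dataset
#'
#' Aggregates technical replicates, assembles the complete mean-Cq matrix
#' for the dataset, transforms to efficiency-corrected relative quantities,
#' and runs both stability analyses. Reference-gene stability is assessed on
#' the candidate panel only: `exclude_genes` (by default the rhythmic target
#' `"Dbp"`, if present) are removed before ranking but kept in the returned
#' quantity matrix for downstream normalization.
#'
#' @param cq Long-format Cq table.
#' @param meta Sample metadata.
#' @param efficiency Named gene -> efficiency vector.
#' @param dataset Dataset label resolved against `partition` (default) or a
#'   character vector of sample ids.
#' @param partition Output of [partition_datasets()]; computed from `meta`
#'   when `NULL`.
#' @param genes Optional candidate-gene subset (e.g. a tissue-specific
#'   panel); default: all genes measured in every sample of the dataset.
#' @param exclude_genes Genes to keep out of the stability ranking.
#' @param group_by NormFinder subgrouping factor, a column of `meta`;
#'   default `"time_ct"` (circadian sacrifice time). `"strain"` targets
#'   between-background variation in pooled datasets.
#' @param v_threshold geNorm V(n/n+1) decision threshold; default 0.15.
#' @param max_sd Technical-replicate flagging threshold (cycles).
#' @param on_missing Missing-cell policy, see [complete_cq_matrix()].
#' @return List of class `stability_analysis`: `dataset`, `q` (full
#'   quantity matrix), `q_candidates`, `genorm`, `normfinder`, `aggregated`,
#'   `flagged` (rows whose replicate sd exceeded `max_sd`).
#' @export
run_stability_analysis <- function(cq, meta, efficiency, dataset,
                                   partition = NULL, genes = NULL,
                                   exclude_genes = "Dbp",
                                   group_by = "time_ct", v_threshold = 0.15,
                                   max_sd = 0.5,
                                   on_missing = c("drop_gene", "drop_sample", "error")) {
  on_missing <- match.arg(on_missing)
  agg <- aggregate_technical_replicates(cq, max_sd = max_sd)
  if (length(dataset) == 1 && dataset %in% LETTERS) {
    if (is.null(partition)) partition <- partition_datasets(meta)
    sample_ids <- dataset_samples(partition, dataset)
    label <- dataset
  } else {
    sample_ids <- dataset
    label <- "custom"
  }
  m <- complete_cq_matrix(agg, sample_ids, genes = genes, on_missing = on_missing)
  q <- relative_quantities(m, efficiency)
  candidates <- setdiff(rownames(q), exclude_genes)
  q_cand <- q[candidates, , drop = FALSE]
  gn <- genorm(q_cand, threshold = v_threshold)
  nf <- normfinder(q_cand, meta, group_by = group_by)
  structure(
    list(dataset = label, sample_ids = colnames(q), q = q, q_candidates = q_cand,
         genorm = gn, normfinder = nf, aggregated = agg,
         flagged = agg[agg$flag & agg$sample_id %in% sample_ids, ]),
    class = "stability_analysis"
  )
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat(sprintf("Stability analysis for dataset %s (%d samples, %d candidate genes)\n",
              x$dataset, length(x$sample_ids), nrow(x$q_candidates)))
  print(x$genorm)
  print(x$normfinder)
  invisible(x)
}

#' Write geNorm results as CSV
#'
#' Emits `genorm_ranking.csv` (`rank`, `gene`, `m_value`, `excluded_round`;
#' the final pair carries rank `"1-2"`), `genorm_v.csv` (`n`, `v_value`,
#' `below_threshold`), and `nf.csv` (per-sample normalization factor from
#' the recommended top genes, with the gene set recorded).
#'
#' @param result A `genorm_result`.
#' @param q The quantity matrix it was computed from.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_genorm_result <- function(result, q, dir) {
  stopifnot(inherits(result, "genorm_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_genes <- length(result$order)
  final_m <- result$m_by_round[[length(result$m_by_round)]][1]
  excl <- result$exclusion
  ranking <- tibble::tibble(
    rank = c("1-2", "1-2", as.character(3:n_genes)),
    gene = result$order,
    m_value = c(final_m, final_m, rev(excl$m_value)),
    excluded_round = c(NA_integer_, NA_integer_, rev(excl$round))
  )
  p1 <- file.path(dir, "genorm_ranking.csv")
  write.csv(as.data.frame(ranking), p1, row.names = FALSE, quote = FALSE)
  v <- result$v_curve
  p2 <- file.path(dir, "genorm_v.csv")
  write.csv(
    data.frame(n = v$n, v_value = v$v, below_threshold = v$below_threshold),
    p2, row.names = FALSE, quote = FALSE
  )
  top <- result$order[seq_len(result$recommended_n)]
  nf <- normalization_factor(q, top)
  p3 <- file.path(dir, "nf.csv")
  write.csv(
    data.frame(sample_id = names(nf), nf = unname(nf),
               gene_set = paste(top, collapse = "|")),
    p3, row.names = FALSE, quote = FALSE
  )
  invisible(c(p1, p2, p3))
}

#' Write NormFinder results as CSV/JSON
#'
#' Emits `normfinder.csv` (`gene`, `stability`, `rank`, `floored_cells`),
#' `normfinder_groups.csv` (per-(gene, group) `sigma2`, `d_hat`, `d_tilde`)
#' and `best_pair.json`.
#'
#' @param result A `normfinder_result`.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_normfinder_result <- function(result, dir) {
  stopifnot(inherits(result, "normfinder_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- result$stability
  st$floored_cells <- result$fit$n_floored
  p1 <- file.path(dir, "normfinder.csv")
  write.csv(as.data.frame(st), p1, row.names = FALSE, quote = FALSE)
  fit <- result$fit
  long <- expand.grid(gene = rownames(fit$sigma2), group = colnames(fit$sigma2),
                      stringsAsFactors = FALSE)
  long$sigma2 <- fit$sigma2[cbind(long$gene, long$group)]
  long$d_hat <- fit$d_hat[cbind(long$gene, long$group)]
  long$d_tilde <- fit$d_tilde[cbind(long$gene, long$group)]
  long <- long[order(long$gene, long$group), ]
  p2 <- file.path(dir, "normfinder_groups.csv")
  write.csv(long, p2, row.names = FALSE, quote = FALSE)
  paths <- c(p1, p2)
  if (!is.null(result$best_pair)) {
    bp <- result$best_pair
    p3 <- file.path(dir, "best_pair.json")
    jsonlite::write_json(
      list(gene_a = bp$gene_a, gene_b = bp$gene_b,
           combined_stability = bp$combined_stability,
           best_single = bp$best_single,
           combined_lt_single = bp$combined_lt_single),
      p3, auto_unbox = TRUE, digits = NA
    )
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Cross-dataset stability report
#'
#' Lays out NormFinder stability values as genes x datasets (the customary
#' result-table layout, with a best-two footer) and collects each dataset's
#' V-curve into one table.
#'
#' @param analyses Named list of `stability_analysis` objects (names =
#'   dataset labels).
#' @return List with `stability_table` (tibble, one gene per row, one
#'   column per dataset, `NA` where a gene was not in that dataset's
#'   panel), `best_two` (tibble `dataset`, `gene_a`, `gene_b`,
#'   `combined_stability`), and `v_table` (tibble `dataset`, `n`, `v`,
#'   `below_threshold`).
#' @export
stability_report <- function(analyses) {
  if (is.null(names(analyses))) names(analyses) <- vapply(analyses, `[[`, "", "dataset")
  all_genes <- sort(unique(unlist(lapply(analyses, function(a) a$normfinder$stability$gene))))
  stab <- tibble::tibble(gene = all_genes)
  best_rows <- list()
  v_rows <- list()
  for (label in names(analyses)) {
    a <- analyses[[label]]
    st <- a$normfinder$stability
    stab[[label]] <- st$stability[match(all_genes, st$gene)]
    bp <- a$normfinder$best_pair
    if (!is.null(bp)) {
      best_rows[[label]] <- tibble::tibble(
        dataset = label, gene_a = bp$gene_a, gene_b = bp$gene_b,
        combined_stability = bp$combined_stability
      )
    }
    v_rows[[label]] <- dplyr::mutate(a$genorm$v_curve, dataset = label, .before = 1)
  }
  list(
    stability_table = stab,
    best_two = dplyr::bind_rows(best_rows),
    v_table = dplyr::bind_rows(v_rows)
  )
}

#' Write a JSON run manifest
#'
#' Records input-file MD5 hashes, the analysis parameters, the seed, and
#' the package version, so a run's outputs are reproducible from the
#' manifest alone.
#'
#' @param input_paths Named character vector of input files (hashed).
#' @param params Named list of analysis parameters.
#' @param seed Integer seed governing any stochastic stage (the analysis
#'   stages themselves are deterministic).
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
run_manifest <- function(input_paths, params, seed, path) {
  existing <- input_paths[file.exists(input_paths)]
  manifest <- list(
    package = "refstab",
    version = as.character(utils::packageVersion("refstab")),
    inputs = as.list(tools::md5sum(existing)),
    params = params,
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
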