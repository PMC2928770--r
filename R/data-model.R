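# Long-format Cq tables, sample metadata, efficiency maps, and the
# partitioning of samples into per-strain / per-tissue analysis datasets.

cq_table_columns <- c("sample_id", "gene", "replicate", "cq")
sample_meta_columns <- c("sample_id", "strain", "tissue", "time_ct", "animal_id")

#' Validate a long-format Cq table
#'
#' A Cq table holds one row per technical replicate: the sample identifier,
#' gene symbol, 1-based technical replicate index, and the raw quantification
#' cycle. Cq must be finite and positive, and (sample_id, gene, replicate)
#' must be unique.
#'
#' @param x A data frame with columns `sample_id`, `gene`, `replicate`, `cq`.
#' @return `x` invisibly (as a tibble), or an error describing the violation.
#' @export
validate_cq_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(cq_table_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("Cq table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(x$cq) || anyNA(x$cq) || any(!is.finite(x$cq)) || any(x$cq <= 0)) {
    stop("Cq values must be finite and > 0")
  }
  if (any(x$replicate != as.integer(x$replicate)) || any(x$replicate < 1)) {
    stop("replicate must be a 1-based integer index")
  }
  key <- paste(x$sample_id, x$gene, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate (sample_id, gene, replicate) key: (%s, %s, %d)",
      dup$sample_id, dup$gene, dup$replicate
    ))
  }
  invisible(x)
}

#' Read a long-format Cq table from CSV
#'
#' The file must have the exact header `sample_id,gene,replicate,cq`
#' (UTF-8, comma-separated, `.` decimal). Malformed numeric fields are
#' reported with their row number; duplicate replicate keys are rejected.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `sample_id`, `gene`, `replicate`, `cq`.
#' @seealso [write_cq_table()], [aggregate_technical_replicates()]
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), cq_table_columns)) {
    stop(
      "expected header 'sample_id,gene,replicate,cq', got '",
      paste(names(raw), collapse = ","), "'"
    )
  }
  parse_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad) > 0) {
      stop(sprintf(
        "malformed numeric field '%s' in column '%s' at data row %d",
        v[bad[1]], col, bad[1]
      ))
    }
    out
  }
  x <- tibble::tibble(
    sample_id = raw$sample_id,
    gene = raw$gene,
    replicate = as.integer(parse_num(raw$replicate, "replicate")),
    cq = parse_num(raw$cq, "cq")
  )
  validate_cq_table(x)
  x
}

#' Write a Cq table to CSV with deterministic row order
#'
#' Rows are sorted by (sample_id, gene, replicate) ascending so repeated
#' writes of the same table are byte-identical; values are written at full
#' precision.
#'
#' @param x A valid Cq table.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_cq_table <- function(x, path) {
  x <- validate_cq_table(x)
  ord <- order(x$sample_id, x$gene, x$replicate)
  write.csv(as.data.frame(x[ord, cq_table_columns]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' @param x Data frame with columns `sample_id`, `strain`, `tissue`,
#'   `time_ct`, `animal_id`.
#' @param strains,tissues,time_points Allowed label sets; defaults follow the
#'   reference design ([default_strains()], [default_tissues()],
#'   [default_time_points()]).
#' @return `x` invisibly as a tibble.
#' @export
validate_sample_meta <- function(x, strains = default_strains(),
                                 tissues = default_tissues(),
                                 time_points = default_time_points()) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(sample_meta_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("sample metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ", x$sample_id[duplicated(x$sample_id)][1])
  }
  bad_strain <- setdiff(unique(x$strain), strains)
  if (length(bad_strain) > 0) stop("unknown strain label(s): ", paste(bad_strain, collapse = ", "))
  bad_tissue <- setdiff(unique(x$tissue), tissues)
  if (length(bad_tissue) > 0) stop("unknown tissue label(s): ", paste(bad_tissue, collapse = ", "))
  bad_time <- setdiff(unique(x$time_ct), time_points)
  if (length(bad_time) > 0) {
    stop("time_ct outside configured time points: ", paste(bad_time, collapse = ", "))
  }
  invisible(x)
}

#' Read sample metadata from CSV
#'
#' @inheritParams validate_sample_meta
#' @param path Path to a CSV with header
#'   `sample_id,strain,tissue,time_ct,animal_id`.
#' @return A tibble of sample annotations.
#' @export
read_sample_meta <- function(path, strains = default_strains(),
                             tissues = default_tissues(),
                             time_points = default_time_points()) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, check.names = FALSE)
  if (!identical(names(x), sample_meta_columns)) {
    stop(
      "expected header '", paste(sample_meta_columns, collapse = ","),
      "', got '", paste(names(x), collapse = ","), "'"
    )
  }
  x <- tibble::as_tibble(x)
  x$sample_id <- as.character(x$sample_id)
  x$animal_id <- as.character(x$animal_id)
  validate_sample_meta(x, strains, tissues, time_points)
  x
}

#' Write sample metadata to CSV (sorted by sample_id)
#' @param x Sample metadata.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_sample_meta <- function(x, path) {
  x <- tibble::as_tibble(x)[, sample_meta_columns]
  write.csv(as.data.frame(x[order(x$sample_id), ]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene -> amplification efficiency map from CSV
#'
#' Efficiencies are fold-amplification per cycle: E = 2 is perfect doubling.
#' Values must lie in (1, 2.1]; values outside [1.6, 2.05] (the plausible
#' range for validated primer pairs) trigger a warning but are accepted.
#'
#' @param path CSV with header `gene,efficiency`.
#' @return Named numeric vector of efficiencies.
#' @export
read_efficiency <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, check.names = FALSE)
  if (!identical(names(x), c("gene", "efficiency"))) {
    stop("expected header 'gene,efficiency'")
  }
  validate_efficiency(setNames(as.numeric(x$efficiency), as.character(x$gene)))
}

#' @rdname read_efficiency
#' @param eff Named numeric vector, gene -> efficiency.
#' @export
validate_efficiency <- function(eff) {
  if (is.null(names(eff)) || anyDuplicated(names(eff))) {
    stop("efficiencies must be uniquely named by gene")
  }
  if (anyNA(eff) || any(eff <= 1) || any(eff > 2.1)) {
    stop("efficiencies must lie in (1, 2.1]")
  }
  out_of_range <- names(eff)[eff < 1.6 | eff > 2.05]
  if (length(out_of_range) > 0) {
    warning(
      "efficiency outside the usual [1.6, 2.05] range for: ",
      paste(out_of_range, collapse = ", ")
    )
  }
  eff
}

#' @rdname read_efficiency
#' @export
write_efficiency <- function(eff, path) {
  eff <- eff[order(names(eff))]
  write.csv(
    data.frame(gene = names(eff), efficiency = unname(eff)),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Aggregate technical replicates
#'
#' Collapses each (sample, gene) cell to the arithmetic mean of its technical
#' replicate Cq values. Dispersion is reported as the sample standard
#' deviation (0 when only one replicate exists) and cells whose sd exceeds
#' `max_sd` are flagged -- never dropped: outlier handling is left to the
#' analyst, so downstream sample counts match the study design exactly.
#'
#' @param x A valid Cq table.
#' @param max_sd Flagging threshold on the replicate standard deviation, in
#'   cycles. Default 0.5.
#' @return Tibble with one row per (sample_id, gene):
#'   `mean_cq`, `sd_cq`, `n_replicates`, `flag`.
#' @export
aggregate_technical_replicates <- function(x, max_sd = 0.5) {
  x <- validate_cq_table(x)
  out <- x |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(
      mean_cq = mean(.data$cq),
      sd_cq = if (dplyr::n() > 1) sd(.data$cq) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = .data$sd_cq > max_sd) |>
    dplyr::arrange(.data$sample_id, .data$gene)
  out
}

#' Partition samples into per-strain / per-tissue analysis datasets
#'
#' Builds the eight standard analysis datasets: A-F are the (strain, tissue)
#' cells in the order strains-within-tissue (A = first strain/first tissue,
#' B = first strain/second tissue, C = second strain/first tissue, ...),
#' G pools all strains for the first tissue and H for the second. A-F are
#' disjoint and G (resp. H) is exactly the union of the liver (resp. adrenal)
#' cells.
#'
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param strains Ordered strain labels; defaults to [default_strains()].
#' @param tissues Ordered tissue labels (length 2); defaults to
#'   [default_tissues()].
#' @return A tibble with one row per dataset: `label`, `strain` (the strain
#'   label or `"all"`), `tissue`, `sample_ids` (list-column), `n_samples`.
#' @examples
#' meta <- simulate_study(default_sim_config(), seed = 1)$meta
#' partition_datasets(meta)
#' @export
partition_datasets <- function(meta, strains = default_strains(),
                               tissues = default_tissues()) {
  meta <- validate_sample_meta(meta, strains = strains, tissues = tissues,
                               time_points = sort(unique(meta$time_ct)))
  if (length(tissues) != 2) stop("partitioning expects exactly two tissues")
  cells <- expand.grid(tissue = tissues, strain = strains,
                       stringsAsFactors = FALSE)[, c("strain", "tissue")]
  # row order: (strain1,t1), (strain1,t2), (strain2,t1), ... -> labels A..F
  cells <- cells[order(match(cells$strain, strains), match(cells$tissue, tissues)), ]
  specs <- vector("list", nrow(cells) + 2)
  for (i in seq_len(nrow(cells))) {
    ids <- meta$sample_id[meta$strain == cells$strain[i] & meta$tissue == cells$tissue[i]]
    specs[[i]] <- tibble::tibble(
      label = LETTERS[i],
      strain = cells$strain[i],
      tissue = cells$tissue[i],
      sample_ids = list(sort(ids)),
      n_samples = length(ids)
    )
  }
  for (j in 1:2) {
    ids <- meta$sample_id[meta$tissue == tissues[j]]
    specs[[nrow(cells) + j]] <- tibble::tibble(
      label = LETTERS[nrow(cells) + j],
      strain = "all",
      tissue = tissues[j],
      sample_ids = list(sort(ids)),
      n_samples = length(ids)
    )
  }
  dplyr::bind_rows(specs)
}

#' Look up the samples of one dataset
#' @param partition Output of [partition_datasets()].
#' @param label Dataset label, e.g. `"A"`.
#' @return Character vector of sample ids.
#' @export
dataset_samples <- function(partition, label) {
  i <- match(label, partition$label)
  if (is.na(i)) stop("unknown dataset label: ", label)
  partition$sample_ids[[i]]
}

#' Build a complete genes x samples mean-Cq matrix
#'
#' Stability analyses require a complete matrix: every gene measured in every
#' sample of the dataset. Incomplete cells are resolved by an explicit policy,
#' never silently: `"drop_gene"` (default) removes genes not measured in all
#' samples with a warning naming them; `"drop_sample"` removes samples missing
#' any gene; `"error"` refuses.
#'
#' @param agg Aggregated Cq table from [aggregate_technical_replicates()].
#' @param sample_ids Samples defining the dataset scope.
#' @param genes Optional gene subset; default is every gene seen in scope.
#' @param on_missing One of `"drop_gene"`, `"drop_sample"`, `"error"`.
#' @return Numeric matrix (genes x samples) of mean Cq values.
#' @export
complete_cq_matrix <- function(agg, sample_ids,
                               genes = NULL,
                               on_missing = c("drop_gene", "drop_sample", "error")) {
  on_missing <- match.arg(on_missing)
  sub <- agg[agg$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(sub) == 0) stop("no measurements for the requested samples")
  missing_samples <- setdiff(sample_ids, unique(sub$sample_id))
  if (length(missing_samples) > 0) {
    stop("no measurements at all for sample(s): ", paste(missing_samples, collapse = ", "))
  }
  if (is.null(genes)) genes <- sort(unique(sub$gene))
  sub <- sub[sub$gene %in% genes, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids),
              dimnames = list(genes, sort(sample_ids)))
  m[cbind(match(sub$gene, rownames(m)), match(sub$sample_id, colnames(m)))] <- sub$mean_cq
  if (anyNA(m)) {
    incomplete_genes <- rownames(m)[rowSums(is.na(m)) > 0]
    incomplete_samples <- colnames(m)[colSums(is.na(m)) > 0]
    if (on_missing == "error") {
      stop("incomplete matrix; missing cells for gene(s): ",
           paste(incomplete_genes, collapse = ", "))
    } else if (on_missing == "drop_gene") {
      warning("dropping gene(s) not measured in every sample: ",
              paste(incomplete_genes, collapse = ", "))
      m <- m[setdiff(rownames(m), incomplete_genes), , drop = FALSE]
    } else {
      warning("dropping sample(s) missing one or more genes: ",
              paste(incomplete_samples, collapse = ", "))
      m <- m[, setdiff(colnames(m), incomplete_samples), drop = FALSE]
    }
  }
  if (nrow(m) == 0 || ncol(m) == 0) stop("no complete data left after applying missing-data policy")
  m
}
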