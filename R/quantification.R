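# Standard-curve efficiency estimation and the efficiency-corrected
# delta-Cq transform from mean Cq to relative quantities.

#' Estimate amplification efficiency from a dilution series
#'
#' Fits the least-squares line of Cq on log10 relative concentration over a
#' serial dilution of template and converts its slope to an amplification
#' efficiency, `E = 10^(-1/slope)`. A perfect assay doubles product every
#' cycle (slope -3.3219, E = 2).
#'
#' @param dilution Data frame with columns `log10_relative_conc` and `cq`
#'   (one row per replicate measurement; a `gene` column, if present, must
#'   hold a single gene). At least 3 distinct concentrations are required.
#' @return An object of class `efficiency_fit`: a list with `gene`,
#'   `efficiency`, `slope` (cycles per decade), `intercept`, `r_squared`,
#'   and `n_points`.
#' @details A slope that is non-negative or shallower than 0.5 cycles per
#'   decade cannot come from well-behaved amplification and raises an error
#'   rather than returning a nonsense efficiency.
#' @examples
#' d <- simulate_dilution_series("Actb", efficiency = 1.98, base_cq = 18)
#' estimate_efficiency(d)
#' @export
estimate_efficiency <- function(dilution) {
  dilution <- tibble::as_tibble(dilution)
  if (!all(c("log10_relative_conc", "cq") %in% names(dilution))) {
    stop("dilution series needs columns 'log10_relative_conc' and 'cq'")
  }
  gene <- if ("gene" %in% names(dilution)) {
    g <- unique(dilution$gene)
    if (length(g) != 1) stop("dilution series must contain a single gene")
    g
  } else {
    NA_character_
  }
  if (length(unique(dilution$log10_relative_conc)) < 3) {
    stop("at least 3 distinct concentrations are required")
  }
  fit <- lm(cq ~ log10_relative_conc, data = dilution)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    stop("degenerate dilution series: fitted slope is non-negative (Cq must fall with concentration)")
  }
  if (abs(slope) < 0.5) {
    stop("degenerate dilution series: |slope| < 0.5 cycles/decade")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((dilution$cq - mean(dilution$cq))^2)
  structure(
    list(
      gene = gene,
      efficiency = 10^(-1 / slope),
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n_points = nrow(dilution)
    ),
    class = "efficiency_fit"
  )
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf(
    "Standard-curve fit%s: E = %.4f (slope %.4f cycles/decade, r^2 = %.4f, n = %d)\n",
    if (is.na(x$gene)) "" else paste0(" for ", x$gene),
    x$efficiency, x$slope, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Efficiency-corrected relative quantities
#'
#' Transforms a complete genes x samples mean-Cq matrix to relative
#' quantities by the efficiency-corrected delta-Cq method:
#' \deqn{Q_{g,s} = E_g^{\min_{s'} Cq_{g,s'} - Cq_{g,s}}}
#' so each gene's most abundant sample (lowest Cq) has Q = 1 and every other
#' sample a quantity in (0, 1]. The minimum is taken within the supplied
#' matrix, i.e. within the analysis dataset at hand; quantities are only
#' meaningful relative to that cohort.
#'
#' @param cq_matrix Genes x samples matrix of aggregated mean Cq (e.g. from
#'   [complete_cq_matrix()]).
#' @param efficiency Named numeric vector, gene -> E; every gene in the
#'   matrix must be present.
#' @return Genes x samples numeric matrix of relative quantities, with
#'   attribute `"scope"` recording the sample set the per-gene minimum was
#'   taken over.
#' @export
relative_quantities <- function(cq_matrix, efficiency) {
  if (!is.matrix(cq_matrix)) stop("cq_matrix must be a genes x samples matrix")
  if (ncol(cq_matrix) == 0) stop("empty scope: no samples")
  if (is.null(rownames(cq_matrix)) || is.null(colnames(cq_matrix))) {
    stop("cq_matrix must be a genes x samples matrix with dimnames")
  }
  if (anyNA(cq_matrix)) stop("cq_matrix must be complete (no NA cells)")
  efficiency <- validate_efficiency(efficiency)
  missing_eff <- setdiff(rownames(cq_matrix), names(efficiency))
  if (length(missing_eff) > 0) {
    stop("no efficiency for gene(s): ", paste(missing_eff, collapse = ", "))
  }
  e <- efficiency[rownames(cq_matrix)]
  dcq <- apply(cq_matrix, 1, min) - cq_matrix   # recycles the per-gene minimum
  q <- e^dcq
  dimnames(q) <- dimnames(cq_matrix)
  attr(q, "scope") <- colnames(cq_matrix)
  q
}

#' Write / read a quantity matrix as wide CSV
#'
#' First column `gene`, remaining columns sample ids; rows sorted by gene and
#' columns by sample id so output is deterministic.
#'
#' @param q Genes x samples quantity matrix.
#' @param path Output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_quantities <- function(q, path) {
  q <- q[order(rownames(q)), order(colnames(q)), drop = FALSE]
  df <- data.frame(gene = rownames(q), q, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_quantities
#' @export
read_quantities <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "gene") stop("expected first column 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}
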