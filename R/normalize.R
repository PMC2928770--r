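# Applying normalization factors to a target gene and quantifying how the
# choice of reference genes distorts circadian profiles and between-strain
# comparisons.

#' Normalize a target gene by a per-sample normalization factor
#'
#' Divides the target's relative quantities by the normalization factor,
#' sample by sample, and summarises the normalized expression per
#' (strain, time) cell.
#'
#' @param q_target Named numeric vector of the target gene's relative
#'   quantities (names = sample ids).
#' @param nf Named numeric vector of per-sample normalization factors (e.g.
#'   from [normalization_factor()]). Sample sets must match exactly.
#' @param meta Sample metadata covering all samples.
#' @param strategy Label describing how the NF was built (e.g.
#'   `"single:Actb"`, `"genorm_top2"`); carried through to outputs.
#' @return Object of class `normalized_profile`: `samples` (tibble
#'   `sample_id`, `strain`, `tissue`, `time_ct`, `value`), `summary`
#'   (tibble `strain`, `time_ct`, `mean`, `sd`, `n`), `strategy`.
#' @export
normalize_target <- function(q_target, nf, meta, strategy = "custom") {
  if (!setequal(names(q_target), names(nf))) {
    only_t <- setdiff(names(q_target), names(nf))
    only_n <- setdiff(names(nf), names(q_target))
    stop(
      "sample sets differ between target and NF",
      if (length(only_t) > 0) paste0("; only in target: ", paste(only_t, collapse = ", ")) else "",
      if (length(only_n) > 0) paste0("; only in NF: ", paste(only_n, collapse = ", ")) else ""
    )
  }
  ids <- sort(names(q_target))
  meta <- tibble::as_tibble(meta)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for sample(s): ", paste(ids[is.na(idx)], collapse = ", "))
  samples <- tibble::tibble(
    sample_id = ids,
    strain = meta$strain[idx],
    tissue = meta$tissue[idx],
    time_ct = meta$time_ct[idx],
    value = unname(q_target[ids] / nf[ids])
  )
  summary <- samples |>
    dplyr::group_by(.data$strain, .data$time_ct) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$strain, .data$time_ct)
  structure(list(samples = samples, summary = summary, strategy = strategy),
            class = "normalized_profile")
}

# Least-squares 24 h cosinor on log2 values:
# log2(value) ~ mesor + A cos(2 pi (t - phi)/24), fit linearly via the
# cos/sin basis. Returns log2 amplitude and acrophase (= peak time) in hours.
cosinor_fit <- function(time_ct, value) {
  ylog <- log2(value)
  w <- 2 * pi * time_ct / 24
  fit <- lm(ylog ~ cos(w) + sin(w))
  b <- coef(fit)
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  acrophase <- (atan2(b[3], b[2]) * 24 / (2 * pi)) %% 24
  list(mesor = unname(b[1]), amplitude_log2 = unname(amplitude),
       acrophase = unname(acrophase))
}

#' Summarise the circadian rhythm of a normalized profile
#'
#' Fits a 24 h cosinor (mesor + cosine) to the log2 normalized values and
#' reports the peak time (the acrophase) and the peak/trough fold change
#' `amplitude_fold = 2^(2 * amplitude)`. When two strains are present (or a
#' `strain_pair` is given) also reports `strain_fold`, the ratio of the two
#' strains' profile levels: the geometric mean over time points of the ratio
#' of per-time mean expression. The cosinor is a reporting convenience for
#' profile summaries, not a rhythm-detection test.
#'
#' @param profile A `normalized_profile`.
#' @param strain_pair Optional character vector of two strains
#'   (numerator, denominator) for `strain_fold`.
#' @return List of class `rhythm_summary`: `peak_time` (h, `NA` with
#'   `rhythmic = FALSE` for an essentially flat profile), `amplitude_log2`,
#'   `amplitude_fold`, `mesor`, `strain_fold` (`NA` if not applicable),
#'   `strategy`.
#' @export
estimate_rhythm <- function(profile, strain_pair = NULL) {
  stopifnot(inherits(profile, "normalized_profile"))
  s <- profile$samples
  if (length(unique(s$time_ct)) < 4) {
    stop("at least 4 distinct time points are required for the cosinor fit")
  }
  fit <- cosinor_fit(s$time_ct, s$value)
  flat <- fit$amplitude_log2 < 1e-8
  strains <- sort(unique(s$strain))
  if (is.null(strain_pair) && length(strains) == 2) strain_pair <- strains
  strain_fold <- NA_real_
  if (!is.null(strain_pair)) {
    if (length(strain_pair) != 2 || !all(strain_pair %in% strains)) {
      stop("strain_pair must name two strains present in the profile")
    }
    tp_means <- profile$summary
    a <- tp_means[tp_means$strain == strain_pair[1], ]
    b <- tp_means[tp_means$strain == strain_pair[2], ]
    common <- intersect(a$time_ct, b$time_ct)
    strain_fold <- 2^mean(log2(a$mean[match(common, a$time_ct)] /
                                 b$mean[match(common, b$time_ct)]))
  }
  structure(
    list(
      peak_time = if (flat) NA_real_ else fit$acrophase,
      rhythmic = !flat,
      amplitude_log2 = fit$amplitude_log2,
      amplitude_fold = 2^(2 * fit$amplitude_log2),
      mesor = fit$mesor,
      strain_fold = strain_fold,
      strain_pair = strain_pair,
      strategy = profile$strategy
    ),
    class = "rhythm_summary"
  )
}

#' @export
print.rhythm_summary <- function(x, ...) {
  cat(sprintf(
    "Rhythm summary [%s]: peak CT%.1f, amplitude fold %.2f%s\n",
    x$strategy,
    if (x$rhythmic) x$peak_time else NA,
    x$amplitude_fold,
    if (!is.na(x$strain_fold)) {
      sprintf(", strain fold (%s/%s) %.3f", x$strain_pair[1], x$strain_pair[2], x$strain_fold)
    } else ""
  ))
  invisible(x)
}

#' Compare normalization strategies for a target gene
#'
#' Builds one normalization factor per strategy, normalizes the target by
#' each, and summarises the resulting profile: peak time, amplitude fold,
#' and the between-strain fold. A strategy is either a character vector of
#' reference genes or the shorthand string `"single:GENE"`. Strategy names
#' label the output (e.g. `genorm_top2`, `normfinder_top2`).
#'
#' @param q Genes x samples quantity matrix containing the target and all
#'   reference genes.
#' @param meta Sample metadata.
#' @param target Target gene symbol (must not appear in any reference set).
#' @param strategies Named list of reference-gene sets (or `"single:GENE"`
#'   strings).
#' @param strain_pair Optional strain pair for the fold comparison.
#' @return List with `summaries` (tibble: `strategy`, `peak_time`,
#'   `amplitude_fold`, `strain_fold`) and `profiles` (named list of
#'   `normalized_profile`s).
#' @export
compare_strategies <- function(q, meta, target, strategies, strain_pair = NULL) {
  check_quantity_matrix(q, min_genes = 2)
  if (!target %in% rownames(q)) stop("target gene not in quantity matrix: ", target)
  if (is.null(names(strategies)) || any(names(strategies) == "")) {
    stop("strategies must be a named list")
  }
  resolve <- function(strat) {
    if (is.character(strat) && length(strat) == 1 && startsWith(strat, "single:")) {
      strat <- sub("^single:", "", strat)
    }
    unknown <- setdiff(strat, rownames(q))
    if (length(unknown) > 0) {
      stop("unknown reference gene(s) in strategy: ", paste(unknown, collapse = ", "))
    }
    if (target %in% strat) stop("target gene cannot be its own reference")
    strat
  }
  profiles <- list()
  rows <- list()
  for (label in names(strategies)) {
    genes <- resolve(strategies[[label]])
    nf <- normalization_factor(q, genes)
    prof <- normalize_target(q[target, ], nf, meta, strategy = label)
    rs <- estimate_rhythm(prof, strain_pair = strain_pair)
    profiles[[label]] <- prof
    rows[[label]] <- tibble::tibble(
      strategy = label,
      peak_time = rs$peak_time,
      amplitude_fold = rs$amplitude_fold,
      strain_fold = rs$strain_fold
    )
  }
  list(summaries = dplyr::bind_rows(rows), profiles = profiles)
}

#' Write normalized profiles and strategy comparisons to disk
#'
#' `write_normalized()` emits one long CSV
#' (`sample_id,strain,tissue,time_ct,strategy,value`, sorted by strategy
#' then sample) for a list of normalized profiles; `write_comparison()`
#' emits the per-strategy rhythm/fold summaries as JSON.
#'
#' @param profiles A list of `normalized_profile` objects (e.g.
#'   `compare_strategies()$profiles`).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_normalized <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    dplyr::mutate(p$samples, strategy = p$strategy)
  })
  out <- dplyr::bind_rows(rows)[, c("sample_id", "strain", "tissue",
                                    "time_ct", "strategy", "value")]
  out <- out[order(out$strategy, out$sample_id), ]
  write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_normalized
#' @param summaries Tibble from `compare_strategies()$summaries`.
#' @export
write_comparison <- function(summaries, path) {
  out <- lapply(seq_len(nrow(summaries)), function(i) {
    list(peak_time = summaries$peak_time[i],
         amplitude_fold = summaries$amplitude_fold[i],
         strain_fold = summaries$strain_fold[i])
  })
  names(out) <- summaries$strategy
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a normalized circadian profile
#'
#' Per-(strain, time) mean with +/- sd ribbons over circadian time; a thin
#' visual check, not an analysis step. Requires ggplot2.
#'
#' @param profile A `normalized_profile`.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  s <- profile$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_ct, y = .data$mean,
                                  colour = .data$strain, group = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(s$time_ct))) +
    ggplot2::labs(x = "circadian time (h)", y = "normalized expression",
                  title = profile$strategy) +
    ggplot2::theme_minimal()
}
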