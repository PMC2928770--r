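# Synthetic circadian qPCR studies with known ground truth, emulating a
# three-strain, two-tissue design sampled every 4 h over 24 h with ragged
# biological replication and triplicate technical measurements.
#
# Noise placement mirrors the physical layers: biological variation and
# sample loading act on log2 abundance, technical (pipetting/instrument)
# noise acts on Cq cycles. Abundance couples to Cq through each gene's own
# amplification efficiency, so efficiency-corrected quantification inverts
# the simulation exactly when given the true efficiencies.

#' Construct a simulation configuration
#'
#' @param genes Tibble with one row per assayed gene: `gene`, `base_cq`
#'   (population mean Cq at zero effects, cycles), `efficiency` (fold per
#'   cycle, in (1, 2.1]), `bio_sd` (between-animal sd in log2 abundance),
#'   `amplitude` (log2 rhythm amplitude, 0 for arrhythmic genes),
#'   `acrophase` (peak time in hours, `NA` when amplitude is 0).
#' @param design Tibble `strain`, `tissue`, `time_ct`, `n_animals`:
#'   biological replicates per cell (may be ragged).
#' @param strain_offsets Named list, gene -> named numeric vector of log2
#'   expression offsets per strain (absent strains get offset 0). Offsets
#'   model genes whose level depends on genetic background -- the mechanism
#'   by which a reference gene stable within each strain becomes unstable
#'   across strains.
#' @param tech_reps Technical replicates per (sample, gene); default 3.
#' @param tech_sd Technical replicate sd in Cq cycles; default 0.15.
#' @param loading_sd Sd of the per-sample loading effect (shared by all
#'   genes of a sample) in log2; default 0.3.
#' @param seed Default seed for [simulate_study()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genes, design, strain_offsets = list(),
                       tech_reps = 3, tech_sd = 0.15, loading_sd = 0.3,
                       seed = 1) {
  cfg <- structure(
    list(genes = tibble::as_tibble(genes), design = tibble::as_tibble(design),
         strain_offsets = strain_offsets, tech_reps = as.integer(tech_reps),
         tech_sd = tech_sd, loading_sd = loading_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genes
  need <- c("gene", "base_cq", "efficiency", "bio_sd", "amplitude", "acrophase")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0) stop("genes table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(g$gene)) stop("duplicate gene in config")
  if (any(g$efficiency <= 1 | g$efficiency > 2.1)) stop("efficiencies must lie in (1, 2.1]")
  if (any(g$bio_sd < 0) || any(g$amplitude < 0)) stop("sds and amplitudes must be >= 0")
  bad_acro <- g$amplitude > 0 & (is.na(g$acrophase) | g$acrophase < 0 | g$acrophase >= 24)
  if (any(bad_acro)) stop("rhythmic genes need an acrophase in [0, 24)")
  d <- config$design
  need_d <- c("strain", "tissue", "time_ct", "n_animals")
  if (length(setdiff(need_d, names(d))) > 0) stop("design table missing column(s)")
  if (any(d$n_animals < 1)) stop("each design cell needs at least one animal")
  unknown <- setdiff(names(config$strain_offsets), g$gene)
  if (length(unknown) > 0) stop("strain_offsets for unknown gene(s): ", paste(unknown, collapse = ", "))
  if (config$tech_reps < 1 || config$tech_sd < 0 || config$loading_sd < 0) {
    stop("tech_reps must be >= 1 and sds >= 0")
  }
  invisible(config)
}

#' Default configuration replicating the reference study design
#'
#' Ten candidate reference genes plus one rhythmic target, assayed in three
#' strains x two tissues x seven circadian times with the study's exact
#' ragged replicate counts (131 liver + 97 adrenal = 228 samples).
#' Calibration: the ribosomal-RNA analogue `Rn18s` sits at mean Cq 8.8 and
#' the low-abundance `Tbcc` at 28.5, all other candidates between Cq 18 and
#' 29; `Actb` and `Hmbs` combine large biological sd with strain-specific
#' offsets (producing ~12-cycle ranges and cross-strain instability), while
#' `Eif2a`, `Tbcc` and `Utp6c` are tight (< 4-cycle range); the `Dbp`-like
#' target has a 2-log2 rhythm peaking at CT12. Efficiencies are the
#' validated primer-panel values. The full gene panel is simulated in both
#' tissues; tissue-specific candidate panels are applied at the analysis
#' layer by gene filtering.
#'
#' @return A `sim_config`.
#' @export
default_sim_config <- function() {
  # Candidate reference genes carry weak circadian modulation (0.08-0.5
  # log2): no transcript is perfectly flat across the day, and the mild
  # time-of-day drift of "stable" genes is exactly what subgroup-aware
  # stability analysis is meant to weigh. Amplitudes scale inversely with
  # the intended stability of each gene.
  genes <- tibble::tribble(
    ~gene,    ~base_cq, ~efficiency, ~bio_sd, ~amplitude, ~acrophase,
    "Rplp0",  19.5,     1.98,        0.50,    0.15,        6,
    "Ppib",   21.0,     1.93,        0.50,    0.15,       20,
    "Gapdh",  18.5,     1.94,        0.50,    0.30,       15,
    "Actb",   18.0,     1.98,        1.00,    0.50,        3,
    "Hmbs",   25.0,     1.64,        1.00,    0.40,        9,
    "Hprt1",  23.5,     1.89,        0.50,    0.25,       18,
    "Rn18s",   8.8,     1.79,        0.40,    0.10,        0,
    "Eif2a",  24.5,     1.95,        0.20,    0.08,        8,
    "Utp6c",  27.0,     1.82,        0.20,    0.08,       16,
    "Tbcc",   28.5,     1.90,        0.20,    0.08,        4,
    "Dbp",    22.0,     1.93,        0.35,    2,          12
  )
  strains <- default_strains()
  tp <- default_time_points()
  counts <- list(
    # per-time-point biological replicates, CT0..CT24
    list(strain = strains[1], tissue = "liver",   n = c(5, 5, 5, 5, 5, 5, 5)),  # A = 35
    list(strain = strains[1], tissue = "adrenal", n = c(5, 4, 5, 5, 5, 5, 4)),  # B = 33
    list(strain = strains[2], tissue = "liver",   n = c(6, 6, 7, 6, 6, 7, 7)),  # C = 45
    list(strain = strains[2], tissue = "adrenal", n = c(3, 4, 4, 5, 4, 5, 5)),  # D = 30
    list(strain = strains[3], tissue = "liver",   n = c(8, 7, 7, 7, 7, 8, 7)),  # E = 51
    list(strain = strains[3], tissue = "adrenal", n = c(5, 5, 4, 5, 5, 5, 5))   # F = 34
  )
  design <- dplyr::bind_rows(lapply(counts, function(cc) {
    tibble::tibble(strain = cc$strain, tissue = cc$tissue, time_ct = tp, n_animals = cc$n)
  }))
  # background-level offsets: shared by the two mixed-background strains
  offsets <- list(
    Actb = c("mixed-CremKO" = 4.0, "mixed-WT" = 4.0),
    Hmbs = c("mixed-CremKO" = -2.5, "mixed-WT" = -2.5)
  )
  sim_config(genes, design, strain_offsets = offsets)
}

#' Simulate a complete study
#'
#' For each animal, each gene's log2 abundance (relative to its own
#' baseline) is
#' `a = loading + offset(gene, strain) + amplitude * cos(2*pi*(t - acrophase)/24) + N(0, bio_sd)`
#' and the underlying Cq is `base_cq - a / log2(E)`, so at zero effects the
#' population mean Cq equals `base_cq`. Technical replicates add
#' `N(0, tech_sd)` cycles. CT0 and CT24 are independent samplings of the
#' same circadian phase, never copies. Fully deterministic given the seed.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Object of class `sim_study`: `cq` (long Cq table), `meta`
#'   (sample metadata), `efficiency` (named vector), `truth` (the generating
#'   parameters: per-gene sd/rhythm, offsets, per-sample loading effects).
#' @export
simulate_study <- function(config, seed = config$seed) {
  validate_sim_config(config)
  g <- config$genes
  d <- config$design
  strain_codes <- setNames(sprintf("S%d", seq_along(unique(d$strain))), unique(d$strain))
  withr::with_seed(seed, {
    meta_rows <- list()
    for (i in seq_len(nrow(d))) {
      n <- d$n_animals[i]
      sid <- sprintf("%s-%s-CT%02d-%02d", strain_codes[[d$strain[i]]],
                     substr(d$tissue[i], 1, 3), d$time_ct[i], seq_len(n))
      meta_rows[[i]] <- tibble::tibble(
        sample_id = sid, strain = d$strain[i], tissue = d$tissue[i],
        time_ct = d$time_ct[i], animal_id = paste0("an-", sid)
      )
    }
    meta <- dplyr::bind_rows(meta_rows)
    n_samples <- nrow(meta)
    loading <- rnorm(n_samples, 0, config$loading_sd)
    names(loading) <- meta$sample_id

    offset_of <- function(gene, strain) {
      o <- config$strain_offsets[[gene]]
      if (is.null(o) || is.na(o[strain])) 0 else unname(o[strain])
    }
    cq_rows <- vector("list", nrow(g))
    for (k in seq_len(nrow(g))) {
      rhythm <- if (g$amplitude[k] > 0) {
        g$amplitude[k] * cos(2 * pi * (meta$time_ct - g$acrophase[k]) / 24)
      } else {
        0
      }
      offs <- vapply(meta$strain, function(s) offset_of(g$gene[k], s), numeric(1))
      a <- loading + offs + rhythm + rnorm(n_samples, 0, g$bio_sd[k])
      cq_true <- g$base_cq[k] - a / log2(g$efficiency[k])
      reps <- config$tech_reps
      cq_rows[[k]] <- tibble::tibble(
        sample_id = rep(meta$sample_id, each = reps),
        gene = g$gene[k],
        replicate = rep(seq_len(reps), times = n_samples),
        cq = rep(cq_true, each = reps) + rnorm(n_samples * reps, 0, config$tech_sd)
      )
    }
    cq <- dplyr::bind_rows(cq_rows)
    cq <- cq[order(cq$sample_id, cq$gene, cq$replicate), ]
  })
  structure(
    list(
      cq = cq,
      meta = meta,
      efficiency = setNames(g$efficiency, g$gene),
      truth = list(
        genes = g,
        strain_offsets = config$strain_offsets,
        loading = loading,
        tech_sd = config$tech_sd,
        loading_sd = config$loading_sd,
        seed = seed
      )
    ),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d samples x %d genes (%d Cq measurements), seed %d\n",
    nrow(x$meta), length(x$efficiency), nrow(x$cq), x$truth$seed
  ))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Emits `cq_long.csv`, `samples.csv`, `efficiency.csv` and `truth.json`
#' into a directory.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cq = file.path(dir, "cq_long.csv"),
    samples = file.path(dir, "samples.csv"),
    efficiency = file.path(dir, "efficiency.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_cq_table(study$cq, paths["cq"])
  write_sample_meta(study$meta, paths["samples"])
  write_efficiency(study$efficiency, paths["efficiency"])
  jsonlite::write_json(
    list(
      genes = study$truth$genes,
      strain_offsets = study$truth$strain_offsets,
      loading = as.list(study$truth$loading),
      tech_sd = study$truth$tech_sd,
      loading_sd = study$truth$loading_sd,
      seed = study$truth$seed
    ),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Simulate a standard-curve dilution series
#'
#' Cq follows `base_cq + (-1/log10(E)) * log10(conc)` over a serial dilution
#' starting at relative concentration 1, plus optional Gaussian Cq noise.
#' With no noise, [estimate_efficiency()] recovers `efficiency` exactly.
#'
#' @param gene Gene symbol for the output.
#' @param efficiency True amplification efficiency in (1, 2.1].
#' @param base_cq Cq at the undiluted point; default 20.
#' @param dilution_factor Fold dilution per step (> 1); default 5.
#' @param n_points Number of dilution points (>= 3); default 5.
#' @param replicates Technical replicates per point; default 3.
#' @param noise_sd Gaussian Cq noise sd in cycles; default 0.
#' @param seed Seed; default 1.
#' @return Tibble `gene`, `log10_relative_conc`, `replicate`, `cq`.
#' @export
simulate_dilution_series <- function(gene, efficiency, base_cq = 20,
                                     dilution_factor = 5, n_points = 5,
                                     replicates = 3, noise_sd = 0, seed = 1) {
  if (n_points < 3) stop("at least 3 dilution points are required")
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (efficiency <= 1 || efficiency > 2.1) stop("efficiency must lie in (1, 2.1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  log10_conc <- -(seq_len(n_points) - 1) * log10(dilution_factor)
  grid <- expand.grid(replicate = seq_len(replicates),
                      log10_relative_conc = log10_conc)
  withr::with_seed(seed, {
    cq <- base_cq + (-1 / log10(efficiency)) * grid$log10_relative_conc +
      rnorm(nrow(grid), 0, noise_sd)
  })
  tibble::tibble(
    gene = gene,
    log10_relative_conc = grid$log10_relative_conc,
    replicate = grid$replicate,
    cq = cq
  )
}
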