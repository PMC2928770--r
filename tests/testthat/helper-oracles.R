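# Independent brute-force oracles and fixture builders. Everything here is
# written as plain loops over the defining formulas, deliberately avoiding
# the package's vectorised implementations.

random_quantity_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  q <- matrix(2^rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  q
}

# sd of log2 ratios, one pair at a time
oracle_pairwise_v <- function(q) {
  g <- rownames(q)
  v <- matrix(NA_real_, nrow(q), nrow(q), dimnames = list(g, g))
  for (j in seq_len(nrow(q))) {
    for (k in seq_len(nrow(q))) {
      if (j == k) next
      ratios <- log2(q[j, ] / q[k, ])
      m <- sum(ratios) / length(ratios)
      v[j, k] <- sqrt(sum((ratios - m)^2) / (length(ratios) - 1))
    }
  }
  v
}

oracle_m_values <- function(q) {
  v <- oracle_pairwise_v(q)
  out <- numeric(nrow(q))
  for (j in seq_len(nrow(q))) out[j] <- mean(v[j, -j])
  setNames(out, rownames(q))
}

# exclusion loop re-implemented from scratch, same documented tie-break
oracle_genorm_order <- function(q) {
  remaining <- rownames(q)
  excluded <- character(0)
  while (length(remaining) > 2) {
    m <- oracle_m_values(q[remaining, , drop = FALSE])
    worst <- names(m)[m >= max(m) - 1e-12]
    worst <- sort(worst)[length(worst)]
    excluded <- c(worst, excluded)
    remaining <- setdiff(remaining, worst)
  }
  c(sort(remaining), excluded)
}

oracle_nf <- function(q, genes) {
  out <- numeric(ncol(q))
  for (s in seq_len(ncol(q))) out[s] <- prod(q[genes, s])^(1 / length(genes))
  setNames(out, colnames(q))
}

oracle_v_curve <- function(q, ranking) {
  ns <- 2:(nrow(q) - 1)
  vapply(ns, function(n) {
    r <- log2(oracle_nf(q, ranking[1:n]) / oracle_nf(q, ranking[1:(n + 1)]))
    sqrt(sum((r - mean(r))^2) / (length(r) - 1))
  }, numeric(1))
}

# NormFinder estimators re-derived with explicit loops
oracle_normfinder <- function(y, group) {
  levs <- sort(unique(group))
  I <- nrow(y); G <- length(levs)
  v <- z <- matrix(0, I, G)
  ng <- integer(G)
  for (g in seq_len(G)) {
    Y <- y[, group == levs[g], drop = FALSE]
    n <- ncol(Y); ng[g] <- n
    for (i in seq_len(I)) {
      for (j in seq_len(n)) {
        r <- Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + mean(Y)
        v[i, g] <- v[i, g] + r^2
      }
      v[i, g] <- v[i, g] / (n - 1)
    }
    gm <- numeric(I)
    for (i in seq_len(I)) gm[i] <- mean(Y[i, ])
    for (i in seq_len(I)) z[i, g] <- gm[i] - mean(gm)
  }
  s2 <- matrix(0, I, G)
  for (g in seq_len(G)) {
    for (i in seq_len(I)) {
      s2[i, g] <- max(0, (I / (I - 2)) * (v[i, g] - mean(v[, g]) / (I - 1)))
    }
  }
  d <- matrix(0, I, G)
  for (i in seq_len(I)) d[i, ] <- z[i, ] - sum(ng * z[i, ]) / sum(ng)
  if (G > 1) {
    s2n <- matrix(0, I, G)
    for (g in seq_len(G)) s2n[, g] <- s2[, g] / ng[g]
    gam <- max(0, sum(d^2) / ((I - 1) * (G - 1)) - mean(s2n))
    rho <- se <- numeric(I)
    for (i in seq_len(I)) {
      acc <- 0
      for (g in seq_len(G)) {
        w <- if (gam + s2n[i, g] == 0) 0 else gam / (gam + s2n[i, g])
        acc <- acc + abs(d[i, g] * w) + sqrt(w * s2n[i, g])
      }
      rho[i] <- acc / G
      se[i] <- mean(sqrt(s2n[i, ]))
    }
  } else {
    rho <- sqrt(s2[, 1])
    se <- sqrt(s2[, 1] / ng[1])
  }
  list(sigma2 = s2, d_hat = d, rho = setNames(rho, rownames(y)),
       intragroup_se = setNames(se, rownames(y)))
}

# exhaustive best-pair search through the oracle fit, same tie-break
oracle_best_pair <- function(y, group) {
  genes <- rownames(y)
  pairs <- utils::combn(genes, 2)
  rho <- se <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    keep <- setdiff(genes, pairs[, p])
    y2 <- rbind(y[keep, , drop = FALSE],
                ..pair.. = (y[pairs[1, p], ] + y[pairs[2, p], ]) / 2)
    o <- oracle_normfinder(y2, group)
    rho[p] <- o$rho["..pair.."]
    se[p] <- o$intragroup_se["..pair.."]
  }
  best <- order(rho, se, pairs[1, ], pairs[2, ])[1]
  list(pair = pairs[, best], rho = rho[best])
}

# closed-form simple linear regression via explicit sums
oracle_lsq <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# cosinor via normal equations
oracle_cosinor <- function(t, ylog) {
  w <- 2 * pi * t / 24
  X <- cbind(1, cos(w), sin(w))
  b <- solve(t(X) %*% X, t(X) %*% ylog)
  amp <- sqrt(b[2]^2 + b[3]^2)
  list(mesor = b[1], amplitude = amp,
       acrophase = (atan2(b[3], b[2]) * 24 / (2 * pi)) %% 24)
}

# metadata replicating the reference design's sample counts
design_replica_meta <- function() {
  simulate_study(default_sim_config(), seed = 1)$meta
}

# small fast config for pipeline-level tests
small_sim_config <- function(strain_offsets = list(),
                             n_per_cell = 3,
                             strains = c("C57BL/6JOlaHsd", "mixed-WT"),
                             genes = NULL) {
  if (is.null(genes)) {
    genes <- tibble::tribble(
      ~gene,   ~base_cq, ~efficiency, ~bio_sd, ~amplitude, ~acrophase,
      "ref1",  20,       2.0,         0.10,    0.05,        2,
      "ref2",  22,       1.9,         0.10,    0.05,       14,
      "ref3",  24,       1.95,        0.10,    0.05,       20,
      "bias",  19,       2.0,         0.10,    0.05,        8,
      "Dbp",   21,       1.93,        0.20,    2.0,        12
    )
  }
  design <- do.call(rbind, lapply(strains, function(s) {
    tibble::tibble(strain = s, tissue = "liver",
                   time_ct = default_time_points(), n_animals = n_per_cell)
  }))
  sim_config(genes, design, strain_offsets = strain_offsets,
             tech_reps = 2, tech_sd = 0.1, loading_sd = 0.2)
}
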