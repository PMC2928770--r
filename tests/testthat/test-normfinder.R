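nf_input_from_y <- function(y, group) {
  normfinder_input(2^y, group)
}

test_that("input assembly validates genes, subgroups and grouping sources", {
  q <- random_quantity_matrix(4, 12, 1)
  expect_error(normfinder_input(q[1:2, ], rep(1:2, 6)), "3 genes")
  expect_error(normfinder_input(q, c(rep(1, 11), 2)), "fewer than 2 samples")
  inp <- normfinder_input(q, rep(c("a", "b", "c"), 4))
  expect_equal(inp$G, 3)
  expect_equal(inp$n_g, rep(4, 3))
  expect_equal(inp$y, log2(q))

  # metadata-driven grouping
  meta <- tibble::tibble(sample_id = colnames(q),
                         strain = "x", tissue = "liver",
                         time_ct = rep(c(0, 12), 6),
                         animal_id = colnames(q))
  inp2 <- normfinder_input(q, meta)
  expect_equal(inp2$G, 2)

  # constant grouping factor engages single-group mode downstream
  inp3 <- normfinder_input(q, rep("all", 12))
  expect_equal(inp3$G, 1)
})

test_that("model-exact data yields zero variances and deviations", {
  I <- 5; n <- 6; G <- 2
  alpha <- seq_len(I)
  beta <- matrix(rnorm(G * n, 0, 1), G, n)
  y <- matrix(NA_real_, I, G * n,
              dimnames = list(paste0("g", 1:I), paste0("s", 1:(G * n))))
  group <- rep(1:G, each = n)
  for (g in 1:G) for (j in 1:n) y[, (g - 1) * n + j] <- alpha + beta[g, j]
  fit <- suppressWarnings(normfinder_fit(nf_input_from_y(y, group)))
  expect_equal(max(abs(fit$sigma2)), 0, tolerance = 1e-20)
  expect_equal(max(abs(fit$d_hat)), 0, tolerance = 1e-12)
})

test_that("a single-gene group offset lands in d_hat as hand-computed", {
  # 3 genes, 2 equal groups of 4, noiseless; gene 1 shifted by delta in group 2
  delta <- 0.9
  I <- 3; n <- 4
  y <- matrix(0, I, 2 * n, dimnames = list(paste0("g", 1:I), paste0("s", 1:(2 * n))))
  y[, ] <- c(1, 2, 3)                      # gene levels
  group <- rep(1:2, each = n)
  y[1, group == 2] <- y[1, group == 2] + delta
  fit <- suppressWarnings(normfinder_fit(nf_input_from_y(y, group)))
  # z removes the gene-average per group; the weighted grand mean splits the
  # offset equally between the two equal-sized groups
  expect_equal(fit$d_hat["g1", ], c(`1` = -1, `2` = 1) * delta * (1 - 1 / I) / 2)
  expect_equal(fit$d_hat["g2", ], c(`1` = 1, `2` = -1) * delta / I / 2)
  expect_equal(fit$d_hat["g3", ], c(`1` = 1, `2` = -1) * delta / I / 2)
  # deviations sum to zero within each group
  expect_equal(colSums(fit$d_hat), c(`1` = 0, `2` = 0), tolerance = 1e-12)
})

test_that("fit matches the loop-based oracle on random heteroscedastic data", {
  for (seed in 1:6) {
    set.seed(seed + 400)
    I <- sample(4:7, 1); G <- sample(2:4, 1)
    n_g <- sample(3:6, G, replace = TRUE)
    group <- rep(seq_len(G), times = n_g)
    y <- matrix(rnorm(I * sum(n_g), 0, 0.5), I, sum(n_g),
                dimnames = list(paste0("g", 1:I), paste0("s", seq_len(sum(n_g)))))
    y <- y + rnorm(I)                     # gene levels
    y <- sweep(y, 2, rnorm(sum(n_g), 0, 0.3), "+")   # sample loadings
    inp <- nf_input_from_y(y, group)
    fit <- suppressWarnings(normfinder_fit(inp))
    o <- oracle_normfinder(y, group)
    expect_equal(unname(fit$sigma2), unname(o$sigma2), tolerance = 1e-10)
    expect_equal(unname(fit$d_hat), unname(o$d_hat), tolerance = 1e-10)
    st <- suppressWarnings(normfinder_stability(fit))
    expect_equal(setNames(st$stability, st$gene)[names(o$rho)], o$rho,
                 tolerance = 1e-10)
    # structural invariants
    expect_equal(max(abs(colSums(fit$d_hat))), 0, tolerance = 1e-10)
    expect_true(all(abs(fit$d_tilde) <= abs(fit$d_hat) + 1e-12))
    expect_true(all(fit$sigma2 >= 0))
    expect_true(all(st$stability >= 0))
  }
})

test_that("stability is invariant to sample loadings and gene-level shifts", {
  set.seed(17)
  I <- 6; G <- 3; n <- 5
  group <- rep(1:G, each = n)
  y <- matrix(rnorm(I * G * n, 0, 0.4), I, G * n,
              dimnames = list(paste0("g", 1:I), paste0("s", 1:(G * n))))
  rho0 <- normfinder_stability(suppressWarnings(normfinder_fit(nf_input_from_y(y, group))))
  y_sample <- y; y_sample[, 3] <- y_sample[, 3] + 2.5     # one sample loading
  y_gene <- y; y_gene[4, ] <- y_gene[4, ] + 1.7           # one gene level
  for (y2 in list(y_sample, y_gene)) {
    rho2 <- normfinder_stability(suppressWarnings(normfinder_fit(nf_input_from_y(y2, group))))
    expect_equal(rho2$stability, rho0$stability, tolerance = 1e-10)
    expect_equal(rho2$gene, rho0$gene)
  }
})

test_that("single-group mode ranks genes by their two-way residual sd", {
  set.seed(19)
  I <- 5; n <- 12
  sds <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  y <- matrix(rnorm(I * n, 0, sds), I, n,   # recycled by row: gene i gets sds[i]
              dimnames = list(paste0("g", 1:I), paste0("s", 1:n)))
  fit <- normfinder_fit(nf_input_from_y(y, rep("all", n)))
  st <- normfinder_stability(fit)
  expect_equal(st$stability[match(paste0("g", 1:I), st$gene)],
               sqrt(fit$sigma2[, 1]), ignore_attr = TRUE)
  # closed-form agreement: ranking equals ordering by corrected residual variance
  expect_equal(st$gene, names(sort(fit$sigma2[, 1])))
})

test_that("intragroup variance estimator is unbiased (small Monte Carlo)", {
  set.seed(23)
  I <- 8; G <- 4; n <- 50
  sig <- seq(0.1, 0.45, length.out = I)       # per-gene sd, same across groups
  group <- rep(1:G, each = n)
  est <- matrix(0, I, G)
  reps <- 300
  for (r in seq_len(reps)) {
    y <- matrix(rnorm(I * G * n, 0, sig), I, G * n)
    y <- sweep(y, 2, rnorm(G * n, 0, 0.5), "+")
    rownames(y) <- paste0("g", 1:I); colnames(y) <- paste0("s", 1:(G * n))
    fit <- suppressWarnings(normfinder_fit(nf_input_from_y(y, group)))
    est <- est + fit$sigma2
  }
  est <- est / reps
  rel_err <- abs(est - sig^2) / sig^2
  expect_lt(max(rowMeans(rel_err)), 0.05)
})

test_that("degenerate zero gamma^2 collapses with a warning and intragroup tie-break", {
  # no group structure at all, tiny noise: gamma^2 estimates to 0
  set.seed(29)
  I <- 5; n <- 40
  sds <- c(0.05, 0.05, 0.05, 0.3, 0.6)
  y <- matrix(rnorm(I * 2 * n, 0, sds), I, 2 * n,
              dimnames = list(paste0("g", 1:I), paste0("s", 1:(2 * n))))
  group <- rep(1:2, each = n)
  expect_warning(fit <- normfinder_fit(nf_input_from_y(y, group)), "gamma\\^2 is 0")
  expect_true(fit$degenerate_gamma)
  st <- normfinder_stability(fit)
  expect_equal(st$stability, rep(0, I))
  expect_false(any(is.na(st$stability)))
  # tie-break ranks the noisiest genes last
  expect_equal(st$gene[4:5], c("g4", "g5"))
})

test_that("best pair is found by exhaustive search with a perfect pair winning", {
  # Noiseless model-exact data: gene levels + sample loadings + centred
  # gene-by-group deviations for g3..g5, none for the twins. The twins are
  # then a perfect reference pair with combined stability exactly 0, while
  # every pair touching g3..g5 inherits a nonzero shrunken deviation.
  set.seed(31)
  n <- 7; G <- 3
  group <- rep(1:G, each = n)
  beta <- rnorm(G * n, 0, 0.5)
  alpha <- c(twinA = 0.3, twinB = -0.1, g3 = 1, g4 = -0.5, g5 = 0.2)
  # deviations already sum to 0 within each group, twins carry none
  d <- rbind(twinA = 0, twinB = 0,
             g3 = c(0.4, -0.2, 0), g4 = c(-0.3, 0.2, 0.1), g5 = c(-0.1, 0, -0.1))
  stopifnot(max(abs(colSums(d))) < 1e-12)
  y <- outer(alpha, beta, "+") + d[, group]
  colnames(y) <- paste0("s", seq_len(G * n))
  inp <- nf_input_from_y(y, group)
  bp <- suppressWarnings(normfinder_best_pair(inp))
  expect_setequal(c(bp$gene_a, bp$gene_b), c("twinA", "twinB"))
  expect_equal(bp$combined_stability, 0, tolerance = 1e-10)
  expect_true(bp$combined_lt_single)
})

test_that("best pair equals the independent exhaustive oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed + 500)
    n <- 18
    group <- rep(1:3, each = 6)
    y <- matrix(rnorm(6 * n, 0, 0.4), 6, n,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
    dev <- matrix(rnorm(6 * 3, 0, 0.2), 6, 3)  # mild gene-by-group structure
    y <- y + dev[, group]
    inp <- nf_input_from_y(y, group)
    bp <- suppressWarnings(normfinder_best_pair(inp))
    o <- oracle_best_pair(y, group)
    expect_setequal(c(bp$gene_a, bp$gene_b), o$pair)
    expect_equal(bp$combined_stability, o$rho, tolerance = 1e-10)
  }
  # too few genes for the refit
  q3 <- random_quantity_matrix(3, 12, 1)
  expect_error(normfinder_best_pair(normfinder_input(q3, rep(1:3, 4))),
               "at least 4 genes")
})

test_that("injected intergroup deviation raises stability monotonically", {
  set.seed(37)
  I <- 6; G <- 7; n <- 5
  group <- rep(1:G, each = n)
  base <- matrix(rnorm(I * G * n, 0, 0.1), I, G * n,
                 dimnames = list(paste0("g", 1:I), paste0("s", 1:(G * n))))
  # keep some genuine group structure so gamma^2 > 0
  base[2, ] <- base[2, ] + rep(c(0.3, -0.3, 0, 0.2, 0, -0.2, 0), each = n)
  rho_g1 <- vapply(c(0, 0.2, 0.4, 0.8), function(d) {
    y <- base
    y[1, group == 3] <- y[1, group == 3] + d
    st <- suppressWarnings(
      normfinder_stability(normfinder_fit(nf_input_from_y(y, group)))
    )
    st$stability[st$gene == "g1"]
  }, numeric(1))
  expect_true(all(diff(rho_g1) > 0))
})
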