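test_that("Cq tables round-trip through CSV losslessly", {
  set.seed(11)
  for (rep in 1:5) {
    n_samples <- sample(2:6, 1)
    n_genes <- sample(2:5, 1)
    grid <- expand.grid(sample_id = paste0("s", seq_len(n_samples)),
                        gene = paste0("g", seq_len(n_genes)),
                        replicate = 1:3, stringsAsFactors = FALSE)
    tab <- tibble::tibble(
      sample_id = grid$sample_id, gene = grid$gene,
      replicate = as.integer(grid$replicate),
      cq = runif(nrow(grid), 8, 35)
    )
    path <- withr::local_tempfile(fileext = ".csv")
    write_cq_table(tab, path)
    back <- read_cq_table(path)
    ord <- order(tab$sample_id, tab$gene, tab$replicate)
    expect_equal(as.data.frame(back), as.data.frame(tab[ord, ]),
                 ignore_attr = TRUE)
  }
})

test_that("Cq table reader rejects bad headers, duplicates and malformed numbers", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("sample_id,gene,rep,cq", "s1,Actb,1,21"), path)
  expect_error(read_cq_table(path), "expected header")

  writeLines(c("sample_id,gene,replicate,cq",
               "s1,Actb,1,21", "s1,Actb,1,22"), path)
  expect_error(read_cq_table(path), "duplicate")

  writeLines(c("sample_id,gene,replicate,cq", "s1,Actb,1,twenty"), path)
  expect_error(read_cq_table(path), "malformed numeric")

  writeLines(c("sample_id,gene,replicate,cq", "s1,Actb,1,-3"), path)
  expect_error(read_cq_table(path), "finite and > 0")

  writeLines(c("sample_id,gene,replicate,cq",
               "s1,Actb,1,21.1", "s1,Actb,2,21.2", "s1,Actb,3,20.9"), path)
  tab <- read_cq_table(path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cq, c(21.1, 21.2, 20.9))
})

test_that("technical replicate aggregation computes mean/sd and flags, never drops", {
  tab <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    gene = "Actb",
    replicate = rep(1:3, 2),
    cq = c(21, 21, 21, 20, 21, 22)
  )
  agg <- aggregate_technical_replicates(tab, max_sd = 0.5)
  expect_equal(nrow(agg), 2)
  s1 <- agg[agg$sample_id == "s1", ]
  expect_equal(s1$mean_cq, 21)
  expect_equal(s1$sd_cq, 0)
  expect_false(s1$flag)
  s2 <- agg[agg$sample_id == "s2", ]
  expect_equal(s2$mean_cq, 21)
  expect_equal(s2$sd_cq, 1)
  expect_true(s2$flag)

  # single replicate: sd reported as 0
  single <- aggregate_technical_replicates(
    tibble::tibble(sample_id = "s1", gene = "g", replicate = 1L, cq = 25)
  )
  expect_equal(single$sd_cq, 0)
})

test_that("aggregation agrees with direct recomputation and ignores replicate order", {
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    cq <- runif(k, 15, 30)
    tab <- tibble::tibble(sample_id = "s", gene = "g",
                          replicate = seq_len(k), cq = cq)
    agg <- aggregate_technical_replicates(tab)
    expect_equal(agg$mean_cq, sum(cq) / k)
    expect_equal(agg$sd_cq, sqrt(sum((cq - mean(cq))^2) / (k - 1)))

    shuf <- tab[sample(k), ]
    shuf$replicate <- seq_len(k)
    agg2 <- aggregate_technical_replicates(shuf)
    expect_equal(agg2$mean_cq, agg$mean_cq)
    expect_equal(agg2$sd_cq, agg$sd_cq)
  }
})

test_that("partitioning reproduces the study's eight dataset sizes", {
  meta <- design_replica_meta()
  part <- partition_datasets(meta)
  expect_equal(part$label, LETTERS[1:8])
  expect_equal(part$n_samples, c(35, 33, 45, 30, 51, 34, 131, 97))
  expect_equal(sum(part$n_samples[1:6]), 228)
  # pooled groups are exact unions of the per-strain cells
  expect_setequal(part$sample_ids[[7]],
                  c(part$sample_ids[[1]], part$sample_ids[[3]], part$sample_ids[[5]]))
  expect_setequal(part$sample_ids[[8]],
                  c(part$sample_ids[[2]], part$sample_ids[[4]], part$sample_ids[[6]]))
})

test_that("partition conservation holds for random unbalanced metadata", {
  set.seed(31)
  strains <- default_strains()
  for (rep in 1:5) {
    n <- sample(30:80, 1)
    meta <- tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      strain = sample(strains, n, replace = TRUE),
      tissue = sample(default_tissues(), n, replace = TRUE),
      time_ct = sample(default_time_points(), n, replace = TRUE),
      animal_id = paste0("a", seq_len(n))
    )
    part <- partition_datasets(meta)
    expect_equal(part$n_samples[7], sum(part$n_samples[c(1, 3, 5)]))
    expect_equal(part$n_samples[8], sum(part$n_samples[c(2, 4, 6)]))
    expect_equal(sum(part$n_samples[1:6]), n)
    expect_false(anyDuplicated(unlist(part$sample_ids[1:6])) > 0)
  }
})

test_that("degenerate single-strain metadata collapses the partition", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    strain = "C57BL/6JOlaHsd",
    tissue = "liver",
    time_ct = rep(c(0, 12), 3),
    animal_id = paste0("a", 1:6)
  )
  part <- partition_datasets(meta, strains = "C57BL/6JOlaHsd",
                             tissues = c("liver", "adrenal"))
  expect_setequal(part$sample_ids[[1]], meta$sample_id)   # strain/liver cell
  expect_setequal(part$sample_ids[[3]], meta$sample_id)   # pooled liver
  expect_equal(part$n_samples[[2]], 0)                    # empty adrenal cell

  bad <- meta
  bad$strain[1] <- "BALB/c"
  expect_error(partition_datasets(bad, strains = "C57BL/6JOlaHsd"),
               "unknown strain")
})

test_that("efficiency maps validate ranges and warn outside the usual band", {
  expect_error(validate_efficiency(c(Actb = 0.9)), "\\(1, 2.1\\]")
  expect_error(validate_efficiency(c(Actb = 2.2)), "\\(1, 2.1\\]")
  expect_warning(validate_efficiency(c(Odd = 1.5)), "outside the usual")
  expect_silent(validate_efficiency(c(Actb = 1.98, Hmbs = 1.64)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_efficiency(c(Actb = 1.98, Hmbs = 1.64), path)
  expect_equal(read_efficiency(path), c(Actb = 1.98, Hmbs = 1.64))
})

test_that("complete-matrix policies drop genes or samples explicitly", {
  agg <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s2", "s3"),
    gene = c("g1", "g2", "g1", "g2", "g1"),
    mean_cq = c(20, 22, 21, 23, 20.5)
  )
  expect_warning(m <- complete_cq_matrix(agg, c("s1", "s2", "s3")), "dropping gene")
  expect_equal(rownames(m), "g1")
  expect_warning(
    m2 <- complete_cq_matrix(agg, c("s1", "s2", "s3"), on_missing = "drop_sample"),
    "dropping sample"
  )
  expect_equal(colnames(m2), c("s1", "s2"))
  expect_equal(rownames(m2), c("g1", "g2"))
  expect_error(
    complete_cq_matrix(agg, c("s1", "s2", "s3"), on_missing = "error"),
    "incomplete"
  )
  full <- complete_cq_matrix(agg, c("s1", "s2"))
  expect_equal(dim(full), c(2, 2))
  expect_equal(full["g1", "s2"], 21)
})
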