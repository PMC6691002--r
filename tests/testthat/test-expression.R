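small_sheet <- make_sample_sheet(genotypes = "8", treatments = "control",
                                 days = 0, replicates = 3)

test_that("low-count filtering uses a strict threshold", {
  cm <- rbind(keep = c(6, 6, 0, 0), edge = c(5, 5, 5, 5),
              single = c(100, 0, 0, 0), zero = c(0, 0, 0, 0))
  out <- filter_low_counts(cm)
  expect_equal(rownames(out), "keep")
  expect_equal(attr(out, "log")$n_in, 4)
  expect_equal(attr(out, "log")$n_out, 1)
  expect_equal(nrow(filter_low_counts(matrix(0L, 5, 4))), 0L)
  expect_error(filter_low_counts(matrix(-1, 2, 2)), "non-negative")
})

test_that("size factors follow the median-of-ratios formula", {
  base <- matrix(rpois(400, 50) + 1L, 100, 4)
  expect_equal(unname(size_factors(base[, c(1, 1)])), c(1, 1),
               ignore_attr = TRUE)
  doubled <- cbind(base[, 1], base[, 1] * 2L)
  expect_equal(unname(size_factors(doubled)), c(2^-0.5, 2^0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # log size factors sum to zero
  s <- size_factors(base)
  expect_lt(abs(mean(log(s))), 1e-9)
  expect_true(all(s > 0))
})

test_that("planted size factors are recovered within 5%", {
  cm <- synth_counts(n_genes = 2000, sheet = small_sheet, sf = c(0.5, 1, 2),
                     de_fraction = 0, dispersion = 0.02, seed = 404)
  s <- size_factors(cm$counts)
  expect_lt(max(abs(s / c(0.5, 1, 2) - 1)), 0.05)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(15)
  for (i in 1:25) {
    p <- runif(sample(3:50, 1))
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12))
    expect_true(all(got <= 1))
    # monotone in the raw p-values
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
})

test_that("a flat gene yields zero fold change and p near 1", {
  sheet <- make_sample_sheet(genotypes = "8", replicates = 1) # 10 libraries
  flat <- matrix(50L, 3, nrow(sheet),
                 dimnames = list(c("f1", "f2", "f3"), sheet$library_id))
  res <- nb_lrt(flat, sheet)
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-6)
  expect_true(all(res$pvalue > 0.99))
  expect_true(all(res$lrt_stat >= 0))
  expect_true(all(res$padj >= res$pvalue - 1e-12))
})

test_that("the LRT is calibrated under the null and powered for 4x effects", {
  null <- synth_counts(n_genes = 600, de_fraction = 0, seed = 808)
  res <- nb_lrt(null$counts, null$sheet)
  expect_true(all(res$lrt_stat >= 0))
  frac <- mean(res$pvalue < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
  pow <- synth_counts(n_genes = 300, de_fraction = 0.3, log2fc = 2,
                      seed = 809)
  rp <- nb_lrt(pow$counts, pow$sheet)
  de_true <- pow$truth$gene[pow$truth$is_de]
  expect_gte(mean(rp$padj[match(de_true, rp$gene)] < 0.05), 0.9)
  # status encodes direction at the FDR threshold
  expect_true(all(rp$status[rp$padj < 0.05 & rp$log2fc > 0] == "up"))
  expect_true(all(rp$status[rp$padj >= 0.05] == "ns"))
  # planted signs are recovered in the reported log2FC
  up_true <- pow$truth$gene[pow$truth$log2fc > 0]
  expect_gt(mean(rp$log2fc[match(up_true, rp$gene)]), 1)
})

test_that("genotype-covariate mode fits and tests the same genes", {
  pow <- synth_counts(n_genes = 60, de_fraction = 0.3, seed = 11)
  r1 <- nb_lrt(pow$counts, pow$sheet)
  r2 <- nb_lrt(pow$counts, pow$sheet, genotype_covariate = TRUE)
  expect_equal(r1$gene, r2$gene)
  expect_true(all(r2$lrt_stat >= 0))
})

test_that("expression grouping separates planted archetypes", {
  sheet <- make_sample_sheet()
  n <- 30
  up <- t(replicate(n / 2, rpois(nrow(sheet), 20) +
                      ifelse(sheet$treatment == "drought", 200L, 0L)))
  down <- t(replicate(n / 2, rpois(nrow(sheet), 20) +
                        ifelse(sheet$treatment == "control", 200L, 0L)))
  cm <- rbind(up, down) + 1L
  rownames(cm) <- sprintf("g%02d", 1:n)
  colnames(cm) <- sheet$library_id
  eg <- expression_groups(rownames(cm), cm, sheet, k = 2)
  grp <- eg$membership
  expect_equal(length(unique(grp[1:(n / 2)])), 1L)
  expect_equal(length(unique(grp[(n / 2 + 1):n])), 1L)
  expect_false(grp[1] == grp[n])
  # k = number of genes gives singletons
  eg_all <- expression_groups(rownames(cm), cm, sheet, k = n)
  expect_equal(max(table(eg_all$membership)), 1L)
  # permuting gene order leaves the partition unchanged
  perm <- sample(rownames(cm))
  eg2 <- expression_groups(perm, cm, sheet, k = 2)
  agree <- outer(eg$membership[perm], eg$membership[perm], "==") ==
    outer(eg2$membership[perm], eg2$membership[perm], "==")
  expect_true(all(agree))
  expect_error(expression_groups(rownames(cm), cm, sheet, k = n + 1), "k")
})

test_that("subfamily DE summaries count directions per category", {
  de <- data.frame(gene = sprintf("g%02d", 1:20),
                   log2fc = c(rep(2, 8), rep(-2, 5), rep(1, 4), rep(-3, 3)),
                   lrt_stat = 10, df = 5, pvalue = 1e-4, padj = 1e-3,
                   status = c(rep("up", 8), rep("down", 5), rep("up", 4),
                              rep("down", 3)),
                   stringsAsFactors = FALSE)
  calls <- data.frame(seq_id = de$gene,
                      category = c(rep("RNL", 13), rep("TNL", 7)),
                      stringsAsFactors = FALSE)
  tab <- subfamily_de_summary(de, calls)
  rnl <- tab[tab$category == "RNL", ]
  expect_equal(rnl$n_de, 13)
  expect_equal(rnl$up_fraction, 8 / 13)
  expect_equal(sum(tab$n_de), nrow(de))
  expect_equal(sum(tab$n_up) + sum(tab$n_down), nrow(de))
  none <- de[0, ]
  expect_equal(nrow(subfamily_de_summary(none, calls)), 0L)
})
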