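test_that("HWE exact test matches closed cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)  # monomorphic
  expect_equal(hwe_exact_test(50, 0, 50), oracle_hwe(50, 0, 50), tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  set.seed(14)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                 tolerance = 1e-12,
                 label = sprintf("table (%d,%d,%d)", nAA, nAa, naa))
  }
})

test_that("differential missingness equals the contingency-test oracle", {
  # identical proportions in both groups -> chi-square 0, p = 1
  miss <- rep(c(TRUE, FALSE, FALSE, FALSE), 50)
  grp <- rep(c("case", "control"), each = 100)
  expect_equal(differential_missingness(miss, grp), 1)

  miss2 <- c(rep(TRUE, 10), rep(FALSE, 90), rep(FALSE, 100))
  p_pkg <- differential_missingness(miss2, grp)
  tab <- table(miss2, grp)
  p_oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  expect_error(differential_missingness(miss2, rep("one", 200)), "two groups")

  # permuting labels leaves the permutation-null distribution invariant:
  # the statistic itself is symmetric in the labels
  set.seed(15)
  perm <- sample(grp)
  tab_p <- table(miss2, perm)
  expect_equal(sort(colSums(tab)), sort(colSums(tab_p)))
})

test_that("neighbour-genotype grouping works as a 2x3 test", {
  set.seed(16)
  neighbour <- sample(0:2, 300, replace = TRUE)
  miss <- runif(300) < ifelse(neighbour == 2, 0.5, 0.02)
  expect_lt(differential_missingness(miss, neighbour), 1e-6)
})

test_that("sample filters find planted duplicates and heterozygosity outliers", {
  set.seed(17)
  n <- 300; m <- 600
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%03d", 1:m)))
  inj <- inject_artifacts(G, artifact_config(n_duplicates = 2, n_het_samples = 4))
  res <- sample_filters(inj$genotypes)
  dup_removed <- res$removed$id[res$removed$step == "duplicates"]
  expect_equal(length(dup_removed), 2)
  het_removed <- res$removed$id[res$removed$step == "heterozygosity"]
  expect_gte(sum(inj$truth$het_samples$individual_id %in% het_removed), 3)

  # clean matrix: nothing removed
  res2 <- sample_filters(G)
  expect_identical(res2$genotypes, G)
  expect_equal(sum(res2$steps$n_removed), 0)
  expect_error(sample_filters(G, call_rate = 1.2), "thresholds")
})

test_that("SNP filters apply thresholds at the documented boundaries", {
  set.seed(18)
  n <- 500
  G <- cbind(
    mono = rep(0L, n),
    low_maf = rbinom(n, 2, 0.0045),
    ok_maf = rbinom(n, 2, 0.011),
    common = rbinom(n, 2, 0.4)
  )
  rownames(G) <- sprintf("s%03d", 1:n)
  # fix realised frequencies right at the boundary
  G[, "low_maf"] <- c(rep(1L, 9), rep(0L, n - 9))    # MAF 0.009
  G[, "ok_maf"] <- c(rep(1L, 11), rep(0L, n - 11))   # MAF 0.011
  res <- snp_filters(G, maf = 0.01, hwe_p = 1e-20)
  expect_false("mono" %in% colnames(res$genotypes))
  expect_false("low_maf" %in% colnames(res$genotypes))
  expect_true("ok_maf" %in% colnames(res$genotypes))
  expect_true("common" %in% colnames(res$genotypes))
  # report telescopes correctly
  expect_equal(res$steps$n_remaining,
               ncol(G) - cumsum(res$steps$n_removed))
})

test_that("planted SNP defects are recovered with high sensitivity", {
  set.seed(19)
  n <- 1000; m <- 80
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("s%04d", 1:n), sprintf("m%03d", 1:m)))
  pheno <- rep(c(TRUE, FALSE), n / 2)
  inj <- inject_artifacts(G, artifact_config(n_hwe_snps = 10,
                                             n_pheno_miss_snps = 5,
                                             pheno_miss_rate = 0.2),
                          phenotype = pheno)
  res <- snp_filters(inj$genotypes, hwe_p = 1e-6, diff_miss_p = 1e-3,
                     phenotype = inj$phenotype)
  dropped <- setdiff(colnames(G), colnames(res$genotypes))
  planted <- c(inj$truth$hwe_snps$snp, inj$truth$pheno_miss_snps$snp)
  expect_gte(sum(planted %in% dropped) / length(planted), 0.9)
})

test_that("iterative QC is a fixed point on clean data and idempotent", {
  set.seed(20)
  G <- matrix(rbinom(200 * 100, 2, 0.3), 200, 100,
              dimnames = list(sprintf("s%03d", 1:200), sprintf("m%03d", 1:100)))
  rep1 <- iterative_qc(G)
  expect_true(rep1$converged)
  expect_equal(rep1$n_iter, 1L)
  expect_identical(rep1$genotypes, G)
  rep2 <- iterative_qc(rep1$genotypes)
  expect_equal(sum(rep2$steps$n_removed), 0)
  # internal consistency: telescoping within each unit
  for (u in unique(rep1$steps$unit)) {
    s <- rep1$steps[rep1$steps$unit == u, ]
    expect_true(all(diff(s$n_remaining) <= 0))
  }
})

test_that("removing bad samples rescues borderline SNPs in later iterations", {
  set.seed(21)
  n <- 120; m <- 60
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%03d", 1:m)))
  # 12 terrible samples: 60% missing overall, concentrated so that 10 SNPs
  # fall just below the call-rate threshold only while those samples remain
  bad_s <- 1:12
  bad_m <- 1:10
  G[bad_s, ] <- ifelse(matrix(runif(12 * m) < 0.5, 12, m), NA_integer_, G[bad_s, ])
  G[bad_s, bad_m] <- NA_integer_
  single_pass <- snp_filters(G)
  iter <- iterative_qc(G)
  n_snp_single <- ncol(single_pass$genotypes)
  n_snp_iter <- ncol(iter$genotypes)
  expect_gt(n_snp_iter, n_snp_single)
  expect_true(all(sprintf("m%03d", bad_m) %in% colnames(iter$genotypes)))
})

test_that("empty matrices abort the cascade", {
  G <- matrix(NA_integer_, 5, 5,
              dimnames = list(paste0("s", 1:5), paste0("m", 1:5)))
  expect_error(iterative_qc(G), "empty matrix")
})

test_that("ancestry outliers: homogeneous cohorts are clean, drifted samples flagged", {
  set.seed(22)
  n <- 300; m <- 3000
  p <- runif(m, 0.1, 0.5)
  G <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%04d", 1:m)))
  res <- ancestry_outliers(G)
  expect_lt(mean(res$flagged), 0.01)

  inj <- inject_artifacts(G, artifact_config(n_ancestry = 10, ancestry_fst = 0.3))
  res2 <- ancestry_outliers(inj$genotypes)
  hits <- res2$individual_id[res2$flagged]
  expect_gte(sum(inj$truth$ancestry$individual_id %in% hits), 9)

  # a duplicate of an inlier lands inside the cluster
  inlier <- setdiff(rownames(G), inj$truth$ancestry$individual_id)[1]
  G3 <- rbind(inj$genotypes, dup_of_inlier = inj$genotypes[inlier, ])
  res3 <- ancestry_outliers(G3)
  expect_false(res3$flagged[res3$individual_id == "dup_of_inlier"])
  expect_error(ancestry_outliers(G[, 1:10]), "SNPs")
})

test_that("LD r-squared and greedy pruning behave on constructed fixtures", {
  set.seed(23)
  g <- rbinom(200, 2, 0.4)
  expect_equal(ld_r2(g, g), 1)
  expect_error(ld_r2(g[1], g[1]), "overlapping")
  expect_true(is.na(ld_r2(g, rep(1L, 200))))

  # independent SNPs: mean r-squared is tiny
  n <- 10000
  r2s <- replicate(50, ld_r2(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3)))
  expect_lt(mean(r2s), 0.001)

  # A tags B and C but not D -> pruning keeps {A, D}
  A <- rbinom(300, 2, 0.5)
  B <- A; B[1:10] <- pmin(2, B[1:10] + 1)
  C <- A; C[5:12] <- pmax(0, C[5:12] - 1)
  D <- rbinom(300, 2, 0.5)
  G <- cbind(A = A, B = B, C = C, D = D)
  res <- tibble::tibble(snp_id = c("A", "B", "C", "D"), p = c(1e-8, 1e-6, 1e-5, 1e-4))
  kept <- ld_prune(res, G, r2_max = 0.8)
  expect_equal(kept$snp_id, c("A", "D"))
})

test_that("ledger arithmetic is exact and guards against inconsistency", {
  led <- qc_ledger(2163, c(253, 55, 3, 43, 4))
  expect_equal(led$final, 1805)
  expect_equal(qc_ledger(592566, 403)$final, 592163)
  expect_equal(qc_ledger(100, integer(0))$final, 100)
  expect_error(qc_ledger(10, c(5, 6)), "inconsistent ledger")
  expect_equal(led$report$n_remaining, c(1910, 1855, 1852, 1809, 1805))
})
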