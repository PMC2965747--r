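test_that("the generator is fully reproducible from seed and config", {
  cfg <- sim_config(n_families = 120, n_null_snps = 30, seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$carriers, b$carriers)
  expect_identical(a$pedigree, b$pedigree)
})

test_that("family sizes follow the configured distribution", {
  cfg <- sim_config(n_families = 1000, family_size_probs = c(0, 1, 0),
                    n_null_snps = 0, seed = 2)
  set.seed(2)
  fams <- simulate_families(cfg)
  expect_equal(nrow(fams$subjects), 2000)  # deterministic when P(size=2)=1
  # mean-2 mixture: total within 3 SD of 2000
  cfg2 <- sim_config(n_families = 1000, family_size_probs = c(0.25, 0.5, 0.25),
                     n_null_snps = 0, seed = 3)
  set.seed(3)
  n_tot <- nrow(simulate_families(cfg2)$subjects)
  sd_tot <- sqrt(1000 * 0.5)
  expect_lt(abs(n_tot - 2000), 3 * sd_tot)
})

test_that("degenerate stratum weights put every family in one stratum", {
  cfg <- sim_config(n_families = 50, country_weights = c(UK = 1, USA = 0),
                    n_null_snps = 0, seed = 5)
  set.seed(5)
  fams <- simulate_families(cfg)
  expect_true(all(fams$families$country == "UK"))
})

test_that("Mendelian transmission: fixation, parental consistency, HWE founders", {
  cfg <- sim_config(n_families = 200, causal_maf = 0.999, n_null_snps = 500,
                    seed = 6)
  set.seed(6)
  fams <- simulate_families(cfg)
  G <- simulate_genotypes(fams, cfg, keep_founders = TRUE)
  # causal_maf ~ 1: essentially all genotypes 2 (probabilistic upper tail)
  expect_gt(mean(G[, "causal"] == 2L), 0.98)

  # no offspring is opposite-homozygous to either parent, and every offspring
  # allele is transmissible from its parents
  FA <- attr(G, "father"); MO <- attr(G, "mother")
  fam_of <- match(fams$subjects$family_id, fams$families$family_id)
  expect_false(any(abs(G - FA[fam_of, ]) == 2L))
  expect_false(any(abs(G - MO[fam_of, ]) == 2L))
  expect_true(all(G <= ceiling(FA[fam_of, ] / 2) + ceiling(MO[fam_of, ] / 2)))

  # founder genotypes pass the HWE exact test at alpha = 0.001 almost always
  founders <- rbind(FA[, -1], MO[, -1])
  pvals <- vapply(seq_len(ncol(founders)), function(j) {
    g <- founders[, j]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  expect_gte(mean(pvals >= 0.001), 0.99)
})

test_that("onset ages follow the configured survival function", {
  cfg <- sim_config(n_families = 2500, family_size_probs = 1, beta = 0,
                    frailty_sd = 0, ovarian_rate = 0, bpm_rate = 0,
                    last_obs_range = c(80, 80), n_null_snps = 0, seed = 12)
  set.seed(12)
  fams <- simulate_families(cfg)
  g <- rep(0L, nrow(fams$subjects))
  ph <- simulate_phenotypes(fams, g, cfg)
  # probability-integral transform of observed onsets, conditional on T <= 80
  Fcap <- 1 - exp(-cumulative_hazard(cfg$incidence, 80))
  obs <- ph$breast_dx_age[!is.na(ph$breast_dx_age)]
  u <- (1 - exp(-cumulative_hazard(cfg$incidence, obs))) / Fcap
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  # observed onset fraction matches F(80)
  expect_lt(abs(mean(!is.na(ph$breast_dx_age)) - Fcap), 0.03)
})

test_that("zero hazard produces no affected carriers", {
  cfg <- sim_config(n_families = 100, incidence = incidence_model(c(0, 80), 0),
                    ovarian_rate = 0, bpm_rate = 0, n_null_snps = 0, seed = 7)
  coh <- simulate_cohort(cfg, stage = NULL)
  expect_equal(sum(coh$carriers$affected), 0)
})

test_that("risk alleles are enriched among affected carriers", {
  cfg <- sim_config(n_families = 1200, family_size_probs = 1, beta = log(2),
                    causal_maf = 0.3, n_null_snps = 0, frailty_sd = 0, seed = 8)
  coh <- simulate_cohort(cfg, stage = NULL)
  g <- coh$genotypes[, "causal"]
  tt <- stats::t.test(g[coh$carriers$affected], g[!coh$carriers$affected],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("ascertainment applies the phenotype rules and ignores genotype", {
  carriers <- tibble::tibble(
    individual_id = c("a", "b", "c"),
    censor_age = c(39, 38, 45), affected = c(FALSE, TRUE, TRUE))
  sc <- default_ascertainment()$stage1
  sel <- apply_ascertainment(carriers, sc)
  expect_false("a" %in% sel$individual_id)  # unaffected at 39: too young a control
  expect_true("b" %in% sel$individual_id)   # case diagnosed at 38
  expect_error(apply_ascertainment(
    tibble::tibble(individual_id = "x", censor_age = 39, affected = FALSE), sc),
    "zero carriers")

  # under the null, genotype distribution of selected vs unselected matches
  cfg <- sim_config(n_families = 2500, family_size_probs = 1, beta = 0,
                    n_null_snps = 0, seed = 31)
  set.seed(cfg$seed)
  fams <- simulate_families(cfg)
  Gfull <- simulate_genotypes(fams, cfg)
  pool <- derive_time_at_risk(simulate_phenotypes(fams, Gfull[, "causal"], cfg))
  sel <- apply_ascertainment(pool, cfg$ascertainment$stage1)
  selected <- rownames(Gfull) %in% sel$individual_id
  tab <- table(Gfull[, "causal"], selected)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
})

test_that("artifact injection honours zero rates and plants detectable defects", {
  set.seed(9)
  G <- matrix(rbinom(400 * 50, 2, 0.3), 400, 50,
              dimnames = list(sprintf("s%03d", 1:400), sprintf("m%02d", 1:50)))
  clean <- inject_artifacts(G, artifact_config())
  expect_identical(clean$genotypes, G)

  inj <- inject_artifacts(G, artifact_config(n_duplicates = 3, n_hwe_snps = 5),
                          phenotype = rep(c(TRUE, FALSE), 200))
  expect_equal(nrow(inj$genotypes), 403)
  for (i in seq_len(3)) {
    d <- inj$truth$duplicates
    expect_equal(ibs_proportion(inj$genotypes[d$original[i], ],
                                inj$genotypes[d$duplicate[i], ]), 1.0)
  }
  # planted HWE violations are detectable at stringent thresholds
  hw <- vapply(inj$truth$hwe_snps$snp, function(s) {
    g <- inj$genotypes[, s]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  expect_gte(sum(hw < 1e-4), 4)
  expect_error(inject_artifacts(G, artifact_config(missing_rate = 1.2)), "rates")
})
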