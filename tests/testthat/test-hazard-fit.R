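# brute-force per-carrier retrospective likelihood: numerically build
# P(t, delta | g) * p(g) / sum_g' P(t, delta | g') p(g') for each carrier
oracle_retro_loglik <- function(beta, freqs, carriers, g, m) {
  tot <- 0
  for (i in seq_len(nrow(carriers))) {
    t <- carriers$censor_age[i]; d <- carriers$affected[i]
    q <- freqs[[as.character(carriers$stratum[i])]]
    pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    lik_g <- vapply(0:2, function(gg) {
      haz_mult <- exp(beta * gg)
      Lam <- cumulative_hazard(m, t) * haz_mult
      surv <- exp(-Lam)
      if (d) haz_mult * surv else surv   # lambda0(t) factor cancels in ratio
    }, numeric(1))
    tot <- tot + log(lik_g[g[i] + 1] * pg[g[i] + 1] / sum(lik_g * pg))
  }
  tot
}

test_that("the retrospective likelihood reduces to the genotype multinomial at beta 0", {
  carriers <- fixture_carriers(n = 40)
  set.seed(71)
  g <- rbinom(40, 2, 0.3)
  q <- c("A:other" = 0.35, "B:other" = 0.25)
  ll <- retro_loglik(0, q, carriers, g, fixture_incidence())
  qi <- q[carriers$stratum]
  lpg <- log(c((1 - qi)^2, 2 * qi * (1 - qi), qi^2)[cbind(seq_along(g) + 40 * g)])
  lpg <- vapply(seq_along(g), function(i) {
    pg <- c((1 - qi[i])^2, 2 * qi[i] * (1 - qi[i]), qi[i]^2)
    log(pg[g[i] + 1])
  }, numeric(1))
  expect_equal(ll, sum(lpg), tolerance = 1e-12)
})

test_that("the likelihood matches the brute-force oracle at nonzero effects", {
  carriers <- fixture_carriers(n = 35, seed = 72)
  set.seed(72)
  g <- rbinom(35, 2, 0.4)
  m <- fixture_incidence()
  q <- c("A:other" = 0.4, "B:other" = 0.3)
  for (b in c(-0.5, 0.2, 1.1)) {
    expect_equal(retro_loglik(b, q, carriers, g, m),
                 oracle_retro_loglik(b, q, carriers, g, m), tolerance = 1e-10)
  }
})

test_that("fitting recovers the simulated per-allele effect and is stationary", {
  cfg <- sim_config(n_families = 1100, beta = log(1.3), causal_maf = 0.3,
                    n_null_snps = 0, country_weights = c(A = 0.6, B = 0.4),
                    delT_prob = 0, seed = 73)
  coh <- simulate_cohort(cfg)
  carriers <- assign_strata(coh$carriers)$carriers
  g <- coh$genotypes[carriers$individual_id, "causal"]
  fit <- fit_hr(carriers, g, cfg$incidence)
  expect_lt(abs(fit$coef[["per_allele"]] - log(1.3)), 3 * fit$se[["per_allele"]])
  expect_gte(fit$loglik, fit$loglik_null)
  expect_equal(fit$ci_lower, exp(fit$coef - 1.959964 * fit$se), ignore_attr = TRUE)

  # gradient at the reported MLE vanishes in every coordinate
  q <- fit$freqs
  grad_beta <- (retro_loglik(fit$coef + 1e-5, q, carriers, g, cfg$incidence) -
                retro_loglik(fit$coef - 1e-5, q, carriers, g, cfg$incidence)) / 2e-5
  expect_lt(abs(grad_beta), 1e-2 * abs(fit$loglik) * 1e-3 + 0.05)
  for (s in names(q)) {
    qq <- q; qq[s] <- q[s] + 1e-6
    gq <- (retro_loglik(fit$coef, qq, carriers, g, cfg$incidence) -
           retro_loglik(fit$coef, q, carriers, g, cfg$incidence)) / 1e-6
    expect_lt(abs(gq), 0.5)
  }
})

test_that("the 2-df genotype model nests the multiplicative model", {
  cfg <- sim_config(n_families = 900, beta = log(1.4), causal_maf = 0.35,
                    n_null_snps = 0, country_weights = c(A = 1),
                    delT_prob = 0, seed = 74)
  coh <- simulate_cohort(cfg)
  carriers <- assign_strata(coh$carriers, min_size = 1)$carriers
  g <- coh$genotypes[carriers$individual_id, "causal"]
  f1 <- fit_hr(carriers, g, cfg$incidence, model = "per_allele")
  f2 <- fit_hr(carriers, g, cfg$incidence, model = "genotype_2df")
  expect_gte(f2$loglik, f1$loglik - 1e-4)
  # multiplicative truth: 2-df fit gains less than the chi-square(1) 95% bar
  expect_lt(2 * (f2$loglik - f1$loglik), stats::qchisq(0.95, 1))
})

test_that("age-interaction model nests the proportional-hazards fit", {
  cfg <- sim_config(n_families = 700, beta = log(1.3), causal_maf = 0.3,
                    n_null_snps = 0, country_weights = c(A = 1),
                    delT_prob = 0, seed = 75)
  coh <- simulate_cohort(cfg)
  carriers <- assign_strata(coh$carriers, min_size = 1)$carriers
  g <- coh$genotypes[carriers$individual_id, "causal"]
  f0 <- fit_hr(carriers, g, cfg$incidence)
  # at beta1 = 0 the age-varying likelihood equals the proportional one
  q <- f0$freqs
  expect_equal(
    retro_loglik(c(f0$coef, 0), q, carriers, g, cfg$incidence,
                 model = "age_interaction"),
    retro_loglik(f0$coef, q, carriers, g, cfg$incidence), tolerance = 1e-10)
  fi <- fit_age_interaction(carriers, g, cfg$incidence)
  expect_gte(fi$interaction_lrt, 0)
  expect_true(fi$interaction_p > 0 && fi$interaction_p <= 1)
  expect_lt(abs(fi$null_fit$coef[["per_allele"]] - f0$coef[["per_allele"]]), 1e-6)
})

test_that("a positive age slope is recovered in direction", {
  hits <- 0
  for (r in 1:5) {
    cfg <- sim_config(n_families = 1500, family_size_probs = 1, beta = log(1.2),
                      beta_age = 0.04, causal_maf = 0.35, frailty_sd = 0,
                      n_null_snps = 0, country_weights = c(A = 1),
                      delT_prob = 0, seed = 7500 + r)
    coh <- simulate_cohort(cfg, stage = NULL)
    carriers <- assign_strata(coh$carriers, min_size = 1)$carriers
    g <- coh$genotypes[carriers$individual_id, "causal"]
    fi <- fit_age_interaction(carriers, g, cfg$incidence)
    if (fi$coef[["per_allele_x_age"]] > 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("combined-stage fits pool carriers and stage-stratify", {
  cfg <- sim_config(n_families = 700, beta = log(1.3), causal_maf = 0.3,
                    n_null_snps = 0, country_weights = c(A = 0.6, B = 0.4),
                    delT_prob = 0, seed = 76)
  coh <- simulate_cohort(cfg)
  carriers <- assign_strata(coh$carriers)$carriers
  g <- coh$genotypes[carriers$individual_id, "causal"]
  half <- seq_len(nrow(carriers)) <= nrow(carriers) / 2
  c1 <- carriers[half, ]; c2 <- carriers[!half, ]
  g1 <- g[half]; g2 <- g[!half]

  # stage 2 empty: equals the stage-1-only fit
  f_alone <- combined_stage_fit(c1, g1, c2[0, ], integer(0), cfg$incidence)
  c1s <- c1; c1s$stratum <- paste0(c1s$stratum, ":stage1")
  f_ref <- fit_hr(c1s, g1, cfg$incidence)
  expect_equal(f_alone$coef, f_ref$coef, tolerance = 1e-8)

  f_comb <- combined_stage_fit(c1, g1, c2, g2, cfg$incidence)
  f1 <- fit_hr(c1, g1, cfg$incidence); f2 <- fit_hr(c2, g2, cfg$incidence)
  expect_lt(f_comb$se[1], max(f1$se[1], f2$se[1]))
  # agrees with the fixed-effect combination for moderate effects
  mfe <- meta_fixed_effect(c(f1$hr, f2$hr), c(f1$ci_lower, f2$ci_lower),
                           c(f1$ci_upper, f2$ci_upper))
  expect_lt(abs(f_comb$hr - mfe$hr), 0.05)
  expect_error(combined_stage_fit(c1, g1, c1, g1, cfg$incidence), "both stages")
})

test_that("fixed-effect combination reproduces published worked examples", {
  # confirmatory FGFR2 locus
  expect_equal(round(meta_fixed_effect(c(1.30, 1.26), c(1.16, 1.11),
                                       c(1.45, 1.43))$hr, 2), 1.28)
  # novel chromosome-10 locus
  expect_equal(round(meta_fixed_effect(c(0.67, 0.85), c(0.56, 0.70),
                                       c(0.80, 1.04))$hr, 2), 0.75)
  # novel chromosome-20 locus
  expect_equal(round(meta_fixed_effect(c(0.60, 0.84), c(0.47, 0.67),
                                       c(0.78, 1.06))$hr, 2), 0.72)
  # identical inputs: same point estimate, half-width shrunk by sqrt(2)
  one <- meta_fixed_effect(1.3, 1.1, 1.55)
  two <- meta_fixed_effect(c(1.3, 1.3), c(1.1, 1.1), c(1.55, 1.55))
  expect_equal(two$hr, one$hr, tolerance = 1e-12)
  expect_equal(log(two$upper / two$lower),
               log(one$upper / one$lower) / sqrt(2), tolerance = 1e-12)
  expect_error(meta_fixed_effect(1.3, 1.3, 1.3), "degenerate")
  expect_error(meta_fixed_effect(c(1, -1), c(0.5, -2), c(1.5, 0)), "positive")
})

test_that("tidy and glance summarise fits in broom style", {
  cfg <- sim_config(n_families = 400, beta = log(1.3), n_null_snps = 0,
                    country_weights = c(A = 1), delT_prob = 0, seed = 77)
  coh <- simulate_cohort(cfg)
  carriers <- assign_strata(coh$carriers, min_size = 1)$carriers
  fit <- fit_hr(carriers, coh$genotypes[carriers$individual_id, "causal"],
                cfg$incidence)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "hr", "conf.low",
                     "conf.high", "p.value"))
  expect_true(td$conf.low < td$hr & td$hr < td$conf.high)
  gl <- glance(fit)
  expect_equal(gl$n, fit$n)
  expect_s3_class(autoplot(fit), "ggplot")
})
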