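#' Simulation configuration for synthetic carrier cohorts
#'
#' Bundles every parameter of the synthetic-cohort generator: family structure,
#' country-by-founder-mutation strata, the causal variant and null SNP panel,
#' the baseline incidence model and per-allele effect, residual familial
#' clustering (shared log-normal frailty), the phenotype-based ascertainment
#' scheme, and genotyping-artifact injection rates.
#'
#' Families are sibships sharing two unobserved founder parents, so genotypes
#' of relatives are correlated through Mendelian transmission (kinship 0.25
#' between siblings). All study subjects are mutation carriers by design.
#'
#' @param n_families Number of families.
#' @param family_size_probs Probabilities of sibship sizes 1, 2, 3, ...
#' @param country_weights Named numeric vector of country sampling weights.
#' @param delT_prob Named numeric vector: per-country probability that the
#'   family segregates the Ashkenazi founder mutation (6174delT-like flag).
#'   Unnamed scalar applies everywhere.
#' @param causal_maf Causal-allele frequency among founders (scalar, or named
#'   by stratum key `"country:delT"` / `"country:other"`).
#' @param beta Per-allele log hazard ratio of the causal variant.
#' @param beta_age Slope of the age-varying per-allele effect (log-HR per
#'   year, centred at `t_ref`); 0 gives the proportional-hazards model.
#' @param t_ref Centring age in years for `beta_age`.
#' @param n_null_snps Number of independent null SNPs.
#' @param null_maf_range Range of null-SNP founder minor-allele frequencies.
#' @param incidence An [incidence_model()] for the carrier baseline hazard.
#' @param frailty_sd Standard deviation of the shared per-family log-normal
#'   frailty on the hazard (residual familial clustering); 0 disables it.
#' @param ovarian_rate,bpm_rate Constant competing hazards (per year) of
#'   ovarian cancer and bilateral prophylactic mastectomy, active from age 20.
#' @param last_obs_range Range of last-observation (interview) ages, years.
#' @param ascertainment List of per-stage schemes; see [apply_ascertainment()].
#' @param artifacts List of artifact-injection rates; see [inject_artifacts()].
#' @param seed Integer seed; with the config it determines every output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 1000,
                       family_size_probs = c(0.5, 0.3, 0.2),
                       country_weights = default_country_weights(),
                       delT_prob = default_delT_prob(),
                       causal_maf = 0.3,
                       beta = 0,
                       beta_age = 0,
                       t_ref = 50,
                       n_null_snps = 100,
                       null_maf_range = c(0.05, 0.5),
                       incidence = default_incidence_model(),
                       frailty_sd = 0.5,
                       ovarian_rate = 0.002,
                       bpm_rate = 0.002,
                       last_obs_range = c(30, 80),
                       ascertainment = default_ascertainment(),
                       artifacts = artifact_config(),
                       seed = 1L) {
  stopifnot(n_families >= 1, all(family_size_probs >= 0), sum(family_size_probs) > 0)
  if (any(causal_maf <= 0) || any(causal_maf >= 1)) stop("causal_maf must lie in (0, 1)")
  if (!is.finite(beta) || !is.finite(beta_age)) stop("effect sizes must be finite")
  if (null_maf_range[1] <= 0 || null_maf_range[2] > 0.5)
    stop("null_maf_range must be within (0, 0.5]")
  stopifnot(inherits(incidence, "incidence_model"), frailty_sd >= 0,
            ovarian_rate >= 0, bpm_rate >= 0)
  structure(
    list(n_families = as.integer(n_families),
         family_size_probs = family_size_probs / sum(family_size_probs),
         country_weights = country_weights / sum(country_weights),
         delT_prob = delT_prob,
         causal_maf = causal_maf, beta = beta, beta_age = beta_age, t_ref = t_ref,
         n_null_snps = as.integer(n_null_snps), null_maf_range = null_maf_range,
         incidence = incidence, frailty_sd = frailty_sd,
         ovarian_rate = ovarian_rate, bpm_rate = bpm_rate,
         last_obs_range = last_obs_range,
         ascertainment = ascertainment, artifacts = artifact_config_validate(artifacts),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_country_weights <- function() {
  c(Australia = 0.09, Canada = 0.12, Denmark = 0.01, France = 0.035,
    Finland = 0.025, Germany = 0.045, Iceland = 0.015, Israel = 0.065,
    Italy = 0.07, Spain = 0.08, Sweden = 0.012, Netherlands = 0.02,
    UK = 0.165, USA = 0.263)
}

#' @rdname sim_config
#' @export
default_delT_prob <- function() {
  c(Australia = 0.05, Canada = 0.35, Denmark = 0.05, France = 0.05,
    Finland = 0.02, Germany = 0.05, Iceland = 0.01, Israel = 0.9,
    Italy = 0.05, Spain = 0.05, Sweden = 0.05, Netherlands = 0.05,
    UK = 0.08, USA = 0.35)
}

#' @rdname sim_config
#' @export
default_ascertainment <- function() {
  list(
    stage1 = list(case_max_age = 50, case_young_age = 40, case_young_weight = 4,
                  control_min_age = 40, n_cases = NULL, n_controls = NULL),
    stage2 = list(case_max_age = 80, case_young_age = 50, case_young_weight = 1,
                  control_min_age = 18, n_cases = NULL, n_controls = NULL)
  )
}

#' Artifact-injection configuration
#'
#' @param missing_rate Baseline genotype missingness applied everywhere.
#' @param n_pheno_miss_snps Number of SNPs with case/control differential
#'   missingness; `pheno_miss_rate` is the extra missing rate in cases.
#' @param pheno_miss_rate Extra missingness in cases at those SNPs.
#' @param n_batch_miss_snps,batch_miss_rate Same, by genotyping batch.
#' @param n_duplicates Number of planted exact duplicate samples.
#' @param n_het_samples Samples with inflated heterozygosity.
#' @param het_factor Multiplier on the heterozygosity rate of those samples.
#' @param n_hwe_snps SNPs re-drawn with a strong heterozygote deficit.
#' @param hwe_f Inbreeding-like coefficient used for the deficit.
#' @param n_ancestry Samples re-drawn from a drifted allele-frequency profile.
#' @param ancestry_fst Drift (Fst-like) magnitude of the profile.
#' @param error_rate Random genotype-call error rate.
#' @return A named list.
#' @export
artifact_config <- function(missing_rate = 0,
                            n_pheno_miss_snps = 0, pheno_miss_rate = 0.1,
                            n_batch_miss_snps = 0, batch_miss_rate = 0.1,
                            n_duplicates = 0,
                            n_het_samples = 0, het_factor = 1.5,
                            n_hwe_snps = 0, hwe_f = 0.6,
                            n_ancestry = 0, ancestry_fst = 0.15,
                            error_rate = 0) {
  as.list(environment())
}

artifact_config_validate <- function(a) {
  rates <- c(a$missing_rate, a$pheno_miss_rate, a$batch_miss_rate, a$error_rate)
  if (any(rates < 0) || any(rates > 1)) stop("artifact rates must lie in [0, 1]")
  a
}

#' Simulate family structure and stratum assignment
#'
#' Draws sibship sizes and assigns each family a country and founder-mutation
#' flag. Every family is a sibship with two unobserved founder parents; study
#' subjects are the siblings.
#'
#' @param cfg A [sim_config()].
#' @return A list: `pedigree` (tibble including phantom parents, with
#'   `is_subject`), `subjects` (tibble of study subjects with family, country,
#'   delT), and `families` (one row per family).
#' @export
simulate_families <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nf <- cfg$n_families
  sizes <- sample.int(length(cfg$family_size_probs), nf, replace = TRUE,
                      prob = cfg$family_size_probs)
  countries <- sample(names(cfg$country_weights), nf, replace = TRUE,
                      prob = cfg$country_weights)
  dp <- cfg$delT_prob
  pr <- if (is.null(names(dp))) rep(dp[1], nf) else unname(dp[countries])
  pr[is.na(pr)] <- 0.05
  delT <- runif(nf) < pr

  fam_id <- sprintf("f%05d", seq_len(nf))
  parents <- tibble::tibble(
    family_id = rep(fam_id, each = 2),
    individual_id = paste0(rep(fam_id, each = 2), c("_p1", "_p2")),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep(c("M", "F"), nf), is_subject = FALSE
  )
  sub_fam <- rep(seq_len(nf), sizes)
  offspring <- tibble::tibble(
    family_id = fam_id[sub_fam],
    individual_id = paste0(fam_id[sub_fam], "_s",
                           unlist(lapply(sizes, seq_len))),
    father_id = paste0(fam_id[sub_fam], "_p1"),
    mother_id = paste0(fam_id[sub_fam], "_p2"),
    sex = "F", is_subject = TRUE
  )
  families <- tibble::tibble(family_id = fam_id, size = sizes,
                             country = countries, delT = delT)
  subjects <- offspring |>
    dplyr::select("family_id", "individual_id") |>
    dplyr::left_join(families, by = "family_id") |>
    dplyr::select("individual_id", "family_id", "country", "delT")
  list(pedigree = dplyr::bind_rows(parents, offspring),
       subjects = subjects, families = families)
}

#' Simulate genotypes on a sibship cohort
#'
#' Founder (phantom parent) genotypes are drawn binomial(2, p) under
#' Hardy-Weinberg equilibrium — per-stratum frequency for the causal SNP,
#' a shared frequency per null SNP — and offspring genotypes follow by
#' Mendelian transmission (one allele from each parent). Null SNPs are
#' independent across loci.
#'
#' @param fams Output of [simulate_families()].
#' @param cfg A [sim_config()].
#' @param n_null Override for the number of null SNPs (default from `cfg`).
#' @param chunk Number of SNPs simulated per block (memory control).
#' @param keep_founders Also return the phantom-parent genotypes (attributes
#'   `father` and `mother`, one row per family) for transmission checks.
#' @return Integer matrix subjects x SNPs (0/1/2), first column `causal`,
#'   then `null00001`, ... Attribute `maf` stores founder frequencies.
#' @export
simulate_genotypes <- function(fams, cfg, n_null = NULL, chunk = 2000L,
                               keep_founders = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  n_null <- n_null %||% cfg$n_null_snps
  families <- fams$families
  nf <- nrow(families)
  sub <- fams$subjects
  fam_of_sub <- match(sub$family_id, families$family_id)
  n <- nrow(sub)

  stratum <- paste(families$country, ifelse(families$delT, "delT", "other"), sep = ":")
  p_causal <- if (length(cfg$causal_maf) == 1L) rep(cfg$causal_maf, nf) else {
    p <- unname(cfg$causal_maf[stratum])
    p[is.na(p)] <- mean(cfg$causal_maf)
    p
  }
  maf_null <- if (n_null > 0)
    runif(n_null, cfg$null_maf_range[1], cfg$null_maf_range[2]) else numeric(0)

  m <- 1L + n_null
  G <- matrix(NA_integer_, n, m,
              dimnames = list(sub$individual_id,
                              c("causal", if (n_null > 0) sprintf("null%05d", seq_len(n_null)))))
  FA <- MO <- if (keep_founders)
    matrix(NA_integer_, nf, m, dimnames = list(fams$families$family_id, colnames(G)))
  draw_block <- function(p_by_fam_mat, cols) {
    # p_by_fam_mat: nf x k founder allele frequencies
    k <- ncol(p_by_fam_mat)
    fa <- matrix(rbinom(nf * k, 2L, p_by_fam_mat), nf, k)
    mo <- matrix(rbinom(nf * k, 2L, p_by_fam_mat), nf, k)
    if (keep_founders) {
      FA[, cols] <<- fa
      MO[, cols] <<- mo
    }
    fa_s <- fa[fam_of_sub, , drop = FALSE]
    mo_s <- mo[fam_of_sub, , drop = FALSE]
    matrix(rbinom(n * k, 1L, fa_s / 2) + rbinom(n * k, 1L, mo_s / 2), n, k)
  }
  G[, 1] <- draw_block(matrix(p_causal, nf, 1), 1L)
  if (n_null > 0) {
    starts <- seq(1L, n_null, by = chunk)
    for (s in starts) {
      cols <- s:min(s + chunk - 1L, n_null)
      pm <- matrix(maf_null[cols], nf, length(cols), byrow = TRUE)
      G[, 1L + cols] <- draw_block(pm, 1L + cols)
    }
  }
  storage.mode(G) <- "integer"
  attr(G, "maf") <- c(causal = NA_real_, setNames(maf_null, colnames(G)[-1]))
  if (keep_founders) {
    attr(G, "father") <- FA
    attr(G, "mother") <- MO
  }
  G
}

# Inverse-transform onset age under hazard lambda0(t) * exp(eta + beta_age*(t - t_ref)*g).
# Closed form via the cumulative-hazard inverse when beta_age == 0, bisection otherwise.
sample_onset_age <- function(cfg, g, eta, u) {
  target <- -log(u)
  if (cfg$beta_age == 0) {
    cumulative_hazard_inverse(cfg$incidence, target / exp(eta))
  } else {
    cap <- cfg$incidence$edges[length(cfg$incidence$edges)]
    Lam <- function(t) age_varying_cumhaz(cfg$incidence, t, g, cfg$beta,
                                          cfg$beta_age, cfg$t_ref) * exp(eta - cfg$beta * g)
    lo <- rep(0, length(u)); hi <- rep(cap, length(u))
    out <- rep(Inf, length(u))
    reach <- Lam(rep(cap, length(u))) >= target
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      f <- Lam(mid) < target
      lo[f] <- mid[f]; hi[!f] <- mid[!f]
    }
    out[reach] <- hi[reach]
    out
  }
}

#' Simulate event histories from genotypes
#'
#' Onset ages are drawn by inverse-transform sampling from the proportional
#' hazards model \eqn{\lambda_0(t) \exp(\beta g + b_f)} on the configured
#' baseline, where \eqn{b_f} is a shared per-family normal frailty on the log
#' hazard. Competing ovarian-cancer and prophylactic-mastectomy events use
#' constant hazards from age 20; the interview (last observation) age is
#' uniform on `cfg$last_obs_range`. Events falling after the interview age are
#' unobserved.
#'
#' @param fams Output of [simulate_families()].
#' @param g_causal Integer vector of causal genotypes for the subjects.
#' @param cfg A [sim_config()].
#' @return Tibble of per-subject event histories (columns of
#'   [derive_time_at_risk()] plus ids, country, delT).
#' @export
simulate_phenotypes <- function(fams, g_causal, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sub <- fams$subjects
  n <- nrow(sub)
  stopifnot(length(g_causal) == n)
  fam_idx <- match(sub$family_id, fams$families$family_id)
  frailty <- if (cfg$frailty_sd > 0)
    rnorm(nrow(fams$families), 0, cfg$frailty_sd)[fam_idx] else rep(0, n)
  eta <- cfg$beta * g_causal + frailty
  onset <- sample_onset_age(cfg, g_causal, eta, runif(n))
  last_obs <- runif(n, cfg$last_obs_range[1], cfg$last_obs_range[2])
  ovarian <- if (cfg$ovarian_rate > 0) 20 + stats::rexp(n, cfg$ovarian_rate) else rep(Inf, n)
  bpm <- if (cfg$bpm_rate > 0) 20 + stats::rexp(n, cfg$bpm_rate) else rep(Inf, n)

  keep_age <- function(a) ifelse(is.finite(a) & a <= last_obs, a, NA_real_)
  tibble::tibble(
    individual_id = sub$individual_id,
    family_id = sub$family_id,
    country = sub$country,
    delT = sub$delT,
    breast_dx_age = keep_age(onset),
    ovarian_dx_age = keep_age(ovarian),
    bpm_age = keep_age(bpm),
    last_obs_age = last_obs
  )
}

#' Phenotype-based two-stage ascertainment
#'
#' Selects carriers by phenotype only (never by genotype): cases are affected
#' carriers censored at or below `case_max_age`, sampled with extra weight
#' `case_young_weight` when diagnosed below `case_young_age`; controls are
#' unaffected carriers with censoring age above `control_min_age`. When
#' `n_cases`/`n_controls` are `NULL` every eligible carrier is selected.
#'
#' @param carriers Tibble with `censor_age` and `affected` columns (typically
#'   from [derive_time_at_risk()]).
#' @param scheme A list as in [default_ascertainment()]`$stage1`.
#' @param stage Stage label attached to the output (1 or 2).
#' @return The selected rows with a `stage` column.
#' @export
apply_ascertainment <- function(carriers, scheme, stage = 1L) {
  stopifnot(is.data.frame(carriers), all(c("censor_age", "affected") %in% names(carriers)))
  x <- tibble::as_tibble(carriers)
  cases <- x[x$affected & x$censor_age <= scheme$case_max_age, , drop = FALSE]
  controls <- x[!x$affected & x$censor_age > scheme$control_min_age, , drop = FALSE]
  pick <- function(df, n_target, weights = NULL) {
    if (is.null(n_target) || nrow(df) <= n_target) return(df)
    df[sample.int(nrow(df), n_target, prob = weights), , drop = FALSE]
  }
  w <- ifelse(cases$censor_age < scheme$case_young_age, scheme$case_young_weight, 1)
  cases <- pick(cases, scheme$n_cases, if (nrow(cases)) w else NULL)
  controls <- pick(controls, scheme$n_controls)
  out <- dplyr::bind_rows(cases, controls)
  if (!nrow(out)) stop("ascertainment scheme selected zero carriers")
  out$stage <- as.integer(stage)
  out
}

#' Inject genotyping artifacts and record the truth
#'
#' Corrupts a clean genotype matrix with the defect classes a QC cascade must
#' recover: baseline and differential (case/control, batch) missingness,
#' exact duplicate samples, heterozygosity-inflated samples, SNPs re-drawn
#' with a strong heterozygote deficit, samples re-drawn from a drifted
#' allele-frequency profile (distinct ancestry), and random call errors.
#'
#' @param G Integer genotype matrix (samples x SNPs, rownames = ids).
#' @param artifacts An [artifact_config()].
#' @param phenotype Optional logical case indicator per sample.
#' @param batch Optional batch factor per sample (defaults to two batches
#'   split by row order).
#' @return List: `genotypes` (corrupted matrix, duplicates appended as new
#'   rows suffixed `_dup`), `phenotype`, `batch` (extended to match), and
#'   `truth` — a list of tibbles naming every planted defect.
#' @export
inject_artifacts <- function(G, artifacts = artifact_config(),
                             phenotype = NULL, batch = NULL) {
  a <- artifact_config_validate(artifacts)
  n <- nrow(G); m <- ncol(G)
  if (is.null(batch)) batch <- rep(c("b1", "b2"), length.out = n)
  if (is.null(phenotype)) phenotype <- rep(FALSE, n)
  truth <- list()

  # ancestry: redraw sample rows from a Balding-Nichols drifted frequency profile
  if (a$n_ancestry > 0) {
    ids <- sample.int(n, a$n_ancestry)
    p0 <- pmin(pmax(colMeans(G, na.rm = TRUE) / 2, 0.01), 0.99)
    fst <- a$ancestry_fst
    pd <- stats::rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
    for (i in ids) G[i, ] <- rbinom(m, 2L, pd)
    truth$ancestry <- tibble::tibble(individual_id = rownames(G)[ids])
  }

  # heterozygosity inflation
  if (a$n_het_samples > 0) {
    pool <- setdiff(seq_len(n), if (!is.null(truth$ancestry))
      match(truth$ancestry$individual_id, rownames(G)) else integer(0))
    ids <- sample(pool, a$n_het_samples)
    for (i in ids) {
      h <- mean(G[i, ] == 1L, na.rm = TRUE)
      r <- min(1, (a$het_factor - 1) * h / max(1 - h, 1e-9))
      hom <- which(G[i, ] != 1L)
      flip <- hom[runif(length(hom)) < r]
      G[i, flip] <- 1L
    }
    truth$het_samples <- tibble::tibble(individual_id = rownames(G)[ids])
  }

  # HWE-violating SNPs: heterozygote deficit at the same allele frequency
  if (a$n_hwe_snps > 0) {
    js <- sample.int(m, a$n_hwe_snps)
    for (j in js) {
      p <- min(max(mean(G[, j], na.rm = TRUE) / 2, 0.05), 0.95)
      f <- a$hwe_f
      probs <- c((1 - p)^2 + f * p * (1 - p), 2 * p * (1 - p) * (1 - f),
                 p^2 + f * p * (1 - p))
      G[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    }
    truth$hwe_snps <- tibble::tibble(snp = colnames(G)[js])
  }

  # random call errors
  if (a$error_rate > 0) {
    err <- which(matrix(runif(n * m) < a$error_rate, n, m) & !is.na(G))
    G[err] <- (G[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    truth$errors <- tibble::tibble(n_errors = length(err))
  }

  # duplicates: exact copies appended before missingness so IBS = 1
  if (a$n_duplicates > 0) {
    ids <- sample.int(n, a$n_duplicates)
    dup <- G[ids, , drop = FALSE]
    rownames(dup) <- paste0(rownames(G)[ids], "_dup")
    G <- rbind(G, dup)
    phenotype <- c(phenotype, phenotype[ids])
    batch <- c(batch, batch[ids])
    truth$duplicates <- tibble::tibble(original = rownames(dup) |> sub("_dup$", "", x = _),
                                       duplicate = rownames(dup))
    n <- nrow(G)
  }

  # missingness: baseline, then differential by phenotype and batch
  if (a$missing_rate > 0)
    G[matrix(runif(n * m) < a$missing_rate, n, m)] <- NA_integer_
  if (a$n_pheno_miss_snps > 0) {
    js <- sample.int(m, a$n_pheno_miss_snps)
    rows <- which(as.logical(phenotype))
    for (j in js) G[rows[runif(length(rows)) < a$pheno_miss_rate], j] <- NA_integer_
    truth$pheno_miss_snps <- tibble::tibble(snp = colnames(G)[js])
  }
  if (a$n_batch_miss_snps > 0) {
    js <- sample.int(m, a$n_batch_miss_snps)
    rows <- which(batch == batch[1])
    for (j in js) G[rows[runif(length(rows)) < a$batch_miss_rate], j] <- NA_integer_
    truth$batch_miss_snps <- tibble::tibble(snp = colnames(G)[js])
  }

  list(genotypes = G, phenotype = phenotype, batch = batch, truth = truth)
}

#' Simulate a complete ascertained carrier cohort
#'
#' Runs the full generator: families, genotypes, phenotypes, censoring
#' derivation, and stage-1 ascertainment. Reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param stage Which ascertainment scheme to apply (`"stage1"`, `"stage2"`,
#'   or `NULL` for the unselected cohort).
#' @return List: `carriers` (selected, with censoring and stratum fields),
#'   `genotypes` (rows matched to `carriers`), `pedigree`, `fams`, and
#'   `pool` (the full pre-ascertainment cohort).
#' @export
simulate_cohort <- function(cfg, stage = "stage1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fams <- simulate_families(cfg)
  G <- simulate_genotypes(fams, cfg)
  ph <- simulate_phenotypes(fams, G[, 1L], cfg)
  pool <- derive_time_at_risk(ph)
  carriers <- if (is.null(stage)) pool else
    apply_ascertainment(pool, cfg$ascertainment[[stage]],
                        stage = if (identical(stage, "stage2")) 2L else 1L)
  list(carriers = carriers,
       genotypes = G[carriers$individual_id, , drop = FALSE],
       pedigree = fams$pedigree, fams = fams, pool = pool)
}
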