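#' Retrospective log-likelihood of genotypes given phenotypes
#'
#' The likelihood contribution of carrier \eqn{i} is the probability of the
#' observed genotype conditional on the phenotype \eqn{(t_i, \delta_i)}:
#' \deqn{\ell_i = \delta_i \eta(g_i, t_i) - \Lambda(t_i, g_i) + \log p_s(g_i)
#'  - \log \sum_{g'} p_s(g') \exp\{\delta_i \eta(g', t_i) - \Lambda(t_i, g')\},}
#' where \eqn{\eta(g, t)} is the log hazard multiplier of genotype \eqn{g}
#' (per-allele, 2-df genotype-specific, or age-varying coding),
#' \eqn{\Lambda(t, g)} the matching cumulative hazard, and \eqn{p_s(g)} the
#' Hardy-Weinberg genotype prior at the stratum allele frequency. Baseline
#' hazard terms \eqn{\lambda_0(t_i)^{\delta_i}} cancel in the conditional, so
#' the likelihood is valid under phenotype-based (non-random) ascertainment.
#' At \eqn{\beta = 0} it reduces exactly to the multinomial genotype
#' log-likelihood \eqn{\sum_i \log p_s(g_i)}.
#'
#' @param beta Numeric effect vector: length 1 (`per_allele`), 2
#'   (`genotype_2df`: heterozygote and rare-homozygote log-HRs), or 2
#'   (`age_interaction`: intercept and per-year slope).
#' @param freqs Named numeric vector of per-stratum allele frequencies in
#'   (0,1), names = stratum levels.
#' @param carriers Tibble with `censor_age`, `affected`, `stratum` (and
#'   optionally `birth_year`).
#' @param g Genotype vector (0/1/2; `NA` rows are dropped).
#' @param incidence An [incidence_model()].
#' @param model Genotype coding.
#' @param t_ref Centring age for the age-varying model.
#' @param per_carrier Return the vector of per-carrier contributions instead
#'   of their sum.
#' @return Scalar log-likelihood (or a vector when `per_carrier = TRUE`).
#' @export
retro_loglik <- function(beta, freqs, carriers, g, incidence,
                         model = c("per_allele", "genotype_2df", "age_interaction"),
                         t_ref = 50, per_carrier = FALSE) {
  model <- match.arg(model)
  stopifnot(all(is.finite(beta)))
  x <- tibble::as_tibble(carriers)
  ok <- !is.na(g)
  x <- x[ok, , drop = FALSE]; g <- g[ok]
  t <- x$censor_age
  delta <- as.numeric(x$affected)
  s <- as.character(x$stratum)
  q <- freqs[s]
  if (any(is.na(q))) stop("missing allele frequency for stratum: ",
                          paste(unique(s[is.na(q)]), collapse = ", "))
  Lam0 <- cumulative_hazard(incidence, t, x[["birth_year"]])

  # log p_s(g) under HWE, n x 3
  lpg <- cbind(2 * log1p(-q), log(2) + log(q) + log1p(-q), 2 * log(q))

  # delta*eta - Lambda for each genotype class, n x 3
  lp <- matrix(0, length(t), 3)
  for (gg in 0:2) {
    if (model == "per_allele") {
      eta <- beta[1] * gg
      lp[, gg + 1] <- delta * eta - Lam0 * exp(eta)
    } else if (model == "genotype_2df") {
      eta <- c(0, beta)[gg + 1]
      lp[, gg + 1] <- delta * eta - Lam0 * exp(eta)
    } else {
      eta_t <- (beta[1] + beta[2] * (t - t_ref)) * gg
      Lam <- age_varying_cumhaz(incidence, t, gg, beta[1], beta[2], t_ref,
                                birth_year = x[["birth_year"]])
      lp[, gg + 1] <- delta * eta_t - Lam
    }
  }
  z <- lpg + lp
  zmax <- apply(z, 1, max)
  lse <- zmax + log(rowSums(exp(z - zmax)))
  li <- z[cbind(seq_along(g), g + 1)] - lse
  if (per_carrier) li else sum(li)
}

# Cumulative hazard under an age-varying per-allele effect:
# integral of lambda0(u) * exp((b0 + b1 (u - t_ref)) * x) over [0, t],
# evaluated band by band (exact, since lambda0 is a step function).
age_varying_cumhaz <- function(model, t, xval, b0, b1, t_ref, birth_year = NULL) {
  edges <- model$edges
  rates <- model$rates
  n <- max(length(t), length(xval))
  t <- rep_len(t, n); xval <- rep_len(xval, n)
  out <- numeric(n)
  bx <- b1 * xval
  flat <- abs(bx) < 1e-12
  bx_safe <- ifelse(flat, 1, bx)
  for (b in seq_along(rates)) {
    lo <- edges[b]; hi <- pmin(t, edges[b + 1])
    w <- pmax(hi - lo, 0)
    if (all(w == 0)) next
    hi2 <- pmax(hi, lo)
    grow <- rates[b] * exp((b0 - b1 * t_ref) * xval) *
      (exp(bx * hi2) - exp(bx * lo)) / bx_safe * (w > 0)
    out <- out + ifelse(flat, rates[b] * exp(b0 * xval) * w, grow)
  }
  mult <- if (is.null(birth_year)) 1 else cohort_multiplier(model, birth_year)
  out * mult
}

# parameter packing: beta block then logit allele frequencies per stratum
pack_theta <- function(beta, q) c(beta, stats::qlogis(q))
unpack_theta <- function(theta, n_beta, strata_levels) {
  list(beta = theta[seq_len(n_beta)],
       q = setNames(stats::plogis(theta[-seq_len(n_beta)]), strata_levels))
}

#' Fit hazard-ratio models by retrospective maximum likelihood
#'
#' Maximises [retro_loglik()] jointly over the effect parameters and the
#' per-stratum allele frequencies (bounded quasi-Newton, `L-BFGS-B`, effect
#' bounded at |log HR| <= 5, tolerance 1e-8 on the log-likelihood).
#' Standard errors are robust (Huber/Lin-Wei sandwich
#' \eqn{A^{-1} B A^{-1}}), with the score outer products in \eqn{B} summed
#' over family clusters to allow for non-independence of related carriers.
#'
#' @inheritParams retro_loglik
#' @param carriers Tibble with `censor_age`, `affected`, `stratum`,
#'   `family_id`.
#' @param start Optional starting value for the effect parameters.
#' @return An object of class `hr_fit`: effect estimates with robust SEs,
#'   hazard ratios with 95% CIs, per-stratum allele-frequency estimates,
#'   maximised log-likelihood, and cluster counts. Methods: [tidy.hr_fit()],
#'   [glance.hr_fit()], `print`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_families = 300, beta = log(1.3), n_null_snps = 0, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' carriers <- assign_strata(cohort$carriers)$carriers
#' fit <- fit_hr(carriers, cohort$genotypes[carriers$individual_id, "causal"],
#'               cfg$incidence)
#' tidy(fit)
#' }
#' @export
fit_hr <- function(carriers, g, incidence,
                   model = c("per_allele", "genotype_2df", "age_interaction"),
                   t_ref = 50, start = NULL) {
  model <- match.arg(model)
  x <- tibble::as_tibble(carriers)
  stopifnot(all(c("censor_age", "affected", "stratum", "family_id") %in% names(x)))
  ok <- !is.na(g)
  x <- x[ok, , drop = FALSE]; g <- g[ok]
  if (length(unique(g)) < 2) stop("need at least two genotype classes to fit an effect")
  strata_levels <- sort(unique(as.character(x$stratum)))
  x$stratum <- as.character(x$stratum)

  q0 <- vapply(strata_levels, function(s) {
    p <- mean(g[x$stratum == s]) / 2
    min(max(p, 0.01), 0.99)
  }, numeric(1))
  n_beta <- if (model == "per_allele") 1L else 2L
  beta0 <- start %||% rep(0, n_beta)

  negll <- function(theta) {
    th <- unpack_theta(theta, n_beta, strata_levels)
    val <- -retro_loglik(th$beta, th$q, x, g, incidence, model = model, t_ref = t_ref)
    if (!is.finite(val)) 1e10 else val
  }
  # the age slope is per year: a much tighter bound than the main effect
  beta_lo <- if (model == "age_interaction") c(-5, -0.25) else rep(-5, n_beta)
  beta_hi <- if (model == "age_interaction") c(5, 0.25) else rep(5, n_beta)
  lower <- c(beta_lo, rep(stats::qlogis(1e-4), length(strata_levels)))
  upper <- c(beta_hi, rep(stats::qlogis(1 - 1e-4), length(strata_levels)))
  opt <- optim(pack_theta(beta0, q0), negll, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(factr = 1e7, maxit = 500))
  if (opt$convergence != 0)
    stop("retrospective likelihood maximisation failed to converge: ", opt$message)
  if (any(abs(opt$par[seq_len(n_beta)]) >= 5 - 1e-6))
    warning("effect estimate hit the |log HR| <= 5 bound (possible separation)")
  th <- unpack_theta(opt$par, n_beta, strata_levels)

  # robust sandwich variance over family clusters
  ll_vec <- function(theta) {
    u <- unpack_theta(theta, n_beta, strata_levels)
    retro_loglik(u$beta, u$q, x, g, incidence, model = model, t_ref = t_ref,
                 per_carrier = TRUE)
  }
  k <- length(opt$par)
  h <- pmax(1e-5, 1e-4 * abs(opt$par))
  Gmat <- matrix(0, nrow(x), k)            # per-carrier score components
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- h[j]
    Gmat[, j] <- (ll_vec(opt$par + e) - ll_vec(opt$par - e)) / (2 * h[j])
  }
  fam <- as.character(x$family_id)
  Sc <- rowsum(Gmat, fam)                  # per-family score vectors
  B <- crossprod(Sc)
  A <- numeric_hessian(function(p) -sum(ll_vec(p)), opt$par, h)
  Ainv <- tryCatch(solve(A), error = function(e) MASS_ginv(A))
  vcov_rob <- Ainv %*% B %*% Ainv
  se <- sqrt(pmax(diag(vcov_rob)[seq_len(n_beta)], 0))

  beta_hat <- th$beta
  term_names <- switch(model,
    per_allele = "per_allele",
    genotype_2df = c("heterozygote", "homozygote"),
    age_interaction = c("per_allele", "per_allele_x_age"))
  ll0 <- retro_loglik(rep(0, n_beta), q_mle_null(x, g, strata_levels), x, g,
                      incidence, model = model, t_ref = t_ref)

  structure(list(
    model = model, t_ref = t_ref,
    coef = setNames(beta_hat, term_names),
    se = setNames(se, term_names),
    vcov = vcov_rob[seq_len(n_beta), seq_len(n_beta), drop = FALSE],
    hr = exp(beta_hat),
    ci_lower = exp(beta_hat - 1.959964 * se),
    ci_upper = exp(beta_hat + 1.959964 * se),
    freqs = th$q,
    loglik = -opt$value, loglik_null = ll0,
    n = nrow(x), n_families = length(unique(fam)),
    convergence = opt$convergence
  ), class = "hr_fit")
}

# profile allele-frequency MLE at beta = 0 is the stratum sample frequency
q_mle_null <- function(x, g, strata_levels) {
  vapply(strata_levels, function(s) {
    p <- mean(g[x$stratum == s]) / 2
    min(max(p, 1e-4), 1 - 1e-4)
  }, numeric(1))
}

numeric_hessian <- function(f, par, h) {
  k <- length(par)
  H <- matrix(0, k, k)
  f0 <- f(par)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    for (j in i:k) {
      ej <- numeric(k); ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(par + ei + ej) - f(par + ei - ej) - f(par - ei + ej) + f(par - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# minimal Moore-Penrose fallback for a singular observed information
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Age-varying hazard-ratio model with interaction test
#'
#' Fits the hazard multiplier \eqn{\exp\{(\beta_0 + \beta_1 (t - t_{ref}))
#' g\}} by retrospective maximum likelihood and tests \eqn{\beta_1 = 0} with
#' a 1-df likelihood-ratio test against the proportional-hazards
#' (`per_allele`) fit.
#'
#' @inheritParams fit_hr
#' @return An `hr_fit` with extra fields `interaction_lrt` and
#'   `interaction_p`.
#' @export
fit_age_interaction <- function(carriers, g, incidence, t_ref = 50) {
  fit1 <- fit_hr(carriers, g, incidence, model = "age_interaction", t_ref = t_ref)
  fit0 <- fit_hr(carriers, g, incidence, model = "per_allele", t_ref = t_ref)
  lrt <- 2 * (fit1$loglik - fit0$loglik)
  fit1$interaction_lrt <- max(lrt, 0)
  fit1$interaction_p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  fit1$null_fit <- fit0
  fit1
}

#' Combined two-stage fit
#'
#' Pools the carriers of both stages into a single retrospective-likelihood
#' fit with the stage appended to the stratum key. Carriers appearing in both
#' stages are an error: cross-stage duplicates must be removed during QC.
#'
#' @param carriers1,carriers2 Stage-specific carrier tibbles (columns as in
#'   [fit_hr()], plus `individual_id`).
#' @param g1,g2 Stage-specific genotype vectors for the same SNP.
#' @inheritParams fit_hr
#' @return An `hr_fit` on the pooled data.
#' @export
combined_stage_fit <- function(carriers1, g1, carriers2, g2, incidence,
                               model = "per_allele", t_ref = 50) {
  x1 <- tibble::as_tibble(carriers1); x2 <- tibble::as_tibble(carriers2)
  if (nrow(x2) == 0) {
    x1$stratum <- paste0(x1$stratum, ":stage1")
    return(fit_hr(x1, g1, incidence, model = model, t_ref = t_ref))
  }
  overlap <- intersect(x1$individual_id, x2$individual_id)
  if (length(overlap))
    stop("carriers present in both stages (remove duplicates in QC): ",
         paste(head(overlap, 3), collapse = ", "))
  x1$stratum <- paste0(x1$stratum, ":stage1")
  x2$stratum <- paste0(x2$stratum, ":stage2")
  fit_hr(dplyr::bind_rows(x1, x2), c(g1, g2), incidence, model = model, t_ref = t_ref)
}

#' Fixed-effect combination of stage-wise hazard ratios
#'
#' Inverse-variance meta-analysis on the log-HR scale. Each stage's standard
#' error is recovered from its 95% CI as
#' \eqn{SE = (\log u - \log l) / (2 \times 1.959964)}.
#'
#' @param hr Numeric vector of stage hazard ratios.
#' @param lower,upper Matching 95% CI bounds.
#' @return One-row tibble: `hr`, `lower`, `upper`, `log_hr`, `se`.
#' @examples
#' meta_fixed_effect(c(1.30, 1.26), c(1.16, 1.11), c(1.45, 1.43))
#' @export
meta_fixed_effect <- function(hr, lower, upper) {
  stopifnot(length(hr) == length(lower), length(hr) == length(upper))
  if (any(c(hr, lower, upper) <= 0)) stop("HRs and CI bounds must be positive")
  if (any(lower > hr | upper < hr)) stop("each CI must bracket its HR")
  if (any(upper == lower)) stop("degenerate CI (upper = lower)")
  b <- log(hr)
  se <- (log(upper) - log(lower)) / (2 * 1.959964)
  w <- 1 / se^2
  bc <- sum(w * b) / sum(w)
  sec <- sqrt(1 / sum(w))
  tibble::tibble(hr = exp(bc),
                 lower = exp(bc - 1.959964 * sec),
                 upper = exp(bc + 1.959964 * sec),
                 log_hr = bc, se = sec)
}

#' @export
print.hr_fit <- function(x, ...) {
  cat("<hr_fit> model:", x$model, " n =", x$n,
      "(", x$n_families, "families )\n")
  for (i in seq_along(x$coef)) {
    cat(sprintf("  %s: HR %.3f (95%% CI %.3f-%.3f), log-HR %.4f (robust SE %.4f)\n",
                names(x$coef)[i], x$hr[i], x$ci_lower[i], x$ci_upper[i],
                x$coef[i], x$se[i]))
  }
  if (!is.null(x$interaction_p))
    cat(sprintf("  age-interaction LRT p = %.4g\n", x$interaction_p))
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Broom-style tidier for `hr_fit` objects
#'
#' @param x An `hr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per effect term: `term`, `estimate` (log-HR),
#'   `std.error` (robust), `hr`, `conf.low`, `conf.high`, `p.value` (Wald).
#' @export
tidy.hr_fit <- function(x, ...) {
  z <- x$coef / x$se
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se), hr = unname(x$hr),
                 conf.low = unname(x$ci_lower), conf.high = unname(x$ci_upper),
                 p.value = 2 * pnorm(-abs(unname(z))))
}

#' One-row model summary for `hr_fit` objects
#'
#' @param x An `hr_fit`.
#' @param ... Unused.
#' @return Tibble: `logLik`, `logLik_null`, `n`, `n_families`, `model`.
#' @export
glance.hr_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik_null = x$loglik_null,
                 n = x$n, n_families = x$n_families, model = x$model)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
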