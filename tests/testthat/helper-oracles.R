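# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: kinship by exhaustive enumeration of inheritance
# vectors, HWE by normalised exact probabilities built from choose(), the
# cumulative hazard by numerical quadrature of the step function.

# Exhaustive-gene-flow kinship: enumerate every inheritance configuration
# (which parental allele each non-founder inherits), assign founder-allele
# labels, and average allele-matching probabilities.
oracle_kinship <- function(ped, subjects = NULL) {
  ids <- as.character(ped$individual_id)
  fa <- as.character(ped$father_id); mo <- as.character(ped$mother_id)
  fa[fa %in% c("", "0")] <- NA; mo[mo %in% c("", "0")] <- NA
  n <- length(ids)
  nonf <- which(!is.na(fa) | !is.na(mo))
  stopifnot(length(nonf) <= 8)  # 4^k configurations
  if (is.null(subjects)) subjects <- ids
  # topological order by repeated passes
  ord <- integer(0); placed <- setNames(rep(FALSE, n), ids)
  while (length(ord) < n) {
    for (i in seq_len(n)) {
      if (placed[i]) next
      pf <- fa[i]; pm <- mo[i]
      if ((is.na(pf) || placed[pf]) && (is.na(pm) || placed[pm])) {
        ord <- c(ord, i); placed[i] <- TRUE
      }
    }
  }
  k <- length(nonf)
  configs <- if (k) as.matrix(expand.grid(rep(list(0:3), k))) else matrix(0, 1, 0)
  phi_acc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(configs))) {
    alle <- matrix(NA_integer_, n, 2, dimnames = list(ids, NULL))
    counter <- 0L
    cfg_i <- setNames(rep(NA_integer_, n), ids)
    cfg_i[nonf] <- configs[r, ]
    for (i in ord) {
      if (is.na(fa[i]) && is.na(mo[i])) {
        alle[i, ] <- counter + 1:2; counter <- counter + 2L
      } else {
        cc <- cfg_i[i]
        a1 <- if (!is.na(fa[i])) alle[fa[i], (cc %% 2) + 1] else { counter <- counter + 1L; counter }
        a2 <- if (!is.na(mo[i])) alle[mo[i], (cc %/% 2) + 1] else { counter <- counter + 1L; counter }
        alle[i, ] <- c(a1, a2)
      }
    }
    match_prob <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      match_prob[i, j] <- mean(outer(alle[i, ], alle[j, ], "=="))
    phi_acc <- phi_acc + match_prob
  }
  (phi_acc / nrow(configs))[subjects, subjects, drop = FALSE]
}

# Full-enumeration HWE exact p-value via normalised choose() products.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  h <- seq(rare %% 2, rare, by = 2)
  w <- vapply(h, function(hh) {
    choose(n, (nA - hh) / 2) * choose(n - (nA - hh) / 2, hh) * 2^hh
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# quadrature of the piecewise-constant hazard, integrating each smooth band
# separately so the discontinuities never degrade the quadrature
oracle_cumhaz <- function(edges, rates, t) {
  f <- stats::stepfun(edges[-1], c(rates, 0), right = FALSE)
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    cuts <- sort(unique(c(0, edges[edges < tt], tt)))
    sum(vapply(seq_len(length(cuts) - 1), function(i)
      stats::integrate(function(u) f(u), cuts[i], cuts[i + 1],
                       rel.tol = 1e-12)$value, numeric(1)))
  }, numeric(1))
}

# small canonical pedigrees (<= 6 members) for kinship checks
fixture_pedigrees <- function() {
  list(
    trio = data.frame(family_id = "f", individual_id = c("p1", "p2", "c1"),
                      father_id = c(NA, NA, "p1"), mother_id = c(NA, NA, "p2")),
    sibs3 = data.frame(family_id = "f",
                       individual_id = c("p1", "p2", "s1", "s2", "s3"),
                       father_id = c(NA, NA, "p1", "p1", "p1"),
                       mother_id = c(NA, NA, "p2", "p2", "p2")),
    three_gen = data.frame(family_id = "f",
                           individual_id = c("g1", "g2", "m", "f2", "c"),
                           father_id = c(NA, NA, "g1", NA, "f2"),
                           mother_id = c(NA, NA, "g2", NA, "m")),
    half_sibs = data.frame(family_id = "f",
                           individual_id = c("p1", "p2", "p3", "h1", "h2"),
                           father_id = c(NA, NA, NA, "p1", "p1"),
                           mother_id = c(NA, NA, NA, "p2", "p3")),
    inbred = data.frame(family_id = "f",
                        individual_id = c("p1", "p2", "s1", "s2", "i"),
                        father_id = c(NA, NA, "p1", "p1", "s1"),
                        mother_id = c(NA, NA, "p2", "p2", "s2")),
    two_fams = data.frame(family_id = c("a", "a", "b", "b"),
                          individual_id = c("a1", "a2", "b1", "b2"),
                          father_id = c(NA, NA, NA, "b1"),
                          mother_id = c(NA, NA, NA, NA))
  )
}

# quick carrier table for likelihood/score fixtures: two strata, mixed
# affected/unaffected with plausible censoring ages
fixture_carriers <- function(n = 60, seed = 11) {
  set.seed(seed)
  tibble::tibble(
    individual_id = sprintf("i%03d", seq_len(n)),
    family_id = sprintf("f%03d", seq_len(n)),
    country = rep(c("A", "B"), length.out = n),
    delT = FALSE,
    censor_age = runif(n, 25, 75),
    affected = runif(n) < 0.4,
    stratum = rep(c("A:other", "B:other"), length.out = n)
  )
}

fixture_incidence <- function() {
  incidence_model(c(0, 30, 50, 80), c(0.005, 0.012, 0.02))
}
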