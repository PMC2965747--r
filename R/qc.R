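#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the minor-allele count, the p-value is the
#' sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table (standard tail
#' definition, not mid-p). Monomorphic SNPs return p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorised).
#' @return Vector of exact p-values.
#' @examples
#' hwe_exact_test(25, 50, 25)  # 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == length(n_Aa), length(n_AA) == length(n_aa))
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  mapply(hwe_exact_one, n_AA, n_Aa, n_aa)
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("empty genotype table")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare-allele count
  h <- seq(rare %% 2, rare, by = 2)
  # log Pr(h | n, nA) = log [ n! nA! na! 2^h / ( (2n)! hom1! h! hom2! ) ]
  lp <- lgamma(n + 1) + lgamma(nA + 1) + lgamma(na + 1) + h * log(2) -
    lgamma(2 * n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Differential-missingness contingency test
#'
#' Pearson chi-square test (no continuity correction) of the 2 x k table of
#' genotype missingness against a grouping: case/control phenotype,
#' genotyping batch, or the genotype (0/1/2) of an adjacent SNP
#' ("neighbour" mode, which detects missingness informative of local
#' haplotype).
#'
#' @param missing Logical vector: is the call missing.
#' @param group Grouping vector with at least two non-empty levels.
#' @return P-value of the 2 x k chi-square test (df = k - 1). Degenerate
#'   tables (all missing or none missing) return 1.
#' @export
differential_missingness <- function(missing, group) {
  stopifnot(length(missing) == length(group))
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least two groups")
  tab <- table(factor(missing, levels = c(FALSE, TRUE)), g)
  if (any(colSums(tab) == 0)) stop("empty group")
  if (any(rowSums(tab) == 0)) return(1)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  pchisq(stat, df = ncol(tab) - 1, lower.tail = FALSE)
}

snp_call_rate <- function(G) 1 - colMeans(is.na(G))
sample_call_rate <- function(G) 1 - rowMeans(is.na(G))

snp_maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Pairwise allele-sharing (IBS) proportion
#'
#' Mean proportion of alleles shared identical-by-state between two samples
#' over their overlapping non-missing genotypes:
#' `1 - |g1 - g2| / 2` averaged over SNPs.
#'
#' @param g1,g2 Genotype vectors.
#' @return Scalar in \[0, 1\] (NA when there is no overlap).
#' @export
ibs_proportion <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(NA_real_)
  mean(1 - abs(g1[ok] - g2[ok]) / 2)
}

# all pairwise IBS proportions; returns tibble of pairs above a floor
ibs_pairs <- function(G, floor = 0) {
  n <- nrow(G)
  X <- G; storage.mode(X) <- "double"
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  # sum |g1-g2| over shared sites via dosage decomposition:
  # |a-b| = a + b - 2*min(a,b); min over {0,1,2} = sum_k 1(a>=k)1(b>=k), k=1,2
  I1 <- (X0 >= 1) * M; I2 <- (X0 >= 2) * M
  shared <- tcrossprod(M * 1)
  sum_ab <- tcrossprod(X0, M * 1) + tcrossprod(M * 1, X0)
  min_ab <- tcrossprod(I1) + tcrossprod(I2)
  ibs <- 1 - (sum_ab - 2 * min_ab) / (2 * pmax(shared, 1))
  idx <- which(upper.tri(ibs) & ibs >= floor, arr.ind = TRUE)
  tibble::tibble(id1 = rownames(G)[idx[, 1]], id2 = rownames(G)[idx[, 2]],
                 ibs = ibs[idx], n_shared = shared[idx])
}

#' Sample-level quality filters
#'
#' Applies, in a fixed logged order: (1) sample call rate; (2) autosomal
#' heterozygosity outliers — two-sided z-scores of the per-sample
#' heterozygote fraction (robust centre/scale: median and MAD), flagged by
#' Benjamini-Hochberg FDR; (3) duplicate pairs by pairwise IBS proportion at
#' or above `ibs_dup`, dropping the pair member with the lower call rate
#' (ties broken lexicographically by id).
#'
#' @param G Genotype matrix (samples x SNPs) with rownames.
#' @param call_rate Minimum sample call rate (default 0.95).
#' @param het_fdr FDR level for heterozygosity outliers (default 0.001).
#' @param ibs_dup IBS threshold declaring duplicates (default 0.95).
#' @return List: `genotypes` (filtered), `removed` (tibble id/step), `steps`
#'   (QC-report rows).
#' @export
sample_filters <- function(G, call_rate = 0.95, het_fdr = 0.001, ibs_dup = 0.95) {
  for (thr in c(call_rate, het_fdr, ibs_dup))
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]")
  steps <- list(); removed <- list()
  n0 <- nrow(G)

  cr <- sample_call_rate(G)
  drop <- rownames(G)[cr < call_rate]
  removed$call_rate <- drop
  G <- G[setdiff(rownames(G), drop), , drop = FALSE]
  steps$call_rate <- qc_step("sample_call_rate", call_rate, length(drop), nrow(G))
  if (nrow(G) == 0)
    return(list(genotypes = G, removed = removal_table(removed),
                steps = dplyr::bind_rows(steps), n_initial = n0))

  het <- rowMeans(G == 1L, na.rm = TRUE)
  mad_het <- stats::mad(het)
  z <- if (mad_het > 0) (het - median(het)) / mad_het else rep(0, length(het))
  padj <- p.adjust(2 * pnorm(-abs(z)), method = "BH")
  drop <- rownames(G)[padj < het_fdr]
  removed$heterozygosity <- drop
  G <- G[setdiff(rownames(G), drop), , drop = FALSE]
  steps$heterozygosity <- qc_step("sample_heterozygosity_fdr", het_fdr, length(drop), nrow(G))

  dup <- ibs_pairs(G, floor = ibs_dup)
  drop <- character(0)
  if (nrow(dup)) {
    cr <- sample_call_rate(G)
    for (i in seq_len(nrow(dup))) {
      a <- dup$id1[i]; b <- dup$id2[i]
      if (a %in% drop || b %in% drop) next
      loser <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b else max(a, b)
      drop <- c(drop, loser)
    }
  }
  removed$duplicates <- drop
  G <- G[setdiff(rownames(G), drop), , drop = FALSE]
  steps$duplicates <- qc_step("sample_ibs_duplicates", ibs_dup, length(drop), nrow(G))

  list(genotypes = G,
       removed = removal_table(removed),
       steps = dplyr::bind_rows(steps), n_initial = n0)
}

#' SNP-level quality filters
#'
#' Applies, in a fixed logged order: missingness/monomorphism, minor allele
#' frequency, Hardy-Weinberg exact test, and differential missingness by
#' phenotype and batch (when those labels are supplied).
#'
#' @param G Genotype matrix (samples x SNPs) with colnames.
#' @param call_rate Minimum SNP call rate (default 0.95).
#' @param maf Minimum minor allele frequency (default 0.01; monomorphic SNPs
#'   are always removed).
#' @param hwe_p HWE exact-test threshold (default 1e-6).
#' @param diff_miss_p Differential-missingness threshold (default 1e-3).
#' @param phenotype,batch Optional per-sample labels for the differential
#'   missingness tests.
#' @return List as in [sample_filters()].
#' @export
snp_filters <- function(G, call_rate = 0.95, maf = 0.01, hwe_p = 1e-6,
                        diff_miss_p = 1e-3, phenotype = NULL, batch = NULL) {
  steps <- list(); removed <- list()
  m0 <- ncol(G)

  cr <- snp_call_rate(G)
  drop <- colnames(G)[cr < call_rate]
  removed$call_rate <- drop
  G <- G[, setdiff(colnames(G), drop), drop = FALSE]
  steps$call_rate <- qc_step("snp_call_rate", call_rate, length(drop), ncol(G), unit = "snp")

  mafs <- snp_maf(G)
  drop <- colnames(G)[is.na(mafs) | mafs < maf]
  removed$maf <- drop
  G <- G[, setdiff(colnames(G), drop), drop = FALSE]
  steps$maf <- qc_step("snp_maf", maf, length(drop), ncol(G), unit = "snp")

  counts <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE), sum(g == 2L, na.rm = TRUE))
  }, numeric(3))
  hp <- if (ncol(G)) hwe_exact_test(counts[1, ], counts[2, ], counts[3, ]) else numeric(0)
  drop <- colnames(G)[hp < hwe_p]
  removed$hwe <- drop
  G <- G[, setdiff(colnames(G), drop), drop = FALSE]
  steps$hwe <- qc_step("snp_hwe_exact", hwe_p, length(drop), ncol(G), unit = "snp")

  for (nm in c("phenotype", "batch")) {
    grp <- if (nm == "phenotype") phenotype else batch
    if (is.null(grp)) next
    pv <- vapply(seq_len(ncol(G)), function(j) {
      miss <- is.na(G[, j])
      if (!any(miss) || all(miss)) return(1)
      differential_missingness(miss, grp)
    }, numeric(1))
    drop <- colnames(G)[pv < diff_miss_p]
    removed[[paste0("diff_miss_", nm)]] <- drop
    G <- G[, setdiff(colnames(G), drop), drop = FALSE]
    steps[[nm]] <- qc_step(paste0("snp_diff_missing_", nm), diff_miss_p,
                           length(drop), ncol(G), unit = "snp")
  }

  list(genotypes = G, removed = removal_table(removed),
       steps = dplyr::bind_rows(steps), n_initial = m0)
}

qc_step <- function(step, threshold, n_removed, n_remaining, unit = "sample") {
  tibble::tibble(step = step, unit = unit, threshold = threshold,
                 n_removed = as.integer(n_removed),
                 n_remaining = as.integer(n_remaining))
}

removal_table <- function(removed) {
  rows <- purrr::imap(removed, function(ids, step)
    if (length(ids)) tibble::tibble(id = ids, step = step) else NULL)
  dplyr::bind_rows(rows)
}

#' Iterative sample/SNP quality-control cascade
#'
#' Alternates [sample_filters()] and [snp_filters()] until a full pass
#' removes nothing (matrix sizes are monotone decreasing, so the loop
#' terminates). Re-running the cascade on its own output is a no-op.
#'
#' @inheritParams sample_filters
#' @inheritParams snp_filters
#' @param max_iter Safety bound on iterations.
#' @return An object of class `qc_report`: list with `genotypes` (the clean
#'   matrix), `steps` (ordered tibble of every filter application),
#'   `removed` (ids with step and iteration), `converged`, `n_iter`.
#' @export
iterative_qc <- function(G, sample_call_rate = 0.95, het_fdr = 0.001,
                         ibs_dup = 0.95, snp_call_rate = 0.95, maf = 0.01,
                         hwe_p = 1e-6, diff_miss_p = 1e-3,
                         phenotype = NULL, batch = NULL, max_iter = 20L) {
  steps <- list(); removed <- list()
  if (!is.null(phenotype)) phenotype <- setNames(phenotype, rownames(G))
  if (!is.null(batch)) batch <- setNames(batch, rownames(G))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sf <- sample_filters(G, sample_call_rate, het_fdr, ibs_dup)
    G <- sf$genotypes
    nf <- snp_filters(G, snp_call_rate, maf, hwe_p, diff_miss_p,
                      phenotype = phenotype[rownames(G)], batch = batch[rownames(G)])
    G <- nf$genotypes
    if (nrow(G) == 0 || ncol(G) == 0) stop("empty matrix: all samples or SNPs filtered out")
    pass <- dplyr::bind_rows(sf$steps, nf$steps)
    pass$iteration <- it
    steps[[it]] <- pass
    rem <- dplyr::bind_rows(sf$removed, nf$removed)
    if (nrow(rem)) { rem$iteration <- it; removed[[it]] <- rem }
    if (sum(pass$n_removed) == 0L) { converged <- TRUE; break }
  }
  structure(list(genotypes = G,
                 steps = dplyr::bind_rows(steps),
                 removed = dplyr::bind_rows(removed),
                 converged = converged, n_iter = it),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_iter, " iteration(s), converged: ", x$converged, "\n", sep = "")
  cat("  final matrix: ", nrow(x$genotypes), " samples x ", ncol(x$genotypes), " SNPs\n", sep = "")
  print(x$steps, n = 30)
  invisible(x)
}

#' Ancestry outliers by multidimensional scaling of genomic kinship
#'
#' Estimates the genomic kinship matrix from standardised genotype dosages,
#' embeds samples with classical multidimensional scaling (2 coordinates),
#' and flags samples far from the main cluster. The main cluster is the set
#' of samples whose distance from the coordinate-wise medoid is within
#' Q3 + 3 IQR of the distance distribution; a sample is flagged when its
#' distance exceeds `(1 + cutoff)` times the cluster's maximal distance.
#' This is a configurable heuristic for relative-distance outlier flagging,
#' not a reproduction of any specific published metric.
#'
#' @param G Genotype matrix (samples x SNPs), ideally LD-pruned.
#' @param cutoff Relative-distance margin (default 0.11, i.e. 11% beyond the
#'   main-cluster span).
#' @param min_snps Minimum SNP count required (default 50).
#' @return Tibble: `individual_id`, `coord1`, `coord2`, `distance`,
#'   `relative_distance`, `flagged`.
#' @export
ancestry_outliers <- function(G, cutoff = 0.11, min_snps = 50L) {
  if (nrow(G) < 3) stop("need at least 3 samples")
  if (ncol(G) < min_snps) stop("need at least ", min_snps, " SNPs for ancestry inference")
  X <- G; storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / ncol(Z)
  d2 <- outer(diag(K), diag(K), "+") - 2 * K
  d2[d2 < 0] <- 0
  # near-duplicate samples would add a spurious embedding axis of their own;
  # embed unique representatives and give each twin its representative's spot
  dup_thr <- 0.05 * median(d2[upper.tri(d2)])
  rep_of <- seq_len(nrow(d2))
  for (i in seq_len(nrow(d2))[-1]) {
    twin <- which(d2[i, seq_len(i - 1)] < dup_thr)
    if (length(twin)) rep_of[i] <- rep_of[twin[1]]
  }
  uniq <- unique(rep_of)
  coords_u <- cmdscale(sqrt(d2[uniq, uniq, drop = FALSE]), k = 2)
  coords <- coords_u[match(rep_of, uniq), , drop = FALSE]
  centre <- apply(coords, 2, median)
  dist_c <- sqrt(rowSums(sweep(coords, 2, centre)^2))
  q3 <- quantile(dist_c, 0.75); iqr <- stats::IQR(dist_c)
  main <- dist_c <= q3 + 3 * iqr
  span <- max(dist_c[main])
  rel <- dist_c / span
  tibble::tibble(individual_id = rownames(G),
                 coord1 = coords[, 1], coord2 = coords[, 2],
                 distance = dist_c, relative_distance = rel,
                 flagged = rel > 1 + cutoff)
}

#' Squared genotype correlation between two SNPs
#'
#' @param g1,g2 Genotype dosage vectors.
#' @return Pearson r-squared over shared non-missing samples; `NA` when a
#'   genotype has zero variance (treated as independent by [ld_prune()]).
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("need at least 2 overlapping non-missing samples")
  v1 <- stats::var(g1[ok]); v2 <- stats::var(g2[ok])
  if (v1 == 0 || v2 == 0) return(NA_real_)
  cor(g1[ok], g2[ok])^2
}

#' Greedy LD pruning of ranked association results
#'
#' Walks the results in rank order (best first), keeps a SNP only when its
#' r-squared with every already-kept SNP is below `r2_max`, yielding
#' independent top regions. Undefined r-squared (zero-variance genotype) is
#' treated as independence.
#'
#' @param results Tibble with `snp_id` and a ranking column `p`.
#' @param G Genotype matrix whose columns cover `results$snp_id`.
#' @param r2_max Pruning threshold (default 0.80).
#' @param top_k Optional cap on the number of independent SNPs returned.
#' @return The kept rows of `results`, best first.
#' @export
ld_prune <- function(results, G, r2_max = 0.80, top_k = NULL) {
  stopifnot(all(results$snp_id %in% colnames(G)))
  res <- dplyr::arrange(tibble::as_tibble(results), .data$p)
  kept <- character(0)
  for (s in res$snp_id) {
    indep <- all(vapply(kept, function(k) {
      r2 <- ld_r2(G[, s], G[, k])
      is.na(r2) || r2 < r2_max
    }, logical(1)))
    if (indep) kept <- c(kept, s)
    if (!is.null(top_k) && length(kept) >= top_k) break
  }
  res[match(kept, res$snp_id), , drop = FALSE]
}

#' Sequential exclusion-ledger accounting
#'
#' Applies an ordered list of removal counts to an initial count, checking
#' that no intermediate count goes negative; each count applies to the
#' survivors of the previous step.
#'
#' @param initial Initial integer count.
#' @param removals Named or unnamed integer vector of per-step removals.
#' @param unit Label for the report (e.g. `"sample"`, `"snp"`).
#' @return List: `final` count and `report` tibble (step, n_removed,
#'   n_remaining).
#' @examples
#' qc_ledger(2163, c(failed_hybridisation = 253, low_call_rate = 55,
#'                   contaminated = 3, duplicates = 43, male = 4))$final  # 1805
#' @export
qc_ledger <- function(initial, removals, unit = "sample") {
  stopifnot(initial >= 0)
  if (any(removals < 0)) stop("removals must be non-negative")
  remaining <- initial - cumsum(as.integer(removals))
  if (any(remaining < 0)) stop("inconsistent ledger: intermediate count below zero")
  nm <- names(removals) %||% paste0("step", seq_along(removals))
  report <- tibble::tibble(step = nm, unit = unit,
                           n_removed = as.integer(removals),
                           n_remaining = as.integer(remaining))
  list(final = if (length(remaining)) remaining[length(remaining)] else as.integer(initial),
       report = report)
}
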