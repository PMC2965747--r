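#' Analysis run configuration
#'
#' Central container of every pipeline threshold, with defaults matching the
#' package's documented quality-control and analysis conventions: SNP and
#' sample call rate 0.95, MAF 0.01, HWE 1e-6 (initial) and 1e-7 (stringent
#' final pass), differential missingness 1e-3 (phenotype) and 1e-10
#' (neighbouring-SNP mode), IBS duplicate threshold 0.95, heterozygosity FDR
#' 0.001, MDS ancestry cutoff 0.11, LD pruning r-squared 0.80, gene window
#' 110 kb upstream / 40 kb downstream, enrichment percentile 95 with 10,000
#' random sets, IBD minimum segment 5 cM on a 2.5 cM grid, and censoring cap
#' 80 years.
#'
#' @param ... Overrides of any default (unknown names are an error).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    snp_call_rate = 0.95,
    sample_call_rate = 0.95,
    maf = 0.01,
    hwe_p = 1e-6,
    hwe_p_stringent = 1e-7,
    diff_miss_p = 1e-3,
    diff_miss_neighbor_p = 1e-10,
    ibs_dup = 0.95,
    het_fdr = 0.001,
    mds_cutoff = 0.11,
    ld_r2_max = 0.80,
    gsea_window_up = 110000,
    gsea_window_down = 40000,
    gsea_percentile = 95,
    gsea_n_random = 10000,
    ibd_min_cm = 5,
    ibd_grid_cm = 2.5,
    censor_cap = 80,
    top_k = 79,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

# internal self-test of the documented default values
config_self_test <- function(cfg = run_config()) {
  ref <- c(snp_call_rate = 0.95, sample_call_rate = 0.95, maf = 0.01,
           hwe_p = 1e-6, hwe_p_stringent = 1e-7, diff_miss_p = 1e-3,
           diff_miss_neighbor_p = 1e-10, ibs_dup = 0.95, het_fdr = 0.001,
           mds_cutoff = 0.11, ld_r2_max = 0.80, gsea_window_up = 110000,
           gsea_window_down = 40000, gsea_percentile = 95,
           gsea_n_random = 10000, ibd_min_cm = 5, ibd_grid_cm = 2.5,
           censor_cap = 80)
  all(vapply(names(ref), function(k) isTRUE(all.equal(cfg[[k]], unname(ref[k]))),
             logical(1)))
}

#' Run the two-stage modifier analysis pipeline
#'
#' End-to-end driver over in-memory objects: iterative QC on the stage-1
#' matrix, stratum assignment, pedigree kinship, kinship-adjusted genome
#' scan, selection of the top independent regions by LD pruning, per-SNP
#' hazard-ratio fits, and — when a stage-2 cohort is supplied — stage-2 and
#' combined-stage fits with a fixed-effect cross-check. Optional gene-set
#' enrichment runs when annotations and sets are given.
#'
#' @param stage1 List with `genotypes` (matrix), `carriers` (tibble with
#'   event history or censoring columns), and optionally `pedigree`.
#' @param incidence An [incidence_model()].
#' @param cfg A [run_config()].
#' @param stage2 Optional list like `stage1` for the replication cohort.
#' @param annotations,gene_sets Optional enrichment inputs
#'   (see [map_snps_to_genes()] and [gsea_p()]); `snp_meta` (tibble with
#'   `snp_id`, `chr`, `pos`) is required for enrichment.
#' @param snp_meta Optional SNP position table.
#' @param top_k Number of independent top regions to carry into stage 2
#'   (default from `cfg`).
#' @param verbose Log stage progress.
#' @return List: `qc`, `carriers`, `scan`, `top`, `fits` (stage-1 `hr_fit`s),
#'   `stage2_fits`, `combined_fits`, `meta`, `enrichment`, `ledger`.
#' @export
run_pipeline <- function(stage1, incidence, cfg = run_config(), stage2 = NULL,
                         annotations = NULL, gene_sets = NULL, snp_meta = NULL,
                         top_k = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  top_k <- top_k %||% cfg$top_k
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  ledger <- list()

  prep_stage <- function(stage, label) {
    carriers <- tibble::as_tibble(stage$carriers)
    if (!"censor_age" %in% names(carriers))
      carriers <- derive_time_at_risk(carriers, cap = cfg$censor_cap)
    st <- assign_strata(carriers)
    list(carriers = st$carriers, excluded = st$excluded)
  }

  say("stage 1 QC")
  qc <- iterative_qc(stage1$genotypes,
                     sample_call_rate = cfg$sample_call_rate,
                     het_fdr = cfg$het_fdr, ibs_dup = cfg$ibs_dup,
                     snp_call_rate = cfg$snp_call_rate, maf = cfg$maf,
                     hwe_p = cfg$hwe_p,
                     diff_miss_p = cfg$diff_miss_p,
                     phenotype = stage1$phenotype, batch = stage1$batch)
  G <- qc$genotypes
  ledger$qc_steps <- qc$steps

  s1 <- prep_stage(stage1, "stage1")
  carriers <- s1$carriers[s1$carriers$individual_id %in% rownames(G), , drop = FALSE]
  G <- G[carriers$individual_id, , drop = FALSE]
  ledger$carriers_analyzed <- nrow(carriers)

  K <- if (!is.null(stage1$pedigree))
    kinship_matrix(stage1$pedigree, carriers$individual_id) else NULL

  say("genome scan over ", ncol(G), " SNPs, ", nrow(carriers), " carriers")
  scan <- genome_scan(G, carriers, incidence, kinship = K, verbose = verbose)

  say("top-region selection")
  ok <- scan$results[scan$results$flag == "ok", , drop = FALSE]
  top <- ld_prune(ok, G, r2_max = cfg$ld_r2_max, top_k = top_k)

  fits <- purrr::map(top$snp_id, function(s)
    tryCatch(fit_hr(carriers, G[, s], incidence), error = function(e) NULL))
  names(fits) <- top$snp_id

  stage2_fits <- combined_fits <- meta <- NULL
  if (!is.null(stage2)) {
    say("stage 2 fits")
    s2 <- prep_stage(stage2, "stage2")
    c2 <- s2$carriers
    G2 <- stage2$genotypes[c2$individual_id, , drop = FALSE]
    shared <- intersect(top$snp_id, colnames(G2))
    stage2_fits <- purrr::map(shared, function(s)
      tryCatch(fit_hr(c2, G2[, s], incidence), error = function(e) NULL))
    names(stage2_fits) <- shared
    combined_fits <- purrr::map(shared, function(s)
      tryCatch(combined_stage_fit(carriers, G[, s], c2, G2[, s], incidence),
               error = function(e) NULL))
    names(combined_fits) <- shared
    meta <- purrr::map_dfr(shared, function(s) {
      f1 <- fits[[s]]; f2 <- stage2_fits[[s]]
      if (is.null(f1) || is.null(f2)) return(NULL)
      out <- meta_fixed_effect(c(f1$hr[1], f2$hr[1]),
                               c(f1$ci_lower[1], f2$ci_lower[1]),
                               c(f1$ci_upper[1], f2$ci_upper[1]))
      out$snp_id <- s
      out
    })
  }

  enrichment <- NULL
  if (!is.null(annotations) && !is.null(gene_sets) && length(gene_sets) &&
      !is.null(snp_meta)) {
    say("gene-set enrichment")
    assn <- map_snps_to_genes(snp_meta[snp_meta$snp_id %in% ok$snp_id, ],
                              annotations,
                              up = cfg$gsea_window_up, down = cfg$gsea_window_down)
    scores <- gene_scores(assn, ok[, c("snp_id", "p")], G = G)
    enrichment <- purrr::imap_dfr(gene_sets, function(genes, nm) {
      out <- gsea_p(genes, scores, percentile = cfg$gsea_percentile,
                    n_random = cfg$gsea_n_random, seed = cfg$seed)
      out$set <- nm
      out
    })
  } else if (!is.null(annotations) && (is.null(gene_sets) || !length(gene_sets))) {
    warning("empty gene-set input: enrichment stage skipped")
  }

  list(qc = qc, carriers = carriers, scan = scan, top = top, fits = fits,
       stage2_fits = stage2_fits, combined_fits = combined_fits, meta = meta,
       enrichment = enrichment, ledger = ledger)
}
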