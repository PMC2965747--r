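#' Genetic map with linear interpolation
#'
#' Stores per-chromosome anchors of physical (bp) against genetic (cM)
#' position, both strictly increasing, and interpolates linearly between
#' anchors. Positions outside the anchored range are clamped to the ends
#' with a warning (no extrapolation).
#'
#' @param map Tibble with `chr`, `bp`, `cM`.
#' @return Object of class `genetic_map`.
#' @export
genetic_map <- function(map) {
  m <- tibble::as_tibble(map)
  stopifnot(all(c("chr", "bp", "cM") %in% names(m)))
  m <- dplyr::arrange(m, .data$chr, .data$bp)
  bad <- m |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(ok = all(diff(.data$bp) > 0) && all(diff(.data$cM) > 0),
                     .groups = "drop")
  if (!all(bad$ok)) stop("map positions must be strictly increasing in bp and cM")
  structure(list(map = m), class = "genetic_map")
}

#' Interpolate genetic positions
#'
#' @param gm A [genetic_map()].
#' @param chr Chromosome labels.
#' @param bp Physical positions.
#' @return Genetic positions in cM.
#' @export
interpolate_cm <- function(gm, chr, bp) {
  stopifnot(inherits(gm, "genetic_map"))
  out <- rep(NA_real_, length(bp))
  clamped <- FALSE
  for (c_ in unique(chr)) {
    anch <- gm$map[gm$map$chr == c_, , drop = FALSE]
    ii <- which(chr == c_)
    if (nrow(anch) < 2) stop("unmapped chromosome or fewer than 2 anchors: ", c_)
    b <- bp[ii]
    if (any(b < min(anch$bp) | b > max(anch$bp))) clamped <- TRUE
    out[ii] <- stats::approx(anch$bp, anch$cM, xout = b, rule = 2)$y
  }
  if (clamped) warning("positions outside the map range were clamped to the ends")
  out
}

#' Read a genetic map text file
#'
#' Whitespace-separated columns: chromosome, bp position, cM position.
#'
#' @param path File path. A header line is auto-detected.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  header <- any(is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]][-1]))))
  x <- read.table(path, header = header, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chr", "bp", "cM")
  genetic_map(tibble::tibble(chr = as.character(x$chr), bp = x$bp, cM = x$cM))
}

# windowed hashing over haplotype alleles: returns per-pair matched window
# index sets; H is markers x samples (0/1 alleles)
seed_windows <- function(H, window) {
  m <- nrow(H)
  # half-overlapping windows so any run >= 1.5*window markers contains one
  starts <- unique(pmin(seq(1L, max(m - window + 1L, 1L), by = max(window %/% 2L, 1L)),
                        max(m - window + 1L, 1L)))
  pair_windows <- list()
  for (s in starts) {
    rows <- s:min(s + window - 1L, m)
    words <- apply(H[rows, , drop = FALSE], 2, paste0, collapse = "")
    grp <- split(seq_along(words), words)
    for (g in grp) {
      if (length(g) < 2) next
      prs <- utils::combn(g, 2)
      for (k in seq_len(ncol(prs))) {
        key <- paste(prs[1, k], prs[2, k], sep = "|")
        pair_windows[[key]] <- c(pair_windows[[key]], s)
      }
    }
  }
  pair_windows
}

#' Detect long shared segments between sample pairs
#'
#' GERMLINE-style windowed hashing for phased haplotypes: fixed-size marker
#' windows are hashed to find pairs with exact allele-word matches, runs of
#' consecutive matched windows become seeds, and seeds are extended marker by
#' marker in both directions with a mismatch budget (1 per 100 markers by
#' default). For unphased genotypes (`mode = "genotype"`), segments are
#' maximal runs without opposite homozygotes, under the same mismatch
#' budget. Segments of genetic length at least `min_cm` are reported.
#'
#' @param X Marker matrix, markers in rows sorted by position, samples in
#'   columns: alleles 0/1 for `mode = "haplotype"`, dosages 0/1/2 for
#'   `mode = "genotype"`.
#' @param markers Tibble with `chr`, `bp` per row of `X`, sorted by position
#'   within chromosome.
#' @param gm A [genetic_map()] covering the markers.
#' @param min_cm Minimum segment length in cM (default 5).
#' @param mode `"haplotype"` or `"genotype"`.
#' @param window Window size in markers for seed hashing (default 64).
#' @param mismatch_per_100 Extension mismatch budget per 100 markers.
#' @return Tibble of segments: `id1`, `id2`, `chr`, `start_bp`, `end_bp`,
#'   `start_cm`, `end_cm`, `length_cm`.
#' @export
detect_segments <- function(X, markers, gm, min_cm = 5.0,
                            mode = c("haplotype", "genotype"),
                            window = 64L, mismatch_per_100 = 1) {
  mode <- match.arg(mode)
  mk <- tibble::as_tibble(markers)
  stopifnot(nrow(mk) == nrow(X), all(c("chr", "bp") %in% names(mk)))
  out <- list()
  for (c_ in unique(mk$chr)) {
    rows <- which(mk$chr == c_)
    if (is.unsorted(mk$bp[rows], strictly = FALSE)) stop("markers must be sorted by position")
    cm <- interpolate_cm(gm, mk$chr[rows], mk$bp[rows])
    Xc <- X[rows, , drop = FALSE]
    segs <- if (mode == "haplotype")
      segments_haplotype(Xc, window, mismatch_per_100)
    else
      segments_genotype(Xc, mismatch_per_100)
    if (!nrow(segs)) next
    segs$chr <- c_
    segs$start_bp <- mk$bp[rows][segs$from]
    segs$end_bp <- mk$bp[rows][segs$to]
    segs$start_cm <- cm[segs$from]
    segs$end_cm <- cm[segs$to]
    segs$length_cm <- segs$end_cm - segs$start_cm
    out[[length(out) + 1]] <- segs[segs$length_cm >= min_cm, , drop = FALSE]
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res))
    return(tibble::tibble(id1 = character(), id2 = character(), chr = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          start_cm = numeric(), end_cm = numeric(),
                          length_cm = numeric()))
  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  tibble::tibble(id1 = ids[res$i1], id2 = ids[res$i2], chr = res$chr,
                 start_bp = res$start_bp, end_bp = res$end_bp,
                 start_cm = res$start_cm, end_cm = res$end_cm,
                 length_cm = res$length_cm)
}

segments_haplotype <- function(H, window, mismatch_per_100) {
  m <- nrow(H)
  win <- min(window, max(m %/% 2, 1L))
  pw <- seed_windows(H, win)
  res <- list()
  for (key in names(pw)) {
    pr <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    ws <- sort(pw[[key]])
    # merge overlapping/adjacent seed windows into runs of matched markers
    run_id <- cumsum(c(1, diff(ws) > win))
    for (r in split(ws, run_id)) {
      from <- min(r)
      to <- min(max(r) + win - 1L, m)
      ext <- extend_match(H[, pr[1]] == H[, pr[2]], from, to,
                          budget_per_100 = mismatch_per_100)
      res[[length(res) + 1]] <- tibble::tibble(i1 = pr[1], i2 = pr[2],
                                               from = ext[1], to = ext[2])
    }
  }
  segs <- dplyr::bind_rows(res)
  if (!nrow(segs)) return(tibble::tibble(i1 = integer(), i2 = integer(),
                                         from = integer(), to = integer()))
  # a pair's overlapping extended runs collapse to their union
  segs |>
    dplyr::group_by(.data$i1, .data$i2) |>
    dplyr::arrange(.data$from, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(dplyr::lag(cummax(.data$to), default = 0L) < .data$from)) |>
    dplyr::group_by(.data$i1, .data$i2, .data$grp) |>
    dplyr::summarise(from = min(.data$from), to = max(.data$to), .groups = "drop") |>
    dplyr::select(-"grp")
}

# extend a seeded interval outward while the running mismatch count stays
# within budget (1 per 100 markers of current segment length)
extend_match <- function(match_vec, from, to, budget_per_100 = 1) {
  m <- length(match_vec)
  mism <- sum(!match_vec[from:to])
  repeat {
    len <- to - from + 1
    budget <- floor(len / 100) * budget_per_100 + budget_per_100
    moved <- FALSE
    if (from > 1 && (match_vec[from - 1] || mism < budget)) {
      from <- from - 1; mism <- mism + !match_vec[from]; moved <- TRUE
    }
    if (to < m && (match_vec[to + 1] || mism < budget)) {
      to <- to + 1; mism <- mism + !match_vec[to]; moved <- TRUE
    }
    if (!moved) break
  }
  # anchor the ends: shrink until the terminal `anchor` markers match cleanly,
  # so budgeted mismatches cannot drift an endpoint past the true boundary
  anchor <- 12L
  repeat {
    if (to - from + 1 < anchor) break
    if (all(match_vec[from:(from + anchor - 1)])) break
    from <- from + 1
  }
  repeat {
    if (to - from + 1 < anchor) break
    if (all(match_vec[(to - anchor + 1):to])) break
    to <- to - 1
  }
  while (to >= from && !match_vec[from]) from <- from + 1
  while (to >= from && !match_vec[to]) to <- to - 1
  c(from, to)
}

segments_genotype <- function(Gc, mismatch_per_100) {
  n <- ncol(Gc)
  res <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- Gc[, i]; b <- Gc[, j]
    compat <- !(abs(a - b) == 2)          # opposite homozygotes break a match
    compat[is.na(compat)] <- TRUE         # missing calls do not break
    runs <- mismatch_runs(compat, mismatch_per_100)
    if (nrow(runs)) {
      runs$i1 <- i; runs$i2 <- j
      res[[length(res) + 1]] <- runs
    }
  }
  if (!length(res)) return(tibble::tibble(i1 = integer(), i2 = integer(),
                                          from = integer(), to = integer()))
  dplyr::bind_rows(res)
}

# maximal runs of TRUE allowing a budget of isolated FALSE positions
mismatch_runs <- function(compat, budget_per_100) {
  m <- length(compat)
  runs <- list()
  i <- 1
  while (i <= m) {
    if (!compat[i]) { i <- i + 1; next }
    j <- i; mism <- 0
    k <- j + 1
    while (k <= m) {
      if (compat[k]) { j <- k; k <- k + 1; next }
      allowed <- floor((k - i + 1) / 100) * budget_per_100 + budget_per_100
      if (mism + 1 <= allowed && k < m && any(compat[pmin(k + 1, m):pmin(k + 5, m)])) {
        mism <- mism + 1; k <- k + 1
      } else break
    }
    runs[[length(runs) + 1]] <- tibble::tibble(from = i, to = j)
    i <- k + 1
  }
  dplyr::bind_rows(runs)
}

#' Pair-sharing profile on a genetic-position grid
#'
#' For every grid site (every `grid_cm` cM along each chromosome's mapped
#' range, excluding masked intervals), counts the sample pairs whose detected
#' segment spans the site, and reports the proportion out of all possible
#' pairs.
#'
#' @param segments Output of [detect_segments()].
#' @param gm A [genetic_map()] defining per-chromosome cM ranges.
#' @param n_samples Total number of samples (defines the pair denominator).
#' @param grid_cm Grid step in cM (default 2.5).
#' @param mask Optional tibble of excluded intervals: `chr`, `start_cm`,
#'   `end_cm` (telomere/centromere regions).
#' @return List: `profile` tibble (`chr`, `cm`, `n_pairs`, `proportion`) and
#'   `summary` (mean/sd/max of counts across sites).
#' @export
sharing_profile <- function(segments, gm, n_samples, grid_cm = 2.5, mask = NULL) {
  if (grid_cm <= 0) stop("grid step must be positive")
  total_pairs <- n_samples * (n_samples - 1) / 2
  grids <- gm$map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(lo = min(.data$cM), hi = max(.data$cM), .groups = "drop")
  profile <- purrr::pmap_dfr(grids, function(chr, lo, hi) {
    tibble::tibble(chr = chr, cm = seq(lo, hi, by = grid_cm))
  })
  if (!is.null(mask) && nrow(mask)) {
    m <- tibble::as_tibble(mask)
    keep <- !purrr::map_lgl(seq_len(nrow(profile)), function(i) {
      any(m$chr == profile$chr[i] & m$start_cm <= profile$cm[i] &
            m$end_cm >= profile$cm[i])
    })
    profile <- profile[keep, , drop = FALSE]
  }
  segs <- tibble::as_tibble(segments)
  profile$n_pairs <- purrr::map_int(seq_len(nrow(profile)), function(i) {
    sum(segs$chr == profile$chr[i] & segs$start_cm <= profile$cm[i] &
          segs$end_cm >= profile$cm[i])
  })
  profile$proportion <- profile$n_pairs / max(total_pairs, 1)
  list(profile = profile,
       summary = tibble::tibble(mean = mean(profile$n_pairs),
                                sd = sd(profile$n_pairs),
                                max = max(profile$n_pairs),
                                mean_proportion = mean(profile$proportion)))
}

#' Compare sharing between two groups and against a target locus
#'
#' Computes the per-site difference in pair-sharing proportion between two
#' groups on the same grid, with a permutation p-value obtained by permuting
#' sample group labels and re-deriving pair groups, and contrasts the sharing
#' at a target locus against the genome-wide distribution (empirical
#' percentile).
#'
#' @param segments Segment tibble for all samples pooled.
#' @param groups Named character vector: sample id -> group (two groups).
#' @param gm A [genetic_map()].
#' @param target Optional list `list(chr =, cm =)` naming the locus of
#'   interest.
#' @param grid_cm Grid step (default 2.5).
#' @param n_perm Label permutations (default 200).
#' @param mask Optional mask as in [sharing_profile()].
#' @return List: `sites` (per-site proportions by group, difference, and
#'   permutation p), `target` (row with the target site's sharing and its
#'   genome-wide percentile per group, when `target` given).
#' @export
group_excess_sharing <- function(segments, groups, gm, target = NULL,
                                 grid_cm = 2.5, n_perm = 200, mask = NULL) {
  segs <- tibble::as_tibble(segments)
  grp_levels <- sort(unique(groups))
  if (length(grp_levels) != 2) stop("exactly two groups required")
  ids <- names(groups)

  pair_profile <- function(glab) {
    in_g <- ids[groups == glab]
    n_g <- length(in_g)
    sub <- segs[segs$id1 %in% in_g & segs$id2 %in% in_g, , drop = FALSE]
    sharing_profile(sub, gm, n_g, grid_cm = grid_cm, mask = mask)$profile
  }
  p1 <- pair_profile(grp_levels[1])
  p2 <- pair_profile(grp_levels[2])
  stopifnot(nrow(p1) == nrow(p2))
  diff_obs <- p1$proportion - p2$proportion

  perm_diffs <- matrix(NA_real_, n_perm, nrow(p1))
  for (b in seq_len(n_perm)) {
    gp <- setNames(sample(unname(groups)), ids)
    in1 <- ids[gp == grp_levels[1]]; in2 <- ids[gp == grp_levels[2]]
    s1 <- segs[segs$id1 %in% in1 & segs$id2 %in% in1, , drop = FALSE]
    s2 <- segs[segs$id1 %in% in2 & segs$id2 %in% in2, , drop = FALSE]
    q1 <- sharing_profile(s1, gm, length(in1), grid_cm, mask)$profile$proportion
    q2 <- sharing_profile(s2, gm, length(in2), grid_cm, mask)$profile$proportion
    perm_diffs[b, ] <- q1 - q2
  }
  p_site <- vapply(seq_len(nrow(p1)), function(i)
    (1 + sum(abs(perm_diffs[, i]) >= abs(diff_obs[i]))) / (1 + n_perm), numeric(1))

  sites <- tibble::tibble(chr = p1$chr, cm = p1$cm,
                          prop_1 = p1$proportion, prop_2 = p2$proportion,
                          diff = diff_obs, perm_p = p_site)
  names(sites)[3:4] <- paste0("prop_", grp_levels)

  target_row <- NULL
  if (!is.null(target)) {
    i <- which(p1$chr == target$chr)[which.min(abs(p1$cm[p1$chr == target$chr] - target$cm))]
    target_row <- tibble::tibble(
      chr = p1$chr[i], cm = p1$cm[i],
      prop_1 = p1$proportion[i], prop_2 = p2$proportion[i],
      percentile_1 = mean(p1$proportion <= p1$proportion[i]),
      percentile_2 = mean(p2$proportion <= p2$proportion[i]))
    names(target_row)[3:6] <- c(paste0("prop_", grp_levels),
                                paste0("percentile_", grp_levels))
  }
  list(sites = sites, target = target_row)
}
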