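# even 1 cM / 1 Mb map over one chromosome
flat_map <- function(chr = "1", len_cm = 40, bp_per_cm = 1e6) {
  genetic_map(tibble::tibble(chr = chr,
                             bp = c(1, len_cm * bp_per_cm),
                             cM = c(0, len_cm)))
}

random_markers <- function(n, len_cm = 40, bp_per_cm = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(chr = "1", bp = sort(sample.int(len_cm * bp_per_cm - 2, n)) + 1)
}

test_that("genetic-map interpolation matches the piecewise-linear oracle", {
  gm <- genetic_map(tibble::tibble(chr = "1",
                                   bp = c(1e5, 5e5, 2e6, 7e6),
                                   cM = c(0, 1.5, 4, 11)))
  bp <- c(1e5, 3e5, 2e6, 4.3e6)
  got <- interpolate_cm(gm, rep("1", 4), bp)
  want <- stats::approx(c(1e5, 5e5, 2e6, 7e6), c(0, 1.5, 4, 11), xout = bp)$y
  expect_equal(got, want, tolerance = 1e-9)
  expect_warning(interpolate_cm(gm, "1", 9e6), "clamped")
  expect_error(genetic_map(tibble::tibble(chr = "1", bp = c(2, 1), cM = c(0, 1))),
               "increasing")
})

test_that("identical haplotypes share one full-chromosome segment", {
  set.seed(91)
  mk <- random_markers(300)
  gm <- flat_map()
  h <- rbinom(300, 1, 0.5)
  X <- cbind(a = h, b = h)
  segs <- detect_segments(X, mk, gm, min_cm = 5)
  expect_equal(nrow(segs), 1)
  expect_gt(segs$length_cm, 25)
  expect_setequal(c(segs$id1, segs$id2), c("a", "b"))
})

test_that("a planted 8 cM segment is recovered within half a centimorgan", {
  set.seed(92)
  n_mark <- 500
  mk <- random_markers(n_mark, len_cm = 40)
  gm <- flat_map()
  cm <- interpolate_cm(gm, mk$chr, mk$bp)
  maf <- runif(n_mark, 0.1, 0.5)
  h1 <- rbinom(n_mark, 1, maf)
  h2 <- rbinom(n_mark, 1, maf)
  lo_cm <- 16; hi_cm <- 24
  span <- cm >= lo_cm & cm <= hi_cm
  h2[span] <- h1[span]
  X <- cbind(s1 = h1, s2 = h2)
  segs <- detect_segments(X, mk, gm, min_cm = 5)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$start_cm - lo_cm), 0.5)
  expect_lt(abs(segs$end_cm - hi_cm), 0.5)
})

test_that("unrelated haplotype pairs rarely produce long segments", {
  set.seed(93)
  n_false <- 0
  for (r in 1:60) {
    mk <- random_markers(1000)
    gm <- flat_map()
    maf <- runif(1000, 0.1, 0.5)
    X <- cbind(a = rbinom(1000, 1, maf), b = rbinom(1000, 1, maf))
    if (nrow(detect_segments(X, mk, gm, min_cm = 5)) > 0) n_false <- n_false + 1
  }
  expect_lte(n_false / 60, 0.01 + 0.05)  # >= 99% clean with slack for 60 reps
})

test_that("raising the length threshold never yields more segments", {
  set.seed(94)
  mk <- random_markers(600)
  gm <- flat_map()
  maf <- runif(600, 0.1, 0.5)
  cm <- interpolate_cm(gm, mk$chr, mk$bp)
  h1 <- rbinom(600, 1, maf); h2 <- rbinom(600, 1, maf); h3 <- rbinom(600, 1, maf)
  h2[cm >= 5 & cm <= 13] <- h1[cm >= 5 & cm <= 13]
  h3[cm >= 20 & cm <= 26] <- h1[cm >= 20 & cm <= 26]
  X <- cbind(a = h1, b = h2, c = h3)
  counts <- vapply(c(2, 5, 7, 10), function(mc)
    nrow(detect_segments(X, mk, gm, min_cm = mc)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segment detection is symmetric and order-invariant", {
  set.seed(95)
  mk <- random_markers(400)
  gm <- flat_map()
  maf <- runif(400, 0.1, 0.5)
  cm <- interpolate_cm(gm, mk$chr, mk$bp)
  h1 <- rbinom(400, 1, maf); h2 <- rbinom(400, 1, maf)
  h2[cm >= 10 & cm <= 20] <- h1[cm >= 10 & cm <= 20]
  X <- cbind(a = h1, b = h2, c = rbinom(400, 1, maf))
  s1 <- detect_segments(X, mk, gm, min_cm = 5)
  s2 <- detect_segments(X[, c("c", "b", "a")], mk, gm, min_cm = 5)
  key <- function(s) paste(pmin(s$id1, s$id2), pmax(s$id1, s$id2),
                           round(s$start_cm, 6), round(s$end_cm, 6))
  expect_setequal(key(s1), key(s2))
})

test_that("genotype mode breaks segments at opposite homozygotes", {
  set.seed(96)
  mk <- random_markers(400)
  gm <- flat_map()
  g1 <- rbinom(400, 2, 0.4)
  g2 <- g1
  # an opposite-homozygote wall in the middle of the chromosome
  mid <- 195:205
  g1[mid] <- 0L; g2[mid] <- 2L
  X <- cbind(a = g1, b = g2)
  segs <- detect_segments(X, mk, gm, min_cm = 5, mode = "genotype")
  expect_gte(nrow(segs), 2)
  cm_mid <- interpolate_cm(gm, "1", mk$bp[200])
  expect_false(any(segs$start_cm < cm_mid & segs$end_cm > cm_mid))
})

test_that("sharing profiles count spanning pairs and match the stabbing oracle", {
  gm <- flat_map(len_cm = 30)
  one <- tibble::tibble(id1 = "a", id2 = "b", chr = "1",
                        start_bp = 1, end_bp = 30e6,
                        start_cm = 0, end_cm = 30, length_cm = 30)
  prof <- sharing_profile(one, gm, n_samples = 2, grid_cm = 2.5)
  expect_true(all(prof$profile$n_pairs == 1))
  expect_equal(prof$summary$max, 1)

  empty <- one[0, ]
  prof0 <- sharing_profile(empty, gm, n_samples = 5)
  expect_true(all(prof0$profile$n_pairs == 0))
  expect_equal(prof0$summary$mean, 0)
  expect_error(sharing_profile(one, gm, 2, grid_cm = 0), "positive")

  set.seed(97)
  segs <- tibble::tibble(
    id1 = sample(letters, 40, replace = TRUE), id2 = "zz", chr = "1",
    start_cm = runif(40, 0, 25))
  segs$end_cm <- segs$start_cm + runif(40, 1, 5)
  segs$start_bp <- segs$start_cm * 1e6; segs$end_bp <- segs$end_cm * 1e6
  segs$length_cm <- segs$end_cm - segs$start_cm
  prof2 <- sharing_profile(segs, gm, n_samples = 27, grid_cm = 2.5)
  oracle <- vapply(prof2$profile$cm, function(x)
    sum(segs$start_cm <= x & segs$end_cm >= x), numeric(1))
  expect_equal(prof2$profile$n_pairs, as.integer(oracle))

  # masked sites drop out of the grid
  masked <- sharing_profile(one, gm, 2, grid_cm = 2.5,
                            mask = tibble::tibble(chr = "1", start_cm = 0,
                                                  end_cm = 5))
  expect_true(all(masked$profile$cm > 5))
})

test_that("identical groups show no excess sharing; founder cohorts do", {
  set.seed(98)
  gm <- flat_map(len_cm = 40)
  ids <- sprintf("s%02d", 1:16)
  # duplicated sharing structure: the same segments in both label groups
  make_segs <- function(members) {
    prs <- t(utils::combn(members, 2))
    keep <- runif(nrow(prs)) < 0.3
    tibble::tibble(id1 = prs[keep, 1], id2 = prs[keep, 2], chr = "1",
                   start_cm = 10, end_cm = 18,
                   start_bp = 10e6, end_bp = 18e6, length_cm = 8)
  }
  segs_a <- make_segs(ids[1:8])
  segs_b <- segs_a
  segs_b$id1 <- sub("s0?", "t", segs_a$id1); segs_b$id2 <- sub("s0?", "t", segs_a$id2)
  ids_b <- unique(c(segs_b$id1, segs_b$id2, sprintf("t%d", 1:8)))
  groups <- c(setNames(rep("A", 8), ids[1:8]),
              setNames(rep("B", length(ids_b)), ids_b))
  # keep groups the same size: trim B to 8
  ids_b <- sort(unique(c(sub("s0?", "t", ids[1:8]))))
  groups <- c(setNames(rep("A", 8), ids[1:8]), setNames(rep("B", 8), ids_b))
  res <- group_excess_sharing(dplyr::bind_rows(segs_a, segs_b), groups, gm,
                              n_perm = 50)
  expect_true(all(abs(res$sites$diff) < 1e-12))

  # planted founder haplotype at a target locus: sharing there tops the genome
  founder_segs <- tibble::tibble(
    id1 = rep(ids[1:6], each = 2), id2 = rep(ids[7:8], 6), chr = "1",
    start_cm = 19, end_cm = 26, start_bp = 19e6, end_bp = 26e6, length_cm = 7)
  prof <- sharing_profile(founder_segs, gm, n_samples = 16, grid_cm = 2.5)$profile
  target <- prof$proportion[which.min(abs(prof$cm - 22.5))]
  expect_gte(mean(prof$proportion <= target), 0.9)
})
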