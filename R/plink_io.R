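#' Read PLINK genotype files
#'
#' Reads either text (`.ped`/`.map`) or binary (`.bed`/`.bim`/`.fam`)
#' PLINK filesets into the package's internal representation: an integer
#' genotype matrix (samples x SNPs, values = count of the second allele,
#' `NA` = missing) plus SNP and sample metadata. `.map`/`.bim` positions are
#' 1-based. The two encodings of the same data load identically.
#'
#' @param prefix Path prefix (without extension).
#' @param format `"auto"` (default; prefers binary when present), `"ped"`,
#'   or `"bed"`.
#' @return List: `genotypes` (matrix), `snps` (tibble: `snp_id`, `chr`,
#'   `cm`, `pos`, `a1`, `a2`), `fam` (tibble: `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype`).
#' @export
read_plink <- function(prefix, format = c("auto", "ped", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (file.exists(paste0(prefix, ".bed"))) "bed" else "ped"
  if (format == "ped") read_plink_ped(prefix) else read_plink_bed(prefix)
}

read_map_or_bim <- function(path, has_alleles) {
  x <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (has_alleles && ncol(x) < 6) stop("malformed .bim file: ", path)
  if (!has_alleles && ncol(x) < 4) stop("malformed .map file: ", path)
  tibble::tibble(snp_id = x[[2]], chr = x[[1]], cm = as.numeric(x[[3]]),
                 pos = as.integer(x[[4]]),
                 a1 = if (has_alleles) x[[5]] else NA_character_,
                 a2 = if (has_alleles) x[[6]] else NA_character_)
}

read_fam_fields <- function(x) {
  tibble::tibble(family_id = x[[1]], individual_id = x[[2]],
                 father_id = x[[3]], mother_id = x[[4]],
                 sex = x[[5]], phenotype = x[[6]])
}

read_plink_ped <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path)) if (!file.exists(p)) stop("missing file: ", p)
  snps <- read_map_or_bim(map_path, has_alleles = FALSE)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  m <- nrow(snps)
  want <- 6 + 2 * m
  if (any(lengths(fields) != want))
    stop("malformed .ped: expected ", want, " fields per line in ", ped_path)
  fam <- read_fam_fields(as.data.frame(
    lapply(1:6, function(j) vapply(fields, `[[`, character(1), j))))
  allele_mat <- do.call(rbind, lapply(fields, function(f) f[-(1:6)]))
  a_first <- allele_mat[, seq(1, 2 * m, by = 2), drop = FALSE]
  a_second <- allele_mat[, seq(2, 2 * m, by = 2), drop = FALSE]
  G <- matrix(NA_integer_, length(fields), m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    als <- c(a_first[, j], a_second[, j])
    obs <- setdiff(sort(unique(als)), "0")
    if (length(obs) > 2) stop("SNP ", snps$snp_id[j], " has more than two alleles")
    a1[j] <- if (length(obs) >= 1) obs[1] else "A"
    a2[j] <- if (length(obs) == 2) obs[2] else "B"
    miss <- a_first[, j] == "0" | a_second[, j] == "0"
    G[, j] <- (a_first[, j] == a2[j]) + (a_second[, j] == a2[j])
    G[miss, j] <- NA_integer_
  }
  snps$a1 <- a1; snps$a2 <- a2
  dimnames(G) <- list(fam$individual_id, snps$snp_id)
  list(genotypes = G, snps = snps, fam = fam)
}

read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); famf <- paste0(prefix, ".fam")
  for (p in c(bed, bim, famf)) if (!file.exists(p)) stop("missing file: ", p)
  snps <- read_map_or_bim(bim, has_alleles = TRUE)
  famx <- read.table(famf, header = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character")
  fam <- read_fam_fields(famx)
  n <- nrow(fam); m <- nrow(snps)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed magic bytes in ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported: ", bed)
  bps <- ceiling(n / 4)
  if (length(raw) - 3 != bps * m)
    stop("dimension mismatch: ", bed, " holds ", length(raw) - 3,
         " data bytes but .bim/.fam imply ", bps * m)
  body <- raw[-(1:3)]
  # decode 2-bit codes: 00 -> 0 (hom a1), 10 -> 1 (het), 11 -> 2 (hom a2), 01 -> NA
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 8, 2), , drop = FALSE] + 2 * bits[seq(2, 8, 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4 * bps)[seq_len(n), , drop = FALSE]
  lookup <- c(0L, NA_integer_, 1L, 2L)
  G <- matrix(lookup[codes + 1L], n, m)
  dimnames(G) <- list(fam$individual_id, snps$snp_id)
  list(genotypes = G, snps = snps, fam = fam)
}

#' Write PLINK genotype files
#'
#' Writes the internal representation (see [read_plink()]) as `.ped`/`.map`
#' text or `.bed`/`.bim`/`.fam` binary. Round-trips are lossless for hard
#' calls and missing codes.
#'
#' @param G Integer genotype matrix (samples x SNPs; count of allele `a2`).
#' @param prefix Output path prefix.
#' @param snps Optional SNP tibble (`snp_id`, `chr`, `cm`, `pos`, `a1`,
#'   `a2`); defaults built from column names.
#' @param fam Optional sample tibble; defaults built from row names.
#' @param format `"ped"` (default) or `"bed"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix, snps = NULL, fam = NULL,
                        format = c("ped", "bed")) {
  format <- match.arg(format)
  n <- nrow(G); m <- ncol(G)
  if (is.null(snps))
    snps <- tibble::tibble(snp_id = colnames(G) %||% sprintf("snp%d", 1:m),
                           chr = "1", cm = 0, pos = seq_len(m),
                           a1 = "A", a2 = "B")
  if (is.null(fam))
    fam <- tibble::tibble(family_id = rownames(G) %||% sprintf("s%d", 1:n),
                          individual_id = rownames(G) %||% sprintf("s%d", 1:n),
                          father_id = "0", mother_id = "0", sex = "0",
                          phenotype = "-9")
  stopifnot(nrow(snps) == m, nrow(fam) == n)
  if (format == "ped") {
    write.table(data.frame(snps$chr, snps$snp_id, snps$cm, snps$pos),
                paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    al <- matrix("0", n, 2 * m)
    for (j in seq_len(m)) {
      g <- G[, j]
      al[, 2 * j - 1] <- ifelse(is.na(g), "0", ifelse(g >= 1, snps$a2[j], snps$a1[j]))
      al[, 2 * j] <- ifelse(is.na(g), "0", ifelse(g == 2, snps$a2[j], snps$a1[j]))
    }
    ped <- cbind(fam$family_id, fam$individual_id, fam$father_id,
                 fam$mother_id, fam$sex, fam$phenotype, al)
    write.table(ped, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(data.frame(snps$chr, snps$snp_id, snps$cm, snps$pos,
                           snps$a1, snps$a2),
                paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    write.table(data.frame(fam$family_id, fam$individual_id, fam$father_id,
                           fam$mother_id, fam$sex, fam$phenotype),
                paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    code_of <- c(`0` = 0L, `1` = 2L, `2` = 3L)   # NA -> 1
    bps <- ceiling(n / 4)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    pad <- 4 * bps - n
    for (j in seq_len(m)) {
      g <- G[, j]
      codes <- ifelse(is.na(g), 1L, code_of[as.character(g)])
      codes <- c(codes, rep(0L, pad))
      b1 <- codes %% 2L; b2 <- codes %/% 2L
      bits_full <- as.vector(rbind(b1, b2))
      bytes <- packBits(as.logical(bits_full), type = "raw")
      writeBin(bytes, con)
    }
  }
  invisible(prefix)
}

#' Write the pedigree/phenotype table
#'
#' Tab-separated with header; empty field = absent value. Columns:
#' `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`, `country`,
#' `delT`, `breast_dx_age`, `ovarian_dx_age`, `bpm_age`, `last_obs_age`,
#' `birth_year`.
#'
#' @param x Data frame holding (a subset of) those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(x, path) {
  cols <- c("family_id", "individual_id", "father_id", "mother_id", "sex",
            "country", "delT", "breast_dx_age", "ovarian_dx_age", "bpm_age",
            "last_obs_age", "birth_year")
  out <- tibble::as_tibble(x)
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  write.table(out[cols], path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read the pedigree/phenotype table
#'
#' @param path Path written by [write_phenotype_table()] (or hand-made with
#'   the same header).
#' @return Tibble with typed columns; empty fields become `NA`.
#' @export
read_phenotype_table <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  x <- tibble::as_tibble(x)
  if ("delT" %in% names(x)) x$delT <- as.logical(x$delT)
  x
}
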