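#' Assign carriers to analysis strata
#'
#' Builds the stratum key used throughout association testing and hazard
#' ratio estimation: country of study crossed with founder-mutation carrier
#' status (and, for combined two-stage analyses, the stage). Carriers missing
#' a stratification field are flagged and excluded with a logged reason.
#' Strata smaller than `min_size` are merged into a country-level `"rest"`
#' stratum with a warning, mirroring the exclusion of countries with
#' insufficient numbers in replication genotyping.
#'
#' @param carriers Data frame with columns `individual_id`, `country`,
#'   `delT` (logical founder-mutation flag) and, when `by_stage = TRUE`,
#'   `stage`.
#' @param by_stage Append the stage label to the stratum key (combined
#'   two-stage analyses are additionally stratified by stage).
#' @param min_size Minimum carriers per stratum before merging (default 2).
#' @return A list with `carriers` (input rows that could be assigned, plus a
#'   `stratum` column), `excluded` (rows lacking a stratification field, with
#'   `reason`), and `summary` (tibble of stratum sizes).
#' @export
assign_strata <- function(carriers, by_stage = FALSE, min_size = 2) {
  stopifnot(is.data.frame(carriers))
  x <- tibble::as_tibble(carriers)
  need <- c("country", "delT")
  if (by_stage) need <- c(need, "stage")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("carriers are missing stratification columns: ",
         paste(missing_cols, collapse = ", "))

  bad <- rowSums(is.na(x[need])) > 0
  excluded <- x[bad, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- "missing stratification field"
  x <- x[!bad, , drop = FALSE]
  if (!nrow(x)) stop("no carriers with complete stratification fields")

  key <- paste(x$country, ifelse(x$delT, "delT", "other"), sep = ":")
  if (by_stage) key <- paste(key, paste0("stage", x$stage), sep = ":")
  counts <- table(key)
  small <- names(counts)[counts < min_size]
  if (length(small)) {
    warning(length(small), " stratum/strata below min_size merged into country-level 'rest'")
    merge_to <- sub("^([^:]+):[^:]+", "\\1:rest", small)
    key[key %in% small] <- merge_to[match(key[key %in% small], small)]
  }
  x$stratum <- key
  summary <- x |>
    dplyr::count(.data$stratum, name = "n") |>
    dplyr::arrange(.data$stratum)
  list(carriers = x, excluded = tibble::as_tibble(excluded), summary = summary)
}
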