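#' Derive censoring age and affection status from event histories
#'
#' Carriers are censored at the first breast cancer, ovarian cancer, or
#' bilateral prophylactic mastectomy (BPM), whichever occurs first, otherwise
#' at the age of last observation, capped at `cap` years. A carrier who
#' develops cancer is censored at BPM instead only when the BPM preceded the
#' cancer diagnosis by more than one year (this guards against mastectomies
#' performed as part of the diagnostic episode when ages are recorded in
#' rounded years). A carrier censored at breast-cancer diagnosis is a case;
#' censoring at ovarian cancer, BPM, last observation or the age cap yields an
#' unaffected record.
#'
#' @param histories Data frame with one row per carrier and numeric columns
#'   `breast_dx_age`, `ovarian_dx_age`, `bpm_age`, `last_obs_age` (ages in
#'   years; `NA` = event absent). Extra columns are carried through.
#' @param cap Administrative censoring age in years (default 80).
#' @return A tibble: the input columns plus `censor_age`, `affected` (logical),
#'   and `censor_reason` (one of `"breast"`, `"ovarian"`, `"bpm"`,
#'   `"last_obs"`, `"age_cap"`).
#' @examples
#' derive_time_at_risk(data.frame(
#'   breast_dx_age = c(38, NA), ovarian_dx_age = c(NA, 45),
#'   bpm_age = NA_real_, last_obs_age = c(45, 60)))
#' @export
derive_time_at_risk <- function(histories, cap = 80) {
  stopifnot(is.data.frame(histories))
  h <- tibble::as_tibble(histories)
  for (col in c("breast_dx_age", "ovarian_dx_age", "bpm_age", "last_obs_age")) {
    if (!col %in% names(h)) h[[col]] <- NA_real_
  }
  ages <- cbind(h$breast_dx_age, h$ovarian_dx_age, h$bpm_age, h$last_obs_age)
  if (any(ages <= 0, na.rm = TRUE))
    stop("event ages must be positive")
  if (any(rowSums(!is.na(ages)) == 0))
    stop("no observation: every carrier needs at least one recorded age")

  breast <- h$breast_dx_age
  ovarian <- h$ovarian_dx_age
  bpm <- h$bpm_age
  last_obs <- h$last_obs_age

  # first cancer of either site
  cancer <- pmin(breast, ovarian, na.rm = TRUE)
  cancer[is.na(breast) & is.na(ovarian)] <- NA_real_

  # BPM only censors when it precedes the (first) cancer by more than a year;
  # with no cancer it censors at the BPM age itself.
  bpm_wins <- !is.na(bpm) & (is.na(cancer) | (cancer - bpm > 1.0))

  event_age <- ifelse(bpm_wins, bpm, cancer)
  reason <- dplyr::case_when(
    bpm_wins ~ "bpm",
    !is.na(cancer) & !is.na(breast) & cancer == breast ~ "breast",
    !is.na(cancer) ~ "ovarian",
    TRUE ~ NA_character_
  )
  no_event <- is.na(event_age)
  event_age[no_event] <- last_obs[no_event]
  reason[no_event] <- "last_obs"
  if (any(is.na(event_age)))
    stop("no observation: carriers with events only need last_obs_age too")

  capped <- event_age > cap
  censor_age <- pmin(event_age, cap)
  reason[capped] <- "age_cap"

  h$censor_age <- censor_age
  h$affected <- reason == "breast"
  h$censor_reason <- reason
  h
}
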