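#' Pedigree kinship matrix
#'
#' Computes the matrix of kinship coefficients \eqn{\phi_{ij}} (probability
#' that two alleles drawn one from each individual are identical by descent)
#' for a set of subjects, using the standard recursive algorithm on the
#' pedigree: \eqn{\phi_{ii} = 1/2 (1 + \phi_{fm})} and
#' \eqn{\phi_{ij} = \frac{1}{2}[\phi_{f(i)j} + \phi_{m(i)j}]} when `i` is not
#' an ancestor of `j`. Founders (and subjects absent from the pedigree, treated
#' as singleton families) are unrelated across families.
#'
#' @param pedigree Data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (`NA` or `""` = founder). Parent ids must refer
#'   to rows of the same pedigree; cycles are an error.
#' @param subjects Character vector of individual ids to index the output;
#'   defaults to all pedigree members.
#' @return A symmetric numeric matrix with `subjects` as dimnames.
#' @examples
#' ped <- data.frame(family_id = "f1",
#'                   individual_id = c("p1", "p2", "c1"),
#'                   father_id = c(NA, NA, "p1"),
#'                   mother_id = c(NA, NA, "p2"))
#' kinship_matrix(ped)["p1", "c1"]  # 0.25
#' @export
kinship_matrix <- function(pedigree, subjects = NULL) {
  stopifnot(is.data.frame(pedigree))
  ped <- tibble::as_tibble(pedigree)
  ped$individual_id <- as.character(ped$individual_id)
  norm_id <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x %in% c("", "0")] <- NA_character_
    x
  }
  ped$father_id <- norm_id(ped$father_id)
  ped$mother_id <- norm_id(ped$mother_id)
  if (anyDuplicated(ped$individual_id))
    stop("duplicated individual_id in pedigree")
  if (is.null(subjects)) subjects <- ped$individual_id
  subjects <- as.character(subjects)

  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$individual_id)
  fa <- unname(idx[ped$father_id])
  mo <- unname(idx[ped$mother_id])
  if (any(!is.na(ped$father_id) & is.na(fa)) || any(!is.na(ped$mother_id) & is.na(mo)))
    stop("parent id not found in pedigree")

  # topological order: parents before children; failure to make progress = cycle
  ord <- integer(0)
  placed <- rep(FALSE, n)
  while (length(ord) < n) {
    fa_ok <- is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]
    mo_ok <- is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)]
    ready <- !placed & fa_ok & mo_ok
    if (!any(ready)) stop("cyclic pedigree: parent links do not admit a topological order")
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }

  phi <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  for (k in ord) {
    f <- fa[k]; m <- mo[k]
    phi[k, k] <- if (!is.na(f) && !is.na(m)) 0.5 * (1 + phi[f, m]) else 0.5
    prior <- ord[seq_len(match(k, ord) - 1L)]
    if (length(prior)) {
      v <- rep(0, length(prior))
      if (!is.na(f)) v <- v + 0.5 * phi[f, prior]
      if (!is.na(m)) v <- v + 0.5 * phi[m, prior]
      phi[k, prior] <- v
      phi[prior, k] <- v
    }
  }

  extra <- setdiff(subjects, ped$individual_id)
  out <- matrix(0, length(subjects), length(subjects),
                dimnames = list(subjects, subjects))
  known <- intersect(subjects, ped$individual_id)
  out[known, known] <- phi[known, known, drop = FALSE]
  if (length(extra)) out[cbind(extra, extra)] <- 0.5
  diag(out)[diag(out) == 0] <- 0.5
  out
}
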