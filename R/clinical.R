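# Composite clinical scores: BICAMS and (modified) MSFC via z-score
# averaging with the usual sign and reciprocal conventions.

#' Compute BICAMS and MSFC composite scores
#'
#' z-scores each component against the cohort (sample-SD convention, or
#' external norms when supplied) and averages:
#' `BICAMS = mean(z(SDMT), z(RAVLT), z(BVMT-R))` and
#' `MSFC = mean(z(SDMT), z(-T25FW), z(1/9HPT))` — the timed-walk score is
#' sign-flipped and the reciprocal of the peg-test time is used so that
#' higher always means better. Participants missing any component of a
#' composite get a missing composite.
#'
#' @param cohort Tibble with columns `sdmt`, `ravlt`, `bvmtr`, `t25fw`,
#'   `hpt9` (additional columns pass through).
#' @param norms Optional external norm table: a named list with `mean`
#'   and `sd` vectors named by component (components not listed fall back
#'   to cohort-internal norms). Norms apply to the transformed scores
#'   (`-t25fw`, `1/hpt9`).
#' @return The cohort tibble with `bicams` and `msfc` columns appended.
#' @export
#' @examples
#' cohort <- tibble::tibble(sdmt = c(40, 50, 60), ravlt = c(44, 54, 64),
#'                          bvmtr = c(18, 24, 30), t25fw = c(4, 5, 6),
#'                          hpt9 = c(20, 22, 24))
#' compute_composites(cohort)$bicams # -1, 0, 1
compute_composites <- function(cohort, norms = NULL) {
  need <- c("sdmt", "ravlt", "bvmtr", "t25fw", "hpt9")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    abort(sprintf("`cohort` is missing component(s): %s.", paste(miss, collapse = ", ")))
  }
  if (sum(stats::complete.cases(cohort[need])) < 2 && nrow(cohort) < 2) {
    abort("Need at least 2 participants to compute cohort z-scores.")
  }
  zscore <- function(x, name) {
    m <- norms$mean[[name]] %||% mean(x, na.rm = TRUE)
    s <- norms$sd[[name]] %||% sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Component '%s' has zero variance; z-score undefined.", name))
    }
    (x - m) / s
  }
  z_sdmt <- zscore(cohort$sdmt, "sdmt")
  z_ravlt <- zscore(cohort$ravlt, "ravlt")
  z_bvmtr <- zscore(cohort$bvmtr, "bvmtr")
  z_walk <- zscore(-cohort$t25fw, "t25fw")
  z_peg <- zscore(1 / cohort$hpt9, "hpt9")
  cohort$bicams <- (z_sdmt + z_ravlt + z_bvmtr) / 3
  cohort$msfc <- (z_sdmt + z_walk + z_peg) / 3
  cohort
}
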