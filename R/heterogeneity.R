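#' Intra-tumour heterogeneity from an absolute profile
#'
#' ITH is the length-weighted average distance of segment copy numbers from
#' the nearest integer state:
#' \deqn{ITH = \frac{\sum_s \ell_s\,|a_s - [a_s]|}{\sum_s \ell_s}}
#' where \eqn{\ell_s} is the segment length in bp and \eqn{[a_s]} the nearest
#' non-negative integer. A fully clonal profile (all segments at integer
#' states) scores 0; the per-segment distance is bounded by 0.5, so ITH is
#' too. Ties at x.5 resolve to the lower integer, which does not affect the
#' score.
#'
#' @param segments Absolute-space segments (`chrom`, `start`, `end`, and a
#'   `value` or `cn` column), or an `acn_fit` object.
#' @return A single non-negative number.
#' @examples
#' seg <- tibble::tibble(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 4e6),
#'                       value = c(2.25, 2.05))
#' compute_ith(seg) # 0.10
#' @export
compute_ith <- function(segments) {
  if (inherits(segments, "acn_fit")) segments <- segments$segments
  check_segments(segments)
  if (nrow(segments) == 0) {
    stop_paircn("empty segment table", "paircn_validation_error")
  }
  vcol <- if ("value" %in% names(segments)) "value" else "cn"
  a <- segments[[vcol]]
  w <- segments$end - segments$start
  sum(w * abs(a - nearest_state(a))) / sum(w)
}

#' Diagnosis-to-relapse change in intra-tumour heterogeneity
#'
#' @param ith Tibble with columns `patient_id`, `role` (`"diagnosis"` /
#'   `"relapse"`) and `ith` (one row per sample), e.g. built by mapping
#'   [compute_ith()] over a cohort.
#' @return Tibble `patient_id`, `ith_diagnosis`, `ith_relapse`, `delta_ith`
#'   where `delta_ith = ith_relapse - ith_diagnosis`.
#' @export
compute_delta_ith <- function(ith) {
  stopifnot(all(c("patient_id", "role", "ith") %in% names(ith)))
  bad <- setdiff(unique(ith$role), c("diagnosis", "relapse"))
  if (length(bad) > 0) {
    stop_paircn(paste0("unknown role(s): ", paste(bad, collapse = ", ")),
                "paircn_validation_error")
  }
  wide <- tidyr::pivot_wider(ith[, c("patient_id", "role", "ith")],
                             names_from = "role", values_from = "ith",
                             names_prefix = "ith_")
  if (!all(c("ith_diagnosis", "ith_relapse") %in% names(wide)) ||
      anyNA(wide$ith_diagnosis) || anyNA(wide$ith_relapse)) {
    stop_paircn("every patient needs one diagnosis and one relapse ITH value",
                "paircn_validation_error")
  }
  mutate(wide, delta_ith = .data$ith_relapse - .data$ith_diagnosis)
}
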