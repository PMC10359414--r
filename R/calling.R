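#' GC and mappability bias correction of binned counts
#'
#' Converts raw binned read counts into a relative copy-number track. Bins
#' with mappability below `map_min` are masked. The correction is a two-stage
#' median-binning fit: counts are divided by a piecewise-linear fit of the
#' per-quantile-group median count against GC, then against mappability, and
#' the result is median-normalised so the unmasked bins have median relative
#' copy number 1.
#'
#' @param counts Bin tibble with `chrom`, `start`, `end`, `gc`,
#'   `mappability`, `count` (as emitted by [emit_binned_counts()] or read by
#'   [read_binned_counts()]).
#' @param map_min Mappability threshold below which bins are masked
#'   (default 0.25).
#' @param n_groups Number of quantile groups for the median-binning fits.
#' @param min_bins Minimum number of unmasked bins required (default 100).
#' @return The input tibble with columns `r` (relative copy number, `NA` for
#'   masked bins) and `masked` appended.
#' @examples
#' layout <- genome_layout("toy")
#' bins <- layout_bins(layout, seed = 1)
#' seg <- simulate_cn_profile(layout, rep(1 / 7, 7), 10, seed = 1)
#' rel <- correct_bias(emit_binned_counts(seg, bins, purity = 0.8, seed = 1))
#' @export
correct_bias <- function(counts, map_min = 0.25, n_groups = 20, min_bins = 100) {
  needed <- c("chrom", "start", "end", "gc", "mappability", "count")
  if (!all(needed %in% names(counts))) {
    stop_paircn(paste0("counts need columns: ", paste(needed, collapse = ", ")),
                "paircn_validation_error")
  }
  masked <- counts$mappability < map_min | is.na(counts$count)
  if (sum(!masked) < min_bins) {
    stop_paircn("fewer than `min_bins` unmasked bins; cannot fit bias model",
                "paircn_fit_error")
  }
  r <- as.numeric(counts$count)
  r[masked] <- NA_real_
  r <- r / median_bin_fit(counts$gc, r, n_groups)
  r <- r / pmax(counts$mappability, 1e-6)
  r <- r / median_bin_fit(counts$mappability, r, n_groups)
  med <- median(r[!masked])
  if (!is.finite(med) || med <= 0) {
    stop_paircn("degenerate bias fit (non-positive median)", "paircn_fit_error")
  }
  r <- r / med
  out <- counts
  out$r <- r
  out$masked <- masked
  out
}

# Fitted values of a median-binning regression of y on x: group x into
# quantile bins, take the median y per group, interpolate linearly between
# group medians at the group-median x positions.
median_bin_fit <- function(x, y, n_groups) {
  ok <- !is.na(y) & !is.na(x)
  qs <- unique(quantile(x[ok], probs = seq(0, 1, length.out = n_groups + 1),
                        names = FALSE))
  if (length(qs) < 3) {
    return(rep(median(y[ok]), length(x)))
  }
  grp <- cut(x, breaks = qs, include.lowest = TRUE)
  gx <- tapply(x[ok], grp[ok], median)
  gy <- tapply(y[ok], grp[ok], median)
  keep <- !is.na(gx) & !is.na(gy)
  if (sum(keep) < 2) {
    return(rep(median(y[ok]), length(x)))
  }
  fit <- approx(gx[keep], gy[keep], xout = x, rule = 2)$y
  pmax(fit, 1e-9)
}

#' Segment a relative copy-number profile
#'
#' Piecewise-constant segmentation of the bias-corrected track by penalised
#' exact changepoint search (PELT) with an L2 cost on log2 values, run per
#' chromosome on the unmasked bins. The penalty per changepoint is
#' `penalty * sigma^2 * log(n)` where `sigma` is a robust (median absolute
#' difference) noise estimate; larger `penalty` gives fewer segments, and as
#' the penalty grows every chromosome collapses to one segment. Reported
#' segment values are the mean of member bins on the linear scale; segments
#' partition each chromosome exactly (masked bins are absorbed into the
#' enclosing or preceding segment).
#'
#' @param rel Output of [correct_bias()].
#' @param penalty Positive penalty multiplier (default 4).
#' @param min_bins_per_segment Minimum unmasked bins per segment (default 3).
#' @return A segment tibble `chrom`, `start`, `end`, `value`, `n_bins` with
#'   attribute `space = "relative"`.
#' @export
segment_profile <- function(rel, penalty = 4, min_bins_per_segment = 3) {
  if (penalty <= 0) stop_paircn("penalty must be > 0", "paircn_config_error")
  if (!all(c("r", "masked") %in% names(rel))) {
    stop_paircn("`rel` must be the output of correct_bias()",
                "paircn_validation_error")
  }
  use <- !rel$masked & !is.na(rel$r)
  y_all <- log2(pmax(rel$r, 1e-3))
  # pooled robust noise estimate from within-chromosome first differences
  diffs <- unlist(lapply(split(y_all[use], rel$chrom[use]), diff),
                  use.names = FALSE)
  sigma2 <- max((mad(diffs) / sqrt(2))^2, 1e-8)
  n_tot <- sum(use)
  pen <- penalty * sigma2 * log(n_tot)
  chrom_order <- unique(rel$chrom)
  segs <- lapply(chrom_order, function(ch) {
    sel <- which(rel$chrom == ch & use)
    if (length(sel) == 0) return(NULL)
    y <- y_all[sel]
    ends_idx <- .pelt_l2(y, pen, as.integer(min_bins_per_segment))
    starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
    chrom_start <- min(rel$start[rel$chrom == ch])
    chrom_end <- max(rel$end[rel$chrom == ch])
    # segment boundaries in genomic coordinates: a segment opens where the
    # previous one closed (chromosome start for the first), and closes at the
    # end of its last unmasked bin (chromosome end for the last), so segments
    # tile the chromosome exactly.
    gend <- rel$end[sel[ends_idx]]
    gend[length(gend)] <- chrom_end
    gstart <- c(chrom_start, head(gend, -1L))
    tibble(
      chrom = ch, start = gstart, end = gend,
      value = vapply(seq_along(ends_idx), function(i) {
        mean(rel$r[sel[starts_idx[i]:ends_idx[i]]])
      }, numeric(1)),
      n_bins = ends_idx - starts_idx + 1L
    )
  })
  out <- list_rbind(segs)
  attr(out, "space") <- "relative"
  out
}

#' Relative to absolute copy number
#'
#' Inverts the two-population mixture model linking relative coverage to
#' tumour copy number: a segment with relative value \eqn{r} in a sample of
#' purity \eqn{\rho} and tumour ploidy \eqn{\psi} has absolute copy number
#' \deqn{n = \frac{r\,[\rho\psi + 2(1-\rho)] - 2(1-\rho)}{\rho}.}
#' The result can be negative for noisy low \eqn{r}; values are clipped only
#' at reporting time, never here.
#'
#' @param r Relative copy number (vector).
#' @param purity Tumour fraction in (0, 1].
#' @param ploidy Tumour ploidy (> 0).
#' @return Absolute copy number, same length as `r`.
#' @examples
#' to_absolute(1, purity = 0.5, ploidy = 2) # 2
#' @export
to_absolute <- function(r, purity, ploidy) {
  if (purity <= 0 || purity > 1) {
    stop_paircn("purity must lie in (0, 1]", "paircn_domain_error")
  }
  if (ploidy <= 0) stop_paircn("ploidy must be > 0", "paircn_domain_error")
  (r * (purity * ploidy + 2 * (1 - purity)) - 2 * (1 - purity)) / purity
}

#' Fit purity and ploidy by grid search
#'
#' Searches a (purity, ploidy) grid for the combination under which the
#' relative segment values, transformed by [to_absolute()], fall closest to
#' non-negative integer copy-number states. The score is the length-weighted
#' mean squared distance to the nearest such state. A relative profile
#' identifies (purity, ploidy) only up to affine relabelings of the integer
#' states (e.g. a 50%-pure genome is indistinguishable from a pure genome
#' with two extra copies of everything), so near-optimal candidates — scores
#' within `tie_tol` of the optimum — are resolved by ploidy parsimony:
#' lowest ploidy first, then highest purity. Down-shifted relabelings are
#' excluded automatically by the non-negativity penalty whenever the genome
#' carries a homozygous deletion. Because tumour ploidy is defined as the length-weighted mean
#' copy number, segment values are first renormalised to unit length-weighted
#' mean (the median-normalisation of [correct_bias()] fixes the median, not
#' the mean).
#'
#' Quantitative QC: the fit passes iff the score is at most `qc_max_score`
#' and at least half the genome (by length) lies within 0.3 of an integer
#' state.
#'
#' @param segments Relative-space segment tibble from [segment_profile()].
#' @param purity_grid,ploidy_grid Candidate grids (defaults: purity 0.20-1.00
#'   step 0.05; ploidy 1.6-8.0 step 0.05).
#' @param tie_tol Score window regarded as a tie for the parsimony rule
#'   (default 1e-4).
#' @param min_fit_bins Segments supported by fewer unmasked bins than this
#'   are excluded from the score (default 5): sub-resolution segments
#'   average neighbouring states and their fractional means can make scaled
#'   state-relabelings look spuriously exact. They are still transformed in
#'   the output.
#' @param qc_max_score QC cap on the goodness-of-fit score (default 0.1).
#' @param qc_min_frac Minimum genome fraction within 0.3 of an integer state
#'   (default 0.5).
#' @return An `acn_fit` object with elements `purity`, `ploidy` (reported as
#'   the length-weighted mean absolute copy number), `grid_ploidy` (the grid
#'   value selected), `segments` (absolute-space tibble), `qc` (list:
#'   `score`, `frac_integer`, `pass`), and `grid` (all scores, for
#'   diagnostics). Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
fit_purity_ploidy <- function(segments,
                              purity_grid = seq(0.20, 1.00, by = 0.05),
                              ploidy_grid = seq(1.6, 8.0, by = 0.05),
                              tie_tol = 1e-4, min_fit_bins = 5,
                              qc_max_score = 0.1, qc_min_frac = 0.5) {
  check_segments(segments)
  if (!"value" %in% names(segments)) {
    stop_paircn("segments need a `value` column", "paircn_validation_error")
  }
  w_all <- segments$end - segments$start
  if (length(unique(round(segments$value, 3))) < 2) {
    stop_paircn(paste0("flat profile: purity and ploidy are not identifiable ",
                       "from a single copy-number state; manual review required"),
                "paircn_degenerate_fit")
  }
  r_all <- segments$value / weighted.mean(segments$value, w_all)
  use <- if ("n_bins" %in% names(segments)) {
    segments$n_bins >= min_fit_bins
  } else {
    rep(TRUE, nrow(segments))
  }
  if (sum(use) < 2) use <- rep(TRUE, nrow(segments))
  r <- r_all[use]
  w <- w_all[use]
  grid <- tidyr::expand_grid(purity = purity_grid, ploidy = ploidy_grid)
  wn <- w / sum(w)
  score_fn <- function(par) {
    a <- to_absolute(r, par[1], par[2])
    sum(wn * (a - nearest_state(a))^2)
  }
  score <- map_dbl(seq_len(nrow(grid)), function(i) {
    score_fn(c(grid$purity[i], grid$ploidy[i]))
  })
  grid$score <- score
  # The grid has a 0.05 resolution but the optimum need not fall on it, and
  # competing state-relabeled solutions can land closer to their nearest grid
  # point than the true one does to its own. The top grid candidates are
  # therefore refined continuously before comparison; relabeled solutions
  # amplify the residual error by their state-scale factor, so after
  # refinement the correct basin scores strictly best whenever the data carry
  # any noise, and exact ties fall to ploidy parsimony.
  ord <- order(score)
  top <- head(ord, 40)
  refined <- lapply(top, function(i) {
    o <- stats::optim(c(grid$purity[i], grid$ploidy[i]), score_fn,
                      method = "L-BFGS-B",
                      lower = c(min(purity_grid), min(ploidy_grid)),
                      upper = c(1, max(ploidy_grid)),
                      control = list(factr = 1e4))
    tibble(purity = o$par[1], ploidy = o$par[2], score = o$value,
           grid_purity = grid$purity[i], grid_ploidy = grid$ploidy[i])
  }) |> list_rbind()
  best <- min(refined$score)
  cand <- refined[refined$score <= best + tie_tol, , drop = FALSE]
  cand <- cand[order(cand$ploidy, -cand$purity), , drop = FALSE]
  rho <- cand$purity[1]
  psi_grid <- cand$grid_ploidy[1]
  a_all <- to_absolute(r_all, rho, cand$ploidy[1])
  a <- a_all[use]
  seg_abs <- segments
  seg_abs$value <- a_all
  attr(seg_abs, "space") <- "absolute"
  frac <- sum(wn[abs(a - nearest_state(a)) <= 0.3])
  qc <- list(score = cand$score[1], frac_integer = frac,
             pass = cand$score[1] <= qc_max_score && frac >= qc_min_frac)
  structure(
    list(purity = rho, ploidy = weighted.mean(a_all, w_all),
         grid_ploidy = psi_grid, segments = seg_abs, qc = qc, grid = grid),
    class = "acn_fit"
  )
}

#' @export
#' @method print acn_fit
print.acn_fit <- function(x, ...) {
  cat(sprintf("<acn_fit> purity %.2f, ploidy %.2f (grid %.2f), score %.4f, QC %s\n",
              x$purity, x$ploidy, x$grid_ploidy, x$qc$score,
              if (x$qc$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Call a ploidy change between diagnosis and relapse
#'
#' Classifies a pair of absolute copy-number fits as `"increased"`,
#' `"decreased"` or `"stable"` according to whether the relapse ploidy
#' differs from the diagnosis ploidy by more than `threshold` copies. Both
#' fits must pass QC; otherwise the call is refused with a QC report.
#'
#' @param diagnosis,relapse `acn_fit` objects for the two samples.
#' @param threshold Copy-number change regarded as real (default 0.5).
#' @param require_qc Refuse failed-QC inputs (default `TRUE`).
#' @return One of `"increased"`, `"decreased"`, `"stable"`.
#' @export
call_ploidy_change <- function(diagnosis, relapse, threshold = 0.5,
                               require_qc = TRUE) {
  stopifnot(inherits(diagnosis, "acn_fit"), inherits(relapse, "acn_fit"))
  if (require_qc && (!diagnosis$qc$pass || !relapse$qc$pass)) {
    bad <- c(if (!diagnosis$qc$pass) "diagnosis", if (!relapse$qc$pass) "relapse")
    stop_paircn(paste0(
      "refusing ploidy-change call: QC failed for ", paste(bad, collapse = " and "),
      " (diagnosis score ", signif(diagnosis$qc$score, 3),
      ", frac ", signif(diagnosis$qc$frac_integer, 3),
      "; relapse score ", signif(relapse$qc$score, 3),
      ", frac ", signif(relapse$qc$frac_integer, 3), ")"
    ), "paircn_qc_error")
  }
  d <- relapse$ploidy - diagnosis$ploidy
  if (d > threshold) "increased" else if (d < -threshold) "decreased" else "stable"
}

#' Absolute copy-number pipeline for one sample
#'
#' Convenience wrapper chaining [correct_bias()], [segment_profile()] and
#' [fit_purity_ploidy()] on one sample's binned counts.
#'
#' @param counts Bin tibble with counts for one sample.
#' @param penalty Segmentation penalty multiplier.
#' @param ... Passed to [fit_purity_ploidy()].
#' @return An `acn_fit` object.
#' @export
call_absolute <- function(counts, penalty = 4, ...) {
  counts |>
    correct_bias() |>
    segment_profile(penalty = penalty) |>
    fit_purity_ploidy(...)
}
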