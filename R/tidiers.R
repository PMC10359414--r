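#' Tidy an absolute copy-number fit
#'
#' @param x An `acn_fit` from [fit_purity_ploidy()].
#' @param ... Unused.
#' @return The absolute-space segment table as a tibble.
#' @export
tidy.acn_fit <- function(x, ...) {
  as_tibble(x$segments)
}

#' One-row summary of an absolute copy-number fit
#'
#' @param x An `acn_fit`.
#' @param ... Unused.
#' @return Tibble with `purity`, `ploidy`, `grid_ploidy`, `score`,
#'   `frac_integer`, `qc_pass`, `n_segments`.
#' @export
glance.acn_fit <- function(x, ...) {
  tibble(purity = x$purity, ploidy = x$ploidy, grid_ploidy = x$grid_ploidy,
         score = x$qc$score, frac_integer = x$qc$frac_integer,
         qc_pass = x$qc$pass, n_segments = nrow(x$segments))
}

#' Tidy a global signature-abundance fit
#'
#' @param x An `ilr_fit` from [fit_global_abundance_model()].
#' @param ... Unused.
#' @return Per-coordinate tibble with intercept, group slope and variance
#'   components.
#' @export
tidy.ilr_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a global signature-abundance fit
#'
#' @param x An `ilr_fit`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p.value`, `engine`, group sizes.
#' @export
glance.ilr_fit <- function(x, ...) {
  tibble(statistic = x$wald$statistic, df = x$wald$df1,
         p.value = x$wald$p.value, engine = x$engine,
         n1 = x$n[1], n2 = x$n[2],
         group1 = x$groups[1], group2 = x$groups[2])
}
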