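#' Paired genome subtraction with per-bin rank tests
#'
#' Projects every sample's absolute copy-number segments onto the common bin
#' grid and, per bin, compares the diagnosis and relapse values across
#' patients with a two-sided Mann-Whitney U test (normal approximation with
#' continuity correction; bins whose values are all tied get p = 1).
#' P-values are Benjamini-Hochberg adjusted within each chromosome, and the
#' reported profile is `median(relapse) - median(diagnosis)` per bin, so
#' positive values mean a copy-number increase at relapse. Patients missing a
#' value in a bin are dropped bin-wise.
#'
#' @param segments Long tibble of absolute segments across the cohort:
#'   `patient_id`, `role` (`"diagnosis"`/`"relapse"`), `chrom`, `start`,
#'   `end` and a `value` or `cn` column.
#' @param layout The common [genome_layout()].
#' @param alpha Significance level for the FDR mask (default 0.05).
#' @return A `cn_subtraction` tibble: `chrom`, `start`, `end`, `median_diff`,
#'   `p`, `q`, `significant`.
#' @export
subtract_pairs <- function(segments, layout, alpha = 0.05) {
  stopifnot(all(c("patient_id", "role") %in% names(segments)))
  vcol <- if ("value" %in% names(segments)) "value" else "cn"
  grid <- layout_bin_grid(layout)
  pats <- unique(segments$patient_id)
  if (length(pats) < 2) {
    stop_paircn("need at least 2 pairs", "paircn_validation_error")
  }
  get_mat <- function(role) {
    vapply(pats, function(p) {
      s <- segments[segments$patient_id == p & segments$role == role, , drop = FALSE]
      if (nrow(s) == 0) {
        stop_paircn(paste0("patient ", p, " has no ", role, " segments"),
                    "paircn_validation_error")
      }
      segments_to_bins(s, grid, value_col = vcol)
    }, numeric(nrow(grid)))
  }
  dx <- get_mat("diagnosis")
  rel <- get_mat("relapse")
  p <- vapply(seq_len(nrow(grid)), function(i) {
    a <- dx[i, ]
    b <- rel[i, ]
    ok_a <- !is.na(a); ok_b <- !is.na(b)
    if (sum(ok_a) < 1 || sum(ok_b) < 1) return(NA_real_)
    vals <- c(a[ok_a], b[ok_b])
    if (max(vals) - min(vals) < 1e-12) return(1)
    suppressWarnings(
      wilcox.test(a[ok_a], b[ok_b], exact = FALSE, correct = TRUE)$p.value
    )
  }, numeric(1))
  out <- grid
  out$median_diff <- apply(rel, 1, median, na.rm = TRUE) -
    apply(dx, 1, median, na.rm = TRUE)
  out$p <- p
  out <- out |>
    group_by(.data$chrom) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = !is.na(.data$q) & .data$q < alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("cn_subtraction", class(out))
  out
}

layout_bin_grid <- function(layout) {
  bs <- layout$bin_size
  purrr::pmap(layout$chromosomes, function(chrom, length, centromere) {
    start <- seq(0, length - 1, by = bs)
    tibble(chrom = chrom, start = start, end = pmin(start + bs, length))
  }) |> list_rbind()
}

#' Ploidy-aware focal gene event calling
#'
#' Computes each gene's absolute copy number as the length-weighted mean of
#' the segments overlapping its interval and classifies it against
#' ploidy-relative thresholds: amplified iff
#' \eqn{CN \ge \max(a_{min}, m\,\hat\psi)} (defaults \eqn{a_{min}=5},
#' \eqn{m=2}) and deleted iff \eqn{CN \le \max(\hat\psi - d, 0)} (default
#' \eqn{d = 1.87}, i.e. sub-single-copy loss); otherwise neutral. All
#' thresholds are overridable. Genes with no overlapping segment get `NA`
#' calls and are reported in a message.
#'
#' @param segments One sample's absolute segments (`chrom`, `start`, `end`,
#'   `value` or `cn`), or an `acn_fit` (its ploidy is then used).
#' @param panel Gene panel tibble `chrom`, `start`, `end`, `gene`.
#' @param ploidy Sample ploidy \eqn{\hat\psi}; required when `segments` is a
#'   plain table.
#' @param amp_min,amp_ploidy_mult,del_offset Threshold parameters.
#' @return Tibble `gene`, `cn`, `event` (`"amplified"`, `"deleted"`,
#'   `"neutral"` or `NA`), `ploidy`.
#' @export
call_gene_events <- function(segments, panel, ploidy = NULL, amp_min = 5,
                             amp_ploidy_mult = 2, del_offset = 1.87) {
  if (inherits(segments, "acn_fit")) {
    ploidy <- segments$ploidy
    segments <- segments$segments
  }
  if (is.null(ploidy)) {
    stop_paircn("`ploidy` is required with a plain segment table",
                "paircn_config_error")
  }
  check_segments(segments)
  vcol <- if ("value" %in% names(segments)) "value" else "cn"
  cn <- vapply(seq_len(nrow(panel)), function(i) {
    g <- panel[i, ]
    s <- segments[segments$chrom == g$chrom & segments$end > g$start &
                    segments$start < g$end, , drop = FALSE]
    if (nrow(s) == 0) return(NA_real_)
    ov <- pmin(s$end, g$end) - pmax(s$start, g$start)
    weighted.mean(s[[vcol]], ov)
  }, numeric(1))
  if (anyNA(cn)) {
    inform(paste0("no overlapping segment for gene(s): ",
                  paste(panel$gene[is.na(cn)], collapse = ", ")))
  }
  amp_thr <- max(amp_min, amp_ploidy_mult * ploidy)
  del_thr <- max(ploidy - del_offset, 0)
  event <- dplyr::case_when(
    is.na(cn) ~ NA_character_,
    cn >= amp_thr ~ "amplified",
    cn <= del_thr ~ "deleted",
    .default = "neutral"
  )
  tibble(gene = panel$gene, cn = cn, event = event, ploidy = ploidy)
}

#' Compare focal event rates between two groups
#'
#' For each gene, builds the 2x2 table of samples with/without the event type
#' in each group, runs a two-sided Fisher exact test, and adjusts p-values by
#' Benjamini-Hochberg across the gene family tested.
#'
#' @param events Tibble with columns `gene`, `event` and a grouping column
#'   (one row per sample x gene), e.g. stacked [call_gene_events()] output
#'   joined to sample metadata.
#' @param group_col Name of the two-level grouping column.
#' @param event_type The event compared (default `"amplified"`).
#' @param genes Gene family across which to adjust (default: all genes
#'   present).
#' @return A test-result tibble: `label`, `estimate` (odds ratio), `p`, `q`,
#'   `n1`, `n2`, `method`.
#' @export
compare_event_rates <- function(events, group_col, event_type = "amplified",
                                genes = NULL) {
  stopifnot(all(c("gene", "event", group_col) %in% names(events)))
  grp <- factor(events[[group_col]])
  if (nlevels(grp) != 2) {
    stop_paircn("grouping must have exactly 2 levels", "paircn_config_error")
  }
  if (any(table(grp) == 0)) {
    stop_paircn("both groups must be non-empty", "paircn_validation_error")
  }
  genes <- genes %||% unique(events$gene)
  res <- lapply(genes, function(g) {
    sel <- events$gene == g & !is.na(events$event)
    hit <- events$event[sel] == event_type
    gg <- droplevels(grp[sel])
    if (nlevels(gg) != 2) {
      return(tibble(label = g, estimate = NA_real_, p = NA_real_,
                    n1 = sum(gg == levels(gg)[1]), n2 = sum(gg == levels(gg)[2]),
                    method = "fisher-exact"))
    }
    tab <- table(factor(hit, levels = c(TRUE, FALSE)), gg)
    ft <- fisher.test(tab)
    tibble(label = g, estimate = unname(ft$estimate), p = ft$p.value,
           n1 = sum(gg == levels(gg)[1]), n2 = sum(gg == levels(gg)[2]),
           method = "fisher-exact")
  }) |> list_rbind()
  mutate(res, q = p.adjust(.data$p, method = "BH"), .after = "p")
}

#' Per-signature two-group exposure tests
#'
#' One two-sided rank test per signature: Mann-Whitney U for unpaired groups,
#' Wilcoxon signed-rank for paired designs (matched on `patient_col`).
#' P-values are reported unadjusted by default (matching common practice for
#' per-signature panels); set `adjust = "BH"` for a family-wise q column.
#'
#' @param exposures Tibble with signature columns, a grouping column, and (if
#'   `paired`) a patient column.
#' @param group_col Two-level grouping column name.
#' @param paired Use the matched signed-rank test (default `FALSE`).
#' @param patient_col Pairing key column (default `"patient_id"`).
#' @param sig_cols Signature columns (default: matching `^s[0-9]+$`).
#' @param adjust Multiplicity adjustment across signatures (default
#'   `"none"`).
#' @return Test-result tibble: `label`, `statistic`, `p`, `q`, `n1`, `n2`,
#'   `method`.
#' @export
compare_exposures_univariate <- function(exposures, group_col, paired = FALSE,
                                         patient_col = "patient_id",
                                         sig_cols = NULL, adjust = "none") {
  if (is.null(sig_cols)) {
    sig_cols <- grep("^s[0-9]+$", names(exposures), value = TRUE)
  }
  grp <- factor(exposures[[group_col]])
  if (nlevels(grp) != 2) {
    stop_paircn("grouping must have exactly 2 levels", "paircn_config_error")
  }
  if (paired) {
    if (!patient_col %in% names(exposures)) {
      stop_paircn("paired tests need a patient column", "paircn_validation_error")
    }
    tab <- table(exposures[[patient_col]], grp)
    if (!all(tab == 1)) {
      stop_paircn("paired = TRUE but data are not one sample per patient per group",
                  "paircn_validation_error")
    }
    ord1 <- order(exposures[[patient_col]][grp == levels(grp)[1]])
    ord2 <- order(exposures[[patient_col]][grp == levels(grp)[2]])
  }
  res <- lapply(sig_cols, function(sc) {
    x <- exposures[[sc]][grp == levels(grp)[1]]
    y <- exposures[[sc]][grp == levels(grp)[2]]
    if (paired) {
      x <- x[ord1]
      y <- y[ord2]
      if (all(abs(x - y) < 1e-12)) {
        stat <- 0; pv <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
        stat <- unname(wt$statistic); pv <- wt$p.value
      }
      method <- "wilcoxon-signed-rank"
    } else {
      if (max(c(x, y)) - min(c(x, y)) < 1e-12) {
        stat <- length(x) * length(y) / 2; pv <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
        stat <- unname(wt$statistic); pv <- wt$p.value
      }
      method <- "mann-whitney"
    }
    tibble(label = sc, statistic = stat, p = pv,
           n1 = length(x), n2 = length(y), method = method)
  }) |> list_rbind()
  mutate(res, q = p.adjust(.data$p, method = adjust), .after = "p")
}

#' Correlate signature exposures with immune cell densities
#'
#' Kendall tau and Spearman rho (two-sided, unadjusted) between each
#' signature's exposure and each immune marker density, per tissue
#' compartment. Constant vectors make the correlation undefined; such
#' combinations are reported with `NA` estimates.
#'
#' @param exposures Tibble with `sample_id` and signature columns.
#' @param densities Tibble `sample_id`, `marker` (e.g. CD3/CD8),
#'   `compartment` (e.g. tumour/stroma), `density`.
#' @param sig_cols Signature columns (default: matching `^s[0-9]+$`).
#' @return Tibble `signature`, `marker`, `compartment`, `kendall_tau`,
#'   `kendall_p`, `spearman_rho`, `spearman_p`, `n`.
#' @export
correlate_exposures_immune <- function(exposures, densities, sig_cols = NULL) {
  if (is.null(sig_cols)) {
    sig_cols <- grep("^s[0-9]+$", names(exposures), value = TRUE)
  }
  stopifnot(all(c("sample_id", "marker", "compartment", "density") %in%
                  names(densities)))
  joined <- inner_join(densities, exposures, by = "sample_id")
  combos <- distinct(joined, .data$marker, .data$compartment)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- joined[joined$marker == combos$marker[i] &
                    joined$compartment == combos$compartment[i], , drop = FALSE]
    lapply(sig_cols, function(sc) {
      ok <- complete.cases(sub$density, sub[[sc]])
      x <- sub[[sc]][ok]
      y <- sub$density[ok]
      n <- length(x)
      if (n < 3 || sd(x) == 0 || sd(y) == 0) {
        return(tibble(signature = sc, marker = combos$marker[i],
                      compartment = combos$compartment[i],
                      kendall_tau = NA_real_, kendall_p = NA_real_,
                      spearman_rho = NA_real_, spearman_p = NA_real_, n = n))
      }
      kt <- suppressWarnings(cor.test(x, y, method = "kendall"))
      sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
      tibble(signature = sc, marker = combos$marker[i],
             compartment = combos$compartment[i],
             kendall_tau = unname(kt$estimate), kendall_p = kt$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             n = n)
    }) |> list_rbind()
  }) |> list_rbind()
  res
}
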