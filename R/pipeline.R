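#' Run the full copy-number analysis pipeline on a simulated cohort
#'
#' Orchestrates the analysis end to end: simulate a paired cohort, fit every
#' sample to absolute copy number, quantify signature exposures, score
#' intra-tumour heterogeneity, run the paired genome subtraction, call focal
#' gene events with Fisher comparisons, and test global signature abundance.
#' Every stage writes its table under `out_dir`, a JSON summary records
#' seeds, QC pass counts and all test results, and the run is deterministic
#' given the configuration's seed (re-running reproduces byte-identical
#' outputs).
#'
#' @param config Configuration list or YAML path; see [validate_run_config()]
#'   for keys. The `cohort` sub-list is passed to [simulate_paired_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(paste0(..., "\n"), file = logf, append = TRUE)
  }
  cat("", file = logf)
  summary <- list(seed = cfg$seed, config = cfg[setdiff(names(cfg), "cohort")],
                  stages = list())
  log_line("stage simulate: n_patients=", cfg$n_patients, " seed=", cfg$seed)
  layout <- genome_layout(cfg$genome, bin_size = cfg$bin_size)
  cohort <- simulate_paired_cohort(cfg$n_patients, layout = layout,
                                   config = cfg$cohort, seed = cfg$seed)
  write_clinical(cohort$clinical, file.path(out_dir, "clinical.csv"))
  truth_tab <- select(cohort$truth, -"segments")
  write_table_generic(truth_tab, file.path(out_dir, "truth.tsv"),
                      c("purity", "ploidy", "depth", paste0("s", 1:7)))

  log_line("stage fit: ", nrow(cohort$truth), " samples")
  fits <- purrr::map(split(cohort$counts, cohort$counts$sample_id),
                     function(s) call_absolute(s, penalty = cfg$penalty))
  fits <- fits[unique(cohort$counts$sample_id)]
  fit_tab <- imap(fits, function(f, sid) {
    tibble(sample_id = sid, purity = f$purity, ploidy = f$ploidy,
           score = f$qc$score, frac_integer = f$qc$frac_integer,
           qc_pass = f$qc$pass)
  }) |> list_rbind()
  write_table_generic(fit_tab, file.path(out_dir, "fits.tsv"),
                      c("purity", "ploidy", "score", "frac_integer"))
  seg_long <- imap(fits, function(f, sid) {
    mutate(f$segments, sample_id = sid, .before = 1)
  }) |> list_rbind()
  write_segments(seg_long, file.path(out_dir, "segments.tsv"))
  summary$stages$fit <- list(n_samples = length(fits),
                             qc_pass = sum(fit_tab$qc_pass))

  log_line("stage signatures")
  defs <- calibrate_signature_definitions(layout, n_train = cfg$calibration_n,
                                          seed = cfg$seed)
  write_signature_definitions(defs, file.path(out_dir, "signature_definitions.tsv"))
  profiles <- tibble(sample_id = names(fits),
                     segments = purrr::map(fits, "segments"))
  exposures <- compute_exposures(profiles, layout, defs)
  meta <- select(cohort$truth, "sample_id", "patient_id", "role")
  exposures <- left_join(exposures, meta, by = "sample_id")
  write_exposures(exposures, file.path(out_dir, "exposures.tsv"))

  log_line("stage ith")
  ith <- tibble(sample_id = names(fits),
                ith = map_dbl(fits, compute_ith)) |>
    left_join(meta, by = "sample_id")
  delta <- compute_delta_ith(ith)
  write_table_generic(ith, file.path(out_dir, "ith.tsv"), "ith")
  write_table_generic(delta, file.path(out_dir, "ith_paired.tsv"),
                      c("ith_diagnosis", "ith_relapse", "delta_ith"))

  log_line("stage subtraction")
  sub_in <- left_join(seg_long, meta, by = "sample_id")
  subtraction <- subtract_pairs(sub_in, layout, alpha = cfg$alpha)
  write_table_generic(as_tibble(subtraction), file.path(out_dir, "subtraction.tsv"),
                      c("start", "end", "median_diff", "p", "q"))
  summary$stages$subtraction <- list(
    n_bins = nrow(subtraction),
    n_significant = sum(subtraction$significant, na.rm = TRUE))

  log_line("stage gene events")
  panel <- simulate_gene_panel(layout, seed = cfg$seed)
  events <- imap(fits, function(f, sid) {
    mutate(call_gene_events(f, panel, amp_min = cfg$amp_min,
                            amp_ploidy_mult = cfg$amp_ploidy_mult,
                            del_offset = cfg$del_offset),
           sample_id = sid, .before = 1)
  }) |> list_rbind() |> left_join(meta, by = "sample_id")
  write_table_generic(events, file.path(out_dir, "gene_events.tsv"),
                      c("cn", "ploidy"))
  fisher <- compare_event_rates(events, "role")
  write_table_generic(fisher, file.path(out_dir, "fisher_amplification.tsv"),
                      c("estimate", "p", "q"))

  log_line("stage composition test")
  comp <- tryCatch(
    fit_global_abundance_model(exposures, group_col = "role",
                               exclude = cfg$exclude_signatures,
                               eps = cfg$eps),
    error = function(e) {
      log_line("composition test failed: ", conditionMessage(e))
      NULL
    })
  univ <- compare_exposures_univariate(exposures, "role", paired = TRUE)
  write_table_generic(univ, file.path(out_dir, "signature_tests.tsv"),
                      c("statistic", "p", "q"))
  summary$stages$composition <- if (is.null(comp)) {
    list(status = "failed")
  } else {
    list(wald = comp$wald$statistic, p = comp$wald$p.value, engine = comp$engine)
  }
  summary$tests <- list(
    fisher_amplified = fisher[, c("label", "p", "q")],
    signature_univariate = univ[, c("label", "p", "q")])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(list(cohort = cohort, fits = fits, exposures = exposures,
                 ith = delta, subtraction = subtraction, events = events,
                 fisher = fisher, composition = comp, summary = summary))
}
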