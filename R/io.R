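#' Read and write the package's tabular formats
#'
#' All genomic tables use 0-based, half-open coordinates (BED convention) and
#' tab separation; clinical tables are CSV. Readers validate strictly and
#' report offending data lines by number (line 1 is the header, so the first
#' data row is line 2). Writers serialise floating-point columns at 6
#' significant digits; write-then-read round-trips reproduce the canonical
#' table.
#'
#' @param path File path.
#' @param x Table to write.
#' @name paircn_io
NULL

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x == round(x) & abs(x) < 1e15,
                format(x, scientific = FALSE, trim = TRUE),
                formatC(signif(x, 6), format = "fg", flag = "#")))
}

write_table_generic <- function(x, path, num_cols, sep = "\t") {
  out <- as.data.frame(x)
  for (cc in intersect(num_cols, names(out))) out[[cc]] <- fmt_num(out[[cc]])
  readr::write_delim(out, path, delim = sep, na = "NA")
  invisible(path)
}

validation_fail <- function(path, rows, why) {
  lines <- paste(rows + 1, collapse = ", ")
  stop_paircn(paste0("invalid table ", path, ": ", why, " (line ", lines, ")"),
              "paircn_schema_error")
}

check_columns <- function(x, needed, path) {
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop_paircn(paste0("invalid table ", path, ": missing column(s) ",
                       paste(missing, collapse = ", ")),
                "paircn_schema_error")
  }
}

check_intervals <- function(x, path, sorted = TRUE) {
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$end <= x$start)
  if (length(bad) > 0) validation_fail(path, bad, "end <= start")
  if (sorted) {
    unsorted <- x |>
      group_by(.data$chrom) |>
      mutate(bad = .data$start < lag(.data$start, default = -Inf)) |>
      pull(.data$bad)
    if (any(unsorted)) {
      validation_fail(path, which(unsorted), "intervals not sorted by start")
    }
  }
}

#' @rdname paircn_io
#' @export
read_binned_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("chrom", "start", "end", "gc", "mappability", "count"), path)
  check_intervals(x, path)
  bad <- which(x$gc < 0 | x$gc > 1 | x$mappability < 0 | x$mappability > 1)
  if (length(bad) > 0) validation_fail(path, bad, "gc/mappability outside [0,1]")
  bad <- which(x$count < 0)
  if (length(bad) > 0) validation_fail(path, bad, "negative count")
  x
}

#' @rdname paircn_io
#' @export
write_binned_counts <- function(x, path) {
  write_table_generic(x, path, c("start", "end", "gc", "mappability", "count"))
}

#' @rdname paircn_io
#' @export
read_segments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  vcol <- intersect(c("value", "cn"), names(x))
  if (length(vcol) == 0) {
    stop_paircn(paste0("invalid table ", path, ": missing column(s) value/cn"),
                "paircn_schema_error")
  }
  check_columns(x, c("chrom", "start", "end"), path)
  check_intervals(x, path)
  x
}

#' @rdname paircn_io
#' @export
write_segments <- function(x, path) {
  write_table_generic(x, path, c("start", "end", "value", "cn", "n_bins"))
}

#' @rdname paircn_io
#' @export
read_exposures <- function(path, tol = 1e-6) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, "sample_id", path)
  sig_cols <- grep("^s[0-9]+$", names(x), value = TRUE)
  if (length(sig_cols) < 2) {
    stop_paircn(paste0("invalid table ", path, ": no signature columns (s1, s2, ...)"),
                "paircn_schema_error")
  }
  E <- as.matrix(x[, sig_cols])
  bad <- which(abs(rowSums(E) - 1) > tol | apply(E, 1, min) < 0)
  if (length(bad) > 0) {
    validation_fail(path, bad,
                    "exposures must be non-negative and sum to 1 (simplex invariant)")
  }
  x
}

#' @rdname paircn_io
#' @export
write_exposures <- function(x, path) {
  sig_cols <- grep("^s[0-9]+$", names(x), value = TRUE)
  out <- as.data.frame(x)
  # 8 decimals so that row sums survive the round trip within the 1e-6
  # simplex tolerance
  for (cc in c(sig_cols, "residual")) {
    if (cc %in% names(out)) out[[cc]] <- formatC(out[[cc]], digits = 8, format = "f")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname paircn_io
#' @export
read_clinical <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, "patient_id", path)
  if ("platinum_status" %in% names(x)) {
    bad <- which(!x$platinum_status %in% c("sensitive", "resistant"))
    if (length(bad) > 0) {
      validation_fail(path, bad, "platinum_status must be sensitive/resistant")
    }
  }
  x
}

#' @rdname paircn_io
#' @export
write_clinical <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname paircn_io
#' @export
read_gene_panel <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                       show_col_types = FALSE, progress = FALSE, comment = "#")
  if (is.character(x$start)) {
    # header present
    x <- x[-1, ]
    x$start <- as.numeric(x$start)
    x$end <- as.numeric(x$end)
  }
  check_intervals(x, path, sorted = FALSE)
  x
}

#' @rdname paircn_io
#' @export
read_signature_definitions <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  S <- as.matrix(x[, -1])
  rownames(S) <- x[[1]]
  if (any(S < 0) || any(abs(colSums(S) - 1) > 1e-6)) {
    stop_paircn(paste0("invalid definitions ", path,
                       ": columns must be non-negative and sum to 1"),
                "paircn_schema_error")
  }
  S
}

#' @rdname paircn_io
#' @export
write_signature_definitions <- function(x, path) {
  df <- data.frame(component = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks a pipeline configuration list (or YAML file) against the known keys
#' and their documented ranges before anything runs. Unknown keys are
#' rejected with a message listing the offenders.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated configuration (invisibly usable downstream).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    n_patients = 8, seed = 1, genome = "toy", bin_size = 30000,
    alpha = 0.05, eps = 1e-3, penalty = 4,
    amp_min = 5, amp_ploidy_mult = 2, del_offset = 1.87,
    ploidy_change_threshold = 0.5, exclude_signatures = NULL,
    calibration_n = 40, cohort = list()
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_paircn(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
                "paircn_config_error")
  }
  cfg <- defaults
  cfg[names(config)] <- config
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop_paircn("alpha must lie in (0, 1)", "paircn_config_error")
  }
  if (cfg$eps <= 0 || cfg$eps >= 0.1) {
    stop_paircn("eps must lie in (0, 0.1)", "paircn_config_error")
  }
  if (cfg$penalty <= 0) stop_paircn("penalty must be > 0", "paircn_config_error")
  if (cfg$n_patients < 1) stop_paircn("n_patients must be >= 1", "paircn_config_error")
  cfg
}
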