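#' Simulate a column-stochastic signature-definition matrix
#'
#' Draws a synthetic stand-in for a fixed copy-number signature definition
#' matrix: `n_components` feature components by `n_signatures` signatures,
#' columns non-negative and summing to 1, with full column rank. Entries are
#' drawn from a sparse gamma so each signature loads on a distinct subset of
#' components, mimicking the shape of published definitions. Users with real,
#' externally derived definitions can supply them anywhere a definitions
#' matrix is accepted (see [read_signature_definitions()]).
#'
#' @param n_components Number of feature components (rows), `>= n_signatures`.
#' @param n_signatures Number of signatures (columns), `>= 2`.
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @param identity If `TRUE` (requires `n_components == n_signatures`),
#'   returns the identity matrix, which makes exposures directly readable
#'   from encoded samples — convenient for tests.
#' @param max_tries Retry budget for rank-deficient draws.
#' @return A numeric matrix with rownames `c1..cK` and colnames `s1..sN`.
#' @examples
#' S <- simulate_signature_definitions(36, 7, seed = 1)
#' colSums(S)
#' @export
simulate_signature_definitions <- function(n_components, n_signatures,
                                           seed = 1, identity = FALSE,
                                           max_tries = 20) {
  if (n_signatures < 2 || n_components < n_signatures) {
    stop_paircn("need n_components >= n_signatures >= 2", "paircn_config_error")
  }
  if (identity) {
    if (n_components != n_signatures) {
      stop_paircn("identity definitions need n_components == n_signatures",
                  "paircn_config_error")
    }
    S <- diag(n_signatures)
  } else {
    S <- NULL
    with_seed(seed, {
      for (i in seq_len(max_tries)) {
        M <- matrix(rgamma(n_components * n_signatures, shape = 0.35, rate = 1),
                    n_components, n_signatures)
        M <- sweep(M, 2, colSums(M), "/")
        if (qr(M)$rank == n_signatures) {
          S <- M
          break
        }
      }
    })
    if (is.null(S)) {
      stop_paircn("could not draw a full-rank definitions matrix",
                  "paircn_generation_error")
    }
  }
  dimnames(S) <- list(paste0("c", seq_len(n_components)),
                      paste0("s", seq_len(n_signatures)))
  S
}

# Event-class semantics attached to each of the seven signatures. The classes
# are chosen so that concentrating exposure on a signature produces a
# recognisable contrast in the six copy-number features: s1 few, large
# events; s3 arm-scale losses; s4 high-level focal amplification; s5
# chromothriptic-like shattering; s7 oscillating chains; s2/s6 intermediate
# gains at different scales.
sig_event_class <- function(j) {
  switch(j,
    "large_gain_loss", # s1: 20-60 Mb single-copy change, mostly gains
    "mid_gain",        # s2: 2-6 Mb two-copy gain
    "arm_loss",        # s3: whole-arm single-copy loss
    "focal_amp_high",  # s4: 0.3-2 Mb amplification (+5..+8)
    "shatter",         # s5: 8-20 Mb window with many +/-1 breakpoints
    "focal_gain",      # s6: 0.5-2 Mb three-copy gain
    "oscillate"        # s7: long chain of alternating +2 segments
  )
}

#' Simulate a signature-driven integer copy-number profile
#'
#' Generates an integer copy-number tiling of the genome by applying
#' `event_budget` structural events to a flat baseline. Event classes are
#' drawn with probability proportional to the supplied signature exposures;
#' each of the seven signatures maps to a distinct event style (arm-scale
#' gains/losses, focal amplification, oscillating chains, chromothriptic-like
#' shattering, ...), so the exposure vector shapes the resulting feature
#' distributions. Copy numbers are clipped at 0; the number of clipped bins
#' is reported in the `clipped_bins` attribute.
#'
#' @param layout A [genome_layout()].
#' @param exposures Length-7 non-negative vector summing to 1.
#' @param event_budget Number of events to apply (`>= 0`); 0 gives a flat
#'   genome at `baseline_ploidy`.
#' @param baseline_ploidy Integer baseline copy number (default 2).
#' @param anchor_deletion Plant one focal homozygous deletion (0.8-1.6 Mb at
#'   copy number 0) per genome (default `TRUE`). Tumour-suppressor
#'   homozygous deletions are near-universal in high-grade serous carcinoma,
#'   and a zero-copy segment anchors the absolute scale: without any
#'   low-copy state a relative profile cannot distinguish the true fit from
#'   one with every state shifted by an integer.
#' @param seed Integer seed.
#' @return A tibble of segments (`chrom`, `start`, `end`, `cn`) that tile the
#'   genome exactly, with integer `cn >= 0`.
#' @examples
#' seg <- simulate_cn_profile(genome_layout("toy"), rep(1 / 7, 7),
#'                            event_budget = 10, seed = 1)
#' seg
#' @export
simulate_cn_profile <- function(layout, exposures, event_budget = 20,
                                baseline_ploidy = 2, anchor_deletion = TRUE,
                                seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  check_simplex(exposures, n = 7, what = "exposures")
  if (event_budget < 0) {
    stop_paircn("event_budget must be >= 0", "paircn_config_error")
  }
  bs <- layout$bin_size
  chroms <- layout$chromosomes
  nbin <- ceiling(chroms$length / bs)
  cn <- lapply(nbin, function(n) rep(as.integer(baseline_ploidy), n))
  names(cn) <- chroms$chrom
  clipped <- 0L
  with_seed(seed, {
    if (event_budget > 0) {
      classes <- sample.int(7, event_budget, replace = TRUE, prob = exposures)
      for (j in classes) {
        ci <- sample.int(nrow(chroms), 1)
        n <- nbin[ci]
        cent_bin <- max(1L, min(n, ceiling(chroms$centromere[ci] / bs)))
        v <- cn[[ci]]
        cls <- sig_event_class(j)
        if (cls == "large_gain_loss") {
          len <- round(runif(1, 20e6, 60e6) / bs)
          len <- min(len, n)
          s <- sample.int(n - len + 1L, 1)
          delta <- sample(c(1L, -1L), 1, prob = c(0.75, 0.25))
          idx <- s:(s + len - 1L)
          # arm/large-scale losses bottom out at one copy: whole-region
          # homozygous loss is not a viable genome
          v[idx] <- if (delta < 0) pmax(v[idx] + delta, 1L) else v[idx] + delta
        } else if (cls == "mid_gain") {
          len <- max(2L, round(runif(1, 2e6, 6e6) / bs))
          len <- min(len, n)
          s <- sample.int(n - len + 1L, 1)
          v[s:(s + len - 1L)] <- v[s:(s + len - 1L)] + 2L
        } else if (cls == "arm_loss") {
          if (runif(1) < 0.5) idx <- seq_len(cent_bin) else idx <- seq(cent_bin + 1L, n)
          v[idx] <- pmax(v[idx] - 1L, 1L)
        } else if (cls == "focal_amp_high") {
          len <- max(2L, round(runif(1, 3e5, 2e6) / bs))
          len <- min(len, n)
          s <- sample.int(n - len + 1L, 1)
          v[s:(s + len - 1L)] <- v[s:(s + len - 1L)] + sample(5:8, 1)
        } else if (cls == "focal_gain") {
          len <- max(2L, round(runif(1, 5e5, 2e6) / bs))
          len <- min(len, n)
          s <- sample.int(n - len + 1L, 1)
          v[s:(s + len - 1L)] <- v[s:(s + len - 1L)] + 3L
        } else if (cls == "shatter") {
          len <- round(runif(1, 8e6, 20e6) / bs)
          len <- min(len, n)
          s <- sample.int(n - len + 1L, 1)
          k <- sample(6:12, 1)
          cuts <- sort(sample.int(len - 1L, min(k, len - 1L)))
          bounds <- c(0L, cuts, len)
          for (p in seq_len(length(bounds) - 1L)) {
            idx <- (s + bounds[p]):(s + bounds[p + 1L] - 1L)
            v[idx] <- v[idx] + sample(c(-1L, 0L, 1L), 1)
          }
        } else if (cls == "oscillate") {
          nseg <- sample(seq(7L, 13L, by = 2L), 1)
          seglen <- max(2L, round(runif(1, 3e5, 8e5) / bs))
          total <- nseg * seglen
          if (total < n) {
            s <- sample.int(n - total + 1L, 1)
            for (p in seq_len(nseg)) {
              if (p %% 2L == 1L) {
                idx <- (s + (p - 1L) * seglen):(s + p * seglen - 1L)
                v[idx] <- v[idx] + 2L
              }
            }
          }
        }
        clipped <- clipped + sum(v < 0L)
        v[v < 0L] <- 0L
        cn[[ci]] <- v
      }
    }
    if (anchor_deletion) {
      ci <- sample.int(nrow(chroms), 1)
      n <- nbin[ci]
      len <- max(2L, round(runif(1, 8e5, 1.6e6) / bs))
      s <- sample.int(n - len + 1L, 1)
      cn[[ci]][s:(s + len - 1L)] <- 0L
    }
  })
  if (clipped > 0) {
    inform(paste0(clipped, " bin(s) clipped at copy number 0"))
  }
  segs <- imap(cn, function(v, chrom) {
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0L, head(ends_bin, -1L))
    chr_len <- chroms$length[chroms$chrom == chrom]
    tibble(chrom = chrom,
           start = starts_bin * bs,
           end = pmin(ends_bin * bs, chr_len),
           cn = as.numeric(r$values))
  }) |> list_rbind()
  attr(segs, "clipped_bins") <- clipped
  segs
}

#' Derive a relapse genome from a diagnosis genome
#'
#' Produces the relapse member of a pair from a diagnosis segment profile
#' under a declared perturbation: `"none"` copies the genome unchanged (the
#' stable-genome null), `"planted_region"` adds `delta` copies to a declared
#' interval (for testing subtraction analyses against a known truth), and
#' `"ploidy_shift"` doubles every copy-number state (a whole-genome
#' duplication).
#'
#' @param segments Diagnosis segments (`chrom`, `start`, `end`, `cn`).
#' @param layout The [genome_layout()] the segments live on.
#' @param perturbation One of `"none"`, `"planted_region"`, `"ploidy_shift"`.
#' @param region For `"planted_region"`: a list or one-row data frame with
#'   `chrom`, `start`, `end`.
#' @param delta Copy-number change applied to the planted region (may be
#'   negative; states are clipped at 0).
#' @return A relapse segment tibble in the same format.
#' @export
derive_relapse <- function(segments, layout,
                           perturbation = c("none", "planted_region", "ploidy_shift"),
                           region = NULL, delta = 2) {
  perturbation <- match.arg(perturbation)
  check_segments(segments)
  if (perturbation == "none") {
    return(segments)
  }
  if (perturbation == "ploidy_shift") {
    out <- segments
    out$cn <- out$cn * 2
    return(out)
  }
  if (is.null(region)) {
    stop_paircn("planted_region perturbation needs `region`", "paircn_config_error")
  }
  region <- as.list(as.data.frame(region))
  chroms <- layout$chromosomes
  ci <- match(region$chrom, chroms$chrom)
  if (is.na(ci) || region$start < 0 || region$end > chroms$length[ci] ||
      region$end <= region$start) {
    stop_paircn("planted region lies outside the genome", "paircn_region_error")
  }
  pieces <- purrr::pmap(segments, function(chrom, start, end, cn) {
    if (chrom != region$chrom || end <= region$start || start >= region$end) {
      return(tibble(chrom = chrom, start = start, end = end, cn = cn))
    }
    cuts <- sort(unique(c(start, end, max(start, region$start), min(end, region$end))))
    tibble(chrom = chrom, start = head(cuts, -1), end = cuts[-1], cn = cn) |>
      mutate(cn = ifelse(.data$start >= region$start & .data$end <= region$end,
                         pmax(cn + delta, 0), cn))
  })
  out <- list_rbind(pieces) |>
    arrange(match(.data$chrom, chroms$chrom), .data$start)
  merge_equal_segments(out)
}

# Merge adjacent segments with identical values (used after perturbation and
# after integer rounding in feature extraction).
merge_equal_segments <- function(segments, value_col = "cn") {
  if (nrow(segments) <= 1) return(segments)
  v <- segments[[value_col]]
  new_run <- c(TRUE, segments$chrom[-1] != segments$chrom[-nrow(segments)] |
                 v[-1] != v[-nrow(segments)] |
                 segments$start[-1] != segments$end[-nrow(segments)])
  run <- cumsum(new_run)
  segments |>
    mutate(.run = run) |>
    group_by(.data$.run) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
              across(all_of(value_col), ~ .x[1]), .groups = "drop") |>
    select(-".run")
}

#' Emit binned read counts for a tumour genome
#'
#' Simulates shallow whole-genome sequencing read counts on the bin grid from
#' an integer copy-number genome mixed with diploid non-tumour cells. The
#' expected count of a bin with tumour copy number \eqn{n} is
#' \deqn{\mu = d \cdot \frac{\rho n + 2(1-\rho)}{\rho \psi + 2(1-\rho)}
#'   \cdot b_{gc} \cdot m}
#' where \eqn{\rho} is purity, \eqn{\psi} the tumour ploidy (length-weighted
#' mean copy number of `segments`), \eqn{d} the mean reads per bin,
#' \eqn{b_{gc}} a unimodal GC bias factor and \eqn{m} the bin mappability.
#' Counts are drawn Poisson (`noise = "poisson"`), negative binomial with the
#' given `dispersion` (`"nbinom"`), or returned as exact expectations
#' (`"none"`, for noiseless recovery experiments). The default depth of 60
#' reads per 30 kb bin corresponds to a 0.1x coverage target with 50 bp
#' single-end reads.
#'
#' @param segments Integer copy-number segments (`chrom`, `start`, `end`, `cn`).
#' @param bins Annotated bin grid from [layout_bins()].
#' @param purity Tumour fraction in (0, 1].
#' @param depth Mean reads per bin (> 0).
#' @param noise `"poisson"`, `"nbinom"`, or `"none"`.
#' @param dispersion Negative-binomial dispersion (1/size); only used for
#'   `noise = "nbinom"`; 0 recovers the Poisson limit.
#' @param gc_strength Strength of the quadratic GC bias (0 disables it).
#' @param seed Integer seed.
#' @return The bin tibble with a `count` column appended.
#' @export
emit_binned_counts <- function(segments, bins, purity, depth = 60,
                               noise = c("poisson", "nbinom", "none"),
                               dispersion = 0.05, gc_strength = 0.3, seed = 1) {
  noise <- match.arg(noise)
  if (depth <= 0) stop_paircn("depth must be > 0", "paircn_config_error")
  if (purity <= 0 || purity > 1) {
    stop_paircn("purity must lie in (0, 1]", "paircn_config_error")
  }
  check_segments(segments)
  cn_bin <- segments_to_bins(segments, bins, value_col = "cn")
  psi <- weighted.mean(segments$cn, segments$end - segments$start)
  mix <- (purity * cn_bin + 2 * (1 - purity)) /
    (purity * psi + 2 * (1 - purity))
  gc_bias <- 1 - 4 * gc_strength * (bins$gc - 0.45)^2
  gc_bias <- pmax(gc_bias, 0.05)
  mu <- depth * mix * gc_bias * bins$mappability
  out <- bins
  if (noise == "none") {
    out$count <- mu
  } else if (noise == "poisson" || dispersion <= 0) {
    out$count <- with_seed(seed, rpois(length(mu), mu))
  } else {
    out$count <- with_seed(seed, rnbinom(length(mu), mu = mu, size = 1 / dispersion))
  }
  out
}

# Length-weighted projection of a segment value onto the bin grid.
segments_to_bins <- function(segments, bins, value_col = "cn") {
  out <- rep(NA_real_, nrow(bins))
  for (ch in unique(segments$chrom)) {
    sb <- bins$chrom == ch
    ss <- segments[segments$chrom == ch, , drop = FALSE]
    mid <- (bins$start[sb] + bins$end[sb]) / 2
    idx <- findInterval(mid, ss$start)
    idx[idx < 1] <- 1L
    idx[idx > nrow(ss)] <- nrow(ss)
    out[sb] <- ss[[value_col]][idx]
  }
  out
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

check_simplex <- function(x, n = NULL, what = "vector", tol = 1e-6) {
  if (!is.null(n) && length(x) != n) {
    stop_paircn(paste0(what, " must have length ", n), "paircn_config_error")
  }
  if (any(x < 0) || abs(sum(x) - 1) > tol) {
    stop_paircn(paste0(what, " must be non-negative and sum to 1"),
                "paircn_validation_error")
  }
  invisible(x)
}

check_segments <- function(segments) {
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(segments))) {
    stop_paircn("segments need columns chrom, start, end", "paircn_validation_error")
  }
  if (any(segments$end <= segments$start)) {
    stop_paircn("segments must have end > start", "paircn_validation_error")
  }
  invisible(segments)
}

default_cohort_config <- function() {
  list(
    depth = 60,
    noise = "poisson",
    dispersion = 0.05,
    gc_strength = 0.3,
    event_budget = 20,
    baseline_ploidy_probs = c(`2` = 0.6, `3` = 0.25, `4` = 0.15),
    purity_range = c(0.2, 1.0),
    # sub-1 concentration: real tumours are dominated by one or two
    # mutational processes, so exposure vectors are sparse
    exposure_alpha = rep(0.7, 7),
    perturbation = "none",
    region = NULL,
    delta = 2,
    resistant_fraction = 0.24,
    primary_resistant_fraction = 0.1,
    brca_mutant_fraction = 0.2,
    prior_lines_probs = c(0.605, 0.246, 0.072, 0.029, 0.048),
    tissue_probs = c(abdominal = 0.25, `lymph node` = 0.20, pelvic = 0.25,
                     peritoneal = 0.20, other = 0.10)
  )
}

#' Simulate a paired diagnosis/relapse cohort
#'
#' Generates a full synthetic cohort with known ground truth: per patient one
#' diagnosis and one relapse sample, each with a known purity, signature
#' exposure vector, integer copy-number genome, binned read counts, and a
#' clinical record. Clinical labels follow the platinum-interval rule:
#' a patient is platinum-resistant iff the relapse interval since last
#' platinum chemotherapy is under 6 months; primary platinum resistance means
#' relapse under 6 months after first-line treatment.
#'
#' The default cohort shape mirrors a relapsed high-grade serous carcinoma
#' study population: purities 0.4-1.0, baseline ploidies 2-4, ~0.1x coverage
#' (60 reads per 30 kb bin), ~24% platinum-resistant and ~10% primary
#' platinum-resistant patients.
#'
#' @param n_patients Number of patients (`>= 1`).
#' @param layout A [genome_layout()] (default toy genome).
#' @param config Named list overriding the default generator configuration;
#'   unknown keys raise an error listing the offenders. Keys include `depth`,
#'   `noise`, `dispersion`, `gc_strength`, `event_budget`,
#'   `baseline_ploidy_probs`, `purity_range`, `exposure_alpha`,
#'   `perturbation` (applied to every relapse genome), `region`, `delta`,
#'   `resistant_fraction`, `primary_resistant_fraction`,
#'   `brca_mutant_fraction`, `prior_lines_probs`, `tissue_probs`.
#' @param seed Integer seed; the whole cohort is deterministic given the seed.
#' @return A `paired_cohort` list with elements `counts` (long bin tibble
#'   with `sample_id`, `patient_id`, `role`), `truth` (per-sample tibble with
#'   purity, ploidy, depth, exposures `s1..s7` and a `segments` list-column),
#'   `clinical` (per-patient tibble), `bins`, `layout`, `config`.
#' @export
simulate_paired_cohort <- function(n_patients, layout = genome_layout("toy"),
                                   config = list(), seed = 1) {
  if (n_patients < 1) stop_paircn("n_patients must be >= 1", "paircn_config_error")
  cfg <- default_cohort_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0) {
    stop_paircn(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
                "paircn_config_error")
  }
  cfg[names(config)] <- config
  bins <- layout_bins(layout, seed = child_seed(seed, 1))
  pat_ids <- sprintf("PT%03d", seq_len(n_patients))

  draws <- with_seed(child_seed(seed, 2), {
    list(
      purity_dx = runif(n_patients, cfg$purity_range[1], cfg$purity_range[2]),
      purity_rel = runif(n_patients, cfg$purity_range[1], cfg$purity_range[2]),
      baseline = as.integer(sample(names(cfg$baseline_ploidy_probs), n_patients,
                                   replace = TRUE, prob = cfg$baseline_ploidy_probs)),
      exposures = t(vapply(seq_len(n_patients),
                           function(i) rdirichlet1(cfg$exposure_alpha),
                           numeric(7))),
      primary_resistant = runif(n_patients) < cfg$primary_resistant_fraction,
      resistant_extra = runif(n_patients),
      interval_res = runif(n_patients, 1, 5.9),
      interval_sens = pmax(6, rlnorm(n_patients, log(14), 0.5)),
      prior_lines = sample.int(5, n_patients, replace = TRUE,
                               prob = cfg$prior_lines_probs),
      diag_to_reg = rlnorm(n_patients, log(31.5), 0.6),
      tissue = sample(names(cfg$tissue_probs), n_patients, replace = TRUE,
                      prob = cfg$tissue_probs),
      brca = ifelse(runif(n_patients) < cfg$brca_mutant_fraction,
                    "mutant", "wildtype")
    )
  })
  # primary-resistant patients are a subset of the resistant patients
  p_extra <- max(0, (cfg$resistant_fraction - cfg$primary_resistant_fraction) /
                   max(1e-12, 1 - cfg$primary_resistant_fraction))
  resistant <- draws$primary_resistant | draws$resistant_extra < p_extra
  interval <- ifelse(resistant, draws$interval_res, draws$interval_sens)

  truth <- vector("list", 2 * n_patients)
  counts <- vector("list", 2 * n_patients)
  k <- 0
  for (i in seq_len(n_patients)) {
    e <- draws$exposures[i, ]
    seg_dx <- simulate_cn_profile(layout, e, event_budget = cfg$event_budget,
                                  baseline_ploidy = draws$baseline[i],
                                  seed = child_seed(seed, 100 + i))
    seg_rel <- derive_relapse(seg_dx, layout, perturbation = cfg$perturbation,
                              region = cfg$region, delta = cfg$delta)
    for (role in c("diagnosis", "relapse")) {
      k <- k + 1
      segs <- if (role == "diagnosis") seg_dx else seg_rel
      rho <- if (role == "diagnosis") draws$purity_dx[i] else draws$purity_rel[i]
      sid <- paste0(pat_ids[i], "_", substr(role, 1, 3))
      cts <- emit_binned_counts(segs, bins, purity = rho, depth = cfg$depth,
                                noise = cfg$noise, dispersion = cfg$dispersion,
                                gc_strength = cfg$gc_strength,
                                seed = child_seed(seed, 1000 + k))
      counts[[k]] <- mutate(cts, sample_id = sid, patient_id = pat_ids[i],
                            role = role, .before = 1)
      truth[[k]] <- tibble(
        sample_id = sid, patient_id = pat_ids[i], role = role,
        purity = rho,
        ploidy = weighted.mean(segs$cn, segs$end - segs$start),
        depth = cfg$depth,
        !!!setNames(as.list(e), paste0("s", 1:7)),
        segments = list(segs)
      )
    }
  }
  clinical <- tibble(
    patient_id = pat_ids,
    platinum_interval_months = interval,
    platinum_status = ifelse(interval < 6, "resistant", "sensitive"),
    primary_platinum_resistant = draws$primary_resistant,
    prior_lines = draws$prior_lines,
    diagnosis_to_registration = draws$diag_to_reg,
    tissue_site = draws$tissue,
    brca_status = draws$brca
  )
  structure(
    list(counts = list_rbind(counts), truth = list_rbind(truth),
         clinical = clinical, bins = bins, layout = layout, config = cfg),
    class = "paired_cohort"
  )
}

#' @export
#' @method print paired_cohort
print.paired_cohort <- function(x, ...) {
  cat("<paired_cohort> ", nrow(x$clinical), " patients, ",
      nrow(x$truth), " samples, ", nrow(x$bins), " bins\n", sep = "")
  invisible(x)
}

#' Simulate paired signature-exposure data
#'
#' Generates per-sample exposure vectors directly (without genomes), for
#' studying the compositional differential-abundance test: each patient has a
#' Dirichlet-drawn baseline composition, samples scatter around it with
#' logistic-normal noise, and the relapse group optionally receives an
#' absolute shift in one signature (added, then renormalised to the simplex).
#'
#' @param n_patients Number of patients; each contributes one diagnosis and
#'   one relapse sample.
#' @param shift_signature Index (1-7) of the signature shifted at relapse, or
#'   `NULL` for the null of no difference.
#' @param shift Absolute exposure shift planted at relapse (default 0).
#' @param alpha Dirichlet concentration for patient baselines.
#' @param sample_sd Logistic-normal within-patient noise (log scale).
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, `sample_id`, `role`, `s1..s7`.
#' @export
simulate_exposure_cohort <- function(n_patients, shift_signature = NULL,
                                     shift = 0, alpha = rep(1.5, 7),
                                     sample_sd = 0.3, seed = 1) {
  with_seed(seed, {
    rows <- vector("list", 2 * n_patients)
    k <- 0
    for (i in seq_len(n_patients)) {
      base <- rdirichlet1(alpha)
      for (role in c("diagnosis", "relapse")) {
        k <- k + 1
        z <- log(pmax(base, 1e-8)) + rnorm(7, 0, sample_sd)
        e <- exp(z) / sum(exp(z))
        if (role == "relapse" && !is.null(shift_signature) && shift != 0) {
          e[shift_signature] <- e[shift_signature] + shift
          e <- e / sum(e)
        }
        rows[[k]] <- tibble(
          patient_id = sprintf("PT%03d", i),
          sample_id = sprintf("PT%03d_%s", i, substr(role, 1, 3)),
          role = role,
          !!!setNames(as.list(e), paste0("s", 1:7))
        )
      }
    }
    list_rbind(rows)
  })
}

#' Simulate a focal gene panel on a layout
#'
#' Places `n_genes` gene-sized intervals (labelled with the names of genes
#' recurrently altered in high-grade serous carcinoma, for familiarity)
#' uniformly across the genome, avoiding centromeres. The panel is synthetic:
#' on the toy genome the coordinates have no biological meaning and the gene
#' names are labels only.
#'
#' @param layout A [genome_layout()].
#' @param n_genes Number of genes (default 18).
#' @param gene_size Interval width in bp (default 100 kb).
#' @param seed Integer seed.
#' @return Tibble `chrom`, `start`, `end`, `gene`.
#' @export
simulate_gene_panel <- function(layout, n_genes = 18, gene_size = 1e5, seed = 1) {
  hgsc_genes <- c("CCNE1", "KRAS", "MYC", "MECOM", "AKT1", "AKT2", "AKT3",
                  "BRCA1", "BRCA2", "NF1", "CCND2", "SIK2", "TP53", "RB1",
                  "PTEN", "PIK3CA", "TERT", "PAX8")
  gene_names <- if (n_genes <= length(hgsc_genes)) hgsc_genes[seq_len(n_genes)] else
    c(hgsc_genes, sprintf("GENE%02d", seq_len(n_genes - length(hgsc_genes))))
  chroms <- layout$chromosomes
  with_seed(seed, {
    ci <- sample.int(nrow(chroms), n_genes, replace = TRUE,
                     prob = chroms$length)
    start <- vapply(ci, function(j) {
      repeat {
        s <- runif(1, 0, chroms$length[j] - gene_size)
        if (abs(s - chroms$centromere[j]) > 2e6) return(floor(s))
      }
    }, numeric(1))
    tibble(chrom = chroms$chrom[ci], start = start, end = start + gene_size,
           gene = gene_names) |>
      arrange(match(.data$chrom, chroms$chrom), .data$start)
  })
}
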