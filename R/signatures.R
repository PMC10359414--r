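#' Default mixture-component model for copy-number features
#'
#' The component model discretises the six copy-number feature distributions
#' into mixture components; a sample is encoded as the vector of
#' sum-of-posterior-probabilities over components. This default is a
#' synthetic stand-in with the same shape as externally derived component
#' models: per feature a small set of Poisson (count features) or normal
#' (magnitude features; segment sizes on log10 bp) components spanning the
#' range the generator produces. Users may supply their own model in the same
#' format wherever a component model is accepted.
#'
#' @return A tibble with columns `component`, `feature`, `family`
#'   (`"poisson"` or `"norm"`), `p1` (lambda or mean), `p2` (sd, `NA` for
#'   Poisson) and `transform` (`"identity"` or `"log10"`).
#' @export
default_component_model <- function() {
  m <- bind_rows(
    tibble(feature = "segsize", family = "norm", transform = "log10",
           p1 = c(5.7, 6.4, 6.9, 7.45, 7.85),
           p2 = c(0.25, 0.22, 0.2, 0.18, 0.15)),
    tibble(feature = "changepoint", family = "norm", transform = "identity",
           p1 = c(1, 2, 3, 6), p2 = c(0.3, 0.32, 0.38, 1.2)),
    tibble(feature = "copynumber", family = "poisson", transform = "identity",
           p1 = c(1, 2, 3, 5, 8), p2 = NA_real_),
    tibble(feature = "bp10MB", family = "poisson", transform = "identity",
           p1 = c(0.05, 1, 4, 11), p2 = NA_real_),
    tibble(feature = "bpchrarm", family = "poisson", transform = "identity",
           p1 = c(0.5, 2.5, 7, 15), p2 = NA_real_),
    tibble(feature = "osc", family = "poisson", transform = "identity",
           p1 = c(0.5, 3, 8), p2 = NA_real_)
  )
  mutate(m, component = paste0("c", row_number()), .before = 1)
}

#' Extract the six copy-number feature distributions
#'
#' Computes the per-sample multisets of the six features that copy-number
#' signatures are built from:
#' segment size (bp); breakpoint count per 10 Mb window; copy-number
#' change-point magnitude between adjacent segments; segment copy-number
#' state (integer-rounded, capped at 10); breakpoint count per chromosome
#' arm; and lengths of oscillating chains (maximal runs of at least three
#' segments alternating between exactly two copy-number states). Segment
#' values are rounded to the nearest non-negative integer state first and
#' adjacent equal-state segments merged; breakpoints and chains are counted
#' within chromosome arms, so segments are split at centromeres.
#'
#' @param segments Absolute-space segments (`chrom`, `start`, `end` and a
#'   `value` or `cn` column), e.g. `fit$segments` from [fit_purity_ploidy()]
#'   or ground-truth segments from [simulate_cn_profile()].
#' @param layout The [genome_layout()] providing arm boundaries.
#' @return A long tibble `feature`, `value`.
#' @export
extract_features <- function(segments, layout) {
  check_segments(segments)
  vcol <- if ("value" %in% names(segments)) "value" else "cn"
  segs <- tibble(chrom = segments$chrom, start = segments$start,
                 end = segments$end, cn = nearest_state(segments[[vcol]]))
  segs$cn <- pmin(segs$cn, 10)
  segs <- split_by_arm(segs, layout)
  segs <- segs |>
    mutate(.armkey = paste(.data$chrom, .data$arm)) |>
    group_by(.data$.armkey) |>
    mutate(.run = cumsum(c(TRUE, diff(.data$cn) != 0))) |>
    group_by(.data$.armkey, .data$.run) |>
    summarise(chrom = .data$chrom[1], arm = .data$arm[1],
              start = min(.data$start), end = max(.data$end),
              cn = .data$cn[1], .groups = "drop") |>
    arrange(match(.data$chrom, layout$chromosomes$chrom), .data$start)

  by_arm <- split(segs, segs$.armkey)
  segsize <- segs$end - segs$start
  changepoint <- unlist(lapply(by_arm, function(a) abs(diff(a$cn))),
                        use.names = FALSE)
  copynumber <- segs$cn
  bpchrarm <- vapply(by_arm, function(a) nrow(a) - 1, numeric(1))
  # breakpoints per 10 Mb window (windows tile each chromosome)
  brk <- segs |>
    group_by(.data$.armkey) |>
    filter(row_number() > 1) |>
    ungroup()
  bp10 <- purrr::pmap(layout$chromosomes, function(chrom, length, centromere) {
    wstart <- seq(0, length - 1, by = 1e7)
    pos <- brk$start[brk$chrom == chrom]
    vapply(wstart, function(ws) sum(pos >= ws & pos < ws + 1e7), numeric(1))
  })
  bp10 <- unlist(bp10, use.names = FALSE)
  osc <- unlist(lapply(by_arm, oscillating_chain_lengths), use.names = FALSE)

  bind_rows(
    tibble(feature = "segsize", value = as.numeric(segsize)),
    tibble(feature = "changepoint", value = as.numeric(changepoint)),
    tibble(feature = "copynumber", value = as.numeric(copynumber)),
    tibble(feature = "bp10MB", value = as.numeric(bp10)),
    tibble(feature = "bpchrarm", value = as.numeric(bpchrarm)),
    tibble(feature = "osc", value = as.numeric(osc))
  )
}

# Lengths of maximal runs of >= 3 segments alternating between exactly two
# copy-number states (states already integer and merged, so adjacent states
# always differ).
oscillating_chain_lengths <- function(arm_segs) {
  s <- arm_segs$cn
  n <- length(s)
  if (n < 3) return(numeric(0))
  out <- numeric(0)
  i <- 1
  while (i <= n - 2) {
    len <- 2
    while (i + len <= n && s[i + len] == s[i + len - 2]) len <- len + 1
    if (len >= 3) {
      out <- c(out, len)
      i <- i + len - 1
    } else {
      i <- i + 1
    }
  }
  out
}

#' Encode a feature catalogue against a component model
#'
#' Computes the sum-of-posteriors vector: for every observed feature value,
#' the posterior probability of each of that feature's mixture components
#' (equal component priors) is accumulated, giving a non-negative vector of
#' length K (the total component count). Values with zero likelihood under
#' every component of their feature are assigned entirely to the component
#' with the nearest mean, and a message reports how many such values were
#' seen. An empty catalogue encodes to the zero vector.
#'
#' @param features Long tibble `feature`, `value` from [extract_features()].
#' @param model Component model tibble (see [default_component_model()]).
#' @return Named numeric vector of length `nrow(model)`.
#' @export
encode_sample <- function(features, model = default_component_model()) {
  if (!all(unique(features$feature) %in% model$feature)) {
    stop_paircn("component model does not cover all features present",
                "paircn_validation_error")
  }
  v <- setNames(numeric(nrow(model)), model$component)
  n_rescued <- 0L
  for (f in unique(model$feature)) {
    comps <- model[model$feature == f, , drop = FALSE]
    x <- features$value[features$feature == f]
    if (length(x) == 0) next
    xt <- if (comps$transform[1] == "log10") log10(pmax(x, 1)) else x
    lik <- vapply(seq_len(nrow(comps)), function(k) {
      if (comps$family[k] == "poisson") {
        dpois(round(xt), comps$p1[k])
      } else {
        dnorm(xt, comps$p1[k], comps$p2[k])
      }
    }, numeric(length(xt)))
    lik <- matrix(lik, nrow = length(xt))
    tot <- rowSums(lik)
    zero <- tot <= 0 | !is.finite(tot)
    if (any(zero)) {
      n_rescued <- n_rescued + sum(zero)
      nearest <- vapply(xt[zero], function(z) which.min(abs(comps$p1 - z)),
                        integer(1))
      lik[zero, ] <- 0
      lik[cbind(which(zero), nearest)] <- 1
      tot[zero] <- 1
    }
    post <- lik / tot
    v[comps$component] <- v[comps$component] + colSums(post)
  }
  if (n_rescued > 0) {
    inform(paste0(n_rescued, " feature value(s) had zero likelihood under all ",
                  "components; assigned to the nearest component mean"))
  }
  v
}

#' Quantify signature exposures by constrained decomposition
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_x \|S x - \hat v\|_2,\ x \ge 0}, where \eqn{\hat v} is the
#' encoded component vector normalised to sum 1 and \eqn{S} the
#' column-stochastic signature-definition matrix, then renormalises
#' \eqn{x} to the simplex. The decomposition is scale-invariant in `v`.
#'
#' @param v Encoded component vector (length `nrow(definitions)`), e.g. from
#'   [encode_sample()].
#' @param definitions Signature-definition matrix (components x signatures).
#' @return A one-row tibble with one column per signature plus `residual`
#'   (the L2 norm of the fit residual).
#' @export
quantify_exposures <- function(v, definitions) {
  if (length(v) != nrow(definitions)) {
    stop_paircn("length(v) must equal nrow(definitions)", "paircn_validation_error")
  }
  if (any(v < 0)) stop_paircn("v must be non-negative", "paircn_validation_error")
  if (sum(v) <= 0) {
    stop_paircn("degenerate sample: encoded vector is all zero",
                "paircn_degenerate_sample")
  }
  vhat <- v / sum(v)
  x <- pracma::lsqnonneg(definitions, vhat)$x
  if (sum(x) <= 0) {
    stop_paircn("degenerate sample: zero decomposition", "paircn_degenerate_sample")
  }
  e <- x / sum(x)
  res <- sqrt(sum((definitions %*% x - vhat)^2))
  out <- as_tibble(setNames(as.list(e), colnames(definitions)))
  out$residual <- res
  out
}

#' Calibrate signature definitions against the generator's event classes
#'
#' Builds a signature-definition matrix consistent with the event-based
#' genome generator and the chosen component model by regression: a training
#' set of genomes with known Dirichlet-drawn exposures is simulated and
#' encoded, and each component's row of the definition matrix is obtained by
#' non-negative least squares of its encoded values on the known exposures.
#' Learning the columns from mixtures (rather than from pure-signature
#' genomes) absorbs the average interaction effects of co-occurring events —
#' stacked events create breakpoints no single event class would — which is
#' also how data-derived definitions behave. Columns are normalised to sum 1.
#'
#' @param layout A [genome_layout()].
#' @param model Component model tibble.
#' @param n_train Training genomes (default 100).
#' @param event_budget Events per training genome (default 30); calibrate
#'   near the event density of the genomes you will quantify.
#' @param exposure_alpha Symmetric Dirichlet concentration for training
#'   exposures (default 1).
#' @param seed Integer seed.
#' @return A K x 7 column-stochastic matrix with full column rank.
#' @export
calibrate_signature_definitions <- function(layout = genome_layout("toy"),
                                            model = default_component_model(),
                                            n_train = 100, event_budget = 30,
                                            exposure_alpha = 1, seed = 1) {
  K <- nrow(model)
  E <- matrix(0, n_train, 7)
  V <- matrix(0, n_train, K)
  for (i in seq_len(n_train)) {
    e <- with_seed(child_seed(seed, 2 * i), rdirichlet1(rep(exposure_alpha, 7)))
    segs <- suppressMessages(
      simulate_cn_profile(layout, e, event_budget = event_budget,
                          seed = child_seed(seed, 2 * i + 1)))
    v <- encode_sample(extract_features(segs, layout), model)
    E[i, ] <- e
    V[i, ] <- v / sum(v)
  }
  S <- t(apply(V, 2, function(vk) pracma::lsqnonneg(E, vk)$x))
  S <- sweep(S, 2, colSums(S), "/")
  dimnames(S) <- list(model$component, paste0("s", 1:7))
  if (qr(S)$rank < 7) {
    stop_paircn("calibrated definitions are rank deficient; increase n_train",
                "paircn_generation_error")
  }
  S
}

#' Signature exposures for a cohort of absolute profiles
#'
#' Maps each sample's absolute segments through feature extraction, encoding
#' and exposure quantification, returning a tidy per-sample exposure table.
#'
#' @param profiles Tibble with `sample_id` and a `segments` list-column of
#'   absolute-space segment tibbles (e.g. built from [fit_purity_ploidy()]
#'   results or the `truth` table of a simulated cohort).
#' @param layout A [genome_layout()].
#' @param definitions Signature-definition matrix.
#' @param model Component model tibble.
#' @return Tibble `sample_id`, one column per signature, `residual`.
#' @export
compute_exposures <- function(profiles, layout, definitions,
                              model = default_component_model()) {
  stopifnot(all(c("sample_id", "segments") %in% names(profiles)))
  purrr::map2(profiles$sample_id, profiles$segments, function(sid, segs) {
    v <- encode_sample(extract_features(segs, layout), model)
    mutate(quantify_exposures(v, definitions), sample_id = sid, .before = 1)
  }) |> list_rbind()
}
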