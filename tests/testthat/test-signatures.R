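test_that("feature extraction implements the six feature definitions", {
  # one segment per chromosome: no breakpoints, no change-points, no chains
  flat <- tibble::tibble(chrom = c("chrA", "chrB"), start = c(0, 0),
                         end = c(60e6, 40e6), value = c(2, 3))
  f <- extract_features(flat, mini_layout)
  expect_equal(sum(f$value[f$feature == "bpchrarm"]), 0)
  expect_equal(sum(f$value[f$feature == "bp10MB"]), 0)
  expect_equal(nrow(f[f$feature == "changepoint", ]), 0L)
  expect_setequal(f$value[f$feature == "copynumber"], c(2, 3))

  # states 2,3,2,3,2 on one arm: a single oscillating chain of length 5
  osc <- tibble::tibble(chrom = "chrA",
                        start = seq(0, by = 2e6, length.out = 5),
                        end = seq(2e6, by = 2e6, length.out = 5),
                        value = c(2, 3, 2, 3, 2))
  fo <- extract_features(osc, mini_layout)
  expect_equal(fo$value[fo$feature == "osc"], 5)
  expect_equal(fo$value[fo$feature == "changepoint"], rep(1, 4))

  # a 2 -> 4 adjacency contributes change-point magnitude 2
  cp <- tibble::tibble(chrom = "chrA", start = c(0, 5e6), end = c(5e6, 10e6),
                       value = c(2, 4))
  fc <- extract_features(cp, mini_layout)
  expect_equal(fc$value[fc$feature == "changepoint"], 2)

  # arm boundaries split segments: a boundary at the centromere is not a
  # within-arm breakpoint
  cross <- tibble::tibble(chrom = "chrA", start = c(0, 30e6),
                          end = c(30e6, 60e6), value = c(2, 5))
  fx <- extract_features(cross, mini_layout)
  expect_equal(sum(fx$value[fx$feature == "bpchrarm"]), 0)
  expect_equal(nrow(fx[fx$feature == "changepoint", ]), 0L)

  bad_layout <- genome_layout(data.frame(chrom = "chrZ", length = 1e6,
                                         centromere = 5e5))
  expect_error(extract_features(flat, bad_layout), class = "paircn_layout_error")
})

test_that("oscillating chains require >= 3 alternating segments of two states", {
  chain <- function(states) {
    tibble::tibble(chrom = "chrA",
                   start = seq(0, by = 1e6, length.out = length(states)),
                   end = seq(1e6, by = 1e6, length.out = length(states)),
                   cn = states, arm = "p", .armkey = "chrA p")
  }
  expect_equal(paircn:::oscillating_chain_lengths(chain(c(2, 3))), numeric(0))
  expect_equal(paircn:::oscillating_chain_lengths(chain(c(2, 3, 2))), 3)
  expect_equal(paircn:::oscillating_chain_lengths(chain(c(2, 3, 2, 3, 2))), 5)
  # three states in a row break the chain
  expect_equal(paircn:::oscillating_chain_lengths(chain(c(2, 3, 2, 4, 2, 4))),
               c(3, 4)) # a boundary segment can pivot into a second chain
})

test_that("encoding is a sum of per-value component posteriors", {
  model <- default_component_model()
  # single value at an isolated component mode gives a one-hot block
  f1 <- tibble::tibble(feature = "changepoint", value = 6)
  v1 <- encode_sample(f1, model)
  cp_comp <- model$component[model$feature == "changepoint"]
  expect_equal(sum(v1), 1, tolerance = 1e-9)
  expect_gt(v1[cp_comp[4]], 0.99) # the mean-6 component dominates
  expect_equal(sum(v1[setdiff(names(v1), cp_comp)]), 0)

  # empty catalogue encodes to the zero vector
  v0 <- encode_sample(tibble::tibble(feature = character(), value = numeric()),
                      model)
  expect_equal(unname(v0), rep(0, nrow(model)))

  # doubling every multiset doubles the encoding exactly (linearity)
  seg <- simulate_cn_profile(mini_layout, rep(1 / 7, 7), event_budget = 8,
                             seed = 3)
  f <- extract_features(seg, mini_layout)
  v <- encode_sample(f, model)
  v2 <- encode_sample(dplyr::bind_rows(f, f), model)
  expect_equal(v2, 2 * v, tolerance = 1e-9)
})

test_that("exposure quantification recovers exact and noisy mixtures", {
  S <- simulate_signature_definitions(36, 7, seed = 2)
  # a pure column recovers the unit vector
  e1 <- quantify_exposures(S[, 3], S)
  expect_equal(unname(unlist(e1[paste0("s", 1:7)])),
               c(0, 0, 1, 0, 0, 0, 0), tolerance = 1e-6)
  expect_lt(e1$residual, 1e-9)

  # an exact two-column mixture is recovered to 1e-6
  v <- 0.5 * S[, 1] + 0.5 * S[, 2]
  e2 <- quantify_exposures(v, S)
  expect_equal(unname(unlist(e2[paste0("s", 1:7)])),
               c(0.5, 0.5, 0, 0, 0, 0, 0), tolerance = 1e-6)

  # scale invariance: v and 2v give identical exposures
  e3 <- quantify_exposures(2 * v, S)
  expect_equal(e2, e3, tolerance = 1e-12)

  # permuting the columns of S permutes the exposures identically
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  Sp <- S[, perm]
  colnames(Sp) <- paste0("s", 1:7)
  ep <- quantify_exposures(v, Sp)
  expect_equal(unname(unlist(ep[paste0("s", 1:7)])),
               unname(unlist(e2[paste0("s", 1:7)]))[perm], tolerance = 1e-6)

  # noisy mixtures: mean absolute exposure error < 0.05 over 100 replicates
  errs <- vapply(1:100, function(i) {
    e_true <- withr::with_seed(1000 + i, paircn:::rdirichlet1(rep(1.5, 7)))
    noise <- withr::with_seed(2000 + i, rnorm(36, 0, 0.003))
    v <- pmax(S %*% e_true + noise, 0)
    est <- quantify_exposures(drop(v), S)
    mean(abs(unlist(est[paste0("s", 1:7)]) - e_true))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)

  expect_error(quantify_exposures(rep(0, 36), S),
               class = "paircn_degenerate_sample")
})

test_that("calibrated definitions support end-to-end exposure recovery", {
  model <- default_component_model()
  S <- calibrate_signature_definitions(toy_layout, model, n_train = 60,
                                       event_budget = 50, seed = 42)
  expect_equal(qr(S)$rank, 7L)
  expect_equal(unname(colSums(S)), rep(1, 7), tolerance = 1e-9)

  # simulate samples with known sparse exposures, re-quantify from the true
  # genomes, and check that exposures are genuinely recovered: overall
  # correlation, dominant-signature identification, and tracking of the
  # dominant signature's exposure across samples
  truths <- ests <- list()
  for (i in 1:30) {
    e_true <- withr::with_seed(500 + i, paircn:::rdirichlet1(rep(0.4, 7)))
    seg <- suppressMessages(
      simulate_cn_profile(toy_layout, e_true, event_budget = 50,
                          seed = 600 + i))
    v <- encode_sample(extract_features(seg, toy_layout), model)
    ests[[i]] <- unlist(quantify_exposures(v, S)[paste0("s", 1:7)])
    truths[[i]] <- e_true
  }
  expect_gt(cor(unlist(truths), unlist(ests)), 0.75)
  dom <- vapply(truths, which.max, integer(1))
  expect_gte(mean(dom == vapply(ests, which.max, integer(1))), 0.6)
  true_dom <- vapply(seq_along(dom), function(i) truths[[i]][dom[i]], numeric(1))
  est_dom <- vapply(seq_along(dom), function(i) ests[[i]][dom[i]], numeric(1))
  expect_gt(cor(true_dom, est_dom, method = "spearman"), 0.4)
})
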