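make_pair_segments <- function(n_pairs, layout, diag_cn = 2, planted = NULL,
                               jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n_pairs), function(i) {
      base <- tibble::tibble(chrom = layout$chromosomes$chrom, start = 0,
                             end = layout$chromosomes$length, value = diag_cn)
      dx <- dplyr::mutate(base, value = value + rnorm(dplyr::n(), 0, jitter),
                          patient_id = sprintf("P%02d", i), role = "diagnosis")
      rel <- dplyr::mutate(base, value = value + rnorm(dplyr::n(), 0, jitter),
                           patient_id = sprintf("P%02d", i), role = "relapse")
      if (!is.null(planted)) {
        rel <- dplyr::bind_rows(
          dplyr::filter(rel, chrom != planted$chrom),
          tibble::tibble(
            chrom = planted$chrom,
            start = c(0, planted$start, planted$end),
            end = c(planted$start, planted$end,
                    layout$chromosomes$length[layout$chromosomes$chrom == planted$chrom]),
            value = c(diag_cn, diag_cn + planted$delta, diag_cn),
            patient_id = sprintf("P%02d", i), role = "relapse"
          )
        )
      }
      dplyr::bind_rows(dx, rel)
    }) |> purrr::list_rbind()
  })
}

test_that("subtraction flags a planted region and is antisymmetric under label swap", {
  planted <- list(chrom = "chrA", start = 9e6, end = 15e6, delta = 2)
  segs <- make_pair_segments(10, mini_layout, planted = planted,
                             jitter = 0.15, seed = 5)
  sub <- subtract_pairs(segs, mini_layout, alpha = 0.05)
  inside <- sub$chrom == "chrA" & sub$start >= 9e6 & sub$end <= 15e6
  expect_true(all(sub$significant[inside]))
  expect_equal(median(sub$median_diff[inside]), 2, tolerance = 0.2)
  expect_true(all(sub$q >= sub$p - 1e-12))
  # false positives outside the region controlled at the FDR level
  n_out <- sum(sub$significant[!inside])
  expect_lte(n_out / max(1, sum(sub$significant)), 0.05)

  # swapping role labels negates the difference profile exactly
  swapped <- dplyr::mutate(segs, role = ifelse(role == "diagnosis",
                                               "relapse", "diagnosis"))
  sub_sw <- subtract_pairs(swapped, mini_layout, alpha = 0.05)
  expect_equal(sub_sw$median_diff, -sub$median_diff, tolerance = 1e-12)
  expect_equal(sub_sw$p, sub$p, tolerance = 1e-12)
})

test_that("fully tied bins give p = 1 and an empty significance mask", {
  segs <- make_pair_segments(5, mini_layout, jitter = 0, seed = 2)
  sub <- subtract_pairs(segs, mini_layout)
  expect_true(all(sub$p == 1))
  expect_false(any(sub$significant))
  expect_true(all(sub$median_diff == 0))
  expect_error(subtract_pairs(segs[segs$patient_id == "P01", ], mini_layout),
               class = "paircn_validation_error")
})

test_that("chromosome-wise BH adjustment matches a brute-force oracle", {
  segs <- make_pair_segments(8, mini_layout, jitter = 0.4, seed = 9)
  sub <- subtract_pairs(segs, mini_layout)
  # brute-force step-up BH oracle (independent of p.adjust)
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, adj)[order(o)]
  }
  for (ch in unique(sub$chrom)) {
    p <- sub$p[sub$chrom == ch]
    q <- sub$q[sub$chrom == ch]
    expect_equal(q, bh_oracle(p), tolerance = 1e-12) # within-chromosome family
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p
  }
  # pooled adjustment would differ from the chromosome-wise family
  expect_false(isTRUE(all.equal(sub$q, bh_oracle(sub$p))))
  # the oracle itself matches a hand-checkable 6-value example
  p6 <- c(0.01, 0.04, 0.03, 0.2, 0.5, 1)
  expect_equal(bh_oracle(p6), c(0.06, 0.08, 0.08, 0.3, 0.6, 1))
})

test_that("gene event calls follow the ploidy-aware thresholds", {
  panel <- tibble::tibble(chrom = "chrA", start = c(1e6, 10e6, 20e6),
                          end = c(1.1e6, 10.1e6, 20.1e6),
                          gene = c("G1", "G2", "G3"))
  segs <- tibble::tibble(chrom = "chrA", start = c(0, 5e6, 15e6),
                         end = c(5e6, 15e6, 60e6),
                         value = c(2, 10, 0.05))
  ev <- call_gene_events(segs, panel, ploidy = 2)
  expect_equal(ev$event, c("neutral", "amplified", "deleted"))
  expect_equal(ev$cn, c(2, 10, 0.05))

  # CN exactly at ploidy is neutral
  ev2 <- call_gene_events(tibble::tibble(chrom = "chrA", start = 0, end = 60e6,
                                         value = 3.4),
                          panel, ploidy = 3.4)
  expect_true(all(ev2$event == "neutral"))

  # boundary of the max(5, 2*psi) rule at psi = 3.4: threshold 6.8
  seg67 <- tibble::tibble(chrom = "chrA", start = 0, end = 60e6, value = 6.7)
  seg69 <- tibble::tibble(chrom = "chrA", start = 0, end = 60e6, value = 6.9)
  expect_equal(call_gene_events(seg67, panel[1, ], ploidy = 3.4)$event, "neutral")
  expect_equal(call_gene_events(seg69, panel[1, ], ploidy = 3.4)$event, "amplified")

  # genes without overlap are reported missing
  far_panel <- tibble::tibble(chrom = "chrB", start = 0, end = 1e5, gene = "G9")
  expect_message(evm <- call_gene_events(segs, far_panel, ploidy = 2), "G9")
  expect_true(is.na(evm$event))

  # length-weighted mean across overlapping segments
  seg_mix <- tibble::tibble(chrom = "chrA", start = c(0, 1.05e6),
                            end = c(1.05e6, 2e6), value = c(2, 6))
  evw <- call_gene_events(seg_mix, panel[1, ], ploidy = 2)
  expect_equal(evw$cn, (0.05e6 * 2 + 0.05e6 * 6) / 0.1e6)
})

test_that("event-rate comparisons match the Fisher exact oracle", {
  # 10/10 vs 0/10: p = 2 / choose(20, 10) by hypergeometric enumeration
  events <- tibble::tibble(
    gene = "G1",
    event = rep(c("amplified", "neutral"), each = 10),
    group = rep(c("a", "b"), each = 10)
  )
  res <- compare_event_rates(events, "group")
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)

  # identical groups give p = 1
  events2 <- tibble::tibble(gene = "G1",
                            event = rep(c("amplified", "neutral", "neutral"), 2),
                            group = rep(c("a", "b"), each = 3))
  expect_equal(compare_event_rates(events2, "group")$p, 1)

  # agreement with stats::fisher.test on random 2x2 tables with n <= 30
  for (i in 1:20) {
    tab <- withr::with_seed(300 + i, {
      n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
      k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
      c(n1, k1, n2, k2)
    })
    events3 <- tibble::tibble(
      gene = "G",
      event = c(rep("amplified", tab[2]), rep("neutral", tab[1] - tab[2]),
                rep("amplified", tab[4]), rep("neutral", tab[3] - tab[4])),
      group = c(rep("a", tab[1]), rep("b", tab[3]))
    )
    res3 <- compare_event_rates(events3, "group")
    oracle <- fisher.test(matrix(c(tab[2], tab[1] - tab[2],
                                   tab[4], tab[3] - tab[4]), 2))$p.value
    expect_equal(res3$p, oracle, tolerance = 1e-12)
  }

  # BH across the declared gene family
  events4 <- dplyr::bind_rows(events, dplyr::mutate(events2, gene = "G2"))
  res4 <- compare_event_rates(events4, "group")
  expect_equal(res4$q, p.adjust(res4$p, "BH"))
  expect_error(compare_event_rates(dplyr::mutate(events, group = "a"), "group"),
               class = "paircn_config_error")
})

test_that("per-signature tests use the right rank test and handle ties", {
  ec <- simulate_exposure_cohort(25, seed = 11)
  # identical groups: all p = 1
  same <- ec
  same$role <- rep(c("diagnosis", "relapse"), 25)
  dup <- dplyr::bind_rows(
    dplyr::filter(ec, role == "diagnosis"),
    dplyr::mutate(dplyr::filter(ec, role == "diagnosis"), role = "relapse")
  )
  res_same <- compare_exposures_univariate(dup, "role", paired = TRUE)
  expect_true(all(res_same$p == 1))
  expect_true(all(res_same$method == "wilcoxon-signed-rank"))

  res_unp <- compare_exposures_univariate(ec, "role", paired = FALSE)
  expect_true(all(res_unp$method == "mann-whitney"))
  expect_true(all(res_unp$p >= 0 & res_unp$p <= 1))

  # planted shift in s3 is detected with high power at n = 50 per group
  hits <- vapply(1:20, function(i) {
    shifted <- simulate_exposure_cohort(50, shift_signature = 3, shift = 0.2,
                                        seed = 700 + i)
    res <- compare_exposures_univariate(shifted, "role", paired = TRUE)
    res$p[res$label == "s3"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(compare_exposures_univariate(ec[-1, ], "role", paired = TRUE),
               class = "paircn_validation_error")
})

test_that("immune-density correlations report rank statistics and handle constants", {
  ec <- simulate_exposure_cohort(20, seed = 13)
  ec <- dplyr::filter(ec, role == "diagnosis")
  dens <- dplyr::bind_rows(
    tibble::tibble(sample_id = ec$sample_id, marker = "CD3",
                   compartment = "tumour", density = 100 * ec$s3 + 5),
    tibble::tibble(sample_id = ec$sample_id, marker = "CD8",
                   compartment = "stroma", density = -50 * ec$s3),
    tibble::tibble(sample_id = ec$sample_id, marker = "CD8",
                   compartment = "tumour", density = 7)
  )
  res <- correlate_exposures_immune(ec, dens)
  r3 <- dplyr::filter(res, signature == "s3", marker == "CD3")
  expect_equal(r3$spearman_rho, 1)
  rneg <- dplyr::filter(res, signature == "s3", marker == "CD8",
                        compartment == "stroma")
  expect_equal(rneg$spearman_rho, -1)
  rconst <- dplyr::filter(res, marker == "CD8", compartment == "tumour")
  expect_true(all(is.na(rconst$kendall_tau)))
})
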