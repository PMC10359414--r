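# Shared fixtures: a small layout and annotated bin grid reused across files.
toy_layout <- genome_layout("toy")
toy_bins <- layout_bins(toy_layout, seed = 1)

# A compact two-chromosome layout for fast tests.
mini_layout <- genome_layout(
  data.frame(chrom = c("chrA", "chrB"), length = c(60e6, 40e6),
             centromere = c(30e6, 15e6)),
  bin_size = 30000
)
mini_bins <- layout_bins(mini_layout, seed = 2)

# Ground-truth genome with a homozygous-deletion anchor and >= 5 states,
# suitable for purity/ploidy recovery experiments.
recovery_genome <- function(layout, baseline_ploidy, seed,
                            exposures = rep(1 / 7, 7), event_budget = 10) {
  simulate_cn_profile(layout, exposures, event_budget = event_budget,
                      baseline_ploidy = baseline_ploidy, seed = seed)
}

expect_simplex <- function(x, tol = 1e-6) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = tol)
}
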