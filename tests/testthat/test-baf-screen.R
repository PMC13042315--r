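# One moderately large haploid mixture reused by several blocks below.
sim10 <- recovery_sim(21, 0.10)
prof10 <- compute_baf(sim10$records, 10, genome_id = "hap10")

test_that("compute_baf computes alt fractions and applies the depth floor", {
  s <- rbind_sites(
    data.frame(chrom = "chr1", pos = c(10, 20, 30), ref = "A", alt = "G",
               depth = c(80L, 50L, 5L), alt_depth = c(76L, 0L, 5L),
               truth = "crafted")
  )
  prof <- compute_baf(s, min_depth = 10)
  expect_equal(prof$sites$baf, c(0.95, 0))
  expect_equal(prof$n_excluded, 1)
  expect_equal(prof$median_depth, 65)
  expect_error(compute_baf(s, min_depth = 100), "insufficient depth")
})

test_that("expected band positions match the ploidy arithmetic", {
  expect_equal(round(expected_bands(3, 0)$positions, 2), c(0.33, 0.67, 1.00))
  expect_equal(expected_bands(2, 0)$positions, c(0.5, 1.0))
  expect_equal(expected_bands(1, 0.05, TRUE)$positions, 0.95)
  expect_equal(expected_bands(4, 0)$positions, c(0.25, 0.5, 0.75, 1))
  # full two-population model for a haploid: contaminant ref and alt bands
  expect_equal(expected_bands(1, 0.1)$positions, c(0.1, 0.9, 1.0))
  # continuity at c -> 0: clean bands are (limits of) contaminated bands
  for (p in 1:4) {
    base <- expected_bands(p, 0)$positions
    tiny <- expected_bands(p, 1e-9)$positions
    expect_true(all(vapply(base, function(b) min(abs(tiny - b)) < 1e-6,
                           logical(1))))
  }
})

test_that("ploidy classification recovers the simulated truth", {
  ref <- random_reference(2e5, 2, seed = 31)
  panel <- simulate_panel(ref, 4, 0.005, seed = 31)
  for (p in 1:4) {
    st <- simulate_strain(panel, "L1", p,
                          heterozygosity = if (p > 1) 0.005 else 0,
                          seed = 40 + p)
    r <- simulate_read_counts(st, NULL, mixture_spec(0, 80, seed = 50 + p))
    cls <- classify_ploidy(compute_baf(r, 10))
    expect_equal(cls$ploidy, p)
    expect_length(cls$scores, 4)
  }
})

test_that("a perfect BAF=1 profile is haploid with zero loss", {
  s <- rbind_sites(data.frame(chrom = "chr1", pos = 1:300, ref = "A",
                              alt = "G", depth = 80L, alt_depth = 80L,
                              truth = "crafted"))
  cls <- classify_ploidy(compute_baf(s, 10), eps = 0)
  expect_equal(cls$ploidy, 1)
  expect_equal(unname(cls$scores["p1"]), 0)
  expect_error(classify_ploidy(compute_baf(s[1:10, ], 1)), "too few sites")
})

test_that("contamination estimation recovers a 10% haploid mixture", {
  est <- estimate_contamination(prof10, 1)
  expect_gte(est$c_hat, 0.09)
  expect_lte(est$c_hat, 0.11)
  expect_true(est$contaminated)
  expect_false(est$aneuploidy_suspect)
  expect_gte(est$secondary_band_fraction, 0.05)
})

test_that("clean and 5% mixtures sit on either side of the calling threshold", {
  sim0 <- recovery_sim(22, 0)
  est0 <- estimate_contamination(compute_baf(sim0$records, 10), 1)
  expect_false(est0$contaminated)

  sim5 <- recovery_sim(22, 0.05)
  est5 <- estimate_contamination(compute_baf(sim5$records, 10), 1)
  expect_true(est5$contaminated)
  expect_gte(est5$c_hat, 0.05)
})

test_that("low-depth profiles are marked unreliable", {
  s <- band_sites(500, c(0.5, 1), depth = 15, seed = 3)
  expect_warning(est <- estimate_contamination(compute_baf(s, 10), 2),
                 "unreliable")
  expect_false(est$depth_ok)
  expect_false(est$contaminated)
})

test_that("chromosome-local band shifts are reported as aneuploidy, not contamination", {
  dip <- band_sites(3000, c(0.5, 1), chrom = "chr1", seed = 5)
  tri <- band_sites(1500, c(1 / 3, 2 / 3, 1), chrom = "chr2", seed = 6)
  prof <- compute_baf(rbind_sites(dip, tri), 10)
  est <- estimate_contamination(prof, 2)
  expect_true(est$aneuploidy_suspect)
  expect_false(est$contaminated)

  # the same shifted bands on every chromosome would be a contamination call
  tri2 <- band_sites(1500, c(1 / 3, 2 / 3, 1), chrom = "chr1", seed = 7)
  tri3 <- band_sites(1500, c(1 / 3, 2 / 3, 1), chrom = "chr2", seed = 8)
  est2 <- estimate_contamination(compute_baf(rbind_sites(tri2, tri3), 10), 2)
  expect_true(est2$contaminated)
  expect_false(est2$aneuploidy_suspect)
})

test_that("repeat-like uniform-BAF sites barely move the estimate", {
  base <- recovery_sim(23, 0.10, L = 5e5, repeat_frac = 0)
  with_rep <- recovery_sim(23, 0.10, L = 5e5, repeat_frac = 0.01)
  c1 <- estimate_contamination(compute_baf(base$records, 10), 1)$c_hat
  c2 <- estimate_contamination(compute_baf(with_rep$records, 10), 1)$c_hat
  expect_lt(abs(c1 - c2), 0.01)
})

test_that("plot data is coordinate-ordered and keeps empty chromosomes", {
  s <- rbind_sites(data.frame(chrom = "chr1", pos = c(30, 10, 20), ref = "A",
                              alt = "G", depth = 80L,
                              alt_depth = c(40L, 80L, 80L), truth = "crafted"))
  attr(s, "map") <- list(names = c("chr1", "chr2"), lengths = c(100, 100),
                         offsets = c(0, 100))
  prof <- compute_baf(s, 10)
  d <- export_plot_data(prof)
  expect_equal(nrow(d), 3)
  expect_equal(d$pos, c(10, 20, 30))
  expect_true("chr2" %in% levels(d$chrom))
  expect_s3_class(plot_baf(prof), "ggplot")
})

test_that("the exported table of a 10% mixture has its sub-1 modal bin near 0.90", {
  d <- export_plot_data(prof10)
  bins <- cut(d$baf[d$baf < 0.97], breaks = seq(0, 1, by = 0.01))
  modal <- which.max(table(bins)) / 100
  expect_gte(modal, 0.89)
  expect_lte(modal, 0.91)
})
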