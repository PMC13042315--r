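test_that("panels are deterministic and hit the divergence target", {
  ref <- random_reference(2e4, 2, seed = 3)
  p1 <- simulate_panel(ref, 20, 0.005, seed = 1)
  p2 <- simulate_panel(ref, 20, 0.005, seed = 1)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$tree$edge.length, p2$tree$edge.length)

  # mean pairwise Hamming divergence within a factor two of the target
  m <- do.call(rbind, lapply(p1$sequences, function(s) {
    utf8ToInt(s)
  }))
  pairs <- combn(nrow(m), 2)
  ham <- mean(apply(pairs, 2, function(ij) mean(m[ij[1], ] != m[ij[2], ])))
  expect_gte(ham, 0.0025)
  expect_lte(ham, 0.01)
})

test_that("panel construction validates its inputs", {
  ref <- random_reference(2e4, 2, seed = 3)
  expect_error(simulate_panel(ref, 3, 0.005, seed = 1), "at least 4")
  expect_error(reference_genome(c(a = "ACGT")), "at least 2 chromosomes")
  expect_error(reference_genome(c(a = strrep("ACGX", 2500),
                                  b = strrep("ACGT", 2500))),
               "only A, C, G, T")
})

test_that("strain genomes have the requested ploidy and heterozygosity", {
  ref <- random_reference(1e5, 2, seed = 5)
  panel <- simulate_panel(ref, 4, 0.005, seed = 5)

  hap <- simulate_strain(panel, "L2", 1, heterozygosity = 0.01, seed = 1)
  expect_length(hap$haplotypes, 1)
  expect_identical(hap$haplotypes[[1]], unname(panel$sequences[["L2"]]))

  dip <- simulate_strain(panel, "L2", 2, heterozygosity = 0.005, seed = 1)
  expect_length(dip$haplotypes, 2)
  ndiff <- sum(utf8ToInt(dip$haplotypes[[1]]) != utf8ToInt(dip$haplotypes[[2]]))
  expect_gte(ndiff, 350)  # 500 +/- 30%
  expect_lte(ndiff, 650)

  tet <- simulate_strain(panel, "L3", 4, heterozygosity = 0.005, seed = 2)
  expect_length(tet$haplotypes, 4)
  expect_true(all(nchar(tet$haplotypes) == 1e5))

  expect_error(simulate_strain(panel, "L99", 1), "not a panel lineage")
})

test_that("read counts conserve alleles and respect the no/full mixing limits", {
  sim0 <- recovery_sim(2, 0, L = 1e5)
  r0 <- sim0$records
  expect_true(all(r0$alt_depth >= 0 & r0$alt_depth <= r0$depth))
  expect_true(all(r0$pos >= 1))
  expect_false(anyDuplicated(paste(r0$chrom, r0$pos)) > 0)

  # determinism
  r0b <- simulate_read_counts(sim0$recipient, NULL,
                              mixture_spec(0, 80, seed = 2 + 3000))
  expect_identical(r0, r0b)

  # c > 0 without a contaminant is an error
  expect_error(simulate_read_counts(sim0$recipient, NULL, mixture_spec(0.1)),
               "requires a contaminant")

  # full replacement: c = 1 reproduces the contaminant's own spectrum
  ref <- random_reference(1e5, 2, seed = 9)
  panel <- simulate_panel(ref, 4, 0.01, seed = 9)
  rec <- simulate_strain(panel, "L1", 1, seed = 1, gap_frac = 0)
  don <- simulate_strain(panel, "L4", 1, seed = 2, gap_frac = 0)
  r_full <- simulate_read_counts(rec, don, mixture_spec(1, 80, seed = 7,
                                                        repeat_frac = 0))
  r_don <- simulate_read_counts(don, NULL, mixture_spec(0, 80, seed = 7,
                                                        repeat_frac = 0))
  don_sites <- r_full[r_full$truth == "contaminant_snp", ]
  expect_equal(mean(don_sites$alt_depth / don_sites$depth),
               mean(r_don$alt_depth / r_don$depth), tolerance = 0.02)
  rec_sites <- r_full[r_full$truth == "recipient_snp", ]
  expect_lt(mean(rec_sites$alt_depth / rec_sites$depth), 0.02)
})

test_that("mixing is linear in the contamination fraction", {
  # recipient hom-alt, contaminant hom-ref: E[BAF] = (1-c)(1-eps) + c*eps
  ref <- random_reference(1.5e6, 2, seed = 4)
  panel <- simulate_panel(ref, 4, 0.01, seed = 4)
  rec <- simulate_strain(panel, "L1", 1, seed = 1, gap_frac = 0)
  don <- simulate_strain(panel, "L4", 1, seed = 2, gap_frac = 0)
  for (cc in c(0.05, 0.2)) {
    r <- simulate_read_counts(rec, don,
                              mixture_spec(cc, 80, seed = 11, eps = 0.002,
                                           repeat_frac = 0))
    s <- r[r$truth == "recipient_snp", ]
    expect_gt(nrow(s), 1e4)
    expected <- (1 - cc) * (1 - 0.002) + cc * 0.002
    expect_equal(mean(s$alt_depth / s$depth), expected, tolerance = 0.005)
  }
})

test_that("haploid 5% mixtures show the 0.95 SNP band", {
  ref <- random_reference(1.5e6, 2, seed = 6)
  panel <- simulate_panel(ref, 4, 0.01, seed = 6)
  rec <- simulate_strain(panel, "L1", 1, seed = 1, gap_frac = 0)
  don <- simulate_strain(panel, "L4", 1, seed = 2, gap_frac = 0)
  r <- simulate_read_counts(rec, don, mixture_spec(0.05, 80, seed = 3,
                                                   eps = 0, repeat_frac = 0))
  s <- r[r$truth == "recipient_snp", ]
  expect_gt(nrow(s), 1e4)
  m <- mean(s$alt_depth / s$depth)
  expect_gte(m, 0.94)
  expect_lte(m, 0.96)
  prof <- compute_baf(r, 10)
  expect_equal(unname(median(prof$sites$baf[prof$sites$truth == "recipient_snp"])),
               0.95, tolerance = 0.01)
})

test_that("mix_fastq samples the requested pair counts from each source", {
  tmp <- withr::local_tempdir()
  mk_fq <- function(tag, n) {
    data.frame(id = sprintf("%s_%d/1", tag, seq_len(n)),
               seq = strrep("ACGT", 25), qual = strrep("I", 100))
  }
  a1 <- file.path(tmp, "a1.fastq"); a2 <- file.path(tmp, "a2.fastq")
  b1 <- file.path(tmp, "b1.fastq"); b2 <- file.path(tmp, "b2.fastq")
  write_fastq(mk_fq("a", 1500), a1); write_fastq(mk_fq("a", 1500), a2)
  write_fastq(mk_fq("b", 400), b1); write_fastq(mk_fq("b", 400), b2)

  out <- mix_fastq(c(a1, a2), c(b1, b2), n_total = 1000, c = 0.10, seed = 1,
                   out_prefix = file.path(tmp, "mix"))
  m1 <- read_fastq(out[1]); m2 <- read_fastq(out[2])
  expect_equal(nrow(m1), 1000)
  expect_equal(nrow(m2), 1000)
  expect_equal(sum(startsWith(m1$id, "b")), 100)
  expect_identical(startsWith(m1$id, "b"), startsWith(m2$id, "b"))
  expect_false(anyDuplicated(m1$id) > 0)  # without replacement

  # c = 0: a pure subsample of source a
  out0 <- mix_fastq(c(a1, a2), c(b1, b2), n_total = 200, c = 0, seed = 2,
                    out_prefix = file.path(tmp, "pure"))
  p1 <- read_fastq(out0[1])
  expect_true(all(startsWith(p1$id, "a")))

  expect_error(mix_fastq(c(b1, b2), c(a1, a2), n_total = 1000, c = 0,
                         out_prefix = file.path(tmp, "x")),
               "b1.fastq")
})
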