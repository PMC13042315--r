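random_pair <- function(L, n_diff, seed) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), L, TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
  b <- a
  idx <- sample(L, n_diff)
  b[idx] <- vapply(a[idx], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

test_that("identical sequences have zero distance under both models", {
  s <- strrep("ACGT", 100)
  expect_equal(tn93_distance(s, s), 0)
  expect_equal(f84_distance(s, s), 0)
})

test_that("TN93 matches a direct evaluation of the closed form on counted proportions", {
  # 160 sites with exactly 8 transversions; counts done by hand in the test
  a <- rep(strsplit("AAAACCCCGGGGTTTT", "")[[1]], 10)
  b <- a
  flip <- c(A = "C", C = "A", G = "T", T = "G")  # all transversions
  idx <- seq(1, 160, by = 20)
  b[idx] <- flip[a[idx]]
  sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
  # independent count-based oracle
  P1 <- 0; P2 <- 0; Q <- 8 / 160
  counts <- table(factor(c(a, b), levels = c("A", "G", "C", "T")))
  fr <- as.numeric(counts) / (2 * 160)
  R <- fr[1] + fr[2]; Y <- fr[3] + fr[4]
  k1 <- 2 * fr[1] * fr[2] / R
  k2 <- 2 * fr[3] * fr[4] / Y
  k3 <- 2 * (R * Y - fr[1] * fr[2] * Y / R - fr[3] * fr[4] * R / Y)
  d_oracle <- -k1 * log(1 - P1 / k1 - Q / (2 * R)) -
    k2 * log(1 - P2 / k2 - Q / (2 * Y)) -
    k3 * log(1 - Q / (2 * R * Y))
  expect_equal(tn93_distance(sa, sb), d_oracle, tolerance = 1e-12)
})

test_that("TN93 agrees with ape::dist.dna on random pairs", {
  for (seed in 1:5) {
    p <- random_pair(4000, 120, seed)
    bin <- ape::as.DNAbin(rbind(strsplit(p$a, "")[[1]], strsplit(p$b, "")[[1]]))
    expect_equal(tn93_distance(p$a, p$b),
                 as.numeric(ape::dist.dna(bin, model = "TN93")),
                 tolerance = 1e-10)
  }
})

test_that("ambiguity codes are missing data and masking cannot increase distance", {
  p <- random_pair(2000, 60, seed = 3)
  d0 <- tn93_distance(p$a, p$b)
  # mask a block containing some differing sites
  mask <- function(s, idx) {
    v <- strsplit(s, "")[[1]]; v[idx] <- "N"; paste(v, collapse = "")
  }
  d1 <- tn93_distance(mask(p$a, 1:500), p$b)
  expect_lte(d1, d0 + 1e-12)
  # heterozygous IUPAC codes behave exactly like N
  v <- strsplit(p$a, "")[[1]]; v[1:500] <- "R"
  d2 <- tn93_distance(paste(v, collapse = ""), p$b)
  expect_equal(d1, d2)
  # masking every differing site leaves zero distance over the rest
  av <- strsplit(p$a, "")[[1]]; bv <- strsplit(p$b, "")[[1]]
  d3 <- tn93_distance(mask(p$a, which(av != bv)), p$b)
  expect_equal(d3, 0)
  expect_error(tn93_distance(strrep("N", 10), strrep("A", 10)), "usable sites")
})

test_that("F84 reduces to Jukes-Cantor for equal frequencies at ratio 0.5", {
  # balanced reciprocal transversions keep pooled base frequencies equal
  a <- rep(c("A", "C", "G", "T"), 1000)
  b <- a
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  idx <- c(seq(1, 4000, by = 80), seq(2, 4000, by = 80),
           seq(3, 4000, by = 80), seq(4, 4000, by = 80))
  b[idx] <- flip[a[idx]]
  p <- length(idx) / 4000
  d <- f84_distance(paste(a, collapse = ""), paste(b, collapse = ""), 0.5)
  expect_equal(d, -3 / 4 * log(1 - 4 * p / 3), tolerance = 1e-6)
})

test_that("F84 matches a brute-force likelihood grid", {
  p <- random_pair(4000, 150, seed = 9)
  pc <- bafscreen:::pair_counts(p$a, p$b)
  par <- suppressWarnings(bafscreen:::f84_params(pc$freqs, 0.5))
  ll <- function(t) {
    P <- bafscreen:::f84_pmat(t, par)
    fr <- pc$freqs
    p1 <- 2 * fr[1] * P[1, 2]; p2 <- 2 * fr[3] * P[3, 4]
    ptv <- fr[1] * (P[1, 3] + P[1, 4]) + fr[2] * (P[2, 3] + P[2, 4]) +
      fr[3] * (P[3, 1] + P[3, 2]) + fr[4] * (P[4, 1] + P[4, 2])
    ps <- 1 - p1 - p2 - ptv
    (pc$n - pc$ts1 - pc$ts2 - pc$tv) * log(ps) +
      pc$ts1 * log(p1) + pc$ts2 * log(p2) + pc$tv * log(ptv)
  }
  grid <- seq(0.005, 0.15, by = 1e-5)
  t_grid <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_equal(suppressWarnings(f84_distance(p$a, p$b, 0.5)), t_grid,
               tolerance = 1e-4)
})

test_that("saturated pairs are flagged undefined", {
  set.seed(4)
  a <- sample(c("A", "G"), 1000, TRUE)
  b <- ifelse(a == "A", "C", "T")  # every site a transversion
  expect_true(is.na(tn93_distance(paste(a, collapse = ""),
                                  paste(b, collapse = ""))))
})

test_that("distance matrices are symmetric, zero-diagonal and match the scalar path", {
  aln <- two_clade_alignment(L = 3000, seed = 5)
  dm <- distance_matrix(aln, "TN93")
  expect_equal(diag(dm$D), setNames(rep(0, 8), names(aln)))
  expect_equal(dm$D, t(dm$D))
  expect_equal(dm$D["A1", "B2"], tn93_distance(aln[["A1"]], aln[["B2"]]),
               tolerance = 1e-12)
  dmf <- suppressWarnings(distance_matrix(aln, "F84"))
  expect_equal(dmf$D["A1", "A3"],
               suppressWarnings(f84_distance(aln[["A1"]], aln[["A3"]])),
               tolerance = 1e-12)
  expect_true(all(dm$n_used[upper.tri(dm$n_used)] == 3000))
})
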