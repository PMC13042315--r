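# Shared simulation harnesses for the tests.

# Haploid recipient + distinct contaminant over a small panel; genome size
# chosen so the union of their SNP sites is ~20k at 1.5 Mb (divergence 0.01)
# or scaled down for cheaper tests.
recovery_sim <- function(seed, c, L = 1.5e6, depth = 80, repeat_frac = 0.01,
                         gap_frac = 0.05, eps = 0.002) {
  ref <- random_reference(L, 2, seed = seed)
  panel <- simulate_panel(ref, 4, 0.01, seed = seed)
  rec <- simulate_strain(panel, "L1", 1, seed = seed + 1000,
                         gap_frac = gap_frac)
  don <- simulate_strain(panel, "L4", 1, seed = seed + 2000, gap_frac = 0,
                         role = "contaminant")
  spec <- mixture_spec(c = c, depth = depth, seed = seed + 3000, eps = eps,
                       repeat_frac = repeat_frac)
  records <- simulate_read_counts(rec, if (c > 0) don else NULL, spec)
  list(records = records, recipient = rec, contaminant = don,
       panel = panel, reference = ref)
}

# Site records drawn around given BAF bands at binomial depth: used to craft
# profiles (e.g. aneuploid chromosomes) without a full genome simulation.
band_sites <- function(n, bands, chrom = "chr1", depth = 80, start = 1,
                       seed = 1) {
  set.seed(seed)
  b <- sample(bands, n, replace = TRUE)
  d <- pmax(1L, rpois(n, depth))
  alt <- rbinom(n, d, b)
  out <- data.frame(chrom = chrom, pos = seq(start, length.out = n),
                    ref = "A", alt = "G", depth = as.integer(d),
                    alt_depth = as.integer(alt),
                    truth = "crafted", stringsAsFactors = FALSE)
  class(out) <- c("site_records", "data.frame")
  out
}

rbind_sites <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("site_records", "data.frame")
  out
}

# Alignment of two clearly separated 4-taxon clades over a random backbone.
two_clade_alignment <- function(L = 10000, within = 0.001, between = 0.05,
                                seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mutate_at <- function(s, idx) {
    s[idx] <- vapply(s[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    s
  }
  clade_b_core <- mutate_at(base, sample(L, round(between * L)))
  mk <- function(core, tag) {
    vapply(1:4, function(i) {
      paste(mutate_at(core, sample(L, round(within * L))), collapse = "")
    }, character(1)) |> setNames(paste0(tag, 1:4))
  }
  c(mk(base, "A"), mk(clade_b_core, "B"))
}
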