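#' Construct a reference genome
#'
#' A reference genome is a small ordered set of chromosome sequences against
#' which strains, read counts and consensus sequences are all expressed. Two
#' or more chromosomes are required so that genome-wide signals (such as
#' contamination) can be distinguished from chromosome-local ones (such as
#' aneuploidy).
#'
#' @param chromosomes Named character vector of chromosome sequences
#'   (A/C/G/T only).
#' @return An object of class `reference_genome` with elements `chromosomes`
#'   (named character vector), `lengths` and `total_length`.
#' @export
#' @examples
#' ref <- random_reference(length = 12000, n_chrom = 2, seed = 1)
#' ref$total_length
reference_genome <- function(chromosomes) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes))) {
    stop("chromosomes must be uniquely named")
  }
  if (length(chromosomes) < 2) {
    stop("a reference genome needs at least 2 chromosomes")
  }
  if (any(grepl("[^ACGT]", chromosomes))) {
    stop("chromosome sequences may contain only A, C, G, T")
  }
  lens <- nchar(chromosomes)
  total <- sum(lens)
  if (total < 10000) {
    stop("total reference length must be at least 10 kb")
  }
  structure(
    list(chromosomes = chromosomes, lengths = lens, total_length = total),
    class = "reference_genome"
  )
}

#' Generate a random reference genome
#'
#' @param length Total genome length in bp (>= 10 kb).
#' @param n_chrom Number of chromosomes (>= 2); lengths are split evenly.
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @param gc GC content of the random sequence.
#' @return A `reference_genome`.
#' @export
random_reference <- function(length = 1e5, n_chrom = 2, seed = 1, gc = 0.38) {
  stopifnot(n_chrom >= 2, length >= 10000, gc > 0, gc < 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, G = gc / 2, C = gc / 2, T = (1 - gc) / 2)
  lens <- rep(floor(length / n_chrom), n_chrom)
  lens[n_chrom] <- length - sum(lens[-n_chrom])
  seqs <- vapply(lens, function(l) {
    paste(sample(names(p), l, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  reference_genome(seqs)
}

# Evolve an encoded sequence down every edge of a tree under a single-rate
# substitution process with an optional transition bias. A site is hit on an
# edge of length t with probability 1 - exp(-t) (t in expected
# substitutions/site); a hit site changes to a transition partner with
# probability ts_bias/(ts_bias + 2), else to one of the two transversion
# partners. Multiple hits accumulate across successive edges. Returns tip
# sequences as strings, in tip-label order.
evolve_along_tree <- function(tree, root_int, ts_bias = 1) {
  # transition partner under the internal coding A=1,G=2,C=3,T=4
  ts_partner <- c(2L, 1L, 4L, 3L)
  tv_partners <- list(c(3L, 4L), c(3L, 4L), c(1L, 2L), c(1L, 2L))
  mutate <- function(s, t) {
    if (t <= 0) return(s)
    L <- length(s)
    n_hit <- rbinom(1, L, 1 - exp(-t))
    if (n_hit == 0) return(s)
    pos <- sample.int(L, n_hit)
    is_ts <- runif(n_hit) < ts_bias / (ts_bias + 2)
    cur <- s[pos]
    new <- cur
    new[is_ts] <- ts_partner[cur[is_ts]]
    if (any(!is_ts)) {
      pick <- 1L + (runif(sum(!is_ts)) < 0.5)
      new[!is_ts] <- mapply(function(b, k) tv_partners[[b]][k],
                            cur[!is_ts], pick)
    }
    s[pos] <- new
    s
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- root_int
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    node_seq[[child]] <- mutate(node_seq[[par]], ord$edge.length[k])
  }
  out <- vapply(seq_len(ntip), function(i) int_to_seq(node_seq[[i]]),
                character(1))
  setNames(out, tree$tip.label)
}

# Chromosome map helpers: genomes are manipulated internally in linear
# (concatenated) coordinates; the map converts back to (chrom, pos).
chrom_map <- function(reference) {
  list(names = names(reference$chromosomes),
       lengths = unname(reference$lengths),
       offsets = cumsum(c(0, unname(reference$lengths)))[seq_along(reference$lengths)])
}

linear_to_chrom <- function(pos, map) {
  idx <- findInterval(pos, map$offsets + 1)
  data.frame(chrom = map$names[idx], pos = pos - map$offsets[idx],
             stringsAsFactors = FALSE)
}

reference_string <- function(reference) {
  paste(reference$chromosomes, collapse = "")
}

#' Simulate a lineage panel
#'
#' Generates a rooted pure-birth tree over `n_strains` lineages and evolves
#' the reference sequence along it under a single-rate substitution process
#' (optionally with a transition bias). Branch lengths are rescaled so that
#' the mean pairwise divergence among tips equals `divergence_target`,
#' emulating a within-species reference panel of known phylogeny.
#'
#' @param reference A `reference_genome`.
#' @param n_strains Number of panel lineages (>= 4; neighbor joining needs at
#'   least four taxa for a non-trivial topology).
#' @param divergence_target Mean pairwise divergence among tips, in
#'   substitutions/site, in (0, 0.05].
#' @param seed Integer seed; panels are byte-identical for a fixed seed.
#' @param ts_bias Relative rate of transitions vs transversions (1 = none).
#' @return An object of class `lineage_panel`: `tree` (an [ape::phylo] with
#'   tip labels `L1..Ln`), `sequences` (named character vector of tip
#'   sequences in linear coordinates), `reference`, `map` and
#'   `divergence_target`.
#' @export
simulate_panel <- function(reference, n_strains, divergence_target, seed,
                           ts_bias = 1) {
  if (n_strains < 4) {
    stop("n_strains must be at least 4 (neighbor joining needs >= 4 taxa)")
  }
  stopifnot(divergence_target > 0, divergence_target <= 0.05)
  set.seed(seed)
  tree <- ape::rphylo(n_strains, birth = 1, death = 0)
  tree$tip.label <- paste0("L", seq_len(n_strains))
  # Rescale so the mean pairwise path length equals the divergence target.
  coph <- ape::cophenetic.phylo(tree)
  mean_path <- mean(coph[upper.tri(coph)])
  tree$edge.length <- tree$edge.length * divergence_target / mean_path
  if (divergence_target == 0) tree$edge.length[] <- 0
  refstr <- reference_string(reference)
  seqs <- evolve_along_tree(tree, seq_to_int(refstr), ts_bias)
  structure(
    list(tree = tree, sequences = seqs, reference = refstr,
         map = chrom_map(reference), divergence_target = divergence_target),
    class = "lineage_panel"
  )
}

#' Simulate a strain genome of chosen ploidy
#'
#' A strain genome is a set of `ploidy` haplotypes aligned to reference
#' coordinates. Haplotypes are copies of the lineage sequence carrying
#' additional private mutations, placed so that approximately a fraction
#' `heterozygosity` of sites differ between haplotypes (at each heterozygous
#' site a uniformly chosen number 1..ploidy-1 of copies carries the derived
#' base, so all intermediate B-allele bands are populated). Haploids ignore
#' `heterozygosity`.
#'
#' A fraction `gap_frac` of the genome is marked as coverage gaps: short
#' blocks emulating deleted or highly divergent regions from which the strain
#' contributes no mapped reads. In contaminated mixtures such regions are
#' where contaminant alleles can be called homozygously.
#'
#' @param panel A `lineage_panel`.
#' @param lineage_id Tip label of the lineage the strain belongs to.
#' @param ploidy Integer 1-4.
#' @param heterozygosity Fraction of sites heterozygous between haplotypes,
#'   in `[0, 0.02]`.
#' @param seed Integer seed.
#' @param strain_id Identifier; defaults to `<lineage_id>_s`.
#' @param role One of `"recipient"`, `"contaminant"`, `"panel"`.
#' @param gap_frac Fraction of the genome in coverage gaps (default 0.05).
#' @param gap_block Gap block length in bp.
#' @return An object of class `strain_genome` with `haplotypes` (character
#'   vector of length `ploidy`), `gaps` (sorted integer positions, linear
#'   coordinates), `lineage_id`, `role`, `map`.
#' @export
simulate_strain <- function(panel, lineage_id, ploidy, heterozygosity = 0,
                            seed = 1, strain_id = NULL, role = "recipient",
                            gap_frac = 0.05, gap_block = 100) {
  stopifnot(ploidy %in% 1:4, heterozygosity >= 0, heterozygosity <= 0.02,
            gap_frac >= 0, gap_frac < 1)
  if (!lineage_id %in% names(panel$sequences)) {
    stop("lineage_id '", lineage_id, "' is not a panel lineage")
  }
  set.seed(seed)
  base <- panel$sequences[[lineage_id]]
  L <- nchar(base)
  haps <- matrix(rep(seq_to_int(base), ploidy), nrow = ploidy, byrow = TRUE)
  n_het <- 0L
  if (ploidy >= 2 && heterozygosity > 0) {
    n_het <- round(L * heterozygosity)
    pos <- sample.int(L, n_het)
    k <- sample.int(ploidy - 1, n_het, replace = TRUE)
    which_haps <- lapply(seq_len(n_het), function(i) sample.int(ploidy, k[i]))
    for (i in seq_len(n_het)) {
      cur <- haps[1, pos[i]]
      alt <- sample(setdiff(1:4, cur), 1)
      haps[which_haps[[i]], pos[i]] <- alt
    }
  }
  gaps <- integer(0)
  if (gap_frac > 0) {
    n_blocks <- max(1L, round(L * gap_frac / gap_block))
    starts <- sample.int(max(1L, L - gap_block), n_blocks)
    gaps <- sort(unique(unlist(lapply(starts, function(s) s:(s + gap_block - 1L)))))
    gaps <- gaps[gaps <= L]
  }
  structure(
    list(strain_id = if (is.null(strain_id)) paste0(lineage_id, "_s") else strain_id,
         ploidy = as.integer(ploidy),
         haplotypes = apply(haps, 1, int_to_seq),
         n_het_sites = n_het,
         gaps = gaps,
         lineage_id = lineage_id,
         role = role,
         map = panel$map,
         reference = panel$reference),
    class = "strain_genome"
  )
}

#' Specify a contaminated mixture
#'
#' @param c Contamination fraction in `[0, 1]` (the study grid is
#'   0, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50).
#' @param depth Mean read depth per site (Poisson mean, lambda).
#' @param seed Integer seed.
#' @param eps Per-read per-site sequencing error rate, applied symmetrically
#'   between reference and alternate alleles.
#' @param repeat_frac Fraction of emitted sites that are repeat-like, with
#'   BAF drawn uniformly on (0,1) (emulates multi-copy regions).
#' @param invariant_frac Fraction of additional invariant background sites to
#'   emit (useful when testing the consensus caller); default 0.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(c = 0, depth = 80, seed = 1, eps = 0.002,
                         repeat_frac = 0.01, invariant_frac = 0) {
  stopifnot(c >= 0, c <= 1, depth > 0, eps >= 0, eps < 0.5,
            repeat_frac >= 0, invariant_frac >= 0)
  structure(list(c = c, depth = depth, seed = as.integer(seed), eps = eps,
                 repeat_frac = repeat_frac, invariant_frac = invariant_frac),
            class = "mixture_spec")
}

#' Simulate per-site read allele counts for a (possibly contaminated) strain
#'
#' Emits one record per site at which any haplotype of the recipient or the
#' contaminant differs from the reference. Total depth is
#' Poisson(`spec$depth`) with a floor of 1; of the `d` reads,
#' `m ~ Binomial(d, c)` originate from the contaminant. Each read draws its
#' allele uniformly from the respective strain's haplotypes at that site and
#' is flipped (ref <-> non-ref) with probability `spec$eps`. Reads from a
#' strain are suppressed inside that strain's coverage gaps. Repeat-like and
#' invariant background sites can be added via the spec.
#'
#' @param strain The recipient `strain_genome`.
#' @param contaminant A contaminant `strain_genome`, or `NULL` when
#'   `spec$c == 0`.
#' @param spec A `mixture_spec`.
#' @return A `data.frame` of class `site_records` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_depth` and a `truth` column labelling
#'   each site's origin (`recipient_snp`, `contaminant_snp`, `shared_snp`,
#'   `repeat_like`, `invariant`). The reference chromosome map is attached as
#'   attribute `map`.
#' @export
simulate_read_counts <- function(strain, contaminant = NULL, spec = mixture_spec()) {
  if (spec$c > 0 && is.null(contaminant)) {
    stop("contamination fraction > 0 requires a contaminant strain")
  }
  set.seed(spec$seed)
  ref <- seq_to_int(strain$reference)
  L <- length(ref)
  rh <- do.call(rbind, lapply(strain$haplotypes, seq_to_int))
  r_alt_copies <- colSums(rh != rep(ref, each = nrow(rh)))
  if (!is.null(contaminant)) {
    if (nchar(contaminant$reference) != L) {
      stop("recipient and contaminant must share reference coordinates")
    }
    ch <- do.call(rbind, lapply(contaminant$haplotypes, seq_to_int))
    c_alt_copies <- colSums(ch != rep(ref, each = nrow(ch)))
  } else {
    c_alt_copies <- integer(L)
  }
  sites <- which(r_alt_copies > 0 | c_alt_copies > 0)
  truth <- ifelse(r_alt_copies[sites] > 0 & c_alt_copies[sites] > 0, "shared_snp",
                  ifelse(r_alt_copies[sites] > 0, "recipient_snp", "contaminant_snp"))
  n <- length(sites)

  # Per-strain coverage: reads are assigned to contaminant with prob c, then
  # suppressed if the site lies in the contributing strain's coverage gap.
  d_all <- pmax(1L, rpois(n, spec$depth))
  m_con <- rbinom(n, d_all, spec$c)
  m_rec <- d_all - m_con
  in_rgap <- sites %in% strain$gaps
  m_rec[in_rgap] <- 0L
  if (!is.null(contaminant)) {
    in_cgap <- sites %in% contaminant$gaps
    m_con[in_cgap] <- 0L
  } else {
    m_con[] <- 0L
  }
  d <- m_rec + m_con

  # Allele of each read: uniform over the strain's haplotypes at the site.
  p_alt_rec <- r_alt_copies[sites] / strain$ploidy
  alt_rec <- rbinom(n, m_rec, p_alt_rec)
  p_alt_con <- if (is.null(contaminant)) 0 else c_alt_copies[sites] / contaminant$ploidy
  alt_con <- rbinom(n, m_con, p_alt_con)
  alt <- alt_rec + alt_con
  # Symmetric sequencing error: alt reads flip to ref and vice versa.
  alt <- alt - rbinom(n, alt, spec$eps) + rbinom(n, d - alt, spec$eps)

  keep <- d > 0
  sites <- sites[keep]; d <- d[keep]; alt <- alt[keep]; truth <- truth[keep]

  # Alternate allele character: first non-reference base among haplotypes.
  alt_base <- ref[sites]
  for (h in seq_len(nrow(rh))) {
    sel <- alt_base == ref[sites] & rh[h, sites] != ref[sites]
    alt_base[sel] <- rh[h, sites][sel]
  }
  if (!is.null(contaminant)) {
    for (h in seq_len(nrow(ch))) {
      sel <- alt_base == ref[sites] & ch[h, sites] != ref[sites]
      alt_base[sel] <- ch[h, sites][sel]
    }
  }

  # Repeat-like sites: uniform-BAF noise at otherwise invariant positions.
  n_rep <- round(spec$repeat_frac * length(sites))
  if (n_rep > 0) {
    avail <- setdiff(seq_len(L), sites)
    rpos <- sort(sample(avail, min(n_rep, length(avail))))
    rd <- pmax(1L, rpois(length(rpos), spec$depth))
    ra <- rbinom(length(rpos), rd, runif(length(rpos)))
    rb <- vapply(ref[rpos], function(b) sample(setdiff(1:4, b), 1), integer(1))
    sites <- c(sites, rpos); d <- c(d, rd); alt <- c(alt, ra)
    alt_base <- c(alt_base, rb)
    truth <- c(truth, rep("repeat_like", length(rpos)))
  }

  # Optional invariant background (alt reads arise only from error).
  n_inv <- round(spec$invariant_frac * L)
  if (n_inv > 0) {
    avail <- setdiff(seq_len(L), sites)
    ipos <- sort(sample(avail, min(n_inv, length(avail))))
    id <- pmax(1L, rpois(length(ipos), spec$depth))
    ia <- rbinom(length(ipos), id, spec$eps)
    ib <- vapply(ref[ipos], function(b) sample(setdiff(1:4, b), 1), integer(1))
    sites <- c(sites, ipos); d <- c(d, id); alt <- c(alt, ia)
    alt_base <- c(alt_base, ib)
    truth <- c(truth, rep("invariant", length(ipos)))
  }

  o <- order(sites)
  sites <- sites[o]; d <- d[o]; alt <- alt[o]
  alt_base <- alt_base[o]; truth <- truth[o]
  cc <- linear_to_chrom(sites, strain$map)
  out <- data.frame(
    chrom = cc$chrom, pos = cc$pos,
    ref = .BASE_LEVELS[ref[sites]], alt = .BASE_LEVELS[alt_base],
    depth = as.integer(d), alt_depth = as.integer(alt),
    truth = truth, stringsAsFactors = FALSE
  )
  attr(out, "map") <- strain$map
  class(out) <- c("site_records", "data.frame")
  out
}

#' Mix two paired FASTQ files at a known contamination fraction
#'
#' Samples `round(n_total * (1 - c))` read pairs without replacement from
#' pair `a` and `round(n_total * c)` from pair `b`, shuffles their order, and
#' writes a combined pair. Mate pairing is preserved: the i-th read of each
#' output file forms a pair.
#'
#' @param fastq_a,fastq_b Character vectors of length 2: paths to the R1/R2
#'   FASTQ files (optionally gzipped) of the two sources.
#' @param n_total Total number of output read pairs.
#' @param c Contamination fraction (proportion of pairs drawn from `b`).
#' @param seed Integer seed.
#' @param out_prefix Output path prefix; files are written to
#'   `<out_prefix>_1.fastq[.gz]` and `<out_prefix>_2.fastq[.gz]`.
#' @param gzip Compress output.
#' @return Invisibly, the two output paths.
#' @export
mix_fastq <- function(fastq_a, fastq_b, n_total, c, seed = 1,
                      out_prefix = "mixture", gzip = FALSE) {
  stopifnot(length(fastq_a) == 2, length(fastq_b) == 2, c >= 0, c <= 1)
  set.seed(seed)
  n_b <- round(n_total * c)
  n_a <- n_total - n_b
  a1 <- read_fastq(fastq_a[1]); a2 <- read_fastq(fastq_a[2])
  b1 <- read_fastq(fastq_b[1]); b2 <- read_fastq(fastq_b[2])
  if (nrow(a1) != nrow(a2)) stop("unpaired mates in ", fastq_a[1])
  if (nrow(b1) != nrow(b2)) stop("unpaired mates in ", fastq_b[1])
  if (nrow(a1) < n_a) stop("not enough reads in ", fastq_a[1], ": need ",
                           n_a, ", have ", nrow(a1))
  if (nrow(b1) < n_b) stop("not enough reads in ", fastq_b[1], ": need ",
                           n_b, ", have ", nrow(b1))
  ia <- sample.int(nrow(a1), n_a)
  ib <- sample.int(nrow(b1), n_b)
  ord <- sample.int(n_a + n_b)
  out1 <- rbind(a1[ia, ], b1[ib, ])[ord, ]
  out2 <- rbind(a2[ia, ], b2[ib, ])[ord, ]
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(out_prefix, "_1", ext)
  p2 <- paste0(out_prefix, "_2", ext)
  write_fastq(out1, p1)
  write_fastq(out2, p2)
  invisible(c(p1, p2))
}
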