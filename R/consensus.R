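IUPAC_HET <- c(AG = "R", GA = "R", CT = "Y", TC = "Y",
               GC = "S", CG = "S", AT = "W", TA = "W",
               GT = "K", TG = "K", AC = "M", CA = "M")

log_sum_exp <- function(m) {
  # rowwise log-sum-exp of a matrix of log values
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Genotype-likelihood consensus call for pileup allele counts
#'
#' A simplified diploid (or haploid) consensus caller: genotypes are scored
#' with binomial likelihoods `Binomial(alt_depth; depth, theta)` where theta
#' is `eps` (hom-ref), 0.5 (het) and `1 - eps` (hom-alt) under a flat
#' genotype prior; the call quality is the phred-scaled posterior error of
#' the best genotype, `Q = min(99, round(-10 log10(1 - posterior)))`. Calls
#' with `Q < q_threshold` (default 40, i.e. an estimated error rate above
#' 1 in 10,000) are masked. Depth is capped at 100,000 reads.
#'
#' @param depth,alt_depth Integer vectors of total and alternate-allele read
#'   counts (recycled to common length).
#' @param mode `"diploid"` (default; heterozygous genotypes allowed) or
#'   `"haploid"`.
#' @param eps Per-read error rate.
#' @param q_threshold Phred quality below which a call is masked.
#' @return A `data.frame` with columns `genotype` (`hom-ref`/`het`/`hom-alt`,
#'   or `ref`/`alt` in haploid mode), `qual` (integer phred) and `masked`.
#' @export
#' @examples
#' call_site(80, 40)           # confident heterozygote
#' call_site(1, 1)             # hom-alt but unreachable Q40: masked
call_site <- function(depth, alt_depth, mode = c("diploid", "haploid"),
                      eps = 0.002, q_threshold = 40) {
  mode <- match.arg(mode)
  n <- max(length(depth), length(alt_depth))
  d <- rep_len(as.numeric(depth), n)
  a <- rep_len(as.numeric(alt_depth), n)
  if (any(a > d) || any(a < 0)) stop("alt_depth must be in [0, depth]")
  cap <- d > 1e5
  if (any(cap)) {
    a[cap] <- round(a[cap] * 1e5 / d[cap])
    d[cap] <- 1e5
  }
  thetas <- if (mode == "diploid") c(eps, 0.5, 1 - eps) else c(eps, 1 - eps)
  labels <- if (mode == "diploid") c("hom-ref", "het", "hom-alt") else c("ref", "alt")
  ll <- vapply(thetas, function(th) dbinom(a, d, th, log = TRUE), numeric(n))
  ll <- matrix(ll, nrow = n)
  best <- max.col(ll, ties.method = "first")
  lse_all <- log_sum_exp(ll)
  # log(1 - posterior) computed in log space: logsumexp of the others.
  ll_others <- ll
  ll_others[cbind(seq_len(n), best)] <- -Inf
  log1m_post <- log_sum_exp(ll_others) - lse_all
  qual <- pmin(99, round(-10 * log1m_post / log(10)))
  qual[d == 0] <- 0L
  genotype <- labels[best]
  genotype[d == 0] <- labels[1]
  data.frame(genotype = genotype, qual = as.integer(qual),
             masked = qual < q_threshold, stringsAsFactors = FALSE)
}

#' Call consensus genotypes for a set of site records
#'
#' Applies [call_site()] to every record and attaches the emitted base:
#' the reference base for hom-ref, the alternate for hom-alt, and the
#' two-base IUPAC ambiguity code for heterozygous calls.
#'
#' @param records A `site_records` data frame.
#' @inheritParams call_site
#' @return A `data.frame` of class `consensus_calls` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `genotype`, `base`, `qual`, `masked`.
#' @export
call_sites <- function(records, mode = c("diploid", "haploid"), eps = 0.002,
                       q_threshold = 40) {
  mode <- match.arg(mode)
  cl <- call_site(records$depth, records$alt_depth, mode, eps, q_threshold)
  base <- records$ref
  is_alt <- cl$genotype %in% c("hom-alt", "alt")
  base[is_alt] <- records$alt[is_alt]
  is_het <- cl$genotype == "het"
  if (any(is_het)) {
    base[is_het] <- unname(IUPAC_HET[paste0(records$ref[is_het], records$alt[is_het])])
  }
  out <- data.frame(chrom = records$chrom, pos = records$pos,
                    ref = records$ref, alt = records$alt,
                    genotype = cl$genotype, base = base,
                    qual = cl$qual, masked = cl$masked,
                    stringsAsFactors = FALSE)
  attr(out, "map") <- attr(records, "map")
  class(out) <- c("consensus_calls", "data.frame")
  out
}

#' Build consensus FASTA sequences from calls
#'
#' Starts from the reference and substitutes called bases: alternate alleles
#' at hom-alt sites, IUPAC ambiguity codes at heterozygous sites, and 'N' at
#' masked (low-quality) sites. Uncalled positions keep the reference base;
#' sequence length never changes (indels are out of scope).
#'
#' @param calls A `consensus_calls` data frame (positions unique per
#'   chromosome).
#' @param reference A `reference_genome` or named character vector of
#'   chromosome sequences.
#' @return Named character vector of consensus chromosome sequences.
#' @export
consensus_fasta <- function(calls, reference) {
  chroms <- if (inherits(reference, "reference_genome")) {
    reference$chromosomes
  } else {
    reference
  }
  out <- chroms
  for (cn in unique(calls$chrom)) {
    if (!cn %in% names(out)) stop("unknown chromosome in calls: ", cn)
    sub <- calls[calls$chrom == cn, , drop = FALSE]
    if (anyDuplicated(sub$pos)) stop("duplicate call positions on ", cn)
    if (any(sub$pos > nchar(out[[cn]]))) {
      stop("call position beyond length of ", cn)
    }
    raw <- charToRaw(out[[cn]])
    b <- sub$base
    b[sub$masked] <- "N"
    raw[sub$pos] <- charToRaw(paste(b, collapse = ""))
    out[[cn]] <- rawToChar(raw)
  }
  out
}

#' Count base-call categories in a consensus sequence
#'
#' Tallies high-quality homozygous calls (A/C/G/T), high-quality
#' heterozygous calls (two-base IUPAC codes R/Y/S/W/K/M) and low-quality or
#' masked calls (N and lowercase letters). Counts always sum to the total
#' sequence length.
#'
#' @param seqs A character string or (named) vector of sequences; counts are
#'   pooled.
#' @return An object of class `base_composition`: `hom`, `het`, `low`,
#'   `total`.
#' @export
count_base_calls <- function(seqs) {
  stopifnot(length(seqs) >= 1, all(nchar(seqs) > 0))
  hom_set <- utf8ToInt("ACGT")
  het_set <- utf8ToInt("RYSWKM")
  low_set <- utf8ToInt("Nacgtnryswkm")
  hom <- het <- low <- 0L
  for (i in seq_along(seqs)) {
    v <- utf8ToInt(seqs[[i]])
    known <- v %in% c(hom_set, het_set, low_set)
    if (!all(known)) {
      bad <- which(!known)[1]
      stop("unknown character '", intToUtf8(v[bad]), "' at position ", bad,
           if (!is.null(names(seqs))) paste0(" of ", names(seqs)[i]) else "")
    }
    hom <- hom + sum(v %in% hom_set)
    het <- het + sum(v %in% het_set)
    low <- low + sum(v %in% low_set)
  }
  structure(list(hom = hom, het = het, low = low,
                 total = sum(nchar(seqs))),
            class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  cat("Base-call composition:", x$total, "sites\n")
  cat("  high-quality homozygous:  ", x$hom, "\n")
  cat("  high-quality heterozygous:", x$het, "\n")
  cat("  low-quality/masked:       ", x$low, "\n")
  invisible(x)
}
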