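#' Compute B-allele frequencies from site records
#'
#' The B-allele frequency (BAF) of a site is the fraction of mapped reads
#' carrying the non-reference allele, `alt_depth / depth`. Sites below the
#' depth floor are excluded from the profile (and counted), since their BAFs
#' are too noisy to be informative.
#'
#' @param sites A `site_records` data frame (see [simulate_read_counts()] or
#'   [read_vcf()]).
#' @param min_depth Per-site depth floor; sites with `depth < min_depth` are
#'   dropped.
#' @param genome_id Identifier carried into downstream calls.
#' @return An object of class `baf_profile`: `sites` (with a `baf` column),
#'   `median_depth`, `n_excluded`, `genome_id`, and `chrom_levels`.
#' @export
compute_baf <- function(sites, min_depth = 10, genome_id = "genome") {
  stopifnot(nrow(sites) > 0)
  keep <- sites$depth >= min_depth
  if (!any(keep)) {
    stop("insufficient depth: all ", nrow(sites), " sites are below min_depth = ",
         min_depth)
  }
  s <- sites[keep, , drop = FALSE]
  s$baf <- s$alt_depth / s$depth
  map <- attr(sites, "map")
  lv <- if (!is.null(map)) map$names else unique(s$chrom)
  structure(
    list(genome_id = genome_id, sites = s,
         median_depth = median(s$depth),
         n_excluded = sum(!keep),
         chrom_levels = lv, map = map),
    class = "baf_profile"
  )
}

#' Expected B-allele frequency bands for a ploidy and contamination level
#'
#' In clean data, a site with `k` alternate-allele copies out of ploidy `p`
#' sits at BAF `k/p`: haploids and homozygous sites at 1.0, heterozygous
#' diploids also at 0.5, triploids at 1/3 and 2/3, and so on. With a
#' contaminant fraction `c`, the recipient contributes `(1-c) k/p` and the
#' contaminant adds either 0 (contaminant carries the reference allele) or
#' `c` (contaminant carries the alternate), so the full band set is
#' `{(1-c) k/p : k=1..p}` united with `{(1-c) k/p + c : k=0..p}`, dropping 0.
#' For example, a haploid at 5% contamination shows its SNP band at 0.95 when
#' the contaminant matches the reference.
#'
#' @param p Ploidy, integer 1-4.
#' @param c Contamination fraction in `[0, 0.5]`.
#' @param contaminant_matches_reference If `TRUE`, only the bands produced by
#'   a contaminant carrying the reference allele, `{(1-c) k/p : k=1..p}`, are
#'   returned (the dominant pattern when the contaminant is closer to the
#'   reference than the recipient). Default `FALSE` returns the full model.
#' @return An object of class `band_model` with sorted `positions` in (0,1].
#' @export
#' @examples
#' expected_bands(3, 0)$positions            # 1/3, 2/3, 1
#' expected_bands(1, 0.05, TRUE)$positions   # 0.95
expected_bands <- function(p, c = 0, contaminant_matches_reference = FALSE) {
  stopifnot(p %in% 1:4, c >= 0, c <= 0.5)
  k <- seq_len(p)
  pos <- (1 - c) * k / p
  if (!contaminant_matches_reference && c > 0) {
    pos <- c(pos, (1 - c) * (0:p) / p + c)
  }
  pos <- sort(unique(round(pos[pos > 0], 12)))
  structure(list(ploidy = as.integer(p), contamination = c, positions = pos),
            class = "band_model")
}

# Band positions as seen in reads: sequencing error pulls a band at b to
# b(1-eps) + (1-b)eps.
effective_bands <- function(positions, eps) {
  positions * (1 - eps) + (1 - positions) * eps
}

# Robust band-fit loss: per-site distance to the nearest band in units of
# the binomial standard deviation at that band and the site's depth,
# truncated at 3 SD so off-model (e.g. repeat-like) sites cannot dominate.
band_fit_loss <- function(baf, depth, positions, eps = 0.002, truncate = 3) {
  b <- effective_bands(positions, eps)
  # variance floor keeps z finite for error-free bands at exactly 0 or 1
  z <- row_mins(abs(outer(baf, b, "-")) /
                  sqrt(outer(1 / depth, pmax(b * (1 - b), 1e-12), "*")))
  mean(pmin(z, truncate))
}

row_mins <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Classify ploidy from a BAF profile
#'
#' Fits the clean band model `{k/p}` for each candidate ploidy p in 1..4 and
#' returns the most parsimonious ploidy whose robust band-fit loss is within
#' `tie_tol` (relative) of the best, together with all four scores. Because
#' band sets are nested (every even model contains the simpler bands), plain
#' argmin would always drift to higher ploidy; the tolerance implements the
#' tie-break toward smaller p.
#'
#' @param profile A `baf_profile`.
#' @param min_sites Minimum number of retained SNP sites (default 200).
#' @param eps Sequencing error rate used to position the bands.
#' @param tie_tol Relative loss tolerance for preferring a smaller ploidy.
#' @return List with `ploidy` (integer) and `scores` (named numeric, one loss
#'   per candidate ploidy).
#' @export
classify_ploidy <- function(profile, min_sites = 200, eps = 0.002,
                            tie_tol = 0.10) {
  s <- profile$sites
  if (nrow(s) < min_sites) {
    stop("too few sites to classify ploidy: ", nrow(s), " < ", min_sites)
  }
  scores <- vapply(1:4, function(p) {
    band_fit_loss(s$baf, s$depth, expected_bands(p, 0)$positions, eps)
  }, numeric(1))
  names(scores) <- paste0("p", 1:4)
  best <- min(scores)
  ploidy <- which(scores <= best * (1 + tie_tol) + 1e-12)[1]
  list(ploidy = as.integer(ploidy), scores = scores)
}

# Fraction of sites supporting secondary (contamination-shifted) bands: a
# site counts when it lies within +/- window of a secondary band AND is
# separated from every primary (clean) band by more than the window and
# more than 2 binomial standard deviations of that band at the site's
# depth. The depth-scaled guard keeps ordinary sampling noise around a
# primary band (widest at 0.5) from masquerading as secondary support.
secondary_support <- function(baf, depth, p, c, eps = 0.002, window = 0.03) {
  full <- effective_bands(expected_bands(p, c)$positions, eps)
  primary <- effective_bands(expected_bands(p, 0)$positions, eps)
  secondary <- full[vapply(full, function(b) min(abs(b - primary)) > 1e-9, logical(1))]
  if (length(secondary) == 0) return(0)
  near_sec <- row_mins(abs(outer(baf, secondary, "-"))) <= window
  away_prim <- rep(TRUE, length(baf))
  for (b in primary) {
    thr <- pmax(window, 2 * sqrt(b * (1 - b) / depth))
    away_prim <- away_prim & abs(baf - b) > thr
  }
  mean(near_sec & away_prim)
}

contamination_loss <- function(baf, depth, p, c, eps) {
  band_fit_loss(baf, depth, expected_bands(p, c)$positions, eps)
}

#' Estimate contamination fraction from a BAF profile
#'
#' Scans the contamination fraction c over a grid (default 0.01-0.45 in steps
#' of 0.005) for the two-population band model that minimizes the robust
#' band-fit loss, then refines the best grid point locally. A genome is
#' called contaminated when the fitted fraction is at least `threshold`
#' (default 0.05, the screening rule), the secondary bands carry at least
#' `support_floor` of the SNP sites genome-wide, the secondary signal is
#' present on every chromosome with at least `min_chrom_snps` SNPs (a
#' genome-wide signature; chromosome-local shifts indicate aneuploidy
#' instead), and the profile's median depth reaches `depth_floor`.
#' Fractions near the 0.45 bound are indistinguishable from polyploidy.
#'
#' @param profile A `baf_profile`.
#' @param p Ploidy (from [classify_ploidy()] or known).
#' @param threshold Contamination call threshold on `c_hat` (default 0.05).
#' @param support_floor Minimum genome-wide fraction of SNPs within
#'   `band_window` of a secondary band (default 0.05).
#' @param band_window Half-width around a band position (default 0.03).
#' @param min_chrom_snps Chromosomes with fewer SNPs are not required to show
#'   the secondary band (default 100).
#' @param depth_floor Minimum median depth for a reliable call (default 30).
#' @param eps Sequencing error rate.
#' @param c_grid Grid of candidate contamination fractions.
#' @return An object of class `contamination_call`: `genome_id`, `ploidy`,
#'   `contaminated`, `c_hat`, `secondary_band_fraction`, `per_chromosome_c`,
#'   `aneuploidy_suspect`, `depth_ok`, `loss`, `note`.
#' @export
estimate_contamination <- function(profile, p, threshold = 0.05,
                                   support_floor = 0.05, band_window = 0.03,
                                   min_chrom_snps = 100, depth_floor = 30,
                                   eps = 0.002,
                                   c_grid = seq(0.01, 0.45, by = 0.005)) {
  s <- profile$sites
  baf <- s$baf
  depth <- s$depth
  losses <- vapply(c_grid, function(cc) contamination_loss(baf, depth, p, cc, eps),
                   numeric(1))
  i <- which.min(losses)
  lo <- c_grid[max(1, i - 1)]
  hi <- c_grid[min(length(c_grid), i + 1)]
  opt <- optimize(function(cc) contamination_loss(baf, depth, p, cc, eps),
                  interval = c(lo, hi))
  c_hat <- opt$minimum
  if (opt$objective > losses[i]) c_hat <- c_grid[i]
  support <- secondary_support(baf, depth, p, c_hat, eps, band_window)

  per_chrom <- lapply(split(seq_len(nrow(s)), s$chrom), function(idx) {
    if (length(idx) < min_chrom_snps) {
      return(list(n = length(idx), c_hat = NA_real_, support = NA_real_))
    }
    l <- vapply(c_grid,
                function(cc) contamination_loss(baf[idx], depth[idx], p, cc, eps),
                numeric(1))
    ch <- c_grid[which.min(l)]
    list(n = length(idx), c_hat = ch,
         support = secondary_support(baf[idx], depth[idx], p, c_hat, eps, band_window))
  })
  chrom_ok <- vapply(per_chrom, function(x) {
    is.na(x$support) || x$support >= support_floor
  }, logical(1))
  informative <- vapply(per_chrom, function(x) !is.na(x$support), logical(1))

  depth_ok <- profile$median_depth >= depth_floor
  if (!depth_ok) {
    warning("median depth ", profile$median_depth, " is below ", depth_floor,
            "x; contamination calls are unreliable at low depth")
  }
  evidence <- c_hat >= threshold && support >= support_floor
  genome_wide <- all(chrom_ok) && any(informative)
  contaminated <- evidence && genome_wide && depth_ok
  aneuploidy_suspect <- evidence && !genome_wide
  note <- if (c_hat >= max(c_grid) - 0.005) {
    "fraction at scan bound; indistinguishable from polyploidy"
  } else ""
  structure(
    list(genome_id = profile$genome_id, ploidy = as.integer(p),
         contaminated = contaminated, c_hat = c_hat,
         secondary_band_fraction = support,
         per_chromosome_c = per_chrom,
         aneuploidy_suspect = aneuploidy_suspect,
         depth_ok = depth_ok, median_depth = profile$median_depth,
         loss = min(opt$objective, losses[i]), note = note),
    class = "contamination_call"
  )
}

#' @export
print.contamination_call <- function(x, ...) {
  cat("Contamination call for", x$genome_id, "\n")
  cat("  ploidy:", x$ploidy, "\n")
  cat("  c_hat:", format(x$c_hat, digits = 3),
      if (x$contaminated) "(CONTAMINATED)" else "", "\n")
  cat("  secondary band support:", format(x$secondary_band_fraction, digits = 3), "\n")
  cat("  aneuploidy suspect:", x$aneuploidy_suspect,
      " depth ok:", x$depth_ok, "\n")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Export plot-ready BAF data
#'
#' Returns a per-site table (chrom, pos, baf, depth) in genome-coordinate
#' order, with `chrom` as a factor over all reference chromosomes so that
#' empty chromosomes still appear as axis segments.
#'
#' @param profile A `baf_profile`.
#' @return A `data.frame` ordered by (chrom, pos).
#' @export
export_plot_data <- function(profile) {
  s <- profile$sites
  out <- data.frame(
    chrom = factor(s$chrom, levels = profile$chrom_levels),
    pos = s$pos, baf = s$baf, depth = s$depth
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Plot a B-allele frequency profile
#'
#' BAF against genome position with chromosome panels, the standard visual
#' screen for ploidy, aneuploidy and contamination.
#'
#' @param profile A `baf_profile`.
#' @param bands Optional `band_model` whose positions are drawn as guides.
#' @return A ggplot object.
#' @export
plot_baf <- function(profile, bands = NULL) {
  d <- export_plot_data(profile)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = pos, y = baf)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x",
                        drop = FALSE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position", y = "B-allele frequency",
                  title = profile$genome_id)
  if (!is.null(bands)) {
    gg <- gg + ggplot2::geom_hline(yintercept = bands$positions,
                                   linetype = "dashed", colour = "red",
                                   linewidth = 0.3)
  }
  gg
}
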