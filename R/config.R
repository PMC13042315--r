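#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end contamination experiment:
#' simulate strains over a lineage panel, contaminate them at a grid of
#' known fractions, screen BAF profiles, call consensus bases, count base
#' categories and (optionally) place the contaminated genome in the panel
#' phylogeny.
#'
#' @param seed Master seed; every stage derives a child seed from it.
#' @param levels Contamination fractions (default the study grid
#'   0, 1, 5, 10, 20, 30, 40, 50%).
#' @param ploidies Recipient ploidies to simulate.
#' @param depth Mean read depth (lambda).
#' @param eps Sequencing error rate.
#' @param genome_length,n_chrom Reference genome size and chromosome count.
#' @param divergence Mean pairwise divergence of the lineage panel.
#' @param heterozygosity Within-strain heterozygosity for ploidy >= 2.
#' @param panel_size Number of panel lineages.
#' @param gap_frac Recipient coverage-gap fraction.
#' @param repeat_frac Repeat-like site fraction.
#' @param boot Bootstrap replicates for panel trees (0 = none).
#' @param c_threshold Contamination call threshold (0.05).
#' @param q_threshold Phred masking threshold (40).
#' @param depth_floor Median-depth reliability floor (30).
#' @param min_depth Per-site depth floor for BAF profiles (10).
#' @param tree Build NJ trees and placement diagnostics per cell.
#' @param out_dir Output directory (NULL = return results only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       levels = c(0, 0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
                       ploidies = 1:4,
                       depth = 80, eps = 0.002,
                       genome_length = 1e5, n_chrom = 2,
                       divergence = 0.01, heterozygosity = 0.005,
                       panel_size = 52, gap_frac = 0.05, repeat_frac = 0.01,
                       boot = 0, c_threshold = 0.05, q_threshold = 40,
                       depth_floor = 30, min_depth = 10,
                       tree = FALSE, out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), levels = levels, ploidies = ploidies,
              depth = depth, eps = eps, genome_length = genome_length,
              n_chrom = n_chrom, divergence = divergence,
              heterozygosity = heterozygosity, panel_size = panel_size,
              gap_frac = gap_frac, repeat_frac = repeat_frac, boot = boot,
              c_threshold = c_threshold, q_threshold = q_threshold,
              depth_floor = depth_floor, min_depth = min_depth,
              tree = isTRUE(tree), out_dir = out_dir)
  stopifnot(all(cfg$levels >= 0), all(cfg$levels <= 0.5),
            all(cfg$ploidies %in% 1:4),
            cfg$depth > 0, cfg$c_threshold > 0, cfg$q_threshold > 0,
            cfg$depth_floor > 0, cfg$min_depth > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration (YAML)
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `write_config`: invisibly, `path`; `read_config`: a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  do.call(run_config, vals)
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the end-to-end contamination experiment
#'
#' For every ploidy x contamination level: simulate a recipient strain over
#' a shared lineage panel, contaminate it at the known fraction, screen the
#' BAF profile (ploidy classification + contamination estimate), call
#' consensus bases with Q40 masking, count base-call categories, and, when
#' `config$tree` is set, build a neighbor-joining tree of the panel plus the
#' contaminated consensus and compare its topology against the same strain's
#' clean (c = 0) tree. Fully reproducible from the configuration alone.
#'
#' @param config A `run_config`.
#' @return List of class `experiment_report`: `report` (one data frame row
#'   per cell), `config`, `panel`, `contaminant_lineage`,
#'   `recipient_lineage`, `trees` (when built). Cells that fail are recorded
#'   in the report's `error` column and the run continues.
#' @export
run_experiment <- function(config = run_config()) {
  seed <- config$seed
  ref <- random_reference(config$genome_length, config$n_chrom,
                          seed = child_seed(seed, "reference"))
  panel <- simulate_panel(ref, config$panel_size, config$divergence,
                          seed = child_seed(seed, "panel"))
  # Recipient and contaminant: genetically distinct lineages at typical
  # (mean) within-panel divergence. Their shared ancestry below the
  # reference mirrors the variant backbone that strains of one species
  # share when mapped to a strain reference.
  coph <- ape::cophenetic.phylo(panel$tree)
  off <- coph[upper.tri(coph)]
  pick <- which(abs(coph - mean(off)) == min(abs(coph - mean(off))) &
                  upper.tri(coph), arr.ind = TRUE)[1, ]
  recipient_lineage <- rownames(coph)[pick[1]]
  contaminant_lineage <- rownames(coph)[pick[2]]
  # Lineage sets for placement diagnostics: each strain's close relatives
  # (sharing more than half their ancestry), assigned to the nearer of the
  # two focal strains so the sets are disjoint.
  radius <- mean(off) / 2
  d_rec <- coph[recipient_lineage, ]
  d_con <- coph[contaminant_lineage, ]
  recipient_set <- names(d_rec)[d_rec < radius & d_rec <= d_con]
  contaminant_set <- names(d_con)[d_con < radius & d_con < d_rec]
  contaminant_set <- union(contaminant_set, contaminant_lineage)
  contaminant <- simulate_strain(panel, contaminant_lineage, ploidy = 1,
                                 seed = child_seed(seed, "contaminant"),
                                 strain_id = "donor", role = "contaminant",
                                 gap_frac = 0)
  levels <- sort(unique(config$levels))
  tree_levels <- if (config$tree && !0 %in% levels) c(0, levels) else levels

  rows <- list()
  trees <- list()
  for (p in config$ploidies) {
    het <- if (p >= 2) config$heterozygosity else 0
    recipient <- simulate_strain(panel, recipient_lineage, ploidy = p,
                                 heterozygosity = het,
                                 seed = child_seed(seed, paste0("strain_p", p)),
                                 strain_id = paste0("recipient_p", p),
                                 role = "recipient",
                                 gap_frac = config$gap_frac)
    baseline <- NULL
    for (cc in tree_levels) {
      cell <- paste0("p", p, "_c", cc)
      res <- tryCatch({
        spec <- mixture_spec(c = cc, depth = config$depth,
                             seed = child_seed(seed, paste0("reads_", cell)),
                             eps = config$eps,
                             repeat_frac = config$repeat_frac)
        rec <- simulate_read_counts(recipient,
                                    if (cc > 0) contaminant else NULL, spec)
        prof <- compute_baf(rec, min_depth = config$min_depth,
                            genome_id = cell)
        cls <- tryCatch(classify_ploidy(prof, eps = config$eps),
                        error = function(e) list(ploidy = NA_integer_))
        # the simulation knows the recipient's true ploidy; fall back to it
        # when the profile is too sparse to classify
        p_use <- if (is.na(cls$ploidy)) p else cls$ploidy
        call <- estimate_contamination(prof, p_use,
                                       threshold = config$c_threshold,
                                       depth_floor = config$depth_floor,
                                       eps = config$eps)
        calls <- call_sites(rec, mode = "diploid", eps = config$eps,
                            q_threshold = config$q_threshold)
        cons <- consensus_fasta(calls, ref)
        comp <- count_base_calls(cons)
        rf <- NA_integer_; sister <- NA; within_rec <- NA
        if (config$tree) {
          aln <- c(panel$sequences, focal = paste(cons, collapse = ""))
          tr <- nj_tree(distance_matrix(aln, model = "TN93"))
          trees[[cell]] <- tr
          if (cc == 0) baseline <- tr
          pr <- placement_report(tr, "focal",
                                 contaminant_lineage = contaminant_set,
                                 recipient_lineage = recipient_set,
                                 baseline = baseline)
          rf <- pr$rf_to_baseline
          sister <- pr$sister_to_contaminant
          within_rec <- pr$within_recipient
        }
        data.frame(ploidy = p, c = cc, n_sites = nrow(prof$sites),
                   median_depth = prof$median_depth,
                   ploidy_hat = cls$ploidy, c_hat = call$c_hat,
                   contaminated = call$contaminated,
                   aneuploidy_suspect = call$aneuploidy_suspect,
                   secondary_band_fraction = call$secondary_band_fraction,
                   hom = comp$hom, het = comp$het, low = comp$low,
                   rf_to_clean = rf, sister_to_contaminant = sister,
                   within_recipient = within_rec,
                   error = "", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(ploidy = p, c = cc, n_sites = NA, median_depth = NA,
                   ploidy_hat = NA, c_hat = NA, contaminated = NA,
                   aneuploidy_suspect = NA, secondary_band_fraction = NA,
                   hom = NA, het = NA, low = NA, rf_to_clean = NA,
                   sister_to_contaminant = NA, within_recipient = NA,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      if (cc %in% levels) rows[[cell]] <- res
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  out <- structure(
    list(report = report, config = config, panel = panel,
         contaminant_lineage = contaminant_lineage,
         recipient_lineage = recipient_lineage,
         contaminant_set = contaminant_set,
         recipient_set = recipient_set,
         trees = if (config$tree) trees else NULL),
    class = "experiment_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "experiment_report.tsv")
    con <- file(path, "w")
    writeLines(paste0("# bafscreen ", as.character(utils::packageVersion("bafscreen")),
                      " config=", config_hash(config), " seed=", seed), con)
    write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  out
}
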