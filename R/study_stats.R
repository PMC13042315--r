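#' Construct a study contamination-count table
#'
#' @param study Character vector of study identifiers.
#' @param uncontaminated,contaminated Non-negative integer counts of genomes
#'   per study.
#' @return An object of class `study_table` (a data frame).
#' @export
study_table <- function(study, uncontaminated, contaminated) {
  stopifnot(length(study) >= 2,
            length(uncontaminated) == length(study),
            length(contaminated) == length(study),
            all(uncontaminated >= 0), all(contaminated >= 0),
            all(uncontaminated == round(uncontaminated)),
            all(contaminated == round(contaminated)))
  out <- data.frame(study = as.character(study),
                    uncontaminated = as.integer(uncontaminated),
                    contaminated = as.integer(contaminated),
                    stringsAsFactors = FALSE)
  class(out) <- c("study_table", "data.frame")
  out
}

#' Contamination screening counts for public S. cerevisiae sequencing projects
#'
#' Counts of genome sequence samples called uncontaminated vs contaminated
#' (at least 5% intraspecies contamination) in five public SRA projects,
#' among 1,298 high-depth S. cerevisiae genomes.
#'
#' @param exclude Optional character vector of study ids to drop.
#' @return A `study_table`.
#' @export
sra_study_counts <- function(exclude = NULL) {
  path <- system.file("extdata", "sra_study_counts.tsv", package = "bafscreen")
  tab <- read_study_table(path)
  if (!is.null(exclude)) tab <- tab[!tab$study %in% exclude, , drop = FALSE]
  class(tab) <- c("study_table", "data.frame")
  tab
}

# Enumerate all r x 2 tables with the observed margins: compositions of the
# contaminated-column total over the rows, capped by row sums. Log-space
# multivariate hypergeometric probabilities.
enumerate_rx2 <- function(row_totals, col2_total) {
  r <- length(row_totals)
  comps <- list(integer(0))
  for (i in seq_len(r)) {
    remaining_cap <- if (i < r) sum(row_totals[(i + 1):r]) else 0
    comps <- unlist(lapply(comps, function(x) {
      used <- sum(x)
      lo <- max(0L, col2_total - used - remaining_cap)
      hi <- min(row_totals[i], col2_total - used)
      if (hi < lo) return(list())
      lapply(lo:hi, function(v) c(x, v))
    }), recursive = FALSE)
  }
  do.call(rbind, comps)
}

#' Exact Fisher test for an r x 2 contingency table
#'
#' Two-sided exact test of homogeneity of the contaminated proportion across
#' studies, by complete enumeration of all tables with the observed margins.
#' The p-value is the total multivariate-hypergeometric probability of
#' tables whose probability does not exceed that of the observed table
#' (probability-ordering criterion, the same convention as [stats::fisher.test()]
#' for r x c tables). Probabilities are computed in log space.
#'
#' @param table A `study_table` (or data frame with columns
#'   `uncontaminated` and `contaminated`).
#' @return The p-value, with attributes `n_tables` (number of enumerated
#'   tables) and `observed_logp`.
#' @export
#' @examples
#' tab <- study_table(c("A", "B"), c(10, 10), c(0, 5))
#' fisher_exact_rx2(tab)
fisher_exact_rx2 <- function(table) {
  n_i <- table$uncontaminated + table$contaminated
  x_obs <- table$contaminated
  if (any(n_i <= 0)) stop("every row must have a positive total")
  S <- sum(x_obs)
  N <- sum(n_i)
  if (S == 0 || S == N) {
    out <- 1
    attr(out, "n_tables") <- 1L
    attr(out, "observed_logp") <- 0
    return(out)
  }
  tables <- enumerate_rx2(n_i, S)
  lp <- matrix(0, nrow(tables), length(n_i))
  for (i in seq_along(n_i)) lp[, i] <- lchoose(n_i[i], tables[, i])
  logp <- rowSums(lp) - lchoose(N, S)
  logp_obs <- sum(lchoose(n_i, x_obs)) - lchoose(N, S)
  p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
  p <- min(1, p)
  attr(p, "n_tables") <- nrow(tables)
  attr(p, "observed_logp") <- logp_obs
  p
}

#' Per-study and pooled contamination rate summary
#'
#' @param table A `study_table`.
#' @return List with `per_study` (data frame adding `total` and `percent`)
#'   and `pooled` (list with `contaminated`, `total`, `percent`).
#' @export
rate_summary <- function(table) {
  total <- table$uncontaminated + table$contaminated
  pct <- 100 * table$contaminated / total
  per_study <- data.frame(study = table$study,
                          uncontaminated = table$uncontaminated,
                          contaminated = table$contaminated,
                          total = total, percent = pct,
                          stringsAsFactors = FALSE)
  pooled <- list(contaminated = sum(table$contaminated),
                 total = sum(total),
                 percent = 100 * sum(table$contaminated) / sum(total))
  list(per_study = per_study, pooled = pooled)
}
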