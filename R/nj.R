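#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking: among joins
#' with equal (within 1e-12) Q criterion the pair with the lowest row index,
#' then lowest column index, in the current taxon ordering is merged.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sister branch of the same join, preserving path lengths. NJ is
#' exact on additive matrices: it recovers the generating topology and
#' branch lengths.
#'
#' @param D A `distance_matrix` object, or a symmetric numeric matrix with
#'   dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "distance_matrix")) D <- D$D
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (any(is.na(D))) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distances for pairs: ",
         paste(rownames(D)[bad[, 1]], colnames(D)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  # Each active cluster is a newick fragment; joins nest fragments.
  labs <- rownames(D)
  frag <- labs
  d <- D
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (q[i, j] < best - 1e-12) { best <- q[i, j]; bi <- i; bj <- j }
      }
    }
    li <- d[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    lj <- d[bi, bj] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[bi], ":", fmt(li), ",", frag[bj], ":", fmt(lj), ")")
    newd <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(n), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    n <- n - 1
  }
  la <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The count of non-trivial bipartitions present in one tree but not the
#' other (symmetric difference).
#'
#' @param tree_a,tree_b [ape::phylo] trees over the same taxa.
#' @return Integer RF distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of the full-data tree
#' the percentage of replicate trees containing the same bipartition.
#' Replicates in which some pairwise distance is undefined (saturated) are
#' dropped and counted; more than 20% dropped replicates is an error.
#'
#' @param alignment Named character vector of equal-length sequences
#'   (>= 4 taxa).
#' @param model `"TN93"` or `"F84"`.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param tstv_ratio Transition:transversion ratio for F84.
#' @return An object of class `phylo_result`: `tree` (full-data NJ tree with
#'   `node.label` carrying integer percentage supports; the basal
#'   trifurcation has no support value), `support`, `n_reps`, `n_dropped`,
#'   `model`.
#' @export
bootstrap_support <- function(alignment, model = c("TN93", "F84"),
                              n_reps = 100, seed = 1, tstv_ratio = 0.5) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1)
  m <- encode_alignment(unlist(alignment))
  if (ncol(m) < 4) stop("bootstrap trees need at least 4 taxa")
  full <- nj_tree(matrix_distances(m, model, tstv_ratio))
  set.seed(seed)
  boots <- list()
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    D <- matrix_distances(m[idx, , drop = FALSE], model, tstv_ratio)
    if (any(is.na(D))) {
      dropped <- dropped + 1L
      next
    }
    boots[[length(boots) + 1]] <- nj_tree(D)
  }
  if (dropped > 0.2 * n_reps) {
    stop(dropped, " of ", n_reps, " bootstrap replicates had undefined ",
         "distances (saturation); alignment unsuitable for bootstrapping")
  }
  n_used <- length(boots)
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  support <- round(100 * counts / n_used)
  # The basal node of the stored unrooted tree is not a bipartition.
  support[1] <- NA
  full$node.label <- ifelse(is.na(support), "", as.character(support))
  structure(list(tree = full, support = support, n_reps = n_used,
                 n_dropped = dropped, model = model),
            class = "phylo_result")
}

# Distance matrix straight from an encoded alignment (shared by the
# bootstrap loop so encoding happens once).
matrix_distances <- function(m, model, tstv_ratio = 0.5) {
  st <- pair_site_stats(m)
  N <- ncol(m)
  D <- matrix(0, N, N, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      n <- st$used[i, j]
      if (n == 0) { D[i, j] <- D[j, i] <- NA_real_; next }
      counts <- c(st$cA[i, j], st$cG[i, j], st$cC[i, j], st$cT[i, j])
      freqs <- counts / (2 * n)
      v <- if (model == "TN93") {
        tn93_value(n, st$ts_purine[i, j], st$ts_pyrimidine[i, j],
                   st$tv[i, j], freqs)
      } else {
        f84_value(n, st$ts_purine[i, j], st$ts_pyrimidine[i, j],
                  st$tv[i, j], freqs, tstv_ratio)
      }
      D[i, j] <- D[j, i] <- v
    }
  }
  D
}

# Tip-label sets hanging off the attachment node of a tip, one per incident
# edge (excluding the tip itself). Works on the unrooted tree.
neighbor_subtrees <- function(tree, tip_label) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tip <- match(tip_label, tree$tip.label)
  if (is.na(tip)) stop("taxon '", tip_label, "' not in tree")
  edge <- tree$edge
  v <- edge[edge[, 2] == tip, 1]
  # adjacency over the unrooted tree
  adj <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nbrs <- setdiff(adj[[v]], tip)
  lapply(nbrs, function(start) {
    seen <- c(v)
    stack <- start
    tips <- integer(0)
    while (length(stack)) {
      node <- stack[[1]]; stack <- stack[-1]
      seen <- c(seen, node)
      if (node <= ntip) tips <- c(tips, node)
      stack <- c(stack, setdiff(adj[[node]], seen))
    }
    tree$tip.label[tips]
  })
}

#' Phylogenetic placement diagnostics for a focal taxon
#'
#' Reports whether the focal taxon is sister to the contaminant lineage
#' (some subtree attached at the focal taxon's node consists entirely of
#' contaminant-lineage taxa), whether it remains within the recipient
#' lineage (same test against the recipient set), and the Robinson-Foulds
#' distance to a baseline tree.
#'
#' @param result A `phylo_result` or an [ape::phylo] tree.
#' @param focal Focal taxon label.
#' @param contaminant_lineage,recipient_lineage Disjoint character sets of
#'   taxon labels.
#' @param baseline Optional baseline tree for the RF comparison.
#' @return List with `sister_to_contaminant`, `within_recipient`,
#'   `rf_to_baseline` (NA if no baseline given).
#' @export
placement_report <- function(result, focal, contaminant_lineage,
                             recipient_lineage, baseline = NULL) {
  tree <- if (inherits(result, "phylo_result")) result$tree else result
  if (!focal %in% tree$tip.label) stop("focal taxon '", focal, "' not in tree")
  if (length(intersect(contaminant_lineage, recipient_lineage)) > 0) {
    stop("contaminant and recipient lineages must be disjoint")
  }
  subs <- neighbor_subtrees(tree, focal)
  sis_con <- any(vapply(subs, function(s) {
    length(s) > 0 && all(s %in% contaminant_lineage)
  }, logical(1)))
  sis_rec <- any(vapply(subs, function(s) {
    length(s) > 0 && all(s %in% recipient_lineage)
  }, logical(1)))
  rf <- if (is.null(baseline)) NA_integer_ else rf_distance(tree, baseline)
  list(sister_to_contaminant = sis_con, within_recipient = sis_rec,
       rf_to_baseline = rf)
}

#' Root and ladderize a tree for presentation
#'
#' @param tree An [ape::phylo].
#' @param outgroup Character vector of outgroup taxa.
#' @return A rooted, right-ladderized tree.
#' @export
root_ladderize <- function(tree, outgroup) {
  ape::ladderize(ape::root(tree, outgroup, resolve.root = TRUE), right = TRUE)
}
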