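# Encode sequences for distance computation: IUPAC ambiguity codes and N are
# treated as missing data (heterozygous sites carry no distance information),
# so pairwise deletion drops them.
encode_alignment <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("all sequences must have equal length")
  m <- vapply(seqs, seq_to_int, integer(L))
  storage.mode(m) <- "integer"
  m
}

pair_counts <- function(a, b) {
  ia <- seq_to_int(a); ib <- seq_to_int(b)
  keep <- ia > 0L & ib > 0L
  ia <- ia[keep]; ib <- ib[keep]
  n <- length(ia)
  diff <- ia != ib
  both_pur <- ia <= 2L & ib <= 2L
  both_pyr <- ia >= 3L & ib >= 3L
  ts1 <- sum(diff & both_pur)
  ts2 <- sum(diff & both_pyr)
  tv <- sum(diff & !(both_pur | both_pyr))
  counts <- tabulate(c(ia, ib), 4)
  list(n = n, ts1 = ts1, ts2 = ts2, tv = tv,
       freqs = if (n > 0) counts / (2 * n) else rep(NA_real_, 4))
}

#' Tamura-Nei (TN93) pairwise distance
#'
#' Closed-form TN93 distance computed from the proportions of purine
#' transitions (P1), pyrimidine transitions (P2) and transversions (Q), with
#' base frequencies estimated empirically from the pooled pair. Sites where
#' either sequence is not plain A/C/G/T (IUPAC ambiguity codes, N, gaps) are
#' excluded pairwise: heterozygous consensus positions are missing data.
#'
#' @param seq_a,seq_b Equal-length sequence strings.
#' @return Distance in substitutions/site, or `NA` if saturated (a log
#'   argument became non-positive).
#' @export
tn93_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  pc <- pair_counts(seq_a, seq_b)
  if (pc$n == 0) stop("no usable sites shared by the two sequences")
  tn93_value(pc$n, pc$ts1, pc$ts2, pc$tv, pc$freqs)
}

# The actual TN93 estimator (used by both the scalar and matrix paths).
tn93_value <- function(n, ts1, ts2, tv, freqs) {
  P1 <- ts1 / n; P2 <- ts2 / n; Q <- tv / n
  if (P1 + P2 + Q == 0) return(0)
  pa <- freqs[1]; pg <- freqs[2]; pc <- freqs[3]; pt <- freqs[4]
  R <- pa + pg; Y <- pc + pt
  if (R <= 0 || Y <= 0) return(NA_real_)
  k1 <- 2 * pa * pg / R
  k2 <- 2 * pc * pt / Y
  k3 <- 2 * (R * Y - pa * pg * Y / R - pc * pt * R / Y)
  d <- 0
  if (k1 > 0) {
    w1 <- 1 - P1 / k1 - Q / (2 * R)
    if (w1 <= 0) return(NA_real_)
    d <- d - k1 * log(w1)
  } else if (P1 > 0) return(NA_real_)
  if (k2 > 0) {
    w2 <- 1 - P2 / k2 - Q / (2 * Y)
    if (w2 <= 0) return(NA_real_)
    d <- d - k2 * log(w2)
  } else if (P2 > 0) return(NA_real_)
  w3 <- 1 - Q / (2 * R * Y)
  if (w3 <= 0) return(NA_real_)
  d - k3 * log(w3)
}

# F84 transition-probability matrix under the two-event representation:
# general events at rate b draw a base from pi; within-class events at rate
# k draw from the class-conditional frequencies. Rates are normalized so one
# unit of t is one expected substitution per site.
f84_params <- function(freqs, tstv_ratio) {
  pa <- freqs[1]; pg <- freqs[2]; pc <- freqs[3]; pt <- freqs[4]
  R <- pa + pg; Y <- pc + pt
  ts_base <- 2 * (pa * pg + pc * pt)          # transitions from general events
  ts_within <- 2 * (pa * pg / R + pc * pt / Y) # per unit of within-class rate
  tv_rate <- 2 * R * Y
  k <- (tstv_ratio * tv_rate - ts_base) / ts_within
  if (k < -1e-9) {
    warning("tstv ratio below the F84 minimum for these base frequencies; ",
            "using the F81 limit")
  }
  k <- max(0, k)
  b <- 1
  mu <- b * (tv_rate + ts_base) + k * ts_within
  list(b = b / mu, k = k / mu, freqs = freqs, R = R, Y = Y)
}

f84_pmat <- function(t, par) {
  freqs <- par$freqs
  classfreq <- c(par$R, par$R, par$Y, par$Y)
  e_b <- exp(-par$b * t)
  e_k <- exp(-par$k * t)
  P <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      same_class <- (i <= 2) == (j <= 2)
      P[i, j] <- (1 - e_b) * freqs[j] +
        (if (same_class) e_b * (1 - e_k) * freqs[j] / classfreq[i] else 0) +
        (if (i == j) e_b * e_k else 0)
    }
  }
  P
}

f84_value <- function(n, ts1, ts2, tv, freqs, tstv_ratio) {
  if (ts1 + ts2 + tv == 0) return(0)
  par <- f84_params(freqs, tstv_ratio)
  # Observed 2x2-class pattern counts: same, purine ts, pyrimidine ts, tv.
  n_same <- n - ts1 - ts2 - tv
  pa <- freqs[1]; pg <- freqs[2]; pc <- freqs[3]; pt <- freqs[4]
  loglik <- function(t) {
    P <- f84_pmat(t, par)
    # probabilities of the site-pattern classes under stationarity
    p_ts1 <- 2 * pa * P[1, 2]  # A<->G (detailed balance: pa Pag = pg Pga)
    p_ts2 <- 2 * pc * P[3, 4]
    p_tv <- pa * (P[1, 3] + P[1, 4]) + pg * (P[2, 3] + P[2, 4]) +
      pc * (P[3, 1] + P[3, 2]) + pt * (P[4, 1] + P[4, 2])
    p_same <- 1 - p_ts1 - p_ts2 - p_tv
    if (p_same <= 0) return(-Inf)
    n_same * log(p_same) +
      (if (ts1 > 0) ts1 * log(max(p_ts1, 1e-300)) else 0) +
      (if (ts2 > 0) ts2 * log(max(p_ts2, 1e-300)) else 0) +
      (if (tv > 0) tv * log(max(p_tv, 1e-300)) else 0)
  }
  opt <- optimize(loglik, interval = c(1e-9, 10), maximum = TRUE, tol = 1e-8)
  # refine in a narrow bracket for closed-form-level precision
  w <- max(1e-7, 0.01 * opt$maximum)
  opt <- optimize(loglik, interval = c(max(1e-12, opt$maximum - w),
                                       opt$maximum + w),
                  maximum = TRUE, tol = 1e-12)
  if (opt$maximum > 9.5 || !is.finite(opt$objective)) return(NA_real_)
  opt$maximum
}

#' F84 pairwise distance with a fixed transition:transversion ratio
#'
#' Maximum-likelihood F84 distance given a fixed expected
#' transition:transversion ratio (default 0.5, the classic dnadist setting)
#' and empirical base frequencies pooled over the pair. Ambiguity codes and
#' N are missing data (pairwise deletion). With equal base frequencies and
#' ratio 0.5 the model reduces to Jukes-Cantor.
#'
#' @inheritParams tn93_distance
#' @param tstv_ratio Expected transition:transversion ratio (> 0).
#' @return Distance in substitutions/site, or `NA` when saturated.
#' @export
f84_distance <- function(seq_a, seq_b, tstv_ratio = 0.5) {
  stopifnot(tstv_ratio > 0)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  pc <- pair_counts(seq_a, seq_b)
  if (pc$n == 0) stop("no usable sites shared by the two sequences")
  f84_value(pc$n, pc$ts1, pc$ts2, pc$tv, pc$freqs, tstv_ratio)
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all pairwise TN93 or F84 distances with pairwise deletion of
#' missing data, using a compiled kernel for the site-pattern counts.
#'
#' @param seqs Named character vector (or list) of equal-length sequences.
#' @param model `"TN93"` (default) or `"F84"`.
#' @param tstv_ratio Transition:transversion ratio for F84.
#' @return An object of class `distance_matrix`: `taxa`, `D` (symmetric
#'   numeric matrix, zero diagonal, `NA` for saturated pairs) and `n_used`
#'   (pairwise usable-site counts).
#' @export
distance_matrix <- function(seqs, model = c("TN93", "F84"), tstv_ratio = 0.5) {
  model <- match.arg(model)
  seqs <- unlist(seqs)
  m <- encode_alignment(seqs)
  st <- pair_site_stats(m)
  N <- ncol(m)
  D <- matrix(0, N, N, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      n <- st$used[i, j]
      if (n == 0) {
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
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
  structure(list(taxa = colnames(m), D = D, n_used = st$used,
                 model = model),
            class = "distance_matrix")
}
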