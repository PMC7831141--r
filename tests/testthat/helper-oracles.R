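# Shared fixtures and independent oracles used across the suite.

# The published 18-cell CAM condition table: per-cell mean lifetime (ns),
# rel_Md, and the printed % O2 in N2 column.
published_condition_table <- function() {
  data.frame(
    regime = rep(c("0", "10", "20"), each = 6),
    time   = rep(rep(c("5", "10", "20"), each = 2), 3),
    loc    = rep(c("in", "out"), 9),
    mean_tau = c(710.8, 733.6, 743.1, 768.4, 774.3, 796.6,
                 626.5, 670.4, 616.6, 683.3, 679.6, 681.1,
                 609.0, 633.3, 624.9, 651.3, 644.6, 648.5),
    rel_md = c(0.029, 0.009, 0.013, 0.024, -0.006, 0.030,
               0.005, -0.013, 0.000, -0.018, -0.001, -0.004,
               0.012, -0.005, 0.008, 0.012, 0.005, -0.011),
    rel_oi = c(NA, 0.032, NA, 0.033, NA, 0.028,
               NA, 0.067, NA, 0.103, NA, 0.002,
               NA, 0.039, NA, 0.041, NA, 0.006),
    percent_o2 = c(10.80, 9.83, 9.44, 8.46, 8.24, 7.44,
                   14.99, 12.67, 15.55, 12.05, 12.23, 12.15,
                   16.00, 14.61, 15.08, 13.64, 13.99, 13.79))
}

# Random symmetric non-negative dissimilarity matrix with zero diagonal
# (not necessarily metric).
random_distance_matrix <- function(n, lo = 0.1, hi = 5) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("L", seq_len(n))
  m
}

# Brute-force Ward agglomerator: at every step the merge cost of each
# cluster pair is recomputed FROM SCRATCH from the original squared
# dissimilarities (Ward variance form via within/between sums), never via
# the Lance-Williams recurrence. Same deterministic tie-break rule.
ward_oracle <- function(m) {
  D2 <- m^2
  n <- nrow(m)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  merged <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    bv <- Inf; bi <- NULL; bk <- c(Inf, Inf)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        na <- length(A); nb <- length(B)
        val <- 2 * na * nb / (na + nb) *
          (sum(D2[A, B, drop = FALSE]) / (na * nb) -
             sum(D2[A, A, drop = FALSE]) / 2 / na^2 -
             sum(D2[B, B, drop = FALSE]) / 2 / nb^2)
        key <- sort(c(min(A), min(B)))
        if (val < bv - 1e-15 * (1 + abs(bv)) ||
            (abs(val - bv) <= 1e-15 * (1 + abs(bv)) &&
             (key[1] < bk[1] || (key[1] == bk[1] && key[2] < bk[2])))) {
          bv <- val; bi <- c(i, j); bk <- key
        }
      }
    }
    heights[step] <- sqrt(max(bv, 0))
    merged[[step]] <- list(a = clusters[[bi[1]]], b = clusters[[bi[2]]])
    clusters[[bi[1]]] <- sort(c(clusters[[bi[1]]], clusters[[bi[2]]]))
    clusters[[bi[2]]] <- NULL
  }
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    coph[merged[[step]]$a, merged[[step]]$b] <- heights[step]
    coph[merged[[step]]$b, merged[[step]]$a] <- heights[step]
  }
  list(heights = heights, cophenetic = coph)
}

# Ultrametric check: for every leaf triple the two largest pairwise
# cophenetic distances are equal.
is_ultrametric <- function(cm, tol = 1e-9) {
  n <- nrow(cm)
  if (n < 3) return(TRUE)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 1, n - 1)) {
      for (k in seq(j + 1, n)) {
        s <- sort(c(cm[i, j], cm[i, k], cm[j, k]), decreasing = TRUE)
        if (s[1] - s[2] > tol * (1 + s[1])) return(FALSE)
      }
    }
  }
  TRUE
}

# Amplitude giving an expected total of `total` counts for a
# mono-exponential trace sampled like simulate_decay().
amplitude_for_total <- function(total, tau, n_bins = 256, t_max = 5 * tau) {
  edges <- seq(0, t_max, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  total / sum(exp(-centers / tau))
}
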