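# Independent oracles used to validate the implementation. Each one computes
# the target quantity by a different route than the package code.

# Discrete Frechet distance by explicit enumeration of all order-preserving
# couplings: walk every monotone lattice path from (1,1) to (n,m), track the
# maximal pointwise distance along each, and take the minimum over paths.
frechet_coupling_oracle <- function(p, q) {
  n <- nrow(p)
  m <- nrow(q)
  dd <- function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))
  best <- Inf
  walk <- function(i, j, cur) {
    cur <- max(cur, dd(i, j))
    if (cur >= best) return()  # cannot improve
    if (i == n && j == m) {
      best <<- cur
      return()
    }
    if (i < n) walk(i + 1, j, cur)
    if (i < n && j < m) walk(i + 1, j + 1, cur)
    if (j < m) walk(i, j + 1, cur)
  }
  walk(1L, 1L, 0)
  best
}

# Minimum-total-cost injective assignment by exhaustive enumeration over all
# admissible option combinations (0 = unassigned, priced at the threshold).
assignment_enumeration_oracle <- function(D, threshold) {
  n <- nrow(D)
  opts <- lapply(seq_len(n), function(i) c(0L, which(D[i, ] < threshold)))
  combos <- do.call(expand.grid, opts)
  best_cost <- Inf
  for (r in seq_len(nrow(combos))) {
    a <- as.integer(combos[r, ])
    nz <- a[a > 0L]
    if (anyDuplicated(nz)) next
    cost <- sum(vapply(seq_len(n), function(i) {
      if (a[i] == 0L) threshold else D[i, a[i]]
    }, numeric(1)))
    if (cost < best_cost) best_cost <- cost
  }
  best_cost
}

# Element-wise detection classification: label every relevant ID one at a
# time instead of using set algebra.
detection_elementwise_oracle <- function(ams, detected, registry) {
  tp <- fn <- fp <- 0L
  for (cow in ams) {
    if (cow %in% detected) tp <- tp + 1L else fn <- fn + 1L
  }
  for (id in detected) {
    if (!(id %in% registry)) fp <- fp + 1L
  }
  list(tp_d = tp, fn_d = fn, fp_d = fp)
}

random_trajectory <- function(len, scale = 10) {
  matrix(stats::runif(2 * len, 0, scale), ncol = 2)
}
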