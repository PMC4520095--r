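## Linear assignment (Hungarian algorithm, O(n^3) with potentials).
## Needed to match cluster labels across partitions; kept internal and
## verified against brute-force permutation enumeration in the tests.

.hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n != m) stop("assignment cost matrix must be square")
  V <- m + 1L                       # virtual column
  u <- numeric(n); v <- numeric(V)
  p <- integer(V)                   # p[j]: row matched to column j
  way <- integer(m)
  for (i in seq_len(n)) {
    p[V] <- i; j0 <- V
    minv <- rep(Inf, m); used <- rep(FALSE, V)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(V)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

## permutation sigma (input label -> consensus label) maximizing
## sum_l C[l, sigma(l)]
.best_label_match <- function(C) .hungarian(max(C) - C)
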