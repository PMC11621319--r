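# Kuhn-Munkres (Hungarian) solver for the rectangular minimum-cost
# assignment problem, implemented with row potentials and shortest
# augmenting paths (O(n^2 m)). Rows must not outnumber columns; every row
# is assigned to a distinct column. Ties are resolved by column scan order,
# so the result is deterministic for a given cost matrix.

solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n > m) stop("assignment needs nrow(cost) <= ncol(cost)", call. = FALSE)
  if (any(!is.finite(cost))) {
    stop("assignment cost matrix must be finite", call. = FALSE)
  }
  # index j+1 holds column j; index 1 is the virtual column 0
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- cols[!used[cols + 1L]]
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free + 1L])]
      delta <- minv[j1 + 1L]
      iu <- used[seq_len(m + 1)]
      u[p[which(iu)] + 1L] <- u[p[which(iu)] + 1L] + delta
      v[which(iu)] <- v[which(iu)] - delta
      minv[!iu] <- minv[!iu] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}
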