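## Independent brute-force oracles. These re-derive expected values from
## first principles and must stay independent of the package code paths they
## check.

# Global alignment identity: Needleman-Wunsch maximizing score (match +1,
# mismatch -1, gap -1), tracking the maximum number of matches among
# co-optimal alignments; identity = matches / shorter length.
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  S <- matrix(-Inf, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)
  S[1, ] <- -(0:m)
  S[, 1] <- -(0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- A[i] == B[j]
      cand_s <- c(S[i, j] + if (hit) 1 else -1, S[i, j + 1] - 1, S[i + 1, j] - 1)
      cand_m <- c(M[i, j] + as.integer(hit), M[i, j + 1], M[i + 1, j])
      best <- max(cand_s)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cand_m[cand_s == best])
    }
  }
  M[n + 1, m + 1] / min(n, m)
}

# Exhaustive Ward.D2 agglomeration via the Lance-Williams update on the
# initial Euclidean distances; first-index tie-break. Returns the sequence of
# merge heights and the partition (list of member sets) after each merge.
ward_oracle <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  sizes <- rep(1, nrow(d))
  active <- seq_len(nrow(d))
  heights <- numeric(0)
  partitions <- list()
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]
        j <- active[jj]
        if (d[i, j] < best[1] - 1e-12) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]
    j <- best[3]
    heights <- c(heights, best[1])
    ni <- sizes[i]
    nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dnew <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                      nk * d[i, j]^2) / (ni + nj + nk))
      d[i, k] <- d[k, i] <- dnew
    }
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    partitions[[length(partitions) + 1]] <-
      lapply(active, function(k) clusters[[k]])
  }
  list(heights = heights, partitions = partitions)
}

# Partition of an hclust object after `step` merges (via cutree).
hclust_partition_at <- function(hc, step) {
  n <- length(hc$order)
  unname(split(seq_len(n), stats::cutree(hc, k = n - step)))
}

# Canonical form of a partition (sorted list of sorted member vectors) for
# order-independent comparison.
canon_partition <- function(p) {
  key <- vapply(p, function(v) paste(sort(v), collapse = ","), character(1))
  sort(key)
}

# Literal sequential PERMANOVA from the Gower-centered matrix with explicit
# projection matrices (normal-equations form, not QR).
permanova_oracle <- function(dm, meta, factors) {
  n <- nrow(dm)
  one <- matrix(1, n, n) / n
  G <- (diag(n) - one) %*% (-0.5 * dm^2) %*% (diag(n) - one)
  ss_total <- sum(diag(G))
  hat_of <- function(form) {
    X <- stats::model.matrix(form, data = meta)
    X %*% solve(crossprod(X)) %*% t(X)
  }
  forms <- vector("list", length(factors) + 1)
  forms[[1]] <- ~1
  for (j in seq_along(factors)) {
    forms[[j + 1]] <- stats::as.formula(
      paste("~", paste(factors[seq_len(j)], collapse = " + "))
    )
  }
  trs <- vapply(forms, function(f) sum(hat_of(f) * G), numeric(1))
  ranks <- vapply(forms, function(f) qr(stats::model.matrix(f, data = meta))$rank,
                  numeric(1))
  ss <- diff(trs)
  df <- diff(ranks)
  ss_res <- ss_total - trs[length(trs)]
  df_res <- n - ranks[length(ranks)]
  list(
    ss = ss, df = df, ss_res = ss_res, df_res = df_res, ss_total = ss_total,
    r2 = ss / ss_total,
    f = (ss / df) / (ss_res / df_res)
  )
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[i] <- min(sorted[i:m] * m / (i:m)) |> min(1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}
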