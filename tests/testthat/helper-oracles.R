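# Independent brute-force oracles for the graph measures, kept free of the
# package's own code paths: shortest paths by exhaustive Floyd-Warshall
# relaxation, triangles by triple loops, betweenness by explicit
# shortest-path enumeration. Only suitable for small graphs.

bfDistances <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  D <- L
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bfGlobalEff <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- bfDistances(W)
  iv <- 1 / D
  diag(iv) <- 0
  iv[!is.finite(iv)] <- 0
  sum(iv) / (n * (n - 1))
}

bfLocalEff <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- bfGlobalEff(W[nb, nb, drop = FALSE])
  }
  mean(vals)
}

bfCharPath <- function(W) {
  D <- bfDistances(W)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off))) Inf else mean(off)
}

bfClustTrans <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(c(clustering = 0, transitivity = 0))
  Wh <- W / mx
  tri <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i != j && j != k && i != k && W[i, j] > 0 && W[j, k] > 0 &&
            W[i, k] > 0) {
          tri[i] <- tri[i] + (Wh[i, j] * Wh[j, k] * Wh[i, k])^(1 / 3)
        }
      }
    }
  }
  deg <- rowSums(W > 0)
  denom <- deg * (deg - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  c(clustering = mean(ci),
    transitivity = if (sum(denom) > 0) sum(tri) / sum(denom) else 0)
}

# All shortest paths between s and t via the shortest-path DAG; returns
# list(count, interior visit counts per node).
bfPathEnum <- function(W, D, s, t) {
  L <- ifelse(W > 0, 1 / W, Inf)
  visits <- numeric(nrow(W))
  count <- 0
  recur <- function(v, interior) {
    if (v == t) {
      count <<- count + 1
      for (u in interior) visits[u] <<- visits[u] + 1
      return(invisible())
    }
    for (u in which(W[v, ] > 0)) {
      if (abs(L[v, u] + D[u, t] - D[v, t]) < 1e-9) {
        recur(u, if (u == t) interior else c(interior, u))
      }
    }
  }
  recur(s, integer(0))
  list(count = count, visits = visits)
}

bfBetweenness <- function(W) {
  n <- nrow(W)
  D <- bfDistances(W)
  bt <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      pe <- bfPathEnum(W, D, s, t)
      if (pe$count > 0) bt <- bt + pe$visits / pe$count
    }
  }
  bt
}

bfRichClub <- function(A) {
  k <- rowSums(A > 0)
  phis <- numeric(0)
  for (lev in seq_len(max(1, max(k) - 1))) {
    nodes <- which(k > lev)
    N <- length(nodes)
    if (N < 2) next
    phis <- c(phis, sum(A[nodes, nodes] > 0) / (N * (N - 1)))
  }
  if (length(phis) == 0) NA_real_ else mean(phis)
}

# Newman modularity of a given membership vector.
modularityOf <- function(W, membership) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(W[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

# Two-community split by the sign of the leading eigenvector of the
# modularity matrix.
spectralSplitQ <- function(W) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  B <- W - outer(k, k) / m2
  v <- eigen(B, symmetric = TRUE)$vectors[, 1]
  modularityOf(W, as.integer(v >= 0))
}

# Random symmetric test graph.
randomGraph <- function(n, p = 0.35, weighted = FALSE, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  if (weighted) A[upper.tri(A)] <- A[upper.tri(A)] * runif(n * (n - 1) / 2,
                                                           0.2, 1.5)
  A + t(A)
}

# Small named graphs used across tests.
completeGraph <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}

pathGraph3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  A
}

starGraph <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, 2:(leaves + 1)] <- A[2:(leaves + 1), 1] <- 1
  A
}
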