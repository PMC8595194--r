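# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately share no code with the package implementations.

# exhaustive Kapur maximum-entropy search over all split points
oracleMaxEntropy <- function(h) {
  p <- h$counts / sum(h$counts)
  best <- -Inf
  bt <- NA_integer_
  for (t in seq_len(length(p) - 1L)) {
    P0 <- sum(p[1:t])
    if (P0 <= 0 || P0 >= 1) next
    p0 <- p[1:t] / P0
    p1 <- p[(t + 1L):length(p)] / (1 - P0)
    H <- -sum(p0[p0 > 0] * log(p0[p0 > 0])) -
      sum(p1[p1 > 0] * log(p1[p1 > 0]))
    if (H > best) {
      best <- H
      bt <- t
    }
  }
  h$mids[bt]
}

# exhaustive Huang minimum-fuzziness search
oracleHuang <- function(h) {
  g <- h$mids
  w <- h$counts
  n <- length(g)
  C <- g[n] - g[1]
  S <- function(mu) ifelse(mu > 0 & mu < 1,
                           -mu * log(mu) - (1 - mu) * log(1 - mu), 0)
  best <- Inf
  bt <- NA_integer_
  for (t in seq_len(n - 1L)) {
    P0 <- sum(w[1:t])
    P1 <- sum(w[(t + 1L):n])
    if (P0 == 0 || P1 == 0) next
    m0 <- sum(w[1:t] * g[1:t]) / P0
    m1 <- sum(w[(t + 1L):n] * g[(t + 1L):n]) / P1
    mu <- c(1 / (1 + abs(g[1:t] - m0) / C),
            1 / (1 + abs(g[(t + 1L):n] - m1) / C))
    E <- sum(w * S(mu))
    if (E < best) {
      best <- E
      bt <- t
    }
  }
  g[bt]
}

# random 8-bit histogram with at least two occupied levels
randomHistogram <- function() {
  k <- sample(2:40, 1)
  levels <- sort(sample(0:255, k))
  counts <- integer(256)
  counts[levels + 1L] <- sample(1:500, k, replace = TRUE)
  list(mids = 0:255, counts = counts)
}

# brute-force DBSCAN oracle: connected components of the radius graph
# restricted to core points, plus border points attached to the first core
# neighbor in id order
oracleDbscan <- function(xyz, ids, eps, minCount) {
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  adj <- D < eps
  diag(adj) <- FALSE
  core <- rowSums(adj) >= (minCount - 1L)
  lab <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i]) next
    cur <- cur + 1L
    members <- i
    repeat {
      grow <- which(core & lab == 0L &
                      apply(adj[, members, drop = FALSE], 1L, any))
      grow <- setdiff(grow, members)
      if (!length(grow)) break
      members <- c(members, grow)
    }
    lab[members] <- cur
  }
  for (i in seq_len(n)) {
    if (core[i] || lab[i]) next
    nb <- which(adj[i, ] & core)
    if (length(nb)) lab[i] <- lab[nb[1L]]
  }
  split(ids[lab > 0L], lab[lab > 0L])
}

# canonical cluster representation for comparing clusterings
clusterSets <- function(memberLists) {
  s <- lapply(memberLists, function(m) as.integer(sort(m)))
  unname(s[order(vapply(s, function(m) m[1L], integer(1)))])
}

# two-sided exact Mann-Whitney p by full enumeration of group labelings
oracleMWUExact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  uStat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  uObs <- uStat(a, b)
  us <- apply(idx, 2L, function(ii) uStat(pooled[ii], pooled[-ii]))
  pl <- mean(us <= uObs)
  pg <- mean(us >= uObs)
  min(1, 2 * min(pl, pg))
}
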