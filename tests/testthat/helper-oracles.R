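# Independent brute-force reference implementations. These follow the metric
# definitions literally (explicit loops, exhaustive path enumeration) and
# share no code with the package's implementations.

oracleStrength <- function(net) {
  aw <- weightedAdjacency(net)
  n <- nrow(aw)
  out <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i] <- out[i] + abs(aw[i, j])
  out
}

oracleClustering <- function(net) {
  a <- adjacency(net)
  aw <- weightedAdjacency(net)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    s <- sum(abs(aw[i, ]))
    if (k < 2 || s == 0) next
    num <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == h) next
      num <- num + a[i, j] * a[i, h] * a[j, h] *
        (abs(aw[i, j]) + abs(aw[i, h])) / 2
    }
    out[i] <- num / (s * (k - 1))
  }
  out
}

oracleRg <- function(pts, w = rep(1, nrow(pts))) {
  ctr <- c(sum(pts[, 1] * w), sum(pts[, 2] * w), sum(pts[, 3] * w)) / sum(w)
  acc <- 0
  for (i in seq_len(nrow(pts)))
    acc <- acc + w[i] * sum((pts[i, ] - ctr)^2)
  sqrt(acc / sum(w))
}

# Every simple path between i and j over the finite entries of d.
allSimplePaths <- function(d, i, j) {
  n <- nrow(d)
  paths <- list()
  rec <- function(path, len) {
    u <- path[length(path)]
    if (u == j) {
      paths[[length(paths) + 1]] <<- list(path = path, len = len)
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (v %in% path || !is.finite(d[u, v]) || v == u) next
      rec(c(path, v), len + d[u, v])
    }
  }
  rec(i, 0)
  paths
}

# Exhaustive shortest-path matrix and betweenness (unordered pairs,
# endpoints excluded, all tied shortest paths counted fractionally).
oraclePathInfo <- function(dm, tol = 1e-9) {
  d <- as.matrix(dm)
  n <- nrow(d)
  sp <- matrix(Inf, n, n)
  diag(sp) <- 0
  B <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- allSimplePaths(d, i, j)
    if (!length(ps)) next
    lens <- vapply(ps, function(p) p$len, 0)
    m <- min(lens)
    sp[i, j] <- sp[j, i] <- m
    short <- ps[abs(lens - m) <= tol * pmax(1, abs(m))]
    for (u in seq_len(n)) {
      if (u == i || u == j) next
      thr <- sum(vapply(short, function(p) u %in% p$path, logical(1)))
      B[u] <- B[u] + thr / length(short)
    }
  }
  list(sp = sp, betweenness = B)
}

oracleContactCounts <- function(structure, cutoff) {
  at <- atoms(structure)
  lg <- ligands(structure)
  nd <- nodes(structure)
  counts <- integer(nrow(nd))
  for (r in seq_len(nrow(nd))) {
    ra <- at[at$chain == nd$chain[r] &
               paste0(at$resno, at$insert) == nd$pdbResnum[r], , drop = FALSE]
    for (ai in seq_len(nrow(ra))) for (li in seq_len(nrow(lg))) {
      dd <- sqrt((ra$x[ai] - lg$x[li])^2 + (ra$y[ai] - lg$y[li])^2 +
                   (ra$z[ai] - lg$z[li])^2)
      if (dd < cutoff) counts[r] <- counts[r] + 1L
    }
  }
  counts
}
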