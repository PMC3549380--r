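#' Node strength
#'
#' Weighted generalization of degree: the sum of the absolute weighted-
#' adjacency entries at each node. Covalent links carry weight zero and so
#' contribute nothing.
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @return numeric vector of per-node strengths.
#' @export
nodeStrength <- function(network) {
  rowSums(abs(weightedAdjacency(network)))
}

#' Node degree
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @return integer vector of per-node degrees (covalent links included).
#' @export
nodeDegree <- function(network) {
  as.integer(rowSums(adjacency(network)))
}

#' Weighted clustering coefficient
#'
#' For each node i with degree K_i >= 2 and strength S_i > 0,
#' C_i = (1 / (S_i (K_i - 1))) * sum over ordered neighbour pairs (j, h)
#' with a_ij = a_ih = a_jh = 1 of (|w_ij| + |w_ih|)/2. Nodes with fewer than
#' two links, or with zero strength (all links covalent), get C_i = 0.
#' Covalent links count in the adjacency triangle test but contribute zero
#' weight to the numerator, mirroring their zero contribution to strength.
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @return numeric vector of per-node clustering coefficients in [0, 1].
#' @export
weightedClustering <- function(network) {
  a <- adjacency(network)
  wAbs <- abs(weightedAdjacency(network))
  k <- rowSums(a)
  s <- rowSums(wAbs)
  # sum_{j,h} a_ij a_ih a_jh (|w_ij|+|w_ih|)/2  ==  sum_j |w_ij| (A^2)_ij
  num <- rowSums(wAbs * (a %*% a))
  cc <- ifelse(k >= 2 & s > 0, num / (s * (k - 1)), 0)
  pmin(pmax(cc, 0), 1)
}

# igraph view of a distance matrix (finite off-diagonal entries as edges).
.dmGraph <- function(dm) {
  d <- as.matrix(dm)
  if (any(d[is.finite(d)] < 0))
    stop("negative edge distances; distance clamp contract violated")
  idx <- which(is.finite(d) & upper.tri(d), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(d), directed = FALSE)
  if (nrow(idx))
    g <- igraph::add_edges(g, t(idx), weight = d[idx])
  g
}

#' All-pairs shortest-path distances
#'
#' Dijkstra over the finite link distances; unreachable pairs are Inf.
#'
#' @param dm a [DistanceMatrix-class] object.
#' @return symmetric numeric matrix of graph distances.
#' @export
shortestPathLengths <- function(dm) {
  g <- .dmGraph(dm)
  sp <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(sp) <- NULL
  sp
}

#' Average shortest path length
#'
#' Mean shortest-path distance over all unordered node pairs with a finite
#' distance, together with the fraction of pairs that are connected.
#'
#' @param dm a [DistanceMatrix-class] object (or a precomputed shortest-path
#'   matrix).
#' @return list with `L` (the mean) and `connectedFraction`.
#' @export
averagePathLength <- function(dm) {
  sp <- if (is.matrix(dm)) dm else shortestPathLengths(dm)
  if (nrow(sp) < 2) stop("need at least two nodes")
  v <- sp[upper.tri(sp)]
  fin <- is.finite(v)
  if (!any(fin)) stop("no connected node pair; L is undefined")
  list(L = mean(v[fin]), connectedFraction = mean(fin))
}

#' Betweenness centrality
#'
#' For each node u, the sum over unordered pairs {i, j} (with u not an
#' endpoint) of the fraction of shortest i-j paths that pass through u. All
#' shortest paths are counted; two path lengths are considered tied when
#' they agree to a relative tolerance (default 1e-9), which keeps the count
#' robust to floating-point noise in the link distances.
#'
#' @param dm a [DistanceMatrix-class] object.
#' @param tol relative tolerance for path-length ties.
#' @return numeric vector of per-node betweenness values.
#' @export
betweennessCentrality <- function(dm, tol = 1e-9) {
  d <- as.matrix(dm)
  if (any(d[is.finite(d)] < 0))
    stop("negative edge distances; distance clamp contract violated")
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) {
    j <- which(is.finite(d[i, ]) & seq_len(n) != i)
    list(j = j, w = d[i, j])
  })
  B <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    done <- logical(n)
    preds <- vector("list", n)
    visitOrder <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      visitOrder <- c(visitOrder, u)
      js <- nbr[[u]]$j; ws <- nbr[[u]]$w
      for (k in seq_along(js)) {
        v <- js[k]
        if (done[v]) next
        alt <- dist[u] + ws[k]
        eps <- tol * max(1, abs(alt))
        if (alt < dist[v] - eps) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= eps) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(visitOrder)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) B[w] <- B[w] + delta[w]
    }
  }
  B / 2  # each unordered pair is visited from both endpoints
}

#' Betweenness Z-scores
#'
#' Standardizes betweenness across all residues of one protein:
#' Z_u = (B_u - mean(B)) / sd(B). The population standard deviation
#' (divide by N) is the default; when the spread is zero every Z is 0 and a
#' warning is raised.
#'
#' @param b numeric vector of betweenness values.
#' @param sdType `"population"` (default) or `"sample"`.
#' @return numeric vector of Z-scores.
#' @export
betweennessZScore <- function(b, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (length(b) < 2) stop("need at least two nodes")
  m <- mean(b)
  s <- sd(b)
  if (sdType == "population") s <- s * sqrt((length(b) - 1) / length(b))
  if (!is.finite(s) || s == 0) {
    warning("betweenness spread is zero; all Z-scores set to 0")
    return(rep(0, length(b)))
  }
  (b - m) / s
}

#' Small-world summary
#'
#' Network-level summary against the size-matched random-graph baselines:
#' the mean degree <K>, the mean weighted clustering C and the average
#' shortest path length L, alongside the random expectations C_r = <K>/N and
#' L_r = ln N / ln <K>, and the ratios C/C_r and L/L_r. A small-world
#' network shows C/C_r >> 1 with L/L_r of order one; the ratios are the
#' deliverable, no pass/fail threshold is applied. Betweenness statistics
#' are included on request (they dominate the cost on large networks).
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @param dm a [DistanceMatrix-class] for the same network (definition 1 by
#'   convention).
#' @param includeBetweenness also compute mean betweenness and its
#'   (population) standard deviation.
#' @return named list: N, meanDegree, meanClustering, L, connectedFraction,
#'   randomClustering, randomPath, clusteringRatio, pathRatio, and
#'   optionally meanBetweenness, betweennessSD.
#' @export
smallWorldSummary <- function(network, dm, includeBetweenness = FALSE) {
  n <- nNodes(network)
  k <- mean(rowSums(adjacency(network)))
  cc <- mean(weightedClustering(network))
  apl <- averagePathLength(dm)
  cr <- k / n
  lr <- if (k > 1) log(n) / log(k) else NA_real_
  out <- list(N = n, meanDegree = k, meanClustering = cc, L = apl$L,
              connectedFraction = apl$connectedFraction,
              randomClustering = cr, randomPath = lr,
              clusteringRatio = cc / cr,
              pathRatio = if (is.na(lr)) NA_real_ else apl$L / lr)
  if (includeBetweenness) {
    b <- betweennessCentrality(dm)
    out$meanBetweenness <- mean(b)
    out$betweennessSD <- sd(b) * sqrt((n - 1) / n)
  }
  out
}

#' Per-node metrics table
#'
#' Degree, strength, weighted clustering, betweenness and betweenness
#' Z-score for every residue node.
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @param dm a [DistanceMatrix-class] for the same network.
#' @param sdType Z-score convention, see [betweennessZScore()].
#' @return data.frame with one row per node: chain, resnum, type, K, S, C,
#'   B, Z.
#' @export
nodeMetrics <- function(network, dm, sdType = "population") {
  nd <- nodes(network)
  b <- betweennessCentrality(dm)
  data.frame(chain = nd$chain, resnum = nd$pdbResnum, type = nd$resType,
             K = nodeDegree(network), S = nodeStrength(network),
             C = weightedClustering(network), B = b,
             Z = betweennessZScore(b, sdType = sdType),
             stringsAsFactors = FALSE)
}
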