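# Shared fixtures and independent brute-force oracles.

# build an undirected igraph from a 2-column edge matrix of bin starts
graph_from_pairs <- function(pairs, resolution = 1e4, chrom = "chrT") {
  sig <- data.frame(chrom = chrom, start1 = pairs[, 1L], start2 = pairs[, 2L],
                    count = 1L, probability = 0.99)
  build_network(sig, chrom = chrom, resolution = resolution)
}

# a clique on the given bin starts, as an edge matrix
clique_pairs <- function(starts) {
  t(utils::combn(starts, 2L))
}

# brute-force global transitivity: enumerate all vertex triples
brute_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  triplets <- 0
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    triplets <- triplets + k * (k - 1) / 2
    if (k >= 2) {
      cmb <- utils::combn(nb, 2L)
      triangles <- triangles + sum(adj[cbind(cmb[1L, ], cmb[2L, ])] > 0)
    }
  }
  # each triangle counted once per corner vertex = 3 times
  if (triplets == 0) 0 else triangles / triplets
}

# principal eigenvector of a symmetric adjacency matrix, max-normalized
brute_eigencentrality <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

# exhaustive double-loop window means over a dense symmetric matrix
brute_window_means <- function(records, sig, resolution, n_bins,
                               padding = 5L) {
  M <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(records))) {
    i <- records$start1[r] / resolution + 1
    j <- records$start2[r] / resolution + 1
    M[i, j] <- records$count[r]
    M[j, i] <- records$count[r]
  }
  vapply(seq_len(nrow(sig)), function(t) {
    i <- sig$start1[t] / resolution + 1
    j <- sig$start2[t] / resolution + 1
    s <- 0
    npx <- 0
    for (a in (i - padding):(i + padding)) {
      for (b in (j - padding):(j + padding)) {
        if (a >= 1 && a <= n_bins && b >= 1 && b <= n_bins) {
          s <- s + M[a, b]
          npx <- npx + 1
        }
      }
    }
    s / npx
  }, numeric(1))
}

# naive rank-curve slope scan, written independently of elbow_point()
brute_elbow <- function(values) {
  v <- values[order(values)]
  n <- length(v)
  best <- NA
  best_d <- Inf
  for (i in seq_len(n - 1)) {
    x1 <- (i - 1) / (n - 1); x2 <- i / (n - 1)
    y1 <- (v[i] - v[1]) / (v[n] - v[1])
    y2 <- (v[i + 1] - v[1]) / (v[n] - v[1])
    s <- (y2 - y1) / (x2 - x1)
    if (abs(s - 1) <= best_d + 1e-9) {  # ties toward larger rank
      if (abs(s - 1) < best_d) best_d <- abs(s - 1)
      best <- i
    }
  }
  list(index = best, threshold = v[best])
}

# interval-sweep stitching oracle for a single chromosome
brute_stitch <- function(peaks, gap = 12500) {
  p <- peaks[order(peaks$start), ]
  out <- list()
  cur <- p[1L, ]
  cur$n <- 1L
  for (r in seq_len(nrow(p))[-1L]) {
    if (p$start[r] - cur$end <= gap) {
      cur$end <- max(cur$end, p$end[r])
      cur$occupancy <- cur$occupancy + p$occupancy[r]
      cur$n <- cur$n + 1L
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- p[r, ]
      cur$n <- 1L
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

# default synthetic benchmark pipeline settings (see the methods vignette)
bench_pipeline <- function(records, n_bins = 1000L) {
  find_modules(records, resolution = 1e4, include_zeros = TRUE,
               n_bins = n_bins, method = "louvain", seed = 42L)
}

best_jaccard <- function(modules, span_start, span_end) {
  if (nrow(modules) == 0L) return(0)
  max(interval_jaccard(modules$span_start, modules$span_end,
                       span_start, span_end))
}
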