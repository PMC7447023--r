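# Brute-force oracles, deliberately independent of the package's code paths.

# all unordered pairs of strings at Hamming distance 1, by direct comparison
oracle_hamming_edges <- function(strings) {
  n <- length(strings)
  out <- matrix(integer(0), 0L, 2L)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- strsplit(strings[i], "")[[1L]]
      b <- strsplit(strings[j], "")[[1L]]
      if (sum(a != b) == 1L) out <- rbind(out, c(i, j))
    }
  }
  out
}

# number of 4-cycles via the closed-walk (adjacency trace) identity:
# C4 = (tr(A^4) - 2m - 2*sum_i d_i (d_i - 1)) / 8
oracle_square_count <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  if (nrow(A) < 4L) return(0L)
  A2 <- A %*% A
  tr4 <- sum(diag(A2 %*% A2))
  m <- sum(A) / 2
  deg <- rowSums(A)
  as.integer(round((tr4 - 2 * m - 2 * sum(deg * (deg - 1))) / 8))
}

# exhaustive 4-cycle enumeration over vertex quadruples (small graphs only):
# returns a set of canonical keys "a|b|c|d + diagonal pairing"
oracle_square_sets <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  keys <- character(0)
  if (n < 4L) return(keys)
  quads <- utils::combn(n, 4L)
  pairings <- list(c(1L, 2L, 3L, 4L), c(1L, 2L, 4L, 3L), c(1L, 3L, 2L, 4L))
  for (q in seq_len(ncol(quads))) {
    v <- quads[, q]
    for (p in pairings) {
      cyc <- v[p]
      if (A[cyc[1L], cyc[2L]] & A[cyc[2L], cyc[3L]] &
          A[cyc[3L], cyc[4L]] & A[cyc[4L], cyc[1L]]) {
        d1 <- sort(c(cyc[1L], cyc[3L]))
        d2 <- sort(c(cyc[2L], cyc[4L]))
        diag_key <- paste(sort(c(paste(d1, collapse = "-"),
                                 paste(d2, collapse = "-"))), collapse = "|")
        keys <- c(keys, diag_key)
      }
    }
  }
  sort(unique(keys))
}

# all shortest paths between two vertices by depth-limited exhaustive DFS
oracle_shortest_paths <- function(g, from, to) {
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  s <- match(from, nm); t <- match(to, nm)
  dist <- suppressWarnings(igraph::distances(g, v = from, to = to))[1L, 1L]
  if (!is.finite(dist)) return(list())
  paths <- list()
  dfs <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      if (length(path) - 1L == dist) paths[[length(paths) + 1L]] <<- nm[path]
      return(invisible())
    }
    if (length(path) - 1L >= dist) return(invisible())
    for (w in adj[[u]]) if (!w %in% path) dfs(c(path, w))
  }
  dfs(s)
  paths
}

# betweenness by geodesic counting over all pairs (per component, normalized)
oracle_betweenness <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  out <- stats::setNames(numeric(n), nm)
  comp <- igraph::components(g)$membership
  d <- igraph::distances(g)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (comp[s] != comp[t]) next
    paths <- oracle_shortest_paths(g, nm[s], nm[t])
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
    if (length(inner)) {
      tab <- table(inner) / length(paths)
      out[names(tab)] <- out[names(tab)] + as.numeric(tab)
    }
  }
  for (cid in unique(comp)) {
    sel <- comp == cid
    nc <- sum(sel)
    norm <- if (nc > 2L) (nc - 1) * (nc - 2) / 2 else 1
    out[sel] <- out[sel] / norm
  }
  out
}

# betweenness via geodesic-count dynamic programming (independent of DFS
# and of igraph's Brandes implementation); per-component normalization
oracle_betweenness_dp <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- igraph::distances(g)
  # sigma[s, t]: number of geodesics, by increasing distance
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  for (len in seq_len(maxd)) {
    idx <- which(d == len, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 1L]; t <- idx[r, 2L]
      pred <- which(A[, t] == 1 & d[s, ] == len - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  out <- stats::setNames(numeric(n), nm)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        out[v] <- out[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  comp <- igraph::components(g)$membership
  for (cid in unique(comp)) {
    sel <- comp == cid
    nc <- sum(sel)
    norm <- if (nc > 2L) (nc - 1) * (nc - 2) / 2 else 1
    out[sel] <- out[sel] / norm
  }
  out
}

# epistasis classes from the 3^4 coarse sign patterns of the four edge steps:
# a square's class is read off a lookup of the delta-coarsened step signs
oracle_classify <- function(v_ab, v_Ab, v_aB, v_AB, delta) {
  eps <- v_AB + v_ab - v_Ab - v_aB
  if (abs(eps) <= delta) return("none")
  csign <- function(x) if (abs(x) <= delta) 0L else as.integer(sign(x))
  sA <- c(csign(v_Ab - v_ab), csign(v_AB - v_aB))
  sB <- c(csign(v_aB - v_ab), csign(v_AB - v_Ab))
  flips <- function(s) s[1L] * s[2L] == -1L  # opposite, neither indeterminate
  if (flips(sA) && flips(sB)) "reciprocal_sign"
  else if (flips(sA) || flips(sB)) "simple_sign"
  else "magnitude"
}

# O(n^2) concordant/discordant-pair Kendall tau-b
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# ---- shared fixture builders --------------------------------------------

# a network built directly from haplotype strings and per-string phenotypes
net_from_strings <- function(strings, phen = NULL, accession_reps = 1L) {
  if (is.null(phen)) phen <- seq_along(strings)
  acc_strings <- rep(strings, each = accession_reps)
  acc_phen <- rep(phen, each = accession_reps)
  names(acc_strings) <- sprintf("a%03d", seq_along(acc_strings))
  names(acc_phen) <- names(acc_strings)
  verts <- collapse_haplotypes(acc_strings, acc_phen)
  build_network(verts, accession_haplotypes = acc_strings)
}

# random aligned biallelic string set for oracle sweeps
random_strings <- function(seed, n = NULL, len = NULL) {
  set.seed(seed)
  if (is.null(len)) len <- sample(3:6, 1L)
  if (is.null(n)) n <- sample(8:40, 1L)
  maf <- stats::runif(len, 0.2, 0.5)
  m <- vapply(seq_len(len), function(j) {
    sample(c("A", "T"), n, replace = TRUE, prob = c(1 - maf[j], maf[j]))
  }, character(n))
  unique(apply(matrix(m, n, len), 1L, paste0, collapse = ""))
}
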