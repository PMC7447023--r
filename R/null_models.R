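#' Sample random haplotype strings with observed column compositions
#'
#' Generates the same number of equal-length strings as the input, drawing
#' each column independently from that column's empirical character
#' distribution. This randomization preserves per-position allele
#' compositions while destroying between-position associations, which is the
#' appropriate null for genotype-network topology.
#'
#' @param strings character vector of aligned haplotype strings (the
#'   uncollapsed per-accession strings).
#' @param seed integer seed.
#' @return character vector of random strings, same length and string width.
#' @export
sample_random_panel <- function(strings, seed = 1L) {
  if (length(strings) == 0L) stop("no strings to randomize")
  set.seed(derive_seed(seed, 0L))
  m <- do.call(rbind, strsplit(strings, ""))
  rand <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    chars <- names(tab)
    if (length(chars) == 1L) rep(chars, nrow(m))
    else sample(chars, nrow(m), replace = TRUE, prob = as.numeric(tab))
  }, character(nrow(m)))
  if (nrow(m) == 1L) rand <- matrix(rand, nrow = 1L)
  apply(rand, 1L, paste0, collapse = "")
}

#' Null distribution of genotype-network statistics
#'
#' Repeatedly randomizes the aligned haplotype strings by column composition
#' (see [sample_random_panel()]), builds a genotype network from each
#' replicate with the same machinery used for observed data, and records four
#' summary statistics per replicate: the number of unique genotypes, the
#' number of squares, the size of the largest component with at least two
#' vertices, and the maximum normalized vertex betweenness.
#'
#' @param strings aligned haplotype strings (uncollapsed, per accession).
#' @param n_reps number of replicates (default 10000, the reference
#'   randomization depth).
#' @param seed integer seed; replicate r uses stream `seed + r`.
#' @return object of class `null_distribution`: data frame `stats` with
#'   columns `n_unique_genotypes`, `n_squares`, `largest_component`,
#'   `max_betweenness`, plus `n_reps`, `seed`, and `observed` (the same four
#'   statistics computed on the input strings by the same code path).
#' @export
null_distribution <- function(strings, n_reps = 10000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  observed <- network_stats_from_strings(strings)
  rows <- matrix(NA_real_, n_reps, 4L)
  for (r in seq_len(n_reps)) {
    rand <- sample_random_panel(strings, seed = derive_seed(seed, r))
    rows[r, ] <- unlist(network_stats_from_strings(rand))
  }
  stats <- as.data.frame(rows)
  names(stats) <- c("n_unique_genotypes", "n_squares", "largest_component",
                    "max_betweenness")
  structure(list(stats = stats, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), observed = observed),
            class = "null_distribution")
}

#' Empirical quantile and two-sided P of an observed statistic
#'
#' Rank-based with an add-one pseudo-count, so that an observation beyond
#' every replicate gets P = 1/(n_reps + 1) rather than zero:
#' upper-tail P = (1 + #\{null >= obs\}) / (n_reps + 1), lower tail
#' analogous, two-sided P = min(1, 2 * min(tails)).
#'
#' @param observed numeric statistic.
#' @param null a [null_distribution()] object or numeric vector of null
#'   replicates.
#' @param statistic column name when `null` is a `null_distribution`.
#' @return list: `quantile` (fraction of null strictly below observed),
#'   `p_upper`, `p_lower`, `p_two_sided`, `n_reps`.
#' @export
empirical_quantile <- function(observed, null, statistic = "n_squares") {
  vals <- if (inherits(null, "null_distribution")) null$stats[[statistic]]
          else as.numeric(null)
  if (length(vals) == 0L) stop("empty null distribution")
  n <- length(vals)
  p_up <- (1 + sum(vals >= observed)) / (n + 1)
  p_lo <- (1 + sum(vals <= observed)) / (n + 1)
  list(quantile = mean(vals < observed),
       p_upper = p_up, p_lower = p_lo,
       p_two_sided = min(1, 2 * min(p_up, p_lo)),
       n_reps = n)
}

# internal: the four null-model statistics from raw aligned strings,
# computed through the same collapse/build/count code as observed networks
network_stats_from_strings <- function(strings) {
  names(strings) <- sprintf("s%06d", seq_along(strings))
  phen <- stats::setNames(rep(0, length(strings)), names(strings))
  verts <- collapse_haplotypes(strings, phen)
  net <- build_network(verts)
  n_sq <- count_squares(net)$total
  btw <- if (igraph::vcount(net$graph) > 0L) vertex_betweenness(net) else numeric(0)
  list(n_unique_genotypes = nrow(net$vertices),
       n_squares = n_sq,
       largest_component = net$largest_component,
       max_betweenness = if (length(btw)) max(btw) else 0)
}
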