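#' Normalized vertex betweenness, per component
#'
#' Betweenness of a vertex is the fraction of shortest paths between all
#' other vertex pairs that pass through it (endpoints excluded). Because all
#' path statistics here are intra-component, betweenness is computed and
#' normalized within each connected component: raw betweenness divided by
#' `(n-1)(n-2)/2` for a component of `n` vertices (0 for components of size
#' at most 2).
#'
#' @param network a [build_network()] result or igraph.
#' @return named numeric vector over analysis vertices.
#' @export
vertex_betweenness <- function(network) {
  g <- as_igraph(network)
  out <- numeric(igraph::vcount(g))
  names(out) <- igraph::V(g)$name
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    sub <- igraph::induced_subgraph(g, idx)
    n <- igraph::vcount(sub)
    b <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
    out[igraph::V(sub)$name] <- b / norm
  }
  out
}

#' Detect modules in the largest component
#'
#' Greedy modularity maximization (multilevel/Louvain, resolution 1) on the
#' largest connected component, deterministic given `seed`. A partition whose
#' modularity does not exceed zero is flagged as showing no module
#' structure.
#'
#' @param network a [build_network()] result or igraph.
#' @param seed integer seed for the (stochastic) community search.
#' @return object of class `module_partition`: `membership` (named),
#'   `modularity`, `n_modules`, `has_structure`, `phenotypes` (per-module
#'   list of vertex mean phenotypes, when available).
#' @export
detect_modules <- function(network, seed = 1L) {
  g <- as_igraph(network)
  comp <- igraph::components(g)
  if (comp$no == 0L || max(comp$csize) < 2L) stop("need a component with >= 2 vertices")
  sub <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  set.seed(derive_seed(seed, 0L))
  cl <- igraph::cluster_louvain(sub, resolution = 1)
  membership <- igraph::membership(cl)
  names(membership) <- igraph::V(sub)$name
  mod <- igraph::modularity(cl)
  phen <- igraph::V(sub)$mean_phenotype
  phen_by_module <- NULL
  if (!is.null(phen)) {
    phen_by_module <- split(stats::setNames(phen, igraph::V(sub)$name),
                            as.integer(membership))
  }
  structure(
    list(membership = as.integer(membership) |> stats::setNames(names(membership)),
         modularity = mod,
         n_modules = length(unique(membership)),
         has_structure = mod > 0 && length(unique(membership)) > 1L,
         phenotypes = phen_by_module),
    class = "module_partition"
  )
}

#' Compare phenotypes between the two largest modules
#'
#' Two-sided Wilcoxon rank-sum test on the vertex mean phenotypes of the two
#' largest modules. The exact distribution is used for group sizes up to 10
#' without ties; otherwise the normal approximation with continuity
#' correction.
#'
#' @param partition a [detect_modules()] result with phenotypes.
#' @return list: `p_value`, `statistic`, `modules` (the two module ids
#'   compared), `n` (their sizes); or status `"skipped"` when fewer than two
#'   modules exist.
#' @export
module_phenotype_test <- function(partition) {
  stopifnot(inherits(partition, "module_partition"))
  if (is.null(partition$phenotypes) || length(partition$phenotypes) < 2L) {
    return(list(status = "skipped", p_value = NA_real_))
  }
  sizes <- lengths(partition$phenotypes)
  top2 <- names(sort(sizes, decreasing = TRUE))[1:2]
  x <- partition$phenotypes[[top2[1L]]]
  y <- partition$phenotypes[[top2[2L]]]
  use_exact <- max(length(x), length(y)) <= 10L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(status = "ok", p_value = wt$p.value, statistic = unname(wt$statistic),
       modules = top2, n = c(length(x), length(y)))
}

#' Internal-node count between two tree tips
#'
#' Phylogenetic distance measured as the number of distinct internal nodes on
#' the unique path connecting two tips; branch lengths and bootstrap labels
#' are ignored. A cherry pair is separated by one internal node; a tip and
#' itself by zero.
#'
#' @param tree an `ape::phylo` tree.
#' @param tip_a,tip_b tip labels.
#' @return integer internal-node count.
#' @export
tip_distance <- function(tree, tip_a, tip_b) {
  m <- tip_internal_node_matrix(tree)
  for (tp in c(tip_a, tip_b)) {
    if (!tp %in% rownames(m)) stop("unknown tip id: ", tp)
  }
  as.integer(m[tip_a, tip_b])
}

#' All pairwise tip distances (internal-node counts)
#'
#' @param tree an `ape::phylo` tree.
#' @return symmetric integer matrix with tip labels as dimnames; zero
#'   diagonal.
#' @export
tip_internal_node_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  n_tip <- length(tr$tip.label)
  d <- ape::dist.nodes(tr)[seq_len(n_tip), seq_len(n_tip), drop = FALSE]
  # a path of k edges between distinct tips passes k - 1 internal nodes
  m <- pmax(d - 1, 0)
  dimnames(m) <- list(tr$tip.label, tr$tip.label)
  m
}

#' Pairwise nucleotide differences between accessions
#'
#' Hamming distances between the accessions' concatenated genotype strings
#' over all panel loci (the complementary phylogenetic distance measure).
#'
#' @param panel a [genotype_panel()].
#' @return symmetric integer matrix keyed by accession id.
#' @export
nucleotide_diff_matrix <- function(panel) {
  m <- panel$geno
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(m[i, ] != m[j, ])
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  out
}

#' Both phylogenetic distance flavors for a panel
#'
#' @param tree an `ape::phylo` over accession ids.
#' @param panel a [genotype_panel()] (for nucleotide differences); optional.
#' @return list with `internal_nodes` and (when a panel is given)
#'   `nucleotide_diffs` matrices.
#' @export
phylo_distances <- function(tree, panel = NULL) {
  list(internal_nodes = tip_internal_node_matrix(tree),
       nucleotide_diffs = if (!is.null(panel)) nucleotide_diff_matrix(panel))
}

#' Correlate mutational path length with phylogenetic distance
#'
#' For every connected vertex pair of the network, pairs the shortest-path
#' length with the mean phylogenetic distance over all cross pairs of member
#' accessions (vertices collapse several accessions, hence the mean), then
#' computes Kendall's rank correlation. The tie-corrected tau-b variant is
#' used because path lengths are heavily tied.
#'
#' @param network a [build_network()] result.
#' @param distances accession-by-accession distance matrix (either flavor
#'   from [phylo_distances()]).
#' @return list: `tau`, `p_value`, `n_pairs`, `n_excluded_vertices`
#'   (vertices with no accession present in `distances`, dropped with a
#'   warning).
#' @export
path_vs_phylo_correlation <- function(network, distances) {
  stopifnot(inherits(network, "haplo_network"))
  g <- network$graph
  nm <- igraph::V(g)$name
  members <- lapply(network$members[nm], intersect, y = rownames(distances))
  mapped <- lengths(members) > 0L
  if (any(!mapped)) {
    warning(sum(!mapped), " vertex/vertices without tree tips excluded")
  }
  keep <- which(mapped)
  if (length(keep) < 2L) stop("fewer than two vertices map to the tree")
  d <- igraph::distances(g)
  xs <- numeric(0)
  ys <- numeric(0)
  for (a in seq_along(keep)) {
    for (b in seq_len(a - 1L)) {
      i <- keep[a]; j <- keep[b]
      if (!is.finite(d[i, j])) next
      xs <- c(xs, d[i, j])
      ys <- c(ys, mean(distances[members[[i]], members[[j]]]))
    }
  }
  if (length(xs) < 2L) stop("no connected vertex pairs to correlate")
  ct <- suppressWarnings(stats::cor.test(xs, ys, method = "kendall",
                                         alternative = "two.sided"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n_pairs = length(xs),
       n_excluded_vertices = sum(!mapped))
}
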