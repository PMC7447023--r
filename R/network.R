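#' Select phenotype-associated loci at a P-value cutoff
#'
#' Returns the loci whose association P-value is at most `cutoff`, in a fixed
#' documented order: ascending genomic label (lexicographic locus id). An
#' empty selection is returned as a zero-length character vector; cutoff
#' sweeps treat it as a degenerate grid point.
#'
#' @param assoc association data frame (`locus`, `p`).
#' @param cutoff P-value cutoff in (0, 1).
#' @return character vector of locus ids.
#' @export
select_loci <- function(assoc, cutoff) {
  stopifnot(is.numeric(cutoff), cutoff > 0, cutoff <= 1)
  assoc <- validate_assoc(assoc)
  sel <- assoc$locus[assoc$p <= cutoff]
  sort(sel)
}

#' Concatenate alleles at selected loci into haplotype strings
#'
#' One string per phenotyped accession, in panel accession order; string
#' length equals the number of loci, and all strings are aligned because they
#' represent the same genomic positions in the same order. Accessions without
#' a phenotype are excluded, mirroring the fact that only accessions used in
#' an association study contribute to its genotype network.
#'
#' @param panel a [genotype_panel()].
#' @param loci non-empty vector of panel locus ids.
#' @return named character vector (names = accession ids).
#' @export
build_haplotypes <- function(panel, loci) {
  if (length(loci) == 0L) stop("build_haplotypes: empty locus selection")
  missing <- setdiff(loci, panel$loci)
  if (length(missing)) stop("unknown locus id(s): ", paste(missing, collapse = ", "))
  sub <- panel$geno[panel$phenotyped, loci, drop = FALSE]
  strings <- apply(sub, 1L, paste0, collapse = "")
  names(strings) <- rownames(sub)
  strings
}

#' Collapse identical haplotype strings into network vertices
#'
#' Accessions sharing a haplotype string become one vertex whose phenotype is
#' the arithmetic mean over its (phenotyped) members; member accession lists
#' and raw member phenotype values are preserved for noise estimation.
#'
#' @param strings named character vector from [build_haplotypes()].
#' @param phenotypes numeric vector of phenotype values named by accession;
#'   defaults to the names of `strings` looked up in `panel`. Must cover every
#'   accession in `strings`.
#' @return a data frame of class `haplo_vertices` with columns `haplotype`,
#'   `mean_phenotype`, `n_members`, and attributes `members` and
#'   `member_values` (named lists keyed by haplotype).
#' @export
collapse_haplotypes <- function(strings, phenotypes) {
  if (length(strings) == 0L) stop("collapse_haplotypes: no haplotype strings")
  if (length(unique(nchar(strings))) != 1L) {
    stop("haplotype strings must all have equal length")
  }
  if (is.null(names(strings))) names(strings) <- sprintf("s%d", seq_along(strings))
  phenotypes <- phenotypes[names(strings)]
  if (anyNA(phenotypes)) stop("phenotype missing for accession(s) in `strings`")
  groups <- split(names(strings), strings)
  haplos <- names(groups)
  member_values <- lapply(groups, function(acc) unname(phenotypes[acc]))
  out <- data.frame(
    haplotype = haplos,
    mean_phenotype = vapply(member_values, mean, numeric(1L)),
    n_members = lengths(groups),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "members") <- groups
  attr(out, "member_values") <- member_values
  class(out) <- c("haplo_vertices", "data.frame")
  out
}

#' Build the haplotype network from collapsed vertices
#'
#' Edges join every pair of haplotype strings at Hamming distance exactly 1.
#' Vertices with no one-mutant neighbor are recorded as isolates and excluded
#' from the analysis network, so every analysis component has at least two
#' vertices. Component ids are assigned within the analysis network.
#'
#' @param vertices a [collapse_haplotypes()] result.
#' @param provenance optional list (phenotype name, cutoff, loci) stored on
#'   the network.
#' @param accession_haplotypes optional: the uncollapsed named string vector,
#'   kept for randomization null models.
#' @return object of class `haplo_network`: `graph` (igraph over analysis
#'   vertices; attributes `mean_phenotype`, `n_members`, `component`),
#'   `vertices` (all vertices incl. isolates), `isolates`, `members`,
#'   `member_values`, `n_components`, `largest_component`, `provenance`.
#' @export
build_network <- function(vertices, provenance = list(),
                          accession_haplotypes = NULL) {
  stopifnot(inherits(vertices, "haplo_vertices"))
  haplos <- vertices$haplotype
  edges <- hamming_edges(haplos)
  degree <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = length(haplos))
  isolates <- haplos[degree == 0L]
  keep <- which(degree > 0L)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  igraph::V(g)$name <- haplos[keep]
  if (nrow(edges)) {
    remap <- match(seq_along(haplos), keep)
    g <- igraph::add_edges(g, t(cbind(remap[edges[, 1L]], remap[edges[, 2L]])))
  }
  igraph::V(g)$mean_phenotype <- vertices$mean_phenotype[keep]
  igraph::V(g)$n_members <- vertices$n_members[keep]
  comp <- if (length(keep)) igraph::components(g) else list(membership = integer(0), csize = integer(0), no = 0L)
  igraph::V(g)$component <- as.integer(comp$membership)
  structure(
    list(
      graph = g,
      vertices = as.data.frame(vertices),
      isolates = isolates,
      members = attr(vertices, "members"),
      member_values = attr(vertices, "member_values"),
      n_components = comp$no,
      largest_component = if (comp$no > 0L) max(comp$csize) else 0L,
      accession_haplotypes = accession_haplotypes,
      provenance = provenance
    ),
    class = "haplo_network"
  )
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(
    "<haplo_network> %d unique genotypes (%d in analysis network, %d isolates), %d edges, %d component(s), largest %d\n",
    nrow(x$vertices), igraph::vcount(x$graph), length(x$isolates),
    igraph::ecount(x$graph), x$n_components, x$largest_component))
  invisible(x)
}

#' One-call network construction from a panel
#'
#' Convenience wrapper: select loci at `cutoff` (or use `loci` directly),
#' concatenate haplotypes, collapse, and build the network.
#'
#' @param panel a [genotype_panel()].
#' @param assoc association table; required when `cutoff` is given.
#' @param cutoff association P-value cutoff.
#' @param loci explicit locus selection overriding the cutoff.
#' @param phenotype_name label stored in provenance.
#' @return a [build_network()] result, or `NULL` when the selection is empty.
#' @export
build_genotype_network <- function(panel, assoc = NULL, cutoff = NULL,
                                   loci = NULL, phenotype_name = "phenotype") {
  if (is.null(loci)) {
    if (is.null(assoc) || is.null(cutoff)) {
      stop("supply either `loci` or both `assoc` and `cutoff`")
    }
    loci <- select_loci(assoc, cutoff)
  }
  if (length(loci) == 0L) return(NULL)
  strings <- build_haplotypes(panel, loci)
  verts <- collapse_haplotypes(strings, panel$phenotype)
  build_network(verts,
                provenance = list(phenotype = phenotype_name, cutoff = cutoff,
                                  loci = loci),
                accession_haplotypes = strings)
}

#' Enumerate squares (chordless-or-not four-cycles)
#'
#' Each 4-cycle a--b--c--d--a is reported exactly once, orientation-free, as
#' the cycle-ordered vertex quadruple (v1, v2, v3, v4) with diagonals
#' (v1, v3) and (v2, v4). Enumeration walks non-adjacent vertex pairs and
#' pairs of their common neighbors; a cycle is emitted from the diagonal that
#' contains its smallest vertex index, which de-duplicates the two diagonal
#' representations.
#'
#' @param network a [build_network()] result or an igraph object.
#' @return data frame with columns `v1..v4` (vertex names) and `component`.
#' @export
find_squares <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  empty <- data.frame(v1 = character(0), v2 = character(0),
                      v3 = character(0), v4 = character(0),
                      component = integer(0), stringsAsFactors = FALSE)
  if (n < 4L) return(empty)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  comp <- igraph::components(g)$membership
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  rows <- list()
  for (u in seq_len(n - 1L)) {
    nb_u <- adj[[u]]
    if (length(nb_u) < 2L) next
    # candidate diagonal partners: vertices reachable through u's neighbors
    # (a diagonal may itself be an edge: chordal squares count too)
    cand <- setdiff(unique(unlist(adj[nb_u])), u)
    cand <- cand[cand > u]
    for (v in cand) {
      common <- intersect(nb_u, adj[[v]])
      common <- common[common > u]  # u must be the smallest vertex of the cycle
      if (length(common) < 2L) next
      prs <- utils::combn(sort(common), 2L)
      for (k in seq_len(ncol(prs))) {
        rows[[length(rows) + 1L]] <-
          c(u, prs[1L, k], v, prs[2L, k], comp[[u]])
      }
    }
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  data.frame(v1 = nm[m[, 1L]], v2 = nm[m[, 2L]], v3 = nm[m[, 3L]],
             v4 = nm[m[, 4L]], component = as.integer(m[, 5L]),
             stringsAsFactors = FALSE)
}

#' Count squares per component
#'
#' @param network a [build_network()] result or igraph object.
#' @return list with `total`, `per_component` (named integer vector) and
#'   `max_per_component`.
#' @export
count_squares <- function(network) {
  sq <- find_squares(network)
  g <- as_igraph(network)
  comp <- if (igraph::vcount(g)) igraph::components(g) else list(no = 0L)
  per <- integer(comp$no)
  if (comp$no > 0L) names(per) <- as.character(seq_len(comp$no))
  if (nrow(sq)) {
    tab <- table(sq$component)
    per[names(tab)] <- as.integer(tab)
  }
  list(total = nrow(sq), per_component = per,
       max_per_component = if (length(per)) max(per) else 0L)
}

#' Sweep association P-value cutoffs and pick the analysis network
#'
#' Builds one haplotype network per cutoff on a `-log10` grid and records, per
#' cutoff: selected loci, unique genotypes, components with at least two
#' vertices, largest-component size, and per-component square counts. The
#' selected cutoff maximizes the per-component maximum square count; ties are
#' broken by larger largest-component size, then by the more stringent
#' cutoff. The two half-log-unit neighbors of the selected cutoff are exposed
#' for sensitivity reruns.
#'
#' @param panel a [genotype_panel()].
#' @param assoc association table.
#' @param grid numeric vector of `-log10(P)` cutoffs (default 4 to 9 by 0.5).
#' @param phenotype_name provenance label.
#' @return list of class `sweep_result`: `table` (one row per cutoff),
#'   `selected_neglog10`, `selected_cutoff`, `network` (the selected
#'   network), `sensitivity` (the +/- 0.5 log-unit cutoffs). `NULL` network
#'   and `NA` selection when every grid point is degenerate.
#' @export
sweep_cutoffs <- function(panel, assoc, grid = seq(4, 9, by = 0.5),
                          phenotype_name = "phenotype") {
  stopifnot(length(grid) >= 1L, all(grid > 0))
  grid <- sort(unique(grid))
  nets <- vector("list", length(grid))
  rows <- lapply(seq_along(grid), function(i) {
    cutoff <- 10^(-grid[i])
    net <- build_genotype_network(panel, assoc, cutoff,
                                  phenotype_name = phenotype_name)
    nets[[i]] <<- net
    if (is.null(net)) {
      return(data.frame(neglog10 = grid[i], cutoff = cutoff, n_loci = 0L,
                        n_unique_genotypes = 0L, n_components = 0L,
                        largest_component = 0L, n_squares = 0L,
                        max_component_squares = 0L))
    }
    sq <- count_squares(net)
    data.frame(neglog10 = grid[i], cutoff = cutoff,
               n_loci = length(net$provenance$loci),
               n_unique_genotypes = nrow(net$vertices),
               n_components = net$n_components,
               largest_component = net$largest_component,
               n_squares = sq$total,
               max_component_squares = sq$max_per_component)
  })
  tab <- do.call(rbind, rows)
  usable <- tab$n_unique_genotypes > 0L
  if (!any(usable)) {
    return(structure(list(table = tab, selected_neglog10 = NA_real_,
                          selected_cutoff = NA_real_, network = NULL,
                          sensitivity = numeric(0)),
                     class = "sweep_result"))
  }
  # selection: max square count, then largest component, then most stringent
  ord <- order(-tab$max_component_squares, -tab$largest_component,
               -tab$neglog10)
  ord <- ord[usable[ord]]
  best <- ord[1L]
  structure(
    list(table = tab,
         selected_neglog10 = tab$neglog10[best],
         selected_cutoff = tab$cutoff[best],
         network = nets[[best]],
         sensitivity = c(lower = tab$neglog10[best] - 0.5,
                         upper = tab$neglog10[best] + 0.5)),
    class = "sweep_result"
  )
}

# ---- internal helpers ----------------------------------------------------

# all unordered pairs of strings at Hamming distance exactly 1
hamming_edges <- function(strings) {
  n <- length(strings)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  m <- do.call(rbind, strsplit(strings, ""))
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    mism <- colSums(t(m[rest, , drop = FALSE]) != m[i, ])
    hit <- rest[mism == 1L]
    if (length(hit)) out[[i]] <- cbind(i, hit)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), 0L, 2L) else res
}

as_igraph <- function(x) {
  if (inherits(x, "haplo_network")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  stop("expected a haplo_network or igraph object")
}

# vertex mean phenotypes as a named vector, from network or igraph attrs
vertex_values <- function(x) {
  g <- as_igraph(x)
  v <- igraph::V(g)$mean_phenotype
  if (is.null(v)) stop("graph carries no `mean_phenotype` vertex attribute")
  names(v) <- igraph::V(g)$name
  v
}
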