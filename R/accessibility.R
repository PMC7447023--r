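#' Find the unique phenotypic extremum of the analyzed component
#'
#' Path analyses are intra-component, so uniqueness of the extremum is
#' checked within the analyzed component (the largest, by default). A tie at
#' the extreme value makes the analysis ambiguous and the direction is
#' skipped with a record.
#'
#' @param network a [build_network()] result or igraph with
#'   `mean_phenotype`.
#' @param direction `"max"` or `"min"`.
#' @param component `"largest"` or an explicit component id.
#' @return list: `status` (`"ok"` or `"ambiguous"`), `vertex` (name or `NA`),
#'   `value`, `component`.
#' @export
find_unique_extremum <- function(network, direction = c("max", "min"),
                                 component = "largest") {
  direction <- match.arg(direction)
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) stop("empty network")
  comp <- igraph::components(g)
  cid <- if (identical(component, "largest")) which.max(comp$csize)
         else as.integer(component)
  in_comp <- which(comp$membership == cid)
  vals <- vertex_values(g)[in_comp]
  ext <- if (direction == "max") max(vals) else min(vals)
  hits <- names(vals)[vals == ext]
  if (length(hits) > 1L) {
    return(list(status = "ambiguous", vertex = NA_character_, value = ext,
                component = cid))
  }
  list(status = "ok", vertex = hits, value = ext, component = cid)
}

#' Enumerate every shortest path between two vertices
#'
#' All distinct vertex sequences of minimal edge count connecting `source`
#' and `target` (geodesics), as ordered vertex-name vectors from source to
#' target.
#'
#' @param network a [build_network()] result or igraph.
#' @param source,target vertex names.
#' @return list of character vectors; empty list (with attribute
#'   `no_path = TRUE`) when the pair is disconnected.
#' @export
enumerate_shortest_paths <- function(network, source, target) {
  g <- as_igraph(network)
  suppressWarnings(
    res <- igraph::all_shortest_paths(g, from = source, to = target)
  )
  if (length(res$res) == 0L) {
    out <- list()
    attr(out, "no_path") <- TRUE
    return(out)
  }
  lapply(res$res, function(p) igraph::V(g)$name[as.integer(p)])
}

#' Is a mutational path monotonically accessible?
#'
#' For `direction = "max"` a path is accessible when the phenotype never
#' falls by more than the identity tolerance delta along any edge
#' (`V_next - V_prev >= -delta`); mirrored for `"min"`. This composes the
#' monotonicity requirement with the rule that two neighboring values within
#' delta of each other count as identical. `mode = "strict"` instead demands
#' that every step move in the chosen direction by more than delta.
#'
#' @param values phenotype values along the path, source first.
#' @param delta identity tolerance (>= 0).
#' @param direction `"max"` or `"min"`.
#' @param mode `"tolerant"` (default) or `"strict"`.
#' @return logical.
#' @export
is_accessible <- function(values, delta, direction = c("max", "min"),
                          mode = c("tolerant", "strict")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (length(values) < 2L) return(TRUE)
  steps <- diff(values)
  if (direction == "min") steps <- -steps
  if (mode == "tolerant") all(steps >= -delta) else all(steps > delta)
}

#' Accessibility of the phenotypic extremum from every vertex
#'
#' Identifies the unique extremum of the analyzed component, enumerates all
#' shortest paths from every other vertex of that component to it, flags each
#' path as accessible or not, and aggregates: a per-source table, the global
#' accessible fraction, the mean path length over all paths, and accessible
#' fractions binned by path length (`[1,2)`, `[2,3)`, ...).
#'
#' @param network a [build_network()] result or igraph with
#'   `mean_phenotype`.
#' @param delta identity tolerance.
#' @param direction `"max"` or `"min"`.
#' @param mode passed to [is_accessible()].
#' @param max_paths abort (with an informative error) when the total number
#'   of enumerated paths would exceed this cap; default 1e6.
#' @return object of class `accessibility_report`: `status`, `extremum`,
#'   `per_source` (data frame: source, length, n_paths, n_accessible),
#'   `fraction_accessible`, `mean_path_length`, `n_paths`, `bins`
#'   (data frame: bin, length, n_paths, n_accessible, fraction_accessible).
#'   When the extremum is ambiguous, `status = "ambiguous_extremum"` and the
#'   numeric fields are `NA`.
#' @export
accessibility_summary <- function(network, delta, direction = c("max", "min"),
                                  mode = c("tolerant", "strict"),
                                  max_paths = 1e6) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  ext <- find_unique_extremum(network, direction)
  empty_bins <- data.frame(bin = character(0), length = integer(0),
                           n_paths = integer(0), n_accessible = integer(0),
                           fraction_accessible = numeric(0))
  if (ext$status != "ok") {
    return(structure(list(status = "ambiguous_extremum", extremum = NA_character_,
                          direction = direction, per_source = NULL,
                          fraction_accessible = NA_real_,
                          mean_path_length = NA_real_, n_paths = NA_integer_,
                          bins = empty_bins, delta = delta),
                     class = "accessibility_report"))
  }
  g <- as_igraph(network)
  comp <- igraph::components(g)
  sub <- igraph::induced_subgraph(g, which(comp$membership == ext$component))
  vals <- vertex_values(sub)
  sources <- setdiff(igraph::V(sub)$name, ext$vertex)
  # pre-count geodesics to honor the enumeration cap before materializing
  counts <- count_geodesics(sub, ext$vertex)
  if (sum(counts$n_paths[sources]) > max_paths) {
    stop(sprintf("path enumeration would produce %d paths (cap %g); raise `max_paths` deliberately if this is intended",
                 sum(counts$n_paths[sources]), max_paths))
  }
  suppressWarnings(
    all_paths <- igraph::all_shortest_paths(sub, from = ext$vertex)$res
  )
  per <- data.frame(source = sources,
                    length = as.integer(counts$dist[sources]),
                    n_paths = as.integer(counts$n_paths[sources]),
                    n_accessible = 0L, stringsAsFactors = FALSE)
  rownames(per) <- per$source
  for (p in all_paths) {
    nodes <- rev(igraph::V(sub)$name[as.integer(p)])  # source -> extremum
    if (length(nodes) < 2L) next
    src <- nodes[1L]
    if (is_accessible(unname(vals[nodes]), delta, direction, mode)) {
      per[src, "n_accessible"] <- per[src, "n_accessible"] + 1L
    }
  }
  total_paths <- sum(per$n_paths)
  total_acc <- sum(per$n_accessible)
  bins <- do.call(rbind, lapply(sort(unique(per$length)), function(len) {
    sel <- per$length == len
    data.frame(bin = sprintf("[%d,%d)", len, len + 1L), length = len,
               n_paths = sum(per$n_paths[sel]),
               n_accessible = sum(per$n_accessible[sel]),
               fraction_accessible = sum(per$n_accessible[sel]) / sum(per$n_paths[sel]))
  }))
  if (is.null(bins)) bins <- empty_bins
  structure(
    list(status = "ok", extremum = ext$vertex, direction = direction,
         per_source = per,
         fraction_accessible = if (total_paths > 0L) total_acc / total_paths else NA_real_,
         mean_path_length = if (total_paths > 0L)
           sum(per$length * per$n_paths) / total_paths else NA_real_,
         n_paths = total_paths, bins = bins, delta = delta),
    class = "accessibility_report"
  )
}

#' @export
print.accessibility_report <- function(x, ...) {
  if (x$status != "ok") {
    cat("<accessibility_report> status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("<accessibility_report> direction=%s extremum=%s: %d shortest paths, %.3f accessible, mean length %.3g\n",
              x$direction, x$extremum, x$n_paths, x$fraction_accessible,
              x$mean_path_length))
  invisible(x)
}

#' Distribution of all pairwise shortest-path lengths
#'
#' Path lengths between every connected vertex pair of the analysis network
#' (not only paths to the extremum), as used for network-wide path-length
#' histograms.
#'
#' @param network a [build_network()] result or igraph.
#' @return integer vector of path lengths (one per unordered connected pair).
#' @export
path_length_distribution <- function(network) {
  g <- as_igraph(network)
  d <- igraph::distances(g)
  up <- d[upper.tri(d)]
  as.integer(up[is.finite(up) & up > 0])
}

# internal: BFS geodesic counts from one root (distance + path multiplicity)
count_geodesics <- function(g, root) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  dist <- rep(Inf, n)
  cnt <- numeric(n)
  r <- match(root, nm)
  dist[r] <- 0
  cnt[r] <- 1
  frontier <- r
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[u] + 1
          nxt <- c(nxt, w)
          cnt[w] <- cnt[w] + cnt[u]
        } else if (dist[w] == dist[u] + 1) {
          cnt[w] <- cnt[w] + cnt[u]
        }
      }
    }
    frontier <- unique(nxt)
  }
  names(dist) <- nm
  names(cnt) <- nm
  list(dist = dist, n_paths = cnt)
}
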