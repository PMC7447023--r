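#' Read the three canonical input tables
#'
#' Reads a genotype matrix, a phenotype table and an association table, all
#' tab-separated UTF-8 with mandatory header rows, and validates them against
#' the panel data model. Accessions present in the genotype matrix but absent
#' from the phenotype table are retained and flagged unphenotyped. Loci with
#' more than two alleles are rejected with an error naming the locus;
#' malformed numeric cells are rejected with an error naming file, row and
#' column rather than silently coerced.
#'
#' Expected layouts:
#' \describe{
#'   \item{genotype}{first column `accession`, remaining columns one per locus
#'     id, cells single nucleotide characters.}
#'   \item{phenotype}{columns `accession`, `phenotype`.}
#'   \item{association}{columns `locus`, `p`.}
#' }
#'
#' @param genotype_path,phenotype_path,association_path file paths.
#' @return list with elements `panel` ([genotype_panel()]) and `assoc`
#'   (data frame `locus`, `p`). `association_path` may be `NULL`, in which
#'   case `assoc` is `NULL`.
#' @export
read_panel <- function(genotype_path, phenotype_path, association_path = NULL) {
  gt <- read_tsv_checked(genotype_path)
  if (names(gt)[1L] != "accession") {
    stop(genotype_path, ": first column must be named 'accession'")
  }
  geno <- as.matrix(gt[, -1L, drop = FALSE])
  rownames(geno) <- as.character(gt$accession)
  storage.mode(geno) <- "character"

  ph <- read_tsv_checked(phenotype_path)
  if (!all(c("accession", "phenotype") %in% names(ph))) {
    stop(phenotype_path, ": required columns 'accession' and 'phenotype'")
  }
  vals <- parse_numeric_column(ph$phenotype, phenotype_path, "phenotype")
  names(vals) <- as.character(ph$accession)
  if (anyDuplicated(names(vals))) {
    stop(phenotype_path, ": duplicate accession id '",
         names(vals)[duplicated(names(vals))][1L], "'")
  }
  unknown <- setdiff(names(vals), rownames(geno))
  if (length(unknown)) {
    stop(phenotype_path, ": accession(s) not in genotype matrix: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  vals <- vals[!is.na(vals)]
  panel <- genotype_panel(geno, vals)

  assoc <- NULL
  if (!is.null(association_path)) {
    at <- read_tsv_checked(association_path)
    if (!all(c("locus", "p") %in% names(at))) {
      stop(association_path, ": required columns 'locus' and 'p'")
    }
    assoc <- data.frame(
      locus = as.character(at$locus),
      p = parse_numeric_column(at$p, association_path, "p"),
      stringsAsFactors = FALSE
    )
    assoc <- validate_assoc(assoc, panel)
  }
  list(panel = panel, assoc = assoc)
}

#' Write a panel (and optional association table) as TSV
#'
#' Writes `<prefix>_genotypes.tsv`, `<prefix>_phenotypes.tsv` and, when an
#' association table is supplied, `<prefix>_associations.tsv` in the layouts
#' [read_panel()] expects, so that a write/read round trip is the identity.
#'
#' @param panel a [genotype_panel()].
#' @param dir output directory (created if needed).
#' @param assoc optional association data frame (`locus`, `p`).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of file paths written.
#' @export
write_panel <- function(panel, dir, assoc = NULL, prefix = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, paste0(prefix, "_genotypes.tsv")),
    phenotypes = file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  )
  gt <- data.frame(accession = panel$accessions, panel$geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gt, paths[["genotypes"]])
  ph <- data.frame(accession = panel$accessions[panel$phenotyped],
                   phenotype = panel$phenotype[panel$phenotyped],
                   stringsAsFactors = FALSE)
  write_tsv(ph, paths[["phenotypes"]])
  if (!is.null(assoc)) {
    paths <- c(paths, associations = file.path(dir, paste0(prefix, "_associations.tsv")))
    write_tsv(assoc[, c("locus", "p")], paths[["associations"]])
  }
  invisible(paths)
}

#' Export a haplotype network as GraphML plus an edge-list TSV
#'
#' The GraphML carries, per vertex, the haplotype string, mean phenotype,
#' member count, module id and normalized betweenness (the latter two computed
#' at export time), so the file supports external force-directed layout tools
#' without information loss. An empty network produces a warning and
#' header-only outputs.
#'
#' @param network a [build_network()] result.
#' @param path base output path; `.graphml` and `_edges.tsv` suffixes are
#'   appended.
#' @param seed seed for the module-detection step baked into vertex
#'   attributes.
#' @return invisibly, the two file paths.
#' @export
write_network <- function(network, path, seed = 1L) {
  graphml <- paste0(path, ".graphml")
  edges_tsv <- paste0(path, "_edges.tsv")
  g <- network$graph
  if (igraph::vcount(g) == 0L) {
    warning("write_network: empty analysis network; writing header-only files")
    write_tsv(data.frame(from = character(0), to = character(0)), edges_tsv)
    igraph::write_graph(g, graphml, format = "graphml")
    return(invisible(c(graphml = graphml, edges = edges_tsv)))
  }
  btw <- vertex_betweenness(network)
  mods <- detect_modules(network, seed = seed)
  module <- rep(NA_integer_, igraph::vcount(g))
  names(module) <- igraph::V(g)$name
  module[names(mods$membership)] <- mods$membership
  g <- igraph::set_vertex_attr(g, "haplotype", value = igraph::V(g)$name)
  g <- igraph::set_vertex_attr(g, "mean_phenotype", value = igraph::V(g)$mean_phenotype)
  g <- igraph::set_vertex_attr(g, "n_members", value = igraph::V(g)$n_members)
  g <- igraph::set_vertex_attr(g, "module", value = as.numeric(module[igraph::V(g)$name]))
  g <- igraph::set_vertex_attr(g, "betweenness", value = as.numeric(btw[igraph::V(g)$name]))
  igraph::write_graph(g, graphml, format = "graphml")
  el <- igraph::as_edgelist(network$graph)
  write_tsv(data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE),
            edges_tsv)
  invisible(c(graphml = graphml, edges = edges_tsv))
}

#' Re-import a GraphML network export
#'
#' @param graphml_path path written by [write_network()].
#' @return an igraph object with the exported vertex attributes.
#' @export
read_network <- function(graphml_path) {
  igraph::read_graph(graphml_path, format = "graphml")
}

#' Read a Newick tree, tolerating bootstrap labels
#'
#' Thin wrapper over [ape::read.tree()]; internal-node bootstrap labels are
#' retained but ignored by all distance computations, and branch lengths play
#' no role in internal-node counting.
#'
#' @param path Newick file.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(path, ": could not parse Newick tree")
  tree
}

# ---- internal TSV helpers ------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8", quote = "")
  if (ncol(df) < 1L) stop(path, ": no columns parsed")
  df
}

parse_numeric_column <- function(x, path, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("NA", "")))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                 path, x[bad[1L]], column, bad[1L]))
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
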