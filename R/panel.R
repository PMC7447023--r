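#' Construct a genotype panel
#'
#' A genotype panel bundles the three tables every downstream stage consumes:
#' an accession-by-locus matrix of single nucleotide characters (biallelic
#' loci), per-accession phenotype values (possibly missing for accessions that
#' were genotyped but never phenotyped), and opaque locus identifiers whose
#' lexicographic order is treated as genomic order.
#'
#' @param geno character matrix, rows = accessions, columns = loci; every cell
#'   a single non-missing character; at most two distinct characters per
#'   column.
#' @param phenotype numeric vector named by accession id; `NA` marks an
#'   accession that is genotyped but not phenotyped.
#' @return an object of class `genotype_panel` with elements `geno`,
#'   `phenotype`, `accessions`, `loci` and a logical `phenotyped` flag vector.
#' @export
genotype_panel <- function(geno, phenotype) {
  if (!is.matrix(geno) || !is.character(geno)) {
    stop("`geno` must be a character matrix (accessions x loci)")
  }
  if (nrow(geno) == 0L || ncol(geno) == 0L) {
    stop("genotype matrix must have at least one accession and one locus")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix must carry accession row names and locus column names")
  }
  if (anyDuplicated(rownames(geno))) {
    stop("duplicate accession ids: ",
         paste(unique(rownames(geno)[duplicated(rownames(geno))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(geno))) {
    stop("duplicate locus ids: ",
         paste(unique(colnames(geno)[duplicated(colnames(geno))]), collapse = ", "))
  }
  if (anyNA(geno) || any(nchar(geno) != 1L)) {
    bad <- which(is.na(geno) | nchar(geno) != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid allele at accession '%s', locus '%s': alleles must be single characters",
                 rownames(geno)[bad[1L]], colnames(geno)[bad[2L]]))
  }
  n_alleles <- apply(geno, 2L, function(col) length(unique(col)))
  if (any(n_alleles > 2L)) {
    stop("locus is not biallelic (", n_alleles[which(n_alleles > 2L)[1L]],
         " alleles): ", colnames(geno)[which(n_alleles > 2L)[1L]])
  }
  phen <- rep(NA_real_, nrow(geno))
  names(phen) <- rownames(geno)
  if (!is.null(phenotype)) {
    if (is.null(names(phenotype))) stop("`phenotype` must be named by accession id")
    unknown <- setdiff(names(phenotype), rownames(geno))
    if (length(unknown)) {
      stop("phenotyped accession(s) absent from genotype matrix: ",
           paste(unknown, collapse = ", "))
    }
    phen[names(phenotype)] <- as.numeric(phenotype)
  }
  structure(
    list(
      geno = geno,
      phenotype = phen,
      accessions = rownames(geno),
      loci = colnames(geno),
      phenotyped = !is.na(phen)
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d accessions x %d loci (%d phenotyped)\n",
              length(x$accessions), length(x$loci), sum(x$phenotyped)))
  invisible(x)
}

#' Minor allele frequency per locus
#'
#' Frequencies are computed over phenotyped accessions only, because those are
#' the accessions that enter the haplotype network. Monomorphic loci have
#' frequency 0.
#'
#' @param panel a [genotype_panel()].
#' @return named numeric vector of minor allele frequencies.
#' @export
minor_allele_freq <- function(panel) {
  sub <- panel$geno[panel$phenotyped, , drop = FALSE]
  vapply(seq_len(ncol(sub)), function(j) {
    tab <- table(sub[, j])
    if (length(tab) < 2L) return(0)
    min(tab) / sum(tab)
  }, numeric(1L), USE.NAMES = FALSE) -> maf
  names(maf) <- panel$loci
  maf
}

#' Drop loci with rare minor alleles
#'
#' Removes loci whose minor-allele frequency among phenotyped accessions is
#' strictly below `threshold`; a locus at exactly the threshold is retained.
#'
#' @param panel a [genotype_panel()].
#' @param threshold minimum minor allele frequency, in `[0, 0.5]`.
#' @return a filtered [genotype_panel()].
#' @export
maf_filter <- function(panel, threshold = 0.05) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 0.5)
  if (threshold == 0) return(panel)
  keep <- minor_allele_freq(panel) >= threshold
  if (!any(keep)) stop("maf_filter: no locus passes threshold ", threshold)
  genotype_panel(panel$geno[, keep, drop = FALSE],
                 panel$phenotype[panel$phenotyped])
}

#' Prune loci in strong linkage disequilibrium
#'
#' Greedy representative selection: loci are visited in order of ascending
#' association P (ties broken by locus id), and a locus is dropped when its
#' allelic r-squared with an already retained locus reaches `r2_threshold`.
#' This keeps the smallest-P member of every correlated cluster and is a
#' declared, configurable pruning rule rather than a reconstruction of any
#' particular published LD workflow.
#'
#' @param panel a [genotype_panel()].
#' @param assoc an association table (see [read_panel()]): data frame with
#'   columns `locus`, `p`.
#' @param r2_threshold allelic r-squared at or above which two loci are
#'   considered redundant; in `(0, 1]`.
#' @return a [genotype_panel()] restricted to the retained loci.
#' @export
ld_prune <- function(panel, assoc, r2_threshold = 0.95) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  assoc <- validate_assoc(assoc, panel)
  sub <- panel$geno[panel$phenotyped, , drop = FALSE]
  # numeric coding: indicator of the lexicographically larger allele
  num <- vapply(seq_len(ncol(sub)), function(j) {
    lev <- sort(unique(sub[, j]))
    as.numeric(sub[, j] == lev[length(lev)])
  }, numeric(nrow(sub)))
  colnames(num) <- panel$loci
  p <- assoc$p[match(panel$loci, assoc$locus)]
  ord <- order(p, panel$loci)
  kept <- character(0)
  for (j in ord) {
    id <- panel$loci[j]
    if (length(kept)) {
      r2 <- vapply(kept, function(k) {
        if (stats::sd(num[, id]) == 0 || stats::sd(num[, k]) == 0) {
          # monomorphic against anything: treat a duplicated constant column
          # as perfectly redundant, otherwise uncorrelated
          return(as.numeric(identical(num[, id], num[, k])))
        }
        stats::cor(num[, id], num[, k])^2
      }, numeric(1L))
      if (any(r2 >= r2_threshold)) next
    }
    kept <- c(kept, id)
  }
  kept <- panel$loci[panel$loci %in% kept]
  genotype_panel(panel$geno[, kept, drop = FALSE],
                 panel$phenotype[panel$phenotyped])
}

# internal: check association table against a panel
validate_assoc <- function(assoc, panel = NULL) {
  if (!is.data.frame(assoc) || !all(c("locus", "p") %in% names(assoc))) {
    stop("association table must be a data frame with columns `locus` and `p`")
  }
  assoc$locus <- as.character(assoc$locus)
  if (anyDuplicated(assoc$locus)) {
    stop("duplicate locus id in association table: ",
         assoc$locus[duplicated(assoc$locus)][1L])
  }
  if (any(!is.finite(assoc$p)) || any(assoc$p <= 0) || any(assoc$p > 1)) {
    stop("association P-values must lie in (0, 1]; offending locus: ",
         assoc$locus[which(!is.finite(assoc$p) | assoc$p <= 0 | assoc$p > 1)[1L]])
  }
  if (!is.null(panel)) {
    missing <- setdiff(assoc$locus, panel$loci)
    if (length(missing)) {
      stop("association table names loci absent from the panel: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  assoc
}
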