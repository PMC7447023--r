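#' Configuration for a synthetic GWAS panel
#'
#' Describes a panel of inbred accessions genotyped at independent biallelic
#' loci with a quantitative phenotype generated from a known architecture:
#' additive effects at causal loci, optional pairwise epistatic interaction
#' terms, and Gaussian accession-level noise. Alleles are encoded 'A' (major)
#' and 'T' (minor); the network layer treats characters opaquely, so the
#' alphabet is a convention, not a constraint.
#'
#' @param n_accessions number of accessions (rows).
#' @param n_causal_loci number of loci with nonzero additive effect (>= 1).
#' @param n_neutral_loci number of additional loci with no phenotypic effect.
#' @param minor_allele_freq per-locus minor allele frequency; a single value
#'   or a vector of length `n_causal_loci + n_neutral_loci`; each in (0, 0.5].
#' @param additive_effects phenotype-unit effect of carrying the minor allele,
#'   one value per causal locus (recycled if scalar).
#' @param interaction_terms list of `list(i, j, effect)` triples: accessions
#'   carrying the minor allele at both causal-locus indices `i` and `j`
#'   receive `effect` additional phenotype units.
#' @param noise_sd standard deviation of accession-level Gaussian noise
#'   (phenotype units, >= 0).
#' @param baseline constant added to every phenotype (phenotype units); a
#'   nonzero baseline keeps coefficients of variation well defined.
#' @param seed integer seed; every stochastic stage derives its own stream
#'   from it (see Details).
#'
#' @details Reproducibility contract: genotype sampling uses RNG stream
#' `seed`, noise sampling uses stream `seed + 500009`; both are set
#' immediately before the corresponding draw, so each stage is independently
#' reproducible.
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_accessions,
                              n_causal_loci,
                              n_neutral_loci = 0L,
                              minor_allele_freq = 0.2,
                              additive_effects = 1,
                              interaction_terms = list(),
                              noise_sd = 0,
                              baseline = 0,
                              seed = 1L) {
  n_accessions <- as.integer(n_accessions)
  n_causal_loci <- as.integer(n_causal_loci)
  n_neutral_loci <- as.integer(n_neutral_loci)
  if (n_accessions < 1L) stop("n_accessions must be >= 1")
  if (n_causal_loci < 1L) stop("n_causal_loci must be >= 1")
  if (n_neutral_loci < 0L) stop("n_neutral_loci must be >= 0")
  n_loci <- n_causal_loci + n_neutral_loci
  maf <- rep_len(minor_allele_freq, n_loci)
  if (any(maf <= 0) || any(maf > 0.5)) stop("minor_allele_freq must lie in (0, 0.5]")
  beta <- rep_len(as.numeric(additive_effects), n_causal_loci)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (term in interaction_terms) {
    if (length(term) != 3L) stop("each interaction term must be list(i, j, effect)")
    i <- as.integer(term[[1L]]); j <- as.integer(term[[2L]])
    if (i < 1L || j < 1L || i > n_causal_loci || j > n_causal_loci || i == j) {
      stop("interaction term indices must name two distinct causal loci")
    }
  }
  structure(
    list(n_accessions = n_accessions, n_causal_loci = n_causal_loci,
         n_neutral_loci = n_neutral_loci, minor_allele_freq = maf,
         additive_effects = beta, interaction_terms = interaction_terms,
         noise_sd = as.numeric(noise_sd), baseline = as.numeric(baseline),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a GWAS-style genotype panel with known architecture
#'
#' Draws each accession's allele independently per locus (minor allele with
#' probability `minor_allele_freq`), then computes the phenotype as
#' baseline + sum of additive effects over carried minor alleles + sum of
#' interaction effects over accessions carrying both minor alleles of an
#' interaction pair + Gaussian noise. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_panel()]; the ground truth (effects, interactions,
#'   seed) is attached as attribute `"truth"`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_accessions
  n_loci <- config$n_causal_loci + config$n_neutral_loci
  set.seed(derive_seed(config$seed, 0L))
  minor <- matrix(stats::runif(n * n_loci) <
                    matrix(config$minor_allele_freq, n, n_loci, byrow = TRUE),
                  n, n_loci)
  geno <- matrix(ifelse(minor, "T", "A"), n, n_loci)
  rownames(geno) <- sprintf("acc_%03d", seq_len(n))
  colnames(geno) <- sprintf("1:%07d", 100L * seq_len(n_loci))
  causal <- minor[, seq_len(config$n_causal_loci), drop = FALSE]
  phen <- config$baseline + as.numeric(causal %*% config$additive_effects)
  for (term in config$interaction_terms) {
    both <- causal[, term[[1L]]] & causal[, term[[2L]]]
    phen <- phen + as.numeric(term[[3L]]) * both
  }
  if (config$noise_sd > 0) {
    set.seed(derive_seed(config$seed, 500009L))
    phen <- phen + stats::rnorm(n, 0, config$noise_sd)
  }
  names(phen) <- rownames(geno)
  panel <- genotype_panel(geno, phen)
  attr(panel, "truth") <- list(
    additive_effects = config$additive_effects,
    interaction_terms = config$interaction_terms,
    causal_loci = colnames(geno)[seq_len(config$n_causal_loci)],
    noise_sd = config$noise_sd, baseline = config$baseline,
    seed = config$seed
  )
  panel
}

#' Per-locus association P-values by rank-based test
#'
#' Two-sided Wilcoxon rank-sum test of phenotype grouped by allele at each
#' locus (normal approximation with continuity correction). This is a simple,
#' distribution-free stand-in for a mixed-model association scan: the
#' pipeline only requires a P-value column with the correct qualitative
#' behavior. A monomorphic locus has no defined association and is reported
#' as P = 1 with a warning.
#'
#' @param panel a [genotype_panel()]; only phenotyped accessions are tested.
#' @return data frame with columns `locus`, `p`, P in (0, 1].
#' @export
compute_association_pvalues <- function(panel) {
  sub <- panel$geno[panel$phenotyped, , drop = FALSE]
  phen <- panel$phenotype[panel$phenotyped]
  p <- vapply(seq_len(ncol(sub)), function(j) {
    alleles <- sub[, j]
    lev <- unique(alleles)
    if (length(lev) < 2L) {
      warning("monomorphic locus ", colnames(sub)[j], ": P undefined, reporting 1")
      return(1)
    }
    x <- phen[alleles == lev[1L]]
    y <- phen[alleles == lev[2L]]
    if (stats::sd(phen) == 0) return(1)
    pv <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value
    )
    min(max(pv, .Machine$double.xmin), 1)
  }, numeric(1L))
  data.frame(locus = colnames(sub), p = p, stringsAsFactors = FALSE)
}

#' Plant a four-genotype square with a known epistasis class
#'
#' Returns the four phenotype values (V_ab, V_Ab, V_aB, V_AB) of a square
#' whose classification at delta = 0 equals `class_label`:
#' \describe{
#'   \item{additive}{(0, 1, 1, 2) * scale — the double mutant is exactly the
#'     sum of the single-mutant effects.}
#'   \item{magnitude}{(0, 1, 1, 3) * scale — non-additive, but neither
#'     mutation changes the sign of its effect.}
#'   \item{simple_sign}{(0, -1, 1, 2) * scale — one single mutant falls below
#'     the wild type.}
#'   \item{reciprocal_sign}{(1, 0, 0, 2) * scale — both single mutants fall
#'     below the wild type; the double mutant is the maximum.}
#' }
#'
#' @param class_label one of `"additive"`, `"magnitude"`, `"simple_sign"`,
#'   `"reciprocal_sign"`.
#' @param magnitude_scale positive multiplier applied to the template values.
#' @return object of class `planted_square`: numeric `values` named
#'   `V_ab`, `V_Ab`, `V_aB`, `V_AB`, plus the intended class.
#' @export
plant_square <- function(class_label, magnitude_scale = 1) {
  templates <- list(
    additive        = c(V_ab = 0, V_Ab = 1, V_aB = 1, V_AB = 2),
    magnitude       = c(V_ab = 0, V_Ab = 1, V_aB = 1, V_AB = 3),
    simple_sign     = c(V_ab = 0, V_Ab = -1, V_aB = 1, V_AB = 2),
    reciprocal_sign = c(V_ab = 1, V_Ab = 0, V_aB = 0, V_AB = 2)
  )
  if (!class_label %in% names(templates)) {
    stop("unknown class label '", class_label, "'; expected one of ",
         paste(names(templates), collapse = ", "))
  }
  stopifnot(magnitude_scale > 0)
  structure(
    list(values = templates[[class_label]] * magnitude_scale,
         intended_class = if (class_label == "additive") "none" else class_label),
    class = "planted_square"
  )
}

#' Simulate a two-locus panel realizing one planted square
#'
#' Accessions are assigned round-robin to the four haplotypes AA, TA, AT, TT
#' (ab, Ab, aB, AB), guaranteeing each at least `floor(n/4)` members; each
#' accession's phenotype is `baseline + V(haplotype) + noise`. This gives
#' downstream classification a single square with known ground truth and
#' enough replicate accessions per vertex to estimate the noise threshold.
#'
#' @param class_label passed to [plant_square()].
#' @param n_accessions total accessions (>= 12 recommended so every vertex
#'   has >= 3 members).
#' @param magnitude_scale passed to [plant_square()].
#' @param noise_sd accession-level Gaussian noise, phenotype units.
#' @param baseline constant offset; nonzero keeps coefficients of variation
#'   well defined.
#' @param seed integer seed (noise stream only; the assignment is
#'   deterministic).
#' @return a [genotype_panel()] with attribute `"truth"` carrying the planted
#'   square.
#' @export
simulate_square_panel <- function(class_label, n_accessions = 12L,
                                  magnitude_scale = 1, noise_sd = 0,
                                  baseline = 10, seed = 1L) {
  sq <- plant_square(class_label, magnitude_scale)
  haplos <- c("AA", "TA", "AT", "TT")  # ab, Ab, aB, AB
  assign <- rep_len(seq_len(4L), n_accessions)
  geno <- do.call(rbind, strsplit(haplos[assign], ""))
  rownames(geno) <- sprintf("acc_%03d", seq_len(n_accessions))
  colnames(geno) <- c("1:0000100", "1:0000200")
  phen <- baseline + unname(sq$values[assign])
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 500009L))
    phen <- phen + stats::rnorm(n_accessions, 0, noise_sd)
  }
  names(phen) <- rownames(geno)
  panel <- genotype_panel(geno, phen)
  attr(panel, "truth") <- list(square = sq, baseline = baseline,
                               noise_sd = noise_sd, seed = seed)
  panel
}

#' Write a simulated panel plus its ground truth
#'
#' Writes the three canonical TSV tables via [write_panel()] together with a
#' `truth.json` recording planted effects, interactions and the seed.
#'
#' @param panel a simulated [genotype_panel()] (with `"truth"` attribute).
#' @param dir output directory.
#' @param assoc optional association table to include.
#' @return invisibly, the vector of paths written.
#' @export
write_simulated_panel <- function(panel, dir, assoc = NULL) {
  paths <- write_panel(panel, dir, assoc = assoc)
  truth <- attr(panel, "truth")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, truth = truth_path))
}

# internal: derive a stage-specific RNG seed, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L) + as.integer(offset)
}
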