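test_that("select_loci thresholds and orders deterministically", {
  assoc <- data.frame(locus = c("1:30", "1:10", "1:20"),
                      p = c(1e-3, 1e-6, 1e-5))
  expect_equal(select_loci(assoc, 1e-4), c("1:10", "1:20"))
  expect_equal(select_loci(assoc, 1), c("1:10", "1:20", "1:30"))
  expect_equal(select_loci(assoc, 1e-9), character(0))
})

test_that("haplotype strings concatenate alleles in locus order, phenotyped only", {
  geno <- rbind(acc1 = c("A", "C", "G"), acc2 = c("A", "T", "G"),
                acc3 = c("T", "T", "G"))
  colnames(geno) <- c("1:1", "1:2", "1:3")
  panel <- genotype_panel(geno, c(acc1 = 1, acc2 = 2))  # acc3 unphenotyped
  h <- build_haplotypes(panel, c("1:1", "1:2", "1:3"))
  expect_equal(unname(h), c("ACG", "ATG"))
  expect_equal(names(h), c("acc1", "acc2"))
  h1 <- build_haplotypes(panel, "1:2")
  expect_equal(unname(h1), c("C", "T"))
})

test_that("collapsing averages member phenotypes and keeps member lists", {
  strings <- c(a = "AA", b = "AA", c = "AT")
  v <- collapse_haplotypes(strings, c(a = 3, b = 5, c = 4))
  expect_equal(v$haplotype, c("AA", "AT"))
  expect_equal(v$mean_phenotype, c(4, 4))
  expect_equal(v$n_members, c(2L, 1L))
  expect_equal(attr(v, "members")$AA, c("a", "b"))
  # all distinct / all identical degenerate cases
  expect_equal(nrow(collapse_haplotypes(c(x = "A", y = "T"), c(x = 1, y = 2))), 2L)
  one <- collapse_haplotypes(c(x = "A", y = "A"), c(x = 1, y = 2))
  expect_equal(one$mean_phenotype, 1.5)
})

test_that("edges join exactly Hamming-distance-1 pairs", {
  net <- net_from_strings(c("AA", "AT", "TT"))
  el <- igraph::as_edgelist(net$graph)
  expect_equal(nrow(el), 2L)
  expect_false(any(el[, 1L] == "AA" & el[, 2L] == "TT"))
  # Hamming-2 pair: both isolates, empty analysis network
  iso <- net_from_strings(c("AA", "TT"))
  expect_equal(igraph::vcount(iso$graph), 0L)
  expect_setequal(iso$isolates, c("AA", "TT"))
  # two-locus 4-cycle
  cyc <- net_from_strings(c("AA", "AT", "TA", "TT"))
  expect_equal(igraph::ecount(cyc$graph), 4L)
  expect_equal(count_squares(cyc)$total, 1L)
})

test_that("square enumeration matches exhaustive cycle enumeration", {
  k23 <- igraph::make_full_bipartite_graph(2, 3)
  igraph::V(k23)$name <- letters[1:5]
  expect_equal(nrow(find_squares(k23)), 3L)
  cube <- net_from_strings(apply(expand.grid(c("A", "T"), c("A", "T"), c("A", "T")),
                                 1L, paste0, collapse = ""))
  expect_equal(count_squares(cube)$total, 6L)
  # chordal squares count too
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(nrow(find_squares(k4)), 3L)
  # enumerated squares agree with the quadruple-scan oracle as sets
  for (seed in c(2, 3, 4)) {
    strings <- random_strings(seed, n = 14, len = 4)
    net <- net_from_strings(strings)
    g <- net$graph
    sq <- find_squares(g)
    nm <- igraph::V(g)$name
    keys <- vapply(seq_len(nrow(sq)), function(i) {
      d1 <- sort(match(c(sq$v1[i], sq$v3[i]), nm))
      d2 <- sort(match(c(sq$v2[i], sq$v4[i]), nm))
      paste(sort(c(paste(d1, collapse = "-"), paste(d2, collapse = "-"))),
            collapse = "|")
    }, character(1L))
    expect_setequal(keys, oracle_square_sets(g))
    expect_equal(length(keys), length(unique(keys)))
  }
})

test_that("relaxing the cutoff never shrinks string length or genotype count", {
  p <- simulate_panel(simulation_config(n_accessions = 120L, n_causal_loci = 4L,
                                        n_neutral_loci = 30L,
                                        minor_allele_freq = 0.3,
                                        additive_effects = c(1, 1.5, 2, 2.5),
                                        noise_sd = 0.2, seed = 31L))
  a <- compute_association_pvalues(p)
  prev_len <- 0L; prev_uni <- 0L
  for (nl in c(9, 7, 5, 3, 1)) {  # increasingly relaxed
    loci <- select_loci(a, 10^(-nl))
    if (!length(loci)) next
    strings <- build_haplotypes(p, loci)
    expect_gte(length(loci), prev_len)
    expect_gte(length(unique(strings)), prev_uni)
    prev_len <- length(loci); prev_uni <- length(unique(strings))
  }
})

test_that("component partition is a valid connectivity equivalence", {
  strings <- random_strings(77, n = 30, len = 5)
  net <- net_from_strings(strings)
  g <- net$graph
  memb <- igraph::components(g)$membership
  # union-find oracle over the edge list
  parent <- seq_len(igraph::vcount(g))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el))) {
    ri <- find(el[k, 1L]); rj <- find(el[k, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(parent), function(i) as.integer(find(i)), integer(1L))
  expect_equal(length(unique(roots)), length(unique(memb)))
  expect_true(all(tapply(roots, memb, function(r) length(unique(r)) == 1L)))
})

test_that("cutoff sweep prefers square-rich networks with documented tie-breaks", {
  p <- simulate_panel(simulation_config(n_accessions = 250L, n_causal_loci = 4L,
                                        n_neutral_loci = 50L,
                                        minor_allele_freq = 0.4,
                                        additive_effects = c(1, 1.2, 1.4, 1.6),
                                        noise_sd = 0.05, seed = 8L))
  a <- compute_association_pvalues(p)
  sw <- sweep_cutoffs(p, a)
  expect_s3_class(sw, "sweep_result")
  # selection matches a per-cutoff brute-force rebuild
  rebuilt <- lapply(sw$table$cutoff, function(co)
    build_genotype_network(p, a, co))
  best_sq <- vapply(rebuilt, function(n)
    if (is.null(n)) 0L else count_squares(n)$max_per_component, integer(1L))
  expect_equal(sw$table$max_component_squares, best_sq)
  winners <- which(best_sq == max(best_sq))
  expect_true(sw$selected_neglog10 %in% sw$table$neglog10[winners])
  expect_equal(count_squares(sw$network)$max_per_component, max(best_sq))
  # loci count non-increasing with stringency
  expect_true(all(diff(sw$table$n_loci) <= 0))
  # single-value grid selects that value
  sw1 <- sweep_cutoffs(p, a, grid = 5)
  expect_equal(sw1$selected_neglog10, 5)
  # sensitivity cutoffs are +/- 0.5 log units
  expect_equal(unname(sw$sensitivity), sw$selected_neglog10 + c(-0.5, 0.5))
})

test_that("maf_filter drops strictly-below-threshold loci only", {
  geno <- cbind(`1:1` = c(rep("A", 99), "T"),     # maf 0.01 -> dropped
                `1:2` = c(rep("A", 95), rep("T", 5)),  # maf exactly 0.05 -> kept
                `1:3` = c(rep("A", 50), rep("T", 50)))
  rownames(geno) <- sprintf("a%03d", 1:100)
  panel <- genotype_panel(geno, stats::setNames(stats::rnorm(100), rownames(geno)))
  filt <- maf_filter(panel, 0.05)
  expect_setequal(filt$loci, c("1:2", "1:3"))
  expect_identical(maf_filter(panel, 0)$loci, panel$loci)
})

test_that("ld_prune keeps the smallest-P representative of correlated loci", {
  base <- c(rep("A", 30), rep("T", 30))
  geno <- cbind(`1:1` = base, `1:2` = base,       # perfectly correlated pair
                `1:3` = rep(c("A", "T"), 30))     # independent
  rownames(geno) <- sprintf("a%02d", 1:60)
  panel <- genotype_panel(geno, stats::setNames(stats::rnorm(60), rownames(geno)))
  assoc <- data.frame(locus = c("1:1", "1:2", "1:3"), p = c(1e-3, 1e-8, 1e-5))
  pruned <- ld_prune(panel, assoc, 0.95)
  expect_setequal(pruned$loci, c("1:2", "1:3"))  # smaller P of the pair wins
  # independent loci unchanged
  geno2 <- geno[, c("1:1", "1:3")]
  panel2 <- genotype_panel(geno2, panel$phenotype[panel$phenotyped])
  expect_setequal(ld_prune(panel2, assoc[c(1, 3), ], 0.95)$loci, c("1:1", "1:3"))
  # duplicated column removed at threshold 1
  expect_length(ld_prune(panel, assoc, 1)$loci, 2L)
})
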