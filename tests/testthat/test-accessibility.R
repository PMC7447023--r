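test_that("extremum identification handles ties and directions", {
  net <- net_from_strings(c("AA", "AT", "TT"), phen = c(1, 2, 3))
  expect_equal(find_unique_extremum(net, "max")$vertex, "TT")
  expect_equal(find_unique_extremum(net, "min")$vertex, "AA")
  tied <- net_from_strings(c("AA", "AT", "TT"), phen = c(3, 1, 3))
  expect_equal(find_unique_extremum(tied, "max")$status, "ambiguous")
  expect_equal(find_unique_extremum(tied, "min")$vertex, "AT")
})

test_that("shortest-path enumeration is complete", {
  cyc <- net_from_strings(c("AA", "AT", "TA", "TT"), phen = 1:4)
  paths <- enumerate_shortest_paths(cyc, "AA", "TT")
  expect_length(paths, 2L)
  expect_true(all(vapply(paths, length, integer(1L)) == 3L))
  path_graph <- net_from_strings(c("AAA", "AAT", "ATT", "TTT"), phen = 1:4)
  expect_length(enumerate_shortest_paths(path_graph, "AAA", "TTT"), 1L)
  cube <- net_from_strings(apply(expand.grid(c("A", "T"), c("A", "T"), c("A", "T")),
                                 1L, paste0, collapse = ""), phen = 1:8)
  expect_length(enumerate_shortest_paths(cube, "AAA", "TTT"), 6L)
  disc <- net_from_strings(c("AA", "AT", "GG", "GC"), phen = 1:4)
  p <- enumerate_shortest_paths(disc, "AA", "GG")
  expect_length(p, 0L)
  expect_true(attr(p, "no_path"))
})

test_that("path sets match exhaustive DFS on random networks", {
  for (seed in c(11, 12, 13, 14)) {
    net <- net_from_strings(random_strings(seed, n = 25, len = 4),
                            phen = NULL)
    g <- net$graph
    if (igraph::vcount(g) < 2L) next
    nm <- igraph::V(g)$name
    set.seed(seed)
    for (k in 1:3) {
      st <- sample(nm, 2L)
      mine <- enumerate_shortest_paths(net, st[1L], st[2L])
      oracle <- oracle_shortest_paths(g, st[1L], st[2L])
      key <- function(p) paste(p, collapse = ">")
      expect_setequal(vapply(mine, key, character(1L)),
                      vapply(oracle, key, character(1L)))
    }
  }
})

test_that("per-step accessibility honors the delta tolerance", {
  expect_true(is_accessible(c(0, 1, 2), 0, "max"))
  expect_true(is_accessible(c(0, 1, 0.95, 2), 0.1, "max"))   # dip within delta
  expect_false(is_accessible(c(0, -1, 2), 0.5, "max"))       # step -1 < -0.5
  expect_true(is_accessible(c(2, 1, 0), 0, "min"))
  expect_false(is_accessible(c(2, 3, 0), 0.5, "min"))
  # strict mode requires every step to clear delta
  expect_false(is_accessible(c(0, 0.05, 1), 0.1, "max", mode = "strict"))
  expect_true(is_accessible(c(0, 0.2, 1), 0.1, "max", mode = "strict"))
})

test_that("a lone reciprocal-sign square halves accessibility at delta 0", {
  net <- net_from_strings(c("AA", "TA", "AT", "TT"), phen = c(1, 0, 0, 2))
  rep <- accessibility_summary(net, delta = 0, direction = "max")
  expect_equal(rep$status, "ok")
  expect_equal(rep$n_paths, 4L)  # ab contributes 2, each single mutant 1
  expect_equal(rep$fraction_accessible, 0.5)
  per <- rep$per_source
  expect_equal(per["AA", "n_accessible"], 0L)
  expect_equal(per["TA", "n_accessible"], 1L)
  # binned: both length-1 paths accessible, neither length-2 path is
  expect_equal(rep$bins$fraction_accessible[rep$bins$length == 1], 1)
  expect_equal(rep$bins$fraction_accessible[rep$bins$length == 2], 0)
})

test_that("star and monotone landscapes are fully accessible", {
  star <- net_from_strings(c("AAA", "TAA", "ATA", "AAT"), phen = c(5, 1, 2, 3))
  rep <- accessibility_summary(star, 0, "max")
  expect_equal(rep$fraction_accessible, 1)
  expect_equal(rep$mean_path_length, 1)
  # additive noiseless landscape: every path to the additive maximum climbs
  p <- simulate_panel(simulation_config(n_accessions = 150L, n_causal_loci = 3L,
                                        minor_allele_freq = 0.4,
                                        additive_effects = c(1, 2, 4),
                                        noise_sd = 0, seed = 3L))
  net <- build_genotype_network(p, loci = p$loci)
  rep2 <- accessibility_summary(net, 0, "max")
  expect_equal(rep2$fraction_accessible, 1)
})

test_that("increasing delta never closes paths (tolerance monotonicity)", {
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    strings <- random_strings(seed, n = 30, len = 4)
    net <- net_from_strings(strings, phen = stats::rnorm(length(strings)))
    if (igraph::vcount(net$graph) < 3L) next
    ext <- find_unique_extremum(net, "max")
    if (ext$status != "ok") next
    fracs <- vapply(c(0, 0.2, 0.5, 1, 5), function(d)
      accessibility_summary(net, d, "max")$fraction_accessible, numeric(1L))
    expect_true(all(diff(fracs) >= 0), label = paste("seed", seed))
    expect_equal(fracs[length(fracs)], 1)  # delta beyond the range opens all
  }
})

test_that("ambiguous extrema and the path cap are reported, not papered over", {
  tied <- net_from_strings(c("AA", "AT", "TT"), phen = c(3, 1, 3))
  rep <- accessibility_summary(tied, 0, "max")
  expect_equal(rep$status, "ambiguous_extremum")
  expect_true(is.na(rep$fraction_accessible))
  cube <- net_from_strings(apply(expand.grid(rep(list(c("A", "T")), 4L)),
                                 1L, paste0, collapse = ""),
                           phen = c(1:15, 99))
  expect_error(accessibility_summary(cube, 0, "max", max_paths = 5),
               "cap")
})

test_that("all-pairs path length distribution matches the distance matrix", {
  net <- net_from_strings(c("AAA", "AAT", "ATT", "TTT", "TAT"), phen = 1:5)
  lens <- path_length_distribution(net)
  d <- igraph::distances(net$graph)
  expect_equal(sort(lens), sort(as.integer(d[upper.tri(d)][is.finite(d[upper.tri(d)])])))
  expect_equal(length(lens), choose(igraph::vcount(net$graph), 2L))
})
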