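#' Estimate the non-genetic noise threshold delta
#'
#' Accessions that share a haplotype at every phenotype-associated locus are
#' genetically identical there, so phenotypic variation among them is
#' attributed to non-genetic causes (measurement noise, micro-environment).
#' For every vertex with at least `min_members` member accessions the
#' coefficient of variation (sample standard deviation / mean) of member
#' phenotypes is computed; delta is the unweighted mean of these CVs.
#' Vertices whose member mean is zero have an undefined CV and are excluded
#' with a warning. When no vertex qualifies, delta is unavailable and
#' downstream delta-dependent analyses should be skipped for the phenotype.
#'
#' @param network a [build_network()] result carrying member phenotype
#'   values.
#' @param min_members minimum member accessions per contributing vertex
#'   (default 3).
#' @return object of class `noise_estimate`: `delta`, `available`,
#'   `n_contributing`, `fraction_contributing` (of all unique genotypes),
#'   `cvs` (named per-vertex), `n_excluded_zero_mean`.
#' @export
estimate_delta <- function(network, min_members = 3L) {
  stopifnot(inherits(network, "haplo_network"))
  mv <- network$member_values
  sizes <- lengths(mv)
  qualifying <- names(mv)[sizes >= min_members]
  cvs <- numeric(0)
  n_zero <- 0L
  for (h in qualifying) {
    vals <- mv[[h]]
    m <- mean(vals)
    if (m == 0) {
      n_zero <- n_zero + 1L
      next
    }
    cvs[h] <- stats::sd(vals) / m
  }
  if (n_zero > 0L) {
    warning(n_zero, " vertex/vertices with zero mean phenotype excluded from delta")
  }
  available <- length(cvs) > 0L
  structure(
    list(
      delta = if (available) mean(cvs) else NA_real_,
      available = available,
      n_contributing = length(cvs),
      fraction_contributing = length(cvs) / length(mv),
      cvs = cvs,
      n_excluded_zero_mean = n_zero,
      min_members = as.integer(min_members)
    ),
    class = "noise_estimate"
  )
}

#' @export
print.noise_estimate <- function(x, ...) {
  if (x$available) {
    cat(sprintf("<noise_estimate> delta = %.6g from %d vertices (%.1f%% of genotypes)\n",
                x$delta, x$n_contributing, 100 * x$fraction_contributing))
  } else {
    cat("<noise_estimate> delta unavailable (no vertex with enough members)\n")
  }
  invisible(x)
}

#' Optionally rescale delta before comparing to phenotype differences
#'
#' Delta is a coefficient of variation (dimensionless) and, following the
#' source procedure, is compared directly with absolute phenotype
#' differences. `mode = "mean_phenotype"` instead multiplies delta by the
#' mean absolute vertex phenotype of the network, putting the threshold on
#' the phenotype scale; exposed for sensitivity analyses.
#'
#' @param delta numeric delta (CV scale).
#' @param network the network whose phenotype scale is used when rescaling.
#' @param mode `"raw"` (default, literal comparison) or `"mean_phenotype"`.
#' @return numeric threshold on the scale used by comparisons.
#' @export
scale_delta <- function(delta, network = NULL, mode = c("raw", "mean_phenotype")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(delta)
  stopifnot(!is.null(network))
  delta * mean(abs(vertex_values(network)))
}

#' Fraction of network neighbors with identical phenotypes
#'
#' Two neighboring vertices count as phenotypically identical when the
#' absolute difference of their mean phenotypes does not exceed delta.
#'
#' @param network a [build_network()] result or igraph with
#'   `mean_phenotype`.
#' @param delta identity tolerance (>= 0).
#' @return fraction in `[0, 1]`; `NA` with a warning when the network has no
#'   edges.
#' @export
fraction_identical_neighbors <- function(network, delta) {
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0L) {
    warning("network has no edges; identical-neighbor fraction undefined")
    return(NA_real_)
  }
  v <- vertex_values(network)
  el <- igraph::as_edgelist(g)
  mean(abs(v[el[, 1L]] - v[el[, 2L]]) <= delta)
}

#' Orient a square: identify double mutant, wild type and single mutants
#'
#' By convention the vertex with the highest phenotypic value is the double
#' mutant AB; it must be a strict, unique maximum within the square, else the
#' square is skipped (tied maxima make between-square comparisons
#' meaningless). The wild type ab is AB's diagonal partner (the Hamming-2
#' vertex); the remaining two vertices are the single mutants Ab and aB,
#' whose labelling between themselves is arbitrary and does not affect
#' epsilon or the class.
#'
#' @param cycle character vector of 4 vertex names in cycle order
#'   (diagonals = positions 1,3 and 2,4).
#' @param values numeric phenotype values aligned with `cycle`.
#' @return object of class `epi_square` (`haplotypes`, `values` named
#'   `V_ab`, `V_Ab`, `V_aB`, `V_AB`, `positions` = the two varying string
#'   positions when haplotypes are strings), or `NULL` when the maximum is
#'   tied.
#' @export
orient_square <- function(cycle, values) {
  stopifnot(length(cycle) == 4L, length(values) == 4L)
  vmax <- max(values)
  if (sum(values == vmax) > 1L) return(NULL)
  i_AB <- which.max(values)
  i_ab <- (i_AB + 1L) %% 4L + 1L  # diagonal partner in cycle order
  singles <- setdiff(1:4, c(i_AB, i_ab))
  haps <- c(ab = cycle[i_ab], Ab = cycle[singles[1L]],
            aB = cycle[singles[2L]], AB = cycle[i_AB])
  vals <- c(V_ab = values[i_ab], V_Ab = values[singles[1L]],
            V_aB = values[singles[2L]], V_AB = values[i_AB])
  positions <- integer(0)
  if (all(nchar(cycle) == nchar(cycle[1L])) && nchar(cycle[1L]) > 0L) {
    a <- strsplit(haps[["ab"]], "")[[1L]]
    b <- strsplit(haps[["AB"]], "")[[1L]]
    if (length(a) == length(b)) positions <- which(a != b)
  }
  structure(list(haplotypes = haps, values = vals, positions = positions),
            class = "epi_square")
}

#' Classify an oriented square as none / magnitude / simple / reciprocal sign
#'
#' The epistasis magnitude is `epsilon = V_AB + V_ab - V_Ab - V_aB`. If
#' |epsilon| does not exceed delta, the interaction is conservatively called
#' non-epistatic and epsilon is reported as zero. Otherwise, each mutation is
#' examined for a sign change across genetic backgrounds: mutation A changes
#' sign when its two steps (ab->Ab and aB->AB) have strictly opposite signs,
#' mutation B analogously via ab->aB and Ab->AB. A step whose |difference| is
#' within delta has indeterminate sign and never counts as a change. Both
#' mutations changing sign is reciprocal sign epistasis, exactly one is
#' simple sign epistasis, neither is magnitude epistasis.
#'
#' @param square an [orient_square()] result.
#' @param delta noise threshold (>= 0).
#' @return object of class `epistasis_call`: `epsilon` (zeroed when
#'   non-epistatic), `epsilon_raw`, `delta`, `class`, `sign_change_A`,
#'   `sign_change_B`.
#' @export
classify_square <- function(square, delta) {
  stopifnot(inherits(square, "epi_square"), is.numeric(delta), delta >= 0)
  v <- square$values
  eps <- v[["V_AB"]] + v[["V_ab"]] - v[["V_Ab"]] - v[["V_aB"]]
  # floating-point floor: an exactly additive square must classify as none
  # even at delta = 0, so the threshold never drops below machine roundoff
  # on the scale of the four values
  delta <- max(delta, sqrt(.Machine$double.eps) * max(1, abs(v)))
  if (abs(eps) <= delta) {
    return(structure(list(epsilon = 0, epsilon_raw = eps, delta = delta,
                          class = "none", sign_change_A = FALSE,
                          sign_change_B = FALSE),
                     class = "epistasis_call"))
  }
  damp <- function(x) if (abs(x) <= delta) 0 else x  # indeterminate steps
  a1 <- damp(v[["V_Ab"]] - v[["V_ab"]])   # mutation A in background b
  a2 <- damp(v[["V_AB"]] - v[["V_aB"]])   # mutation A in background B
  b1 <- damp(v[["V_aB"]] - v[["V_ab"]])   # mutation B in background a
  b2 <- damp(v[["V_AB"]] - v[["V_Ab"]])   # mutation B in background A
  # strict triangle inequality <=> the two steps point in opposite directions
  change_A <- abs(a1 + a2) < abs(a1) + abs(a2)
  change_B <- abs(b1 + b2) < abs(b1) + abs(b2)
  cls <- if (change_A && change_B) "reciprocal_sign"
         else if (change_A || change_B) "simple_sign"
         else "magnitude"
  structure(list(epsilon = eps, epsilon_raw = eps, delta = delta, class = cls,
                 sign_change_A = change_A, sign_change_B = change_B),
            class = "epistasis_call")
}

#' Enumerate, orient and classify every square of a network
#'
#' @param network a [build_network()] result (or igraph with
#'   `mean_phenotype`).
#' @param delta noise threshold; see [estimate_delta()].
#' @return list: `calls` (data frame, one row per classified square with
#'   haplotypes, values, epsilon and class), `n_skipped_tied_max`,
#'   `n_squares`.
#' @export
classify_squares <- function(network, delta) {
  sq <- find_squares(network)
  vals <- vertex_values(network)
  n_skipped <- 0L
  rows <- vector("list", nrow(sq))
  for (i in seq_len(nrow(sq))) {
    cyc <- c(sq$v1[i], sq$v2[i], sq$v3[i], sq$v4[i])
    oriented <- orient_square(cyc, unname(vals[cyc]))
    if (is.null(oriented)) {
      n_skipped <- n_skipped + 1L
      next
    }
    call <- classify_square(oriented, delta)
    rows[[i]] <- data.frame(
      ab = oriented$haplotypes[["ab"]], Ab = oriented$haplotypes[["Ab"]],
      aB = oriented$haplotypes[["aB"]], AB = oriented$haplotypes[["AB"]],
      V_ab = oriented$values[["V_ab"]], V_Ab = oriented$values[["V_Ab"]],
      V_aB = oriented$values[["V_aB"]], V_AB = oriented$values[["V_AB"]],
      epsilon = call$epsilon, delta = delta, class = call$class,
      sign_change_A = call$sign_change_A, sign_change_B = call$sign_change_B,
      component = sq$component[i], stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ab = character(0), Ab = character(0), aB = character(0),
               AB = character(0), V_ab = numeric(0), V_Ab = numeric(0),
               V_aB = numeric(0), V_AB = numeric(0), epsilon = numeric(0),
               delta = numeric(0), class = character(0),
               sign_change_A = logical(0), sign_change_B = logical(0),
               component = integer(0), stringsAsFactors = FALSE)
  list(calls = calls, n_skipped_tied_max = n_skipped, n_squares = nrow(sq))
}

#' Per-network epistasis tallies
#'
#' Counts and fractions of the four classes over all classified squares, a
#' flag for networks where every classified square is epistatic, and a
#' not-analyzable flag for networks without squares.
#'
#' @param network a [build_network()] result.
#' @param delta numeric threshold, or a [estimate_delta()] result. When delta
#'   is unavailable the summary records status `"delta_unavailable"`.
#' @return list of class `epistasis_summary` with `status`, `counts`,
#'   `fractions`, `n_classified`, `n_skipped_tied_max`, `epistatic_fraction`,
#'   `all_epistatic`, `delta`.
#' @export
summarize_epistasis <- function(network, delta) {
  if (inherits(delta, "noise_estimate")) {
    if (!delta$available) {
      return(structure(list(status = "delta_unavailable", counts = NULL,
                            fractions = NULL, n_classified = 0L,
                            n_skipped_tied_max = 0L,
                            epistatic_fraction = NA_real_,
                            all_epistatic = NA, delta = NA_real_),
                       class = "epistasis_summary"))
    }
    delta <- delta$delta
  }
  res <- classify_squares(network, delta)
  classes <- c("none", "magnitude", "simple_sign", "reciprocal_sign")
  counts <- vapply(classes, function(k) sum(res$calls$class == k), integer(1L))
  n <- nrow(res$calls)
  if (res$n_squares == 0L) {
    status <- "no_squares"
  } else if (n == 0L) {
    status <- "all_squares_tied"
  } else {
    status <- "ok"
  }
  fractions <- if (n > 0L) counts / n else rep(NA_real_, 4L)
  names(fractions) <- classes
  epi_frac <- if (n > 0L) 1 - fractions[["none"]] else NA_real_
  structure(
    list(status = status, counts = counts, fractions = fractions,
         n_classified = n, n_skipped_tied_max = res$n_skipped_tied_max,
         epistatic_fraction = epi_frac,
         all_epistatic = if (n > 0L) counts[["none"]] == 0L else NA,
         delta = delta, calls = res$calls),
    class = "epistasis_summary"
  )
}

#' @export
print.epistasis_summary <- function(x, ...) {
  if (x$status != "ok") {
    cat("<epistasis_summary> status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("<epistasis_summary> %d squares classified (delta = %.4g), %d skipped (tied max)\n",
              x$n_classified, x$delta, x$n_skipped_tied_max))
  for (k in names(x$counts)) {
    cat(sprintf("  %-16s %3d  (%.3f)\n", k, x$counts[[k]], x$fractions[[k]]))
  }
  cat(sprintf("  epistatic fraction %.3f%s\n", x$epistatic_fraction,
              if (isTRUE(x$all_epistatic)) " (all squares epistatic)" else ""))
  invisible(x)
}
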