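# Exact small-sample Mann-Whitney U by full enumeration, and the
# interdependence-aware Monte-Carlo fraction-of-significant-runs procedure.
#
# Rationale for the Monte-Carlo layer: the five serration values measured at
# one vane position of one feather are not independent (neighbouring
# serrations are densely packed), so a test on all 25 values per species-
# position would overstate the evidence.  Each run instead draws one value
# per feather, giving two honest samples of five, and the exact two-sided
# Mann-Whitney p is computed; the fraction of 5000 runs with p < 0.05 is the
# reported summary.

# cache of enumeration matrices: all C(na+nb, na) group-A index sets
.assignment_cache <- new.env(parent = emptyenv())

assignment_matrix <- function(na, nb) {
  key <- paste(na, nb)
  if (!is.null(.assignment_cache[[key]])) return(.assignment_cache[[key]])
  n <- na + nb
  idx <- combn(n, na)
  m <- matrix(0, ncol(idx), n)
  m[cbind(rep(seq_len(ncol(idx)), each = na), as.vector(idx))] <- 1
  .assignment_cache[[key]] <- m
  m
}

#' Exact two-sided Mann-Whitney U test by full enumeration
#'
#' Computes the exact two-sided p-value of the Mann-Whitney U test by
#' enumerating all `choose(na + nb, na)` assignments of the pooled values to
#' the two groups.  Ties are handled by midranks inside the enumeration,
#' making this a permutation-exact test also for tied data.  The p-value is
#' the proportion of assignments whose U deviates from its null mean
#' `na * nb / 2` at least as much as the observed U.
#'
#' @param sample_a,sample_b numeric vectors of finite values (at most 10 per
#'   side; the study design uses 5 and 5).
#' @return Exact two-sided p-value.
#' @export
#' @examples
#' exact_mann_whitney(1:5, 6:10) # 2/252, complete separation
exact_mann_whitney <- function(sample_a, sample_b) {
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b)))
    stop("samples must contain only finite values")
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 1 || nb < 1) stop("both samples must be non-empty")
  if (na > 10 || nb > 10)
    stop("exact enumeration supports at most 10 values per side")
  r <- rank(c(sample_a, sample_b)) # midranks
  m <- assignment_matrix(na, nb)
  center <- na * (na + nb + 1) / 2
  dev <- abs(as.vector(m %*% r) - center)
  obs <- abs(sum(r[seq_len(na)]) - center)
  mean(dev >= obs - 1e-9)
}

#' Monte-Carlo test settings
#'
#' @param n_runs number of Monte-Carlo runs (default 5000).
#' @param alpha significance criterion per run (default 0.05).
#' @param seed integer seed.
#' @return An `mc_settings` list.
#' @export
mc_settings <- function(n_runs = 5000L, alpha = 0.05, seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(n_runs = n_runs, alpha = alpha, seed = as.integer(seed)),
            class = "mc_settings")
}

as_feather_matrix <- function(group, what) {
  if (is.list(group)) {
    lens <- lengths(group)
    if (length(group) == 0 || any(lens == 0))
      stop(what, ": every feather must supply at least one value")
    if (length(unique(lens)) != 1)
      stop(what, ": feathers must supply equally many values")
    group <- do.call(rbind, group)
  }
  group <- as.matrix(group)
  if (nrow(group) == 0 || ncol(group) == 0)
    stop(what, ": empty feather set")
  if (!all(is.finite(group))) stop(what, ": non-finite values")
  group
}

#' Monte-Carlo Mann-Whitney comparison of two groups of feathers
#'
#' Each group supplies one set of serration values per feather (rows of a
#' matrix, or a list of vectors).  In each run, one value is drawn uniformly
#' per feather in each group; the two resulting samples (one value per
#' feather) are compared with [exact_mann_whitney()], and the run counts as
#' significant when p < `alpha`.  The result is the fraction of significant
#' runs with its significance band.
#'
#' @param group_a,group_b per-feather value sets (matrix feathers x
#'   serrations, or list of numeric vectors).
#' @param settings an [mc_settings()] object.
#' @return A one-row data.frame: `fraction_significant`, `band`, `n_runs`.
#' @export
mc_comparison <- function(group_a, group_b, settings = mc_settings()) {
  a <- as_feather_matrix(group_a, "group_a")
  b <- as_feather_matrix(group_b, "group_b")
  nfa <- nrow(a); nfb <- nrow(b)
  nr <- settings$n_runs

  with_local_seed(settings$seed, {
    ia <- matrix(sample.int(ncol(a), nr * nfa, replace = TRUE), nr, nfa)
    ib <- matrix(sample.int(ncol(b), nr * nfb, replace = TRUE), nr, nfb)
    va <- matrix(a[cbind(rep(seq_len(nfa), each = nr), as.vector(ia))], nr, nfa)
    vb <- matrix(b[cbind(rep(seq_len(nfb), each = nr), as.vector(ib))], nr, nfb)
    pooled <- cbind(va, vb)
    ranks <- t(apply(pooled, 1, rank))
    m <- assignment_matrix(nfa, nfb)
    center <- nfa * (nfa + nfb + 1) / 2
    dev <- abs(ranks %*% t(m) - center)          # runs x assignments
    obs <- abs(rowSums(ranks[, seq_len(nfa), drop = FALSE]) - center)
    p <- rowMeans(dev >= obs - 1e-9)
    frac <- mean(p < settings$alpha)
    data.frame(fraction_significant = frac,
               band = significance_band(frac),
               n_runs = nr, stringsAsFactors = FALSE)
  })
}

#' Significance band for a fraction of significant runs
#'
#' `"***"` when the fraction exceeds 0.99, `"**"` when it exceeds 0.95 (but
#' not 0.99), `"*"` when it exceeds 0.67 (but not 0.95), `"ns"` otherwise.
#' Fractions exactly at a band edge fall in the lower band ("more than" is
#' read strictly).
#'
#' @param fraction numeric vector of fractions in \[0, 1\].
#' @return Character vector of bands.
#' @export
significance_band <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  ifelse(fraction > 0.99, "***",
         ifelse(fraction > 0.95, "**",
                ifelse(fraction > 0.67, "*", "ns")))
}

#' Enumerate a species-comparison scheme
#'
#' Builds the list of unordered species pairs (crossed with vane positions)
#' for one of the study's comparison schemes:
#' * `same_activity_diurnal` -- pairs among the 3 diurnal species (6
#'   comparisons over 2 positions);
#' * `same_activity_nocturnal` -- pairs among the 4 nocturnal species (12);
#' * `diff_activity_all` -- every nocturnal-diurnal pair (24);
#' * `diff_activity_diff_size` -- nocturnal-diurnal pairs of unequal size
#'   class (16);
#' * `within_species_positions` -- each species compared between the two
#'   positions.
#'
#' @param species_table data.frame with `species`, `activity`, `size_class`.
#' @param mode one of the modes above.
#' @param positions vane positions to cross with (default `c(0.2, 0.4)`).
#' @return A data.frame of comparisons with attribute `"mode"`. Between-
#'   species modes have columns `species_a`, `species_b`, `position`;
#'   `within_species_positions` has `species`, `position_a`, `position_b`.
#' @export
build_comparison_scheme <- function(species_table,
                                    mode = c("same_activity_diurnal",
                                             "same_activity_nocturnal",
                                             "diff_activity_all",
                                             "diff_activity_diff_size",
                                             "within_species_positions"),
                                    positions = c(0.2, 0.4)) {
  mode <- match.arg(mode)
  st <- species_table
  if (mode == "within_species_positions") {
    if (length(positions) != 2)
      stop("within_species_positions needs exactly two positions")
    out <- data.frame(species = st$species,
                      position_a = positions[1], position_b = positions[2],
                      stringsAsFactors = FALSE)
    attr(out, "mode") <- mode
    return(out)
  }
  pairs <- t(combn(st$species, 2))
  act <- setNames(st$activity, st$species)
  sz <- setNames(st$size_class, st$species)
  keep <- switch(mode,
    same_activity_diurnal =
      act[pairs[, 1]] == "diurnal" & act[pairs[, 2]] == "diurnal",
    same_activity_nocturnal =
      act[pairs[, 1]] == "nocturnal" & act[pairs[, 2]] == "nocturnal",
    diff_activity_all = act[pairs[, 1]] != act[pairs[, 2]],
    diff_activity_diff_size =
      act[pairs[, 1]] != act[pairs[, 2]] & sz[pairs[, 1]] != sz[pairs[, 2]]
  )
  pairs <- pairs[keep, , drop = FALSE]
  # canonical order inside a pair: species_table order, already guaranteed by
  # combn over st$species
  out <- data.frame(
    species_a = rep(pairs[, 1], times = length(positions)),
    species_b = rep(pairs[, 2], times = length(positions)),
    position = rep(positions, each = nrow(pairs)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$species_a, out$species_b, out$position), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

# Extract the feathers x serrations value matrix for one species-position cell
cell_matrix <- function(dataset, species, position, parameter) {
  rows <- dataset$species == species & dataset$position == position
  if (!any(rows))
    stop("no measurements for (", species, ", ", position, ")")
  d <- dataset[rows, c("feather_id", "serration_index", parameter)]
  feathers <- sort(unique(d$feather_id))
  m <- do.call(rbind, lapply(feathers, function(f) {
    v <- d[d$feather_id == f, ]
    v[[parameter]][order(v$serration_index)]
  }))
  m
}

#' Run every comparison of a scheme on a measurement table
#'
#' For each comparison of `scheme`, extracts the per-feather serration value
#' sets of both groups from `dataset` and runs [mc_comparison()].  Each
#' comparison uses an RNG substream derived from `settings$seed` and the
#' comparison's identity, so adding comparisons never perturbs existing
#' results.
#'
#' @param dataset a measurement table as from [generate_dataset()] or
#'   [read_measurements()].
#' @param scheme a scheme from [build_comparison_scheme()].
#' @param parameter one of `"inclination_deg"`, `"tip_displacement_deg"`,
#'   `"length_mm"`.
#' @param settings an [mc_settings()] object.
#' @return The scheme data.frame with `parameter`, `fraction_significant` and
#'   `band` columns appended, one row per comparison.
#' @export
run_all_comparisons <- function(dataset, scheme, parameter,
                                settings = mc_settings()) {
  stopifnot(parameter %in% PARAMETERS)
  mode <- attr(scheme, "mode")
  res <- vector("list", nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    if (identical(mode, "within_species_positions")) {
      sp <- scheme$species[i]
      ga <- cell_matrix(dataset, sp, scheme$position_a[i], parameter)
      gb <- cell_matrix(dataset, sp, scheme$position_b[i], parameter)
      id <- paste(sp, scheme$position_a[i], scheme$position_b[i], parameter,
                  sep = "|")
    } else {
      ga <- cell_matrix(dataset, scheme$species_a[i], scheme$position[i],
                        parameter)
      gb <- cell_matrix(dataset, scheme$species_b[i], scheme$position[i],
                        parameter)
      id <- paste(scheme$species_a[i], scheme$species_b[i],
                  scheme$position[i], parameter, sep = "|")
    }
    sub <- mc_settings(settings$n_runs, settings$alpha,
                       derive_stream_seed(settings$seed, id))
    res[[i]] <- mc_comparison(ga, gb, sub)
  }
  res <- do.call(rbind, res)
  out <- cbind(scheme, parameter = parameter,
               res[, c("fraction_significant", "band")],
               stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  rownames(out) <- NULL
  out
}
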