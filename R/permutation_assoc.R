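# Bin-level permutation association of a query region set with feature sets.

#' Bin-overlap association statistic
#'
#' The statistic is the number of distinct query bins (after
#' [assign_regions_to_bins()]) containing at least one feature region. An
#' alternative region-count statistic (`stat = "regions"`) counts query
#' regions whose bin carries a feature.
#'
#' @param query,features [region_set()]s.
#' @param bins a [make_bins()] universe.
#' @param mode bin-assignment mode passed through.
#' @param stat `"bins"` (default) or `"regions"`.
#' @return integer overlap statistic.
#' @export
overlap_statistic <- function(query, features, bins, mode = "any_overlap",
                              stat = c("bins", "regions")) {
  stat <- match.arg(stat)
  qb <- suppressWarnings(assign_regions_to_bins(query, bins, mode))
  if (nrow(qb) == 0) stopf("empty query set: overlap statistic undefined")
  fb <- unique(suppressWarnings(assign_regions_to_bins(features, bins, mode))$bin)
  if (stat == "bins") return(sum(unique(qb$bin) %in% fb))
  length(unique(qb$region[qb$bin %in% fb]))
}

.perm_null <- function(n_query, feature_bins, universe, n_perm) {
  B <- length(universe)
  infeat <- universe %in% feature_bins
  vapply(seq_len(n_perm), function(i)
    sum(infeat[sample.int(B, n_query)]), 0L)
}

#' Permutation test of query-bin / feature-set association
#'
#' Each iteration resamples `|query bins|` distinct bins uniformly without
#' replacement from the retained universe and recomputes the overlap
#' statistic against the fixed feature set. The empirical p uses the add-one
#' correction `p = (b + 1) / (n_perm + 1)` and is therefore never 0. The
#' reported null mean/sd (and hence z) use the exact hypergeometric moments
#' of the bin-overlap statistic, so z is deterministic given the sets.
#'
#' @param query,features [region_set()]s.
#' @param bins a [make_bins()] universe (1 Mb for the inter-hub analysis).
#' @param n_perm number of permutations (headline default 100,000).
#' @param seed RNG seed (deterministic result).
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @param universe optional restriction of the bin universe (e.g. bins with
#'   nonzero Hi-C coverage); default all retained bins.
#' @param mode bin-assignment mode.
#' @return `permutation_result` list: label, observed, null_mean, null_sd, z,
#'   p, alternative, n_perm, seed, universe_size.
#' @export
permute_association <- function(query, features, bins, n_perm = 1e5,
                                seed = 1L,
                                alternative = c("greater", "less"),
                                universe = NULL, mode = "any_overlap") {
  alternative <- match.arg(alternative)
  if (n_perm < 100) warnf("n_perm < 100: empirical p resolution is poor")
  uni <- universe %||% universe_bins(bins)
  qb <- unique(suppressWarnings(assign_regions_to_bins(query, bins, mode))$bin)
  qb <- qb[qb %in% uni]
  if (length(qb) == 0) stopf("empty query set after bin assignment")
  if (length(qb) > length(uni)) stopf("|query bins| exceeds universe size")
  fb <- unique(suppressWarnings(assign_regions_to_bins(features, bins, mode))$bin)
  obs <- sum(qb %in% fb)
  if (length(qb) == length(uni)) {
    null <- rep(obs, n_perm)
  } else {
    null <- with_seed(seed, .perm_null(length(qb), fb, uni, n_perm))
  }
  b <- if (alternative == "greater") sum(null >= obs) else sum(null <= obs)
  p <- (b + 1) / (n_perm + 1)
  # null moments are exact (hypergeometric: q bins drawn from B with K
  # feature bins), so z is deterministic given the sets; only the empirical
  # p carries Monte-Carlo noise
  B <- length(uni); K <- sum(uni %in% fb); qn <- length(qb)
  nm <- qn * K / B
  ns <- if (B > 1) sqrt(qn * (K / B) * (1 - K / B) * (B - qn) / (B - 1))
        else 0
  structure(list(label = region_label(features), observed = obs,
                 null_mean = nm, null_sd = ns,
                 z = if (is.na(ns) || ns == 0) NA_real_ else (obs - nm) / ns,
                 p = p, alternative = alternative, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), universe_size = length(uni),
                 n_query_bins = length(qb)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s: observed=%d null=%.2f+-%.2f z=%.2f p=%.4g (%s, n_perm=%d)\n",
              x$label, x$observed, x$null_mean, x$null_sd,
              x$z %||% NA, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Associate a query with several feature sets
#'
#' One [permute_association()] per feature set, with per-set seeds derived
#' deterministically as `seed + set index`. Raw per-set p-values are the
#' headline output (significance stars at 0.05 / 0.01); a BH-adjusted column
#' is added for multiplicity.
#'
#' @inheritParams permute_association
#' @param feature_sets named list of [region_set()]s.
#' @return list: `results` (per set), `table` (data.table label, observed,
#'   null_mean, null_sd, z, p_emp, p_bh, stars).
#' @export
associate_all <- function(query, feature_sets, bins, n_perm = 1e5, seed = 1L,
                          alternative = "greater", universe = NULL,
                          mode = "any_overlap") {
  stopifnot(length(feature_sets) >= 1)
  res <- lapply(seq_along(feature_sets), function(i)
    permute_association(query, feature_sets[[i]], bins, n_perm = n_perm,
                        seed = seed + i, alternative = alternative,
                        universe = universe, mode = mode))
  tab <- rbindlist(lapply(res, function(r)
    data.table(label = r$label, observed = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, z = r$z %||% NA_real_, p_emp = r$p)))
  tab[, p_bh := bh_fdr(p_emp)]
  tab[, stars := fifelse(p_emp < 0.01, "**", fifelse(p_emp < 0.05, "*", ""))]
  list(results = res, table = tab[])
}

#' Exhaustive overlap-statistic null on a tiny universe
#'
#' Enumerates all `choose(B, q)` query placements and returns the exact null
#' distribution of the overlap statistic; usable as an oracle for
#' [permute_association()] on universes of at most ~20 bins.
#'
#' @param n_query number of query bins.
#' @param feature_bins bins carrying features.
#' @param universe bin universe.
#' @return data.table (statistic, probability).
#' @export
exhaustive_null <- function(n_query, feature_bins, universe) {
  B <- length(universe)
  if (choose(B, n_query) > 2e6) stopf("universe too large for enumeration")
  combs <- utils::combn(universe, n_query)
  stats <- colSums(matrix(combs %in% feature_bins, nrow = n_query))
  dt <- data.table(statistic = stats)[, .(probability = .N / ncol(combs)),
                                      by = statistic]
  setorder(dt, statistic)
  dt[]
}
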