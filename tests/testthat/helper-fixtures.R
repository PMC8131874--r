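# Shared fixtures, all built in code at test time.

tiny_sizes <- function() chrom_sizes(c("chr1", "chr2"), c(2e6, 1e6))

tiny_bins <- function(w = 1e6) make_bins(tiny_sizes(), w, exclude = character())

# single-chromosome universe of n 1 Mb bins
line_bins <- function(n = 8) {
  make_bins(chrom_sizes("c1", n * 1e6), 1e6, exclude = character())
}

regions_of_bins <- function(bins, idx, label = "regions") {
  r <- bins_to_regions(bins, idx)
  region_set(r$chrom, r$start, r$end, label = label)
}

# two-block checkerboard intra matrix with per-bin biases
checkerboard <- function(n = 60, enrich = 3, bias_sd = 0.3, noise_sd = 0.1,
                         seed = 1) {
  stopifnot(n %% 2 == 0)
  block <- rep(c(1, -1), each = n / 2)
  m <- 1 + (enrich - 1) * (outer(block, block) > 0)
  set.seed(seed)
  m <- m * exp(matrix(rnorm(n * n, 0, noise_sd), n, n))
  m <- (m + t(m)) / 2
  bias <- exp(rnorm(n, 0, bias_sd))
  list(mat = m * outer(bias, bias), block = block)
}

# NB counts with optional planted group effect and batch factor on a feature
# subset; returns a count_matrix plus truth indices
nb_counts <- function(n_feat = 500, mu = 100, phi = 0.1,
                      group = c("EE", "EE", "CTL", "CTL"),
                      batch_mult = NULL, affected = NULL,
                      de_idx = integer(), fold = 1, seed = 1) {
  set.seed(seed)
  S <- length(group)
  Y <- matrix(0L, n_feat, S)
  aff <- affected %||% seq_len(n_feat)
  for (s in seq_len(S)) {
    m <- rep(mu, n_feat)
    if (!is.null(batch_mult)) m[aff] <- m[aff] * batch_mult[s]
    if (group[s] == "EE" && length(de_idx)) m[de_idx] <- m[de_idx] * fold
    Y[, s] <- rnbinom(n_feat, size = 1 / phi, mu = m)
  }
  rownames(Y) <- paste0("f", seq_len(n_feat))
  count_matrix(Y, group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
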