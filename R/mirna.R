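# Batch-robust small-RNA strategy: low-count filter, rpm, batch-wise fold
# changes, reproducible-direction consensus, per-batch z-scores.

#' Filter miRNAs for low read coverage
#'
#' The printed rule "< 50 counts" is applied as mean raw count across samples
#' below `min_count` (boundary inclusive on the keep side); alternative
#' interpretations are exposed via `rule`.
#'
#' @param cm a [count_matrix()] of raw miRNA counts.
#' @param min_count coverage threshold (default 50).
#' @param rule `"mean"` (default), `"total"`, or `"all_samples"` (every
#'   sample must reach `min_count`).
#' @return filtered [count_matrix()] with a `removed` attribute (ids).
#' @export
filter_low_counts <- function(cm, min_count = 50,
                              rule = c("mean", "total", "all_samples")) {
  rule <- match.arg(rule)
  y <- cm$counts
  keep <- switch(rule,
                 mean = rowMeans(y) >= min_count,
                 total = rowSums(y) >= min_count,
                 all_samples = apply(y, 1, min) >= min_count)
  if (!any(keep)) stopf("all miRNAs removed by the count filter")
  out <- count_matrix(y[keep, , drop = FALSE], cm$samples$group,
                      cm$samples$batch, cm$samples$lib_size)
  setattr(out, "removed", rownames(y)[!keep])
  out
}

#' Reads-per-million normalization
#'
#' `rpm = count / column sum * 1e6`; every column of the result sums to 1e6.
#'
#' @param cm a [count_matrix()].
#' @return real matrix.
#' @export
rpm <- function(cm) {
  cs <- colSums(cm$counts)
  if (any(cs == 0)) stopf("zero column sum in rpm normalization")
  sweep(cm$counts, 2, cs, "/") * 1e6
}

#' Batch-wise fold changes, reproducible-direction consensus and z-scores
#'
#' Per batch, the EE vs CTL log2 fold change of mean rpm (with a pseudocount)
#' is computed per feature; the consensus direction is +1/-1 when every batch
#' agrees in sign (and none is exactly 0), `none` otherwise. Per-batch
#' z-scores standardize each feature's log2FC against the distribution over
#' features within that batch; `min_abs_z` is the reported ranking statistic.
#' `retained` requires a consensus (the count filter is applied upstream).
#'
#' @param rpm_mat an [rpm()] matrix (filtered features x samples).
#' @param groups per-sample condition ("EE"/"CTL").
#' @param batches per-sample batch labels; each batch must contain both
#'   conditions.
#' @param pseudocount rpm pseudocount for fold changes (default 1).
#' @return `mirna_result` data.table: id, one `log2FC_<batch>` and
#'   `z_<batch>` column per batch, consensus (+1/-1/0 for none), min_abs_z,
#'   retained.
#' @export
batchwise_consensus <- function(rpm_mat, groups, batches, pseudocount = 1) {
  bs <- unique(batches)
  for (b in bs) {
    g <- groups[batches == b]
    if (!all(c("EE", "CTL") %in% g))
      stopf("batch %s lacks one condition", b)
  }
  res <- data.table(id = rownames(rpm_mat))
  lfc <- matrix(NA_real_, nrow(rpm_mat), length(bs))
  for (i in seq_along(bs)) {
    je <- which(batches == bs[i] & groups == "EE")
    jc <- which(batches == bs[i] & groups == "CTL")
    me <- rowMeans(rpm_mat[, je, drop = FALSE])
    mc <- rowMeans(rpm_mat[, jc, drop = FALSE])
    lfc[, i] <- log2((me + pseudocount) / (mc + pseudocount))
    res[, (paste0("log2FC_", bs[i])) := lfc[, i]]
  }
  z <- scale(lfc)
  for (i in seq_along(bs)) res[, (paste0("z_", bs[i])) := z[, i]]
  sgn <- sign(lfc)
  consensus <- ifelse(apply(sgn, 1, function(s) all(s == 1)), 1L,
                      ifelse(apply(sgn, 1, function(s) all(s == -1)), -1L, 0L))
  res[, consensus := consensus]
  res[, min_abs_z := apply(abs(z), 1, min)]
  res[, retained := consensus != 0L]
  setattr(res, "class", c("mirna_result", class(res)))
  res[]
}

#' One-call small-RNA strategy
#'
#' Chains [filter_low_counts()], [rpm()] and [batchwise_consensus()].
#'
#' @inheritParams filter_low_counts
#' @inheritParams batchwise_consensus
#' @return a `mirna_result` (see [batchwise_consensus()]).
#' @export
mirna_reproducible <- function(cm, min_count = 50, rule = "mean",
                               pseudocount = 1) {
  f <- filter_low_counts(cm, min_count, rule)
  batchwise_consensus(rpm(f), f$samples$group, f$samples$batch, pseudocount)
}
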