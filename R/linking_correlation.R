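# Enhancer/promoter activity fold changes aggregated to linked genes and
# correlated with transcriptomic / proteomic fold changes.

#' Read an enhancer/promoter-to-gene link table
#'
#' TSV with columns region_id, gene_id, class (`enhancer` / `promoter`);
#' many-to-many links allowed.
#'
#' @param path file path.
#' @return data.table, class `link_table`.
#' @export
read_link_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("region_id", "gene_id", "class") %in% names(dt)))
    stopf("link table needs columns region_id, gene_id, class")
  setattr(dt, "class", c("link_table", class(dt)))
  dt[]
}

#' Aggregate region activity fold changes to target genes
#'
#' Order of operations (fixed): within each condition, RPKM is averaged over
#' samples per region, then averaged over the regions linked to each gene;
#' the gene-level log2 fold change is `log2((EE + pc) / (CTL + pc))`.
#' Averaging precedes the fold change (average-then-FC).
#'
#' @param rpkm_ee,rpkm_ctl region x sample RPKM matrices (rownames =
#'   region ids).
#' @param links a [read_link_table()] table (or data.table with region_id,
#'   gene_id).
#' @param pseudocount RPKM pseudocount (default 0.25).
#' @return data.table (gene_id, n_regions, log2FC); attribute `skipped`
#'   lists link rows whose region is absent from the matrices.
#' @export
aggregate_fc_by_gene <- function(rpkm_ee, rpkm_ctl, links,
                                 pseudocount = 0.25) {
  lk <- as.data.table(links)
  known <- lk$region_id %in% rownames(rpkm_ee) &
           lk$region_id %in% rownames(rpkm_ctl)
  skipped <- lk[!known]
  if (nrow(skipped) > 0)
    warnf("%d link(s) with unknown region id skipped", nrow(skipped))
  lk <- lk[known]
  if (nrow(lk) == 0) stopf("no resolvable links")
  me <- rowMeans(rpkm_ee)[lk$region_id]
  mc <- rowMeans(rpkm_ctl)[lk$region_id]
  agg <- data.table(gene_id = lk$gene_id, ee = me, ctl = mc)[
    , .(n_regions = .N, ee = mean(ee), ctl = mean(ctl)), by = gene_id]
  agg[, log2FC := log2((ee + pseudocount) / (ctl + pseudocount))]
  out <- agg[, .(gene_id, n_regions, log2FC)]
  setattr(out, "skipped", skipped)
  out[]
}

#' Correlate region-derived gene fold changes with target fold changes
#'
#' Pearson and Spearman coefficients are both computed on the gene-id
#' intersection; the headline method is Pearson for transcript targets and
#' Spearman for protein targets (rank-based, robust to the iTRAQ fold-change
#' scale and its outliers).
#'
#' @param gene_fc data.table (gene_id, log2FC) from
#'   [aggregate_fc_by_gene()].
#' @param target_fc data.table (gene_id, log2FC) of DE genes or proteins.
#' @param target_type `"transcript"` or `"protein"` (selects the headline
#'   method).
#' @param label mark label carried into the result.
#' @return `link_cor_result` list: label, target_type, n_genes, pearson_r,
#'   pearson_p, spearman_rho, spearman_p, headline (method name), headline_r.
#' @export
correlate_fc <- function(gene_fc, target_fc,
                         target_type = c("transcript", "protein"),
                         label = "mark") {
  target_type <- match.arg(target_type)
  a <- as.data.table(gene_fc)[, .(gene_id, x = log2FC)]
  b <- as.data.table(target_fc)[, .(gene_id, y = log2FC)]
  m <- merge(a, b, by = "gene_id")
  if (nrow(m) < 3) stopf("fewer than 3 genes in common")
  if (sd(m$x) == 0 || sd(m$y) == 0) stopf("zero-variance fold-change vector")
  pe <- cor.test(m$x, m$y, method = "pearson")
  sp <- suppressWarnings(cor.test(m$x, m$y, method = "spearman"))
  headline <- if (target_type == "protein") "spearman" else "pearson"
  structure(list(label = label, target_type = target_type, n_genes = nrow(m),
                 pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 headline = headline,
                 headline_r = if (headline == "pearson")
                   unname(pe$estimate) else unname(sp$estimate)),
            class = "link_cor_result")
}

#' @export
print.link_cor_result <- function(x, ...) {
  cat(sprintf("%s (%s targets, n=%d): Pearson r=%.3f (p=%.3g), Spearman rho=%.3f (p=%.3g) [headline: %s]\n",
              x$label, x$target_type, x$n_genes, x$pearson_r, x$pearson_p,
              x$spearman_rho, x$spearman_p, x$headline))
  invisible(x)
}
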