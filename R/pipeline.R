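# Orchestration: synthetic dataset emission, end-to-end run, run summary.

.write_matrix <- function(m, path) {
  dt <- data.table(id = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

.read_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Emit a complete synthetic dataset plus truth sidecars
#'
#' Writes every input [run_all()] consumes: per-sample valid-pairs files and
#' chrom.sizes, differential mark-region BEDs (one hub-clustered, one
#' background set), 1 Mb mark-coverage counts, the protein ratio table,
#' miRNA counts, the link/RPKM/gene-FC tables, JSON truth sidecars, and a
#' ready-to-run `config.json`.
#'
#' @param dir output directory.
#' @param cfg a [sim_config()]; pass `null = TRUE` for a no-signal dataset.
#' @param seed master seed; per-generator seeds are derived by fixed offsets.
#' @param null disable all planted signal (fold 1, p_in_hub 0, rho 0).
#' @param force overwrite an existing directory.
#' @return the config (list) with a `path` attribute, invisibly usable by
#'   [run_all()].
#' @export
simulate_dataset <- function(dir, cfg = sim_config(), seed = cfg$seed,
                             null = FALSE, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stopf("directory %s exists; use force = TRUE to overwrite", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (null) {
    cfg$hub_fold <- 1; cfg$p_in_hub <- 0; cfg$rho <- 0
  }
  hic <- simulate_hic(cfg, file.path(dir, "hic"), seed = seed)
  bins_e <- make_bins(load_chrom_sizes(hic$chrom_sizes), cfg$w_inter,
                      exclude = character())
  marks_hub <- simulate_mark_regions(hic$truth$hub_bins, bins_e,
                                     n_regions = cfg$n_regions,
                                     p_in_hub = cfg$p_in_hub,
                                     seed = seed + 11L, label = "mark_hub")
  marks_bg <- simulate_mark_regions(hic$truth$hub_bins, bins_e,
                                    n_regions = cfg$n_regions,
                                    p_in_hub = 0, seed = seed + 12L,
                                    label = "mark_bg")
  write_bed(marks_hub, file.path(dir, "mark_hub.bed"))
  write_bed(marks_bg, file.path(dir, "mark_bg.bed"))
  bc <- simulate_mark_bin_counts(hic$truth$hub_bins, bins_e, cfg,
                                 fold = if (null) 1 else 2.5,
                                 seed = seed + 13L)
  write_count_matrix(bc, file.path(dir, "mark_bins.counts.tsv"))
  pr <- simulate_proteomics(cfg, seed = seed + 14L)
  fwrite(pr$table, file.path(dir, "protein_ratios.tsv"), sep = "\t")
  write_sim_truth(pr$truth, file.path(dir, "protein_truth.json"))
  mi <- simulate_mirna(cfg, seed = seed + 15L)
  write_count_matrix(mi$cm, file.path(dir, "mirna.counts.tsv"))
  write_sim_truth(mi$truth, file.path(dir, "mirna_truth.json"))
  lk <- simulate_links_expression(cfg, seed = seed + 16L)
  fwrite(lk$links, file.path(dir, "links.tsv"), sep = "\t")
  .write_matrix(lk$rpkm_ee, file.path(dir, "region_rpkm_EE.tsv"))
  .write_matrix(lk$rpkm_ctl, file.path(dir, "region_rpkm_CTL.tsv"))
  fwrite(lk$gene_fc, file.path(dir, "gene_fc.tsv"), sep = "\t")
  write_sim_truth(lk$truth, file.path(dir, "links_truth.json"))
  smp <- hic$samples
  config <- list(
    chrom_sizes = hic$chrom_sizes,
    samples = lapply(seq_len(nrow(smp)), function(i)
      list(sample = smp$sample[i], group = smp$group[i],
           batch = smp$batch[i], pairs = unname(hic$pairs_files[i]))),
    feature_beds = list(mark_hub = file.path(dir, "mark_hub.bed"),
                        mark_bg = file.path(dir, "mark_bg.bed")),
    mark_bin_counts = file.path(dir, "mark_bins.counts.tsv"),
    ratio_table = file.path(dir, "protein_ratios.tsv"),
    mirna_counts = file.path(dir, "mirna.counts.tsv"),
    links = list(links = file.path(dir, "links.tsv"),
                 rpkm_ee = file.path(dir, "region_rpkm_EE.tsv"),
                 rpkm_ctl = file.path(dir, "region_rpkm_CTL.tsv"),
                 gene_fc = file.path(dir, "gene_fc.tsv")),
    params = list(w_intra = cfg$w_intra, w_inter = cfg$w_inter,
                  exclude = character(), fdr_contacts = 0.05,
                  fdr_intersect = 0.1, n_perm = 1e5, delta_tol = 0.1,
                  mirna_min_count = 50, k_ruv = 1),
    seed = as.integer(seed),
    out_dir = file.path(dir, "out"))
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(config, "path") <- file.path(dir, "config.json")
  invisible(config)
}

.default_params <- function(p) {
  def <- list(w_intra = 1e5, w_inter = 1e6,
              exclude = c("chrX", "chrY", "chrM"), fdr_contacts = 0.05,
              fdr_intersect = 0.1, n_perm = 1e5, delta_tol = 0.1,
              mirna_min_count = 50, k_ruv = 1)
  def[names(p)] <- p
  def
}

#' Run the full pipeline on a config
#'
#' Stage order: bin + filter contacts, differential contacts (intra, inter),
#' differential 1 Mb mark bins, permutation association of differential
#' inter bins against each feature BED, delta selection, miRNA consensus,
#' linking correlation, summary. Stages whose optional inputs are absent are
#' skipped; a stage error is recorded and dependent stages skipped while
#' independent stages still run. All outputs land in `out_dir` as TSV, plus
#' a `run_summary.json` with md5 checksums of every output for determinism
#' audits.
#'
#' @param config a config list (see [simulate_dataset()]) or path to a
#'   config JSON.
#' @return the run summary (list), invisibly; also written as JSON.
#' @export
run_all <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  par <- .default_params(config$params %||% list())
  out_dir <- config$out_dir %||% "hubdiff_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- list()
  outputs <- character()
  note <- function(name, status, info = NULL)
    stages[[name]] <<- list(status = status, info = info)
  emit <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }
  sizes <- load_chrom_sizes(config$chrom_sizes)
  bins_e <- make_bins(sizes, par$w_inter, exclude = par$exclude)
  inc_bins <- NULL

  # --- contacts ------------------------------------------------------------
  diff_ok <- FALSE
  if (!is.null(config$samples)) {
    res <- try({
      singles <- lapply(config$samples, function(s) {
        bin_contacts(parse_valid_pairs(s$pairs), sizes,
                     w_intra = par$w_intra, w_inter = par$w_inter,
                     exclude = par$exclude, sample_name = s$sample)
      })
      grp <- vapply(config$samples, `[[`, "", "group")
      bt <- vapply(config$samples, function(s) s$batch %||% "b1", "")
      bins_a <- make_bins(sizes, par$w_intra, exclude = par$exclude)
      intra <- filter_contacts(
        merge_contact_tables(lapply(singles, `[[`, "intra"), grp, bt),
        bins_a, min_total = 0)
      inter <- filter_contacts(
        merge_contact_tables(lapply(singles, `[[`, "inter"), grp, bt),
        bins_e, min_total = 0)
      emit(intra, "contacts_intra.tsv", write_contact_table)
      emit(inter, "contacts_inter.tsv", write_contact_table)
      da <- diff_contact_analysis(intra, k = par$k_ruv,
                                  fdr = par$fdr_contacts)
      de <- diff_contact_analysis(inter, k = par$k_ruv,
                                  fdr = par$fdr_contacts)
      emit(da$result, "diff_intra.tsv", write_diff_result)
      emit(de$result, "diff_inter.tsv", write_diff_result)
      inc_bins <- sort(unique(c(de$increased$bin1, de$increased$bin2)))
      note("contacts", "ok",
           list(intra_tested = nrow(da$result), inter_tested = nrow(de$result),
                intra_called = nrow(da$increased) + nrow(da$decreased),
                inter_increased = nrow(de$increased),
                inter_decreased = nrow(de$decreased)))
      diff_ok <- TRUE
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note("contacts", "error", conditionMessage(attr(res, "condition")))
  } else note("contacts", "skipped")

  # --- differential 1 Mb mark bins ----------------------------------------
  if (!is.null(config$mark_bin_counts)) {
    res <- try({
      cmb <- read_count_matrix(config$mark_bin_counts)
      mb <- diff_mark_bins(cmb, bins_e, fdr = par$fdr_contacts)
      emit(mb$result, "diff_mark_bins.tsv", write_diff_result)
      emit(mb$up, "mark_bins_up.bed", write_bed)
      emit(mb$down, "mark_bins_down.bed", write_bed)
      note("mark_bins", "ok",
           list(tested = nrow(mb$result), up = nrow(mb$up),
                down = nrow(mb$down)))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note("mark_bins", "error", conditionMessage(attr(res, "condition")))
  } else note("mark_bins", "skipped")

  # --- permutation association --------------------------------------------
  if (diff_ok && length(inc_bins) > 0 && length(config$feature_beds) > 0) {
    res <- try({
      qreg <- bins_to_regions(bins_e, inc_bins)
      query <- region_set(qreg$chrom, qreg$start, qreg$end,
                          label = "diff_inter_bins")
      feats <- lapply(config$feature_beds, read_bed)
      for (i in seq_along(feats))
        setattr(feats[[i]], "label", names(config$feature_beds)[i])
      aa <- associate_all(query, feats, bins_e, n_perm = par$n_perm,
                          seed = seed + 100L)
      emit(aa$table, "association.tsv",
           function(o, p) fwrite(o, p, sep = "\t"))
      note("association", "ok", list(n_sets = nrow(aa$table)))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note("association", "error", conditionMessage(attr(res, "condition")))
  } else note("association", "skipped")

  # --- proteomic delta -----------------------------------------------------
  if (!is.null(config$ratio_table)) {
    res <- try({
      del <- compute_delta(read_ratio_table(config$ratio_table))
      sel <- select_consistent(del, tolerance = par$delta_tol)
      emit(del[, .(id, phi, beta, delta,
                   consistent = id %in% sel$consistent$id)],
           "delta.tsv", function(o, p) fwrite(o, p, sep = "\t"))
      note("delta", "ok", as.list(sel$summary))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note("delta", "error", conditionMessage(attr(res, "condition")))
  } else note("delta", "skipped")

  # --- miRNA ---------------------------------------------------------------
  if (!is.null(config$mirna_counts)) {
    res <- try({
      cmm <- read_count_matrix(config$mirna_counts)
      mr <- mirna_reproducible(cmm, min_count = par$mirna_min_count)
      emit(mr, "mirna.tsv", function(o, p) fwrite(o, p, sep = "\t"))
      note("mirna", "ok", list(tested = nrow(mr),
                               retained = sum(mr$retained)))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note("mirna", "error", conditionMessage(attr(res, "condition")))
  } else note("mirna", "skipped")

  # --- linking correlation -------------------------------------------------
  if (!is.null(config$links)) {
    res <- try({
      lk <- config$links
      links <- read_link_table(lk$links)
      gfc <- aggregate_fc_by_gene(.read_matrix(lk$rpkm_ee),
                                  .read_matrix(lk$rpkm_ctl), links)
      target <- fread(lk$gene_fc, sep = "\t", header = TRUE)
      cc <- correlate_fc(gfc, target, target_type = "transcript",
                         label = "all_links")
      emit(data.table(label = cc$label, n_genes = cc$n_genes,
                      pearson_r = cc$pearson_r, pearson_p = cc$pearson_p,
                      spearman_rho = cc$spearman_rho,
                      spearman_p = cc$spearman_p),
           "link_correlation.tsv", function(o, p) fwrite(o, p, sep = "\t"))
      note("linkcor", "ok", list(n_genes = cc$n_genes,
                                 pearson_r = cc$pearson_r))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note("linkcor", "error", conditionMessage(attr(res, "condition")))
  } else note("linkcor", "skipped")

  checksums <- as.list(tools::md5sum(outputs))
  names(checksums) <- basename(names(checksums))
  summary <- list(package_version = as.character(
    utils::packageVersion("hubdiff")),
    seed = seed, params = par, stages = stages, checksums = checksums)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  n_err <- sum(vapply(stages, function(s) s$status == "error", TRUE))
  attr(summary, "n_errors") <- n_err
  invisible(summary)
}
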