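# Synthetic inputs with planted ground truth: Hi-C contact counts with an
# inter-chromosomal hub and sample batch factors, clustered differential mark
# regions, two-contrast protein ratios, batch-confounded miRNA counts, and
# linked enhancer/gene fold changes.

#' Simulation configuration
#'
#' Defaults encode the stated world of the pipeline's desk-scale tests: a toy
#' genome of 8 chromosomes x 20 Mb (the hub is planted between synthetic
#' chromosomes "chr7s" and "chr17s"), 2 EE + 2 CTL replicates, 100 kb intra /
#' 1 Mb inter bin widths, negative-binomial counts parameterized by mean mu
#' and dispersion phi with variance `mu + phi * mu^2`, a fold-2 hub of 30
#' inter bin-pairs, and a multiplicative per-sample batch factor on the
#' log-linear scale. See the methods vignette for the power rationale behind
#' the unstated defaults (mu0_inter, phi_nb, batch_sd).
#'
#' @param ... overrides of any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chroms = c(paste0("chr", 1:6, "s"), "chr7s", "chr17s"),
    chrom_length = 20e6,
    w_intra = 1e5, w_inter = 1e6,
    n_ee = 2, n_ctl = 2,
    mu0_intra = 20, alpha = 1,        # intra decay: mu0 * (1 + d)^(-alpha)
    mu0_inter = 100, phi_nb = 0.01,
    hub_fold = 2, n_hub_pairs = 30, hub_chroms = c("chr7s", "chr17s"),
    n_intra_diff = 20,
    batch_sd = 0.3,
    n_proteins = 1000, frac_consistent = 0.6, protein_noise_sd = 0.04,
    n_mirna = 600, n_mirna_batches = 2, frac_reproducible = 0.3,
    mirna_mu = 200, mirna_phi = 0.05, mirna_effect = 1.5,
    n_genes = 500, rho = 0.6, link_noise_sd = 0.05,
    n_regions = 200, p_in_hub = 0.8,
    batch_loading = "per_sample",   # or "per_pair" (feature-specific loadings)
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown sim_config field: %s", unknown[1])
  cfg[names(ov)] <- ov
  if (cfg$hub_fold <= 0) stopf("hub_fold must be > 0")
  for (f in c("frac_consistent", "frac_reproducible", "p_in_hub"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must lie in [0, 1]", f)
  structure(cfg, class = "sim_config")
}

sim_chrom_sizes <- function(cfg)
  chrom_sizes(cfg$chroms, rep(cfg$chrom_length, length(cfg$chroms)))

.sim_samples <- function(cfg) {
  nm <- c(paste0("EE", seq_len(cfg$n_ee)), paste0("CTL", seq_len(cfg$n_ctl)))
  grp <- rep(c("EE", "CTL"), c(cfg$n_ee, cfg$n_ctl))
  bt <- paste0("b", c(seq_len(cfg$n_ee), seq_len(cfg$n_ctl)))
  score <- cfg$batch_sd * ifelse(bt == "b1", 1, -1)
  data.table(sample = nm, group = grp, batch = bt, batch_score = score)
}

#' Simulate binned Hi-C contact counts with a planted hub
#'
#' The in-memory core of the Hi-C generator. Intra-chromosomal bin-pair
#' counts are NB with mean `mu0_intra * (1 + d)^(-alpha)` at bin distance d;
#' inter-chromosomal pairs NB with mean `mu0_inter`. The planted hub pairs
#' (between the two hub chromosomes) have their mean multiplied by
#' `hub_fold` in EE samples only, as do the planted intra pairs. A
#' multiplicative batch factor `exp(b_s * u)` is applied per sample, with
#' per-sample score `b_s` (+-batch_sd by batch) and a single standard-normal
#' loading `u`; with `batch_loading = "per_pair"` the loading instead varies
#' per bin-pair (`u_p ~ N(0,1)`), a harsher batch structure that library
#' offsets cannot absorb.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @param classes which tables to generate (`"intra"`, `"inter"` or both).
#' @return list: `intra`, `inter` (multi-sample `contact_table`s or NULL),
#'   `truth` (class `sim_truth`): hub_pairs, intra_pairs, hub_bins, batch,
#'   seed.
#' @export
simulate_hic_counts <- function(cfg = sim_config(), seed = cfg$seed,
                                classes = c("intra", "inter")) {
  sizes <- sim_chrom_sizes(cfg)
  smp <- .sim_samples(cfg)
  S <- nrow(smp)
  is_ee <- smp$group == "EE"
  per_pair <- identical(cfg$batch_loading, "per_pair")
  with_seed(seed, {
    inter <- NULL; intra <- NULL
    hub_pairs <- data.table(bin1 = integer(), bin2 = integer())
    intra_pairs <- data.table(bin1 = integer(), bin2 = integer())
    u_glob <- rnorm(1)
    if ("inter" %in% classes) {
      be <- make_bins(sizes, cfg$w_inter, exclude = character())
      b <- be$bins
      pr <- CJ(bin1 = b$bin, bin2 = b$bin)[bin1 < bin2]
      ch <- b$chrom[match(pr$bin1, b$bin)]
      ch2 <- b$chrom[match(pr$bin2, b$bin)]
      pr <- pr[ch != ch2]
      c1 <- b$chrom[match(pr$bin1, b$bin)]
      c2 <- b$chrom[match(pr$bin2, b$bin)]
      hubable <- which((c1 == cfg$hub_chroms[1] & c2 == cfg$hub_chroms[2]) |
                       (c1 == cfg$hub_chroms[2] & c2 == cfg$hub_chroms[1]))
      if (cfg$n_hub_pairs > length(hubable))
        stopf("n_hub_pairs exceeds available hub-chromosome pairs")
      hub_idx <- sort(sample(hubable, cfg$n_hub_pairs))
      hub_pairs <- pr[hub_idx]
      u <- if (per_pair) rnorm(nrow(pr)) else rep(u_glob, nrow(pr))
      base <- log(cfg$mu0_inter)
      if (cfg$mu0_inter * cfg$hub_fold < 1)
        warnf("expected hub mean < 1 read; detection power will be ~0")
      Y <- matrix(0L, nrow(pr), S)
      for (s in seq_len(S)) {
        lmu <- base + u * smp$batch_score[s]
        if (is_ee[s]) lmu[hub_idx] <- lmu[hub_idx] + log(cfg$hub_fold)
        Y[, s] <- rnbinom(nrow(pr), size = 1 / max(cfg$phi_nb, 1e-12),
                          mu = exp(lmu))
      }
      dt <- copy(pr)
      for (s in seq_len(S)) set(dt, j = smp$sample[s], value = Y[, s])
      inter <- new_contact_table(dt, "inter", cfg$w_inter,
                                 .sample_table(smp$sample, smp$group,
                                               smp$batch))
    }
    if ("intra" %in% classes) {
      ba <- make_bins(sizes, cfg$w_intra, exclude = character())
      b <- ba$bins
      pl <- b[, {
        n <- .N; lo <- min(bin)
        idx <- CJ(i = 0:(n - 1), j = 0:(n - 1))[i <= j]
        .(bin1 = lo + idx$i, bin2 = lo + idx$j)
      }, by = chrom][, .(bin1, bin2)]
      d <- pl$bin2 - pl$bin1
      mu <- cfg$mu0_intra * (1 + d)^(-cfg$alpha)
      elig <- which(d >= 1 & d <= 10)
      ii <- sort(sample(elig, min(cfg$n_intra_diff, length(elig))))
      intra_pairs <- pl[ii]
      u <- if (per_pair) rnorm(nrow(pl)) else rep(u_glob, nrow(pl))
      Y <- matrix(0L, nrow(pl), S)
      for (s in seq_len(S)) {
        lmu <- log(mu) + u * smp$batch_score[s]
        if (is_ee[s]) lmu[ii] <- lmu[ii] + log(cfg$hub_fold)
        Y[, s] <- rnbinom(nrow(pl), size = 1 / max(cfg$phi_nb, 1e-12),
                          mu = exp(lmu))
      }
      dt <- copy(pl)
      for (s in seq_len(S)) set(dt, j = smp$sample[s], value = Y[, s])
      keep <- rowSums(as.matrix(dt[, smp$sample, with = FALSE])) > 0 |
        seq_len(nrow(dt)) %in% ii
      intra <- new_contact_table(dt[keep], "intra", cfg$w_intra,
                                 .sample_table(smp$sample, smp$group,
                                               smp$batch))
    }
    be1 <- make_bins(sizes, cfg$w_inter, exclude = character())
    truth <- structure(list(hub_pairs = hub_pairs, intra_pairs = intra_pairs,
                            hub_bins = sort(unique(c(hub_pairs$bin1,
                                                     hub_pairs$bin2))),
                            batch = smp, batch_u = u_glob,
                            seed = as.integer(seed)),
                       class = "sim_truth")
    list(intra = intra, inter = inter, truth = truth, sizes = sizes,
         bins_inter = be1)
  })
}

#' Simulate Hi-C valid-pairs files
#'
#' Materializes [simulate_hic_counts()] as one HiC-Pro-style valid-pairs TSV
#' per sample (1-based positions uniform within bins) plus a chrom.sizes
#' file and a JSON truth sidecar. Deterministic: a fixed seed yields
#' byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @param seed RNG seed.
#' @return list: `pairs_files` (named by sample), `chrom_sizes` path,
#'   `truth` (and its `truth_file`), `samples`.
#' @export
simulate_hic <- function(cfg = sim_config(), dir, seed = cfg$seed) {
  sim <- simulate_hic_counts(cfg, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smp <- sim$truth$batch
  sizes_path <- file.path(dir, "genome.chrom.sizes")
  write_chrom_sizes(sim$sizes, sizes_path)
  ba <- make_bins(sim$sizes, cfg$w_intra, exclude = character())
  be <- make_bins(sim$sizes, cfg$w_inter, exclude = character())
  files <- setNames(file.path(dir, paste0(smp$sample, ".validPairs")),
                    smp$sample)
  with_seed(seed + 104729L, {
    for (s in smp$sample) {
      parts <- list()
      for (tab in list(sim$intra, sim$inter)) {
        if (is.null(tab)) next
        bb <- if (attr(tab, "contact_class") == "intra") ba else be
        dt <- as.data.table(tab)[get(s) > 0]
        if (nrow(dt) == 0) next
        cnt <- dt[[s]]
        r1 <- bins_to_regions(bb, rep(dt$bin1, cnt))
        r2 <- bins_to_regions(bb, rep(dt$bin2, cnt))
        n <- nrow(r1)
        parts[[length(parts) + 1]] <- data.table(
          chrom1 = r1$chrom,
          pos1 = r1$start + floor(runif(n) * (r1$end - r1$start)) + 1,
          chrom2 = r2$chrom,
          pos2 = r2$start + floor(runif(n) * (r2$end - r2$start)) + 1)
      }
      out <- rbindlist(parts)
      out[, read_id := paste0(s, "_r", seq_len(.N))]
      fwrite(out[, .(read_id, chrom1, pos1, strand1 = "+", chrom2, pos2,
                     strand2 = "-")],
             files[[s]], sep = "\t", col.names = FALSE, scipen = 50L)
    }
  })
  truth_file <- file.path(dir, "hic_truth.json")
  write_sim_truth(sim$truth, truth_file)
  list(pairs_files = files, chrom_sizes = sizes_path, truth = sim$truth,
       truth_file = truth_file, samples = smp)
}

#' Simulate differential mark regions clustered in hub bins
#'
#' Each region is placed inside a hub-participating 1 Mb bin with probability
#' `p_in_hub`, otherwise uniformly among non-hub bins; lengths are uniform in
#' 1-50 kb.
#'
#' @param hub_bins integer global bin indices of hub bins (e.g.
#'   `truth$hub_bins`).
#' @param bins the [make_bins()] universe at the inter width.
#' @param n_regions number of regions.
#' @param p_in_hub probability of hub placement.
#' @param seed RNG seed.
#' @param label region-set label.
#' @return a [region_set()].
#' @export
simulate_mark_regions <- function(hub_bins, bins, n_regions = 200,
                                  p_in_hub = 0.8, seed = 1L,
                                  label = "mark_regions") {
  if (p_in_hub < 0 || p_in_hub > 1) stopf("p_in_hub must lie in [0, 1]")
  if (p_in_hub > 0 && length(hub_bins) == 0)
    stopf("no hub bins available but p_in_hub > 0")
  if (n_regions == 0)
    return(region_set(character(), numeric(), numeric(), label = label))
  uni <- universe_bins(bins)
  nonhub <- setdiff(uni, hub_bins)
  with_seed(seed, {
    inhub <- runif(n_regions) < p_in_hub
    pick <- integer(n_regions)
    pick[inhub] <- sample(rep(hub_bins, 2), sum(inhub), replace = TRUE)
    pick[!inhub] <- sample(rep(nonhub, 2), sum(!inhub), replace = TRUE)
    reg <- bins_to_regions(bins, pick)
    len <- floor(runif(n_regions, 1e3, 5e4))
    len <- pmin(len, reg$end - reg$start)
    start <- reg$start + floor(runif(n_regions) * (reg$end - reg$start - len))
    region_set(reg$chrom, start, start + len,
               name = paste0("reg", seq_len(n_regions)), label = label)
  })
}

#' Simulate a two-contrast protein ratio table
#'
#' Consistent proteins satisfy `log(phi) = log(beta) + eps` with small
#' Gaussian eps (so that `|phi/beta - 1| <= 0.1` with probability >= 0.95 at
#' the default sd); discrepant proteins get a log-delta offset of at least
#' 0.18, guaranteeing `|delta - 1| > 0.1`.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list: `table` (id, phi, beta), `truth` (consistent protein ids).
#' @export
simulate_proteomics <- function(cfg = sim_config(), seed = cfg$seed) {
  n <- cfg$n_proteins
  if (n == 0)
    return(list(table = data.table(id = character(), phi = numeric(),
                                   beta = numeric()),
                truth = list(consistent_proteins = character())))
  with_seed(seed, {
    id <- sprintf("prot%04d", seq_len(n))
    cons <- runif(n) < cfg$frac_consistent
    lbeta <- rnorm(n, 0, 0.5)
    ldelta <- numeric(n)
    ldelta[cons] <- rnorm(sum(cons), 0, cfg$protein_noise_sd)
    ndis <- sum(!cons)
    ldelta[!cons] <- sample(c(-1, 1), ndis, replace = TRUE) *
      (0.18 + abs(rnorm(ndis, 0, 0.2)))
    tab <- data.table(id = id, phi = exp(lbeta + ldelta), beta = exp(lbeta))
    list(table = tab, truth = list(consistent_proteins = id[cons]))
  })
}

#' Simulate batch-confounded miRNA counts
#'
#' Reproducible features carry the same log2 effect sign in every batch;
#' non-reproducible features get batch-specific signs. Batch library depths
#' differ two-fold; ~10% of (non-reproducible) features are generated at low
#' coverage so the `< 50` count filter has work to do.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list: `cm` (a [count_matrix()] with group and batch labels),
#'   `truth` (reproducible miRNA ids).
#' @export
simulate_mirna <- function(cfg = sim_config(), seed = cfg$seed) {
  nb <- cfg$n_mirna_batches
  n <- cfg$n_mirna
  smp <- CJ(batch = paste0("mb", seq_len(nb)), rep = 1:2,
            group = c("EE", "CTL"), sorted = FALSE)
  smp[, sample := paste0(group, "_", batch, "_", rep)]
  depth <- 2^(as.integer(factor(smp$batch)) - 1)   # >= 2x across batches
  with_seed(seed, {
    id <- sprintf("mir%04d", seq_len(n))
    repro <- runif(n) < cfg$frac_reproducible
    lowcov <- !repro & runif(n) < 0.15
    base <- exp(rnorm(n, log(cfg$mirna_mu), 0.7))
    base[lowcov] <- runif(sum(lowcov), 1, 15)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    Y <- matrix(0L, n, nrow(smp))
    for (s in seq_len(nrow(smp))) {
      b <- as.integer(factor(smp$batch))[s]
      eff <- ifelse(repro, sgn, sgn * (-1)^(b - 1)) * cfg$mirna_effect
      lmu <- log(base) + log(depth[s]) +
        if (smp$group[s] == "EE") eff * log(2) else 0
      Y[, s] <- rnbinom(n, size = 1 / cfg$mirna_phi, mu = exp(lmu))
    }
    rownames(Y) <- id; colnames(Y) <- smp$sample
    list(cm = count_matrix(Y, smp$group, smp$batch),
         truth = list(reproducible_mirnas = id[repro & !lowcov]))
  })
}

#' Simulate linked enhancer/promoter RPKM and gene fold changes
#'
#' Gene-level latent region-activity and expression log2 fold changes are
#' jointly Gaussian with correlation `rho`; each gene gets 1-3 linked
#' regions whose per-sample RPKM realizes the latent region fold change with
#' small log-normal noise.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list: `links` (region_id, gene_id, class), `rpkm_ee`, `rpkm_ctl`
#'   (region x sample matrices), `gene_fc` (gene_id, log2FC), `truth`
#'   (rho).
#' @export
simulate_links_expression <- function(cfg = sim_config(), seed = cfg$seed) {
  n <- cfg$n_genes
  rho <- cfg$rho
  with_seed(seed, {
    gene <- sprintf("gene%04d", seq_len(n))
    x <- rnorm(n)                                   # region-activity latent
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)       # expression latent
    x <- 0.5 * x; y <- 0.5 * y                      # log2FC scale (sd 0.5)
    nreg <- sample(1:3, n, replace = TRUE)
    cls <- sample(c("enhancer", "promoter"), n, replace = TRUE)
    links <- data.table(gene_id = rep(gene, nreg), class = rep(cls, nreg))
    links[, region_id := paste0("regn", seq_len(.N))]
    base <- exp(rnorm(nrow(links), 1, 0.5))
    gx <- rep(x, nreg)
    ns <- 2
    mk <- function(fc_log2) {
      m <- sapply(seq_len(ns), function(j)
        base * 2^fc_log2 * exp(rnorm(nrow(links), 0, cfg$link_noise_sd)))
      rownames(m) <- links$region_id
      colnames(m) <- paste0("s", seq_len(ns))
      m
    }
    list(links = links[, .(region_id, gene_id, class)],
         rpkm_ee = mk(gx), rpkm_ctl = mk(0),
         gene_fc = data.table(gene_id = gene, log2FC = y),
         truth = list(rho = rho))
  })
}

#' Simulate 1 Mb mark-coverage bin counts with hub enrichment
#'
#' Per-bin NB coverage counts for a synthetic mark, with a fold increase in
#' EE samples restricted to the hub bins, feeding [diff_mark_bins()].
#'
#' @param hub_bins global bin indices to enrich.
#' @param bins the 1 Mb universe.
#' @param cfg a [sim_config()] (uses n_ee/n_ctl/phi_nb).
#' @param fold EE enrichment in hub bins (default 2.5).
#' @param mu baseline mean coverage per bin.
#' @param seed RNG seed.
#' @return a [count_matrix()] with bin indices as feature ids.
#' @export
simulate_mark_bin_counts <- function(hub_bins, bins, cfg = sim_config(),
                                     fold = 2.5, mu = 100, seed = cfg$seed) {
  smp <- .sim_samples(cfg)
  uni <- universe_bins(bins)
  with_seed(seed, {
    Y <- matrix(0L, length(uni), nrow(smp))
    inhub <- uni %in% hub_bins
    for (s in seq_len(nrow(smp))) {
      m <- rep(mu, length(uni))
      if (smp$group[s] == "EE") m[inhub] <- m[inhub] * fold
      Y[, s] <- rnbinom(length(uni), size = 1 / cfg$phi_nb, mu = m)
    }
    rownames(Y) <- as.character(uni); colnames(Y) <- smp$sample
    count_matrix(Y, smp$group, smp$batch)
  })
}

#' Write a simulation truth sidecar as JSON
#' @param truth a `sim_truth` (or any truth list).
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  x <- lapply(unclass(truth), function(v)
    if (is.data.table(v)) as.data.frame(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
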