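test_that("generators are pure functions of (cfg, seed)", {
  cfg <- sim_config(chroms = c("chr7s", "chr17s"), chrom_length = 4e6,
                    n_hub_pairs = 3, n_proteins = 50, n_mirna = 50,
                    n_genes = 50)
  a <- simulate_hic_counts(cfg, seed = 5)
  b <- simulate_hic_counts(cfg, seed = 5)
  expect_equal(as.data.frame(a$inter), as.data.frame(b$inter))
  expect_equal(as.data.frame(a$intra), as.data.frame(b$intra))
  expect_equal(a$truth$hub_pairs, b$truth$hub_pairs)
  expect_equal(simulate_proteomics(cfg, seed = 2)$table,
               simulate_proteomics(cfg, seed = 2)$table)
  expect_equal(simulate_mirna(cfg, seed = 2)$cm$counts,
               simulate_mirna(cfg, seed = 2)$cm$counts)

  # valid-pairs files byte-identical across runs at a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_hic(cfg, d1, seed = 5)
  f2 <- simulate_hic(cfg, d2, seed = 5)
  for (s in names(f1$pairs_files))
    expect_identical(unname(tools::md5sum(f1$pairs_files[[s]])),
                     unname(tools::md5sum(f2$pairs_files[[s]])))
})

test_that("null config plants no group signal; totals obey the LLN check", {
  # f = 1, batch off, tiny dispersion: sample totals ~ sum of means
  cfg <- sim_config(chroms = c("chr7s", "chr17s"), chrom_length = 10e6,
                    hub_fold = 1, batch_sd = 0, phi_nb = 1e-6,
                    n_hub_pairs = 5)
  for (s in 1:3) {
    sim <- simulate_hic_counts(cfg, seed = s, classes = "inter")
    tot <- colSums(as.matrix(sim$inter[, c("EE1", "EE2", "CTL1", "CTL2")]))
    expected <- nrow(sim$inter) * cfg$mu0_inter
    expect_true(all(abs(tot - expected) < 3 * sqrt(expected)))
  }
  # truth list present but EE/CTL means identical: few/no discoveries
  da <- diff_contact_analysis(
    filter_contacts(simulate_hic_counts(cfg, seed = 1,
                                        classes = "inter")$inter,
                    make_bins(sim_chrom_sizes <- chrom_sizes(
                      c("chr7s", "chr17s"), c(10e6, 10e6)), 1e6,
                      exclude = character())), k = 1)
  expect_lte(nrow(da$increased) + nrow(da$decreased), 2)
})

test_that("mark regions cluster in hub bins as directed", {
  bins <- line_bins(20)
  hub <- c(3L, 7L, 11L)
  r1 <- simulate_mark_regions(hub, bins, n_regions = 50, p_in_hub = 1,
                              seed = 2)
  a1 <- assign_regions_to_bins(r1, bins, "midpoint")
  expect_true(all(a1$bin %in% hub))

  r0 <- simulate_mark_regions(hub, bins, n_regions = 50, p_in_hub = 0,
                              seed = 2)
  a0 <- assign_regions_to_bins(r0, bins, "midpoint")
  expect_false(any(a0$bin %in% hub))

  expect_equal(nrow(simulate_mark_regions(hub, bins, n_regions = 0)), 0)
  expect_error(simulate_mark_regions(integer(), bins, p_in_hub = 0.5),
               "no hub bins")
  # region lengths in the stated 1-50 kb range
  expect_true(all(r1$end - r1$start <= 5e4 & r1$end - r1$start >= 1e3))
})

test_that("proteomics generator separates consistent and discrepant", {
  # sigma = 0: every consistent protein has delta exactly 1
  pr0 <- simulate_proteomics(sim_config(protein_noise_sd = 0), seed = 3)
  d0 <- compute_delta(pr0$table)
  expect_equal(d0[id %in% pr0$truth$consistent_proteins, delta],
               rep(1, length(pr0$truth$consistent_proteins)))
  # defaults: delta selection recovers truth with high recall/precision
  recs <- sapply(1:5, function(s) {
    pr <- simulate_proteomics(sim_config(), seed = s)
    sel <- select_consistent(compute_delta(pr$table))
    tp <- sum(sel$consistent$id %in% pr$truth$consistent_proteins)
    c(tp / length(pr$truth$consistent_proteins), tp / nrow(sel$consistent))
  })
  expect_gte(mean(recs[1, ]), 0.9)
  expect_gte(mean(recs[2, ]), 0.9)
  expect_equal(nrow(simulate_proteomics(sim_config(n_proteins = 0))$table), 0)
})

test_that("miRNA generator plants reproducible directions and batch depth", {
  mi <- simulate_mirna(sim_config(), seed = 6)
  st <- mi$cm$samples
  # batch library depths differ >= 2x
  d1 <- mean(st$lib_size[st$batch == "mb1"])
  d2 <- mean(st$lib_size[st$batch == "mb2"])
  expect_gte(max(d1, d2) / min(d1, d2), 1.8)
  # truth features are sign-consistent across batches by construction
  res <- mirna_reproducible(mi$cm)
  truth_in <- res[id %in% mi$truth$reproducible_mirnas]
  expect_gte(mean(truth_in$consensus != 0), 0.9)
  # shuffling group labels destroys the truth correspondence of the calls:
  # precision against the planted set collapses to the truth base rate
  truth <- mi$truth$reproducible_mirnas
  real_prec <- mean(res[res$retained == TRUE, ]$id %in% truth)
  set.seed(1)
  shuf_prec <- replicate(10, {
    shuf <- mi$cm
    for (b in unique(st$batch)) {     # swap one EE/CTL pair per batch
      je <- sample(which(st$batch == b & st$group == "EE"), 1)
      jc <- sample(which(st$batch == b & st$group == "CTL"), 1)
      shuf$samples$group[c(je, jc)] <- shuf$samples$group[c(jc, je)]
    }
    r <- mirna_reproducible(shuf)
    mean(r[r$retained == TRUE, ]$id %in% truth)
  })
  expect_lt(mean(shuf_prec), real_prec - 0.2)
})

test_that("link generator realizes the requested correlation", {
  # rho = 1, no noise: recovered r is 1
  lk <- simulate_links_expression(sim_config(rho = 1, link_noise_sd = 0),
                                  seed = 2)
  g <- aggregate_fc_by_gene(lk$rpkm_ee, lk$rpkm_ctl, lk$links,
                            pseudocount = 0)
  cc <- correlate_fc(g, lk$gene_fc)
  expect_gt(cc$pearson_r, 0.99)
  # rho = 0 at n = 500: |r| small
  lk0 <- simulate_links_expression(sim_config(rho = 0), seed = 2)
  g0 <- aggregate_fc_by_gene(lk0$rpkm_ee, lk0$rpkm_ctl, lk0$links)
  expect_lt(abs(correlate_fc(g0, lk0$gene_fc)$pearson_r), 0.15)
})

test_that("every generated file is readable by its pipeline reader", {
  d <- withr::local_tempdir()
  cfg <- sim_config(chroms = c("chr1s", "chr7s", "chr17s"),
                    chrom_length = 4e6, n_hub_pairs = 3, n_proteins = 40,
                    n_mirna = 60, n_genes = 40, n_regions = 20)
  conf <- simulate_dataset(d, cfg, seed = 8, force = TRUE)
  expect_no_warning({
    load_chrom_sizes(conf$chrom_sizes)
    for (s in conf$samples) parse_valid_pairs(s$pairs)
    for (b in conf$feature_beds) read_bed(b)
    read_count_matrix(conf$mark_bin_counts)
    read_ratio_table(conf$ratio_table)
    read_count_matrix(conf$mirna_counts)
    read_link_table(conf$links$links)
  })
})
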