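test_that("cpm and rpkm arithmetic and scale invariance", {
  Y <- matrix(c(100, 50, 200, 100), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(Y, c("EE", "CTL"), lib_size = c(1e6, 1e6))
  expect_equal(cpm(cm)["a", "s1"], 100)
  expect_equal(rpkm(cm, lengths = c(2000, 1000))["a", "s1"], 50)
  # doubling counts and library size together leaves cpm unchanged
  cm2 <- count_matrix(Y * 2, c("EE", "CTL"), lib_size = c(2e6, 2e6))
  expect_equal(cpm(cm2), cpm(cm) * c(2, 2, 2, 2) / 2)
  expect_error(cpm(count_matrix(Y, c("EE", "CTL"), lib_size = c(0, 1))),
               "library")
  expect_error(rpkm(cm, lengths = c(0, 1)), "positive")
})

test_that("TMM matches the independent reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    S <- sample(2:5, 1)
    Y <- matrix(rnbinom(n * S, mu = exp(runif(n * S, 2, 6)), size = 5), n, S)
    # plant composition bias in ~30% of features of one sample
    de <- sample(n, ceiling(0.3 * n))
    Y[de, 1] <- Y[de, 1] * 4
    colnames(Y) <- paste0("s", 1:S)
    cm <- count_matrix(Y, rep(c("EE", "CTL"), length.out = S))
    f_ref <- edgeR::calcNormFactors(Y, lib.size = colSums(Y), method = "TMM")
    f_ours <- tmm_factors(cm)$factors
    expect_equal(unname(f_ours), unname(f_ref), tolerance = 1e-6)
  }
  # identical columns -> unit factors (3 features, so the warning fires too)
  Yc <- matrix(rep(c(5, 50, 500), 3), 3, 3)
  suppressWarnings(
    expect_equal(unname(tmm_factors(count_matrix(Yc, c("EE", "CTL", "EE")))$factors),
                 rep(1, 3)))
  # pure depth difference absorbed by library size, factors stay equal
  # (4 features also exercises the <10-usable-features warning path)
  Yd <- cbind(s1 = c(10L, 100L, 40L, 400L), s2 = c(20L, 200L, 80L, 800L))
  expect_warning(fd <- tmm_factors(count_matrix(Yd, c("EE", "CTL")))$factors,
                 "fewer than 10")
  expect_equal(unname(fd[1]), unname(fd[2]), tolerance = 1e-10)
})

test_that("BH step-up matches the hand-coded oracle and p.adjust", {
  bh_oracle <- function(p) {             # literal q_(i) = min_{j>=i} p_(j)m/j
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
    q
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NA p-values excluded from m
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(p), c(0.02, NA, 0.04))
  expect_error(bh_fdr(c(-0.1, 0.5)), "0, 1")
})

test_that("RUVg recovers a planted batch factor from controls", {
  cors <- sapply(1:20, function(s) {
    batch <- c(1, -1, 1, -1)                      # orthogonal to group
    # batch planted on a feature subset (incl. the controls), so it is a
    # real unwanted factor rather than a pure depth shift
    cm <- nb_counts(n_feat = 400, batch_mult = exp(0.4 * batch),
                    affected = 1:200, seed = s)
    W <- ruv_g(cm, control_ids = paste0("f", 1:100), k = 1)$W
    abs(cor(W[, 1], batch))
  })
  expect_gt(min(cors), 0.9)
  # k = 0 yields an empty W
  cm <- nb_counts(n_feat = 50, seed = 1)
  expect_equal(ncol(ruv_g(cm, paste0("f", 1:10), k = 0)$W), 0)
  # constant controls have no singular structure
  Yc <- matrix(5L, 20, 4, dimnames = list(paste0("f", 1:20), NULL))
  expect_error(ruv_g(count_matrix(Yc, c("EE", "EE", "CTL", "CTL")),
                     paste0("f", 1:5), k = 1), "constant")
  expect_error(ruv_g(cm, paste0("f", 1:10), k = 4), "k must be")
})

test_that("RUVr recovers a batch orthogonal to group from residuals", {
  cors <- sapply(1:20, function(s) {
    batch <- c(1, -1, 1, -1)
    cm <- nb_counts(n_feat = 400, batch_mult = exp(0.4 * batch),
                    affected = 1:200, de_idx = 301:340, fold = 3,
                    seed = 100 + s)
    abs(cor(ruv_r(cm, k = 1)$W[, 1], batch))
  })
  expect_gt(min(cors), 0.9)
  # relabeling the baseline group leaves W invariant (residuals unchanged)
  cm <- nb_counts(n_feat = 200, batch_mult = exp(0.4 * c(1, -1, 1, -1)),
                  affected = 1:100, seed = 3)
  cm_swap <- cm
  cm_swap$samples$group <- rev(cm$samples$group)
  expect_equal(abs(ruv_r(cm, 1)$W), abs(ruv_r(cm_swap, 1)$W),
               tolerance = 1e-8)
  expect_error(ruv_r(cm, k = 3), "rank")
})

test_that("dispersion estimation brackets the truth and shrinks", {
  # Poisson data: common dispersion is tiny
  cmp <- nb_counts(n_feat = 200, mu = 100, phi = 1e-9, seed = 5)
  dp <- estimate_dispersion(cmp)
  expect_lt(dp$common, 0.01)
  # NB at phi = 0.2: common lands in [0.15, 0.25] (2,000 features)
  cms <- lapply(1:5, function(s) nb_counts(n_feat = 2000, mu = 100,
                                           phi = 0.2, seed = 20 + s))
  commons <- vapply(cms, function(cm) estimate_dispersion(cm)$common, 0)
  expect_true(all(commons > 0.15 & commons < 0.25))
  # shrinkage limit: w0 -> large forces phi_i ~ common
  d1 <- estimate_dispersion(cms[[1]], w0 = 1e6)
  expect_lt(max(abs(d1$phi - d1$common), na.rm = TRUE), 1e-3)
  # all-zero feature flagged
  cmz <- cms[[1]]
  cmz$counts[7, ] <- 0L
  dz <- estimate_dispersion(cmz)
  expect_true("f7" %in% dz$flagged)
  expect_true(is.na(dz$phi["f7"]))
})

test_that("NB GLM test: degenerate, null-calibrated and powered cases", {
  # identical group columns: log2FC = 0, p ~ 1
  Y <- matrix(rep(c(40L, 80L, 120L), each = 4), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  cm0 <- count_matrix(Y, c("EE", "EE", "CTL", "CTL"))
  r0 <- nb_glm_test(cm0)
  expect_equal(r0$log2FC, rep(0, 3), tolerance = 1e-6)
  expect_true(all(r0$p > 0.99))

  # null simulation: no q < 0.05 calls, p roughly uniform
  cmn <- nb_counts(n_feat = 2000, mu = 80, phi = 0.1, seed = 31)
  rn <- nb_glm_test(cmn)
  expect_lte(sum(rn$q < 0.05, na.rm = TRUE), 2)
  ks <- suppressWarnings(ks.test(rn$p, "punif"))
  expect_lt(unname(ks$statistic), 0.06)

  # planted 4-fold features at mu = 50, phi = 0.1, n = 2+2: recall >= 0.8.
  # TMM matters here: 6% of features 4-fold up inflate the EE library sizes,
  # and without composition correction the DE log2FCs are attenuated.
  recall <- sapply(1:10, function(s) {
    cm <- nb_counts(n_feat = 500, mu = 50, phi = 0.1, de_idx = 1:30,
                    fold = 4, seed = 40 + s)
    r <- nb_glm_test(cm, norm = tmm_factors(cm))
    mean(r[1:30][["q"]] < 0.05, na.rm = TRUE)
  })
  expect_gte(mean(recall), 0.8)
})

test_that("NB GLM test invariances: antisymmetry and scale", {
  cm <- nb_counts(n_feat = 300, mu = 60, phi = 0.1, de_idx = 1:20, fold = 3,
                  seed = 9)
  r1 <- nb_glm_test(cm)
  cm2 <- cm
  cm2$samples$group <- c("CTL", "CTL", "EE", "EE")
  r2 <- nb_glm_test(cm2)
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-5)
  expect_equal(r1$p, r2$p, tolerance = 1e-5)

  # multiplying one sample's counts and library size by c leaves p (nearly)
  # unchanged: exact invariance holds only in the quasi-likelihood limit,
  # because NB(c*mu, phi) is not the distribution of c*y (the Poisson part
  # of the variance scales by c, not c^2); the fitted effects are invariant
  # and p moves by at most a few percent relative
  cm3 <- cm
  cm3$counts[, 2] <- cm3$counts[, 2] * 4L
  cm3$samples$lib_size[2] <- cm3$samples$lib_size[2] * 4
  disp <- estimate_dispersion(cm)
  r3 <- nb_glm_test(cm3, dispersion = disp)
  r1d <- nb_glm_test(cm, dispersion = disp)
  expect_lt(max(abs(r1d$log2FC - r3$log2FC)), 0.05)
  expect_gt(cor(-log10(r1d$p), -log10(r3$p)), 0.999)
  expect_lt(median(abs(r1d$p - r3$p) / pmax(r1d$p, 1e-12)), 0.05)
})

test_that("select-and-intersect honors qualification and intersection", {
  # planted signal + planted batch on all features
  batch <- c(1, -1, 1, -1)
  cm <- nb_counts(n_feat = 600, mu = 100, phi = 0.05,
                  batch_mult = exp(0.3 * batch), de_idx = 1:40, fold = 3,
                  seed = 12)
  out <- select_and_intersect(cm, strategies = c("g", "r"), k = 1, fdr = 0.1)
  expect_true(length(out$qualified) >= 1)
  truth <- paste0("f", 1:40)
  tp <- sum(out$selected %in% truth)
  expect_gte(tp / length(truth), 0.8)                 # recall of intersection
  expect_gte(tp / max(length(out$selected), 1), 0.8)  # precision

  # single qualifying variant: output equals that variant's calls
  if (length(out$qualified) == 1) {
    v <- out$qualified[1]
    expect_setequal(out$selected,
                    out$results[[v]][!is.na(q) & q < 0.1, id])
  }
  # disjoint per-variant calls intersect to the empty set (constructed)
  expect_equal(intersect(c("a", "b"), c("c")), character(0))
})

test_that("differential contact analysis recovers a small planted hub", {
  cfg <- sim_config(chroms = c(paste0("chr", 1:2, "s"), "chr7s", "chr17s"),
                    chrom_length = 8e6, n_hub_pairs = 8)
  sim <- simulate_hic_counts(cfg, seed = 21, classes = "inter")
  da <- diff_contact_analysis(filter_contacts(sim$inter, sim$bins_inter),
                              k = 1, fdr = 0.05)
  truth <- paste0(sim$truth$hub_pairs$bin1, "_", sim$truth$hub_pairs$bin2)
  expect_gte(mean(truth %in% da$increased$id), 0.75)
  # swapping labels swaps increased/decreased exactly
  swapped <- sim$inter
  st <- attr(swapped, "samples")
  st$group <- c("CTL", "CTL", "EE", "EE")
  data.table::setattr(swapped, "samples", st)
  da2 <- diff_contact_analysis(filter_contacts(swapped, sim$bins_inter),
                               k = 1, fdr = 0.05)
  expect_setequal(da$increased$id, da2$decreased$id)
  expect_setequal(da$decreased$id, da2$increased$id)
})

test_that("differential 1 Mb mark bins recover planted folds, emit BED", {
  bins <- line_bins(60)
  hub <- c(5L, 17L, 33L, 49L)
  cfg <- sim_config()
  cm <- simulate_mark_bin_counts(hub, bins, cfg, fold = 3, mu = 100,
                                 seed = 14)
  mb <- diff_mark_bins(cm, bins, fdr = 0.05)
  called_up <- as.integer(mb$up$name)
  expect_gte(mean(hub %in% called_up), 0.8)
  expect_lte(length(setdiff(called_up, hub)), 2)
  # output BED round-trips through read_bed
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(mb$up, p)
  back <- read_bed(p)
  expect_equal(back$start, mb$up$start)
  # null: ~0 calls
  cm0 <- simulate_mark_bin_counts(hub, bins, cfg, fold = 1, mu = 100,
                                  seed = 15)
  mb0 <- diff_mark_bins(cm0, bins, fdr = 0.05)
  expect_lte(nrow(mb0$up) + nrow(mb0$down), 1)
})
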