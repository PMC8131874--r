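valid_pairs_file <- function(lines) {
  p <- withr::local_tempfile(fileext = ".validPairs", .local_envir =
                               parent.frame())
  writeLines(lines, p)
  p
}

test_that("valid-pairs parsing converts 1-based to 0-based and validates", {
  p <- valid_pairs_file("r1\tchr1\t100\t+\tchr2\t200\t-")
  vp <- parse_valid_pairs(p)
  expect_equal(vp$pos1, 99)
  expect_equal(vp$pos2, 199)

  # 10-column allValidPairs dialect: trailing fields ignored
  p2 <- valid_pairs_file("r1\tchr1\t100\t+\tchr2\t200\t-\t500\tHIC_frag1\tHIC_frag2")
  expect_equal(parse_valid_pairs(p2)$pos2, 199)

  p3 <- valid_pairs_file("r1\tchr1\tabc\t+\tchr2\t200\t-")
  expect_error(parse_valid_pairs(p3), "line 1")
  p4 <- valid_pairs_file("r1\tchr1\t100")
  expect_error(parse_valid_pairs(p4), "< 7")

  # --dedup drops exact read-id duplicates
  p5 <- valid_pairs_file(c("r1\tchr1\t100\t+\tchr2\t200\t-",
                           "r1\tchr1\t100\t+\tchr2\t200\t-"))
  expect_equal(nrow(parse_valid_pairs(p5)), 2)
  expect_equal(nrow(parse_valid_pairs(p5, dedup = TRUE)), 1)
})

test_that("binning routes pairs intra/inter, canonicalizes and conserves", {
  lines <- c("r1\tchr1\t50001\t+\tchr1\t150001\t-",   # intra bins 0,1 @100kb
             "r2\tchr1\t50001\t+\tchr2\t50001\t-",    # inter @1Mb
             "r3\tchr2\t50001\t+\tchr1\t50001\t-",    # same pair, swapped
             "r4\tchrX\t1\t+\tchr1\t1\t-")            # dropped (excluded)
  sizes <- chrom_sizes(c("chr1", "chr2", "chrX"), c(2e6, 1e6, 1e6))
  p <- valid_pairs_file(lines)
  vp <- parse_valid_pairs(p)
  bc <- bin_contacts(vp, sizes, sample_name = "s1")
  expect_equal(bc$intra$bin1, 0L)
  expect_equal(bc$intra$bin2, 1L)
  expect_equal(bc$intra$s1, 1L)
  # both orientations collapse onto one canonical inter row
  expect_equal(nrow(bc$inter), 1)
  expect_equal(bc$inter$s1, 2L)
  expect_equal(bc$dropped, 1L)
  # conservation: intra + inter + dropped = input pairs
  expect_equal(sum(bc$intra$s1) + sum(bc$inter$s1) + bc$dropped, nrow(vp))

  # permutation invariance of input order
  p2 <- valid_pairs_file(rev(lines))
  bc2 <- bin_contacts(parse_valid_pairs(p2), sizes, sample_name = "s1")
  expect_equal(as.data.frame(bc2$inter), as.data.frame(bc$inter))
  expect_equal(as.data.frame(bc2$intra), as.data.frame(bc$intra))
})

test_that("merging aligns bin-pair keys with zero fill and checks widths", {
  sizes <- tiny_sizes()
  mk <- function(lines, nm) {
    p <- valid_pairs_file(lines)
    bin_contacts(parse_valid_pairs(p), sizes, exclude = character(),
                 sample_name = nm)
  }
  a <- mk("r1\tchr1\t1\t+\tchr2\t1\t-", "sA")
  b <- mk("r1\tchr1\t1500001\t+\tchr2\t1\t-", "sB")
  m <- merge_contact_tables(list(a$inter, b$inter), group = c("EE", "CTL"))
  expect_equal(nrow(m), 2)
  expect_equal(m$sA, c(1L, 0L))
  expect_equal(m$sB, c(0L, 1L))
  expect_error(merge_contact_tables(list(a$inter, b$intra), c("EE", "CTL")),
               "different class")
})

test_that("contact filtering removes self-pairs, excluded bins and low rows", {
  sizes <- chrom_sizes(c("chr1", "chrX"), c(3e6, 2e6))
  bins <- make_bins(sizes, 1e6)   # default exclusion drops chrX
  bins_all <- make_bins(sizes, 1e6, exclude = character())
  dt <- data.table::data.table(bin1 = c(0L, 1L, 1L, 3L),
                               bin2 = c(1L, 1L, 2L, 4L),
                               s1 = c(5L, 9L, 1L, 7L),
                               s2 = c(5L, 9L, 0L, 7L))
  tab <- hubdiff:::new_contact_table(dt, "intra", 1e6,
                                     hubdiff:::.sample_table(c("s1", "s2"),
                                                             c("EE", "CTL"),
                                                             NULL))
  f <- filter_contacts(tab, bins, min_total = 2)
  # (1,1) self-pair gone regardless of count; (3,4) on chrX gone; (1,2) low
  expect_equal(nrow(f), 1)
  expect_equal(f$bin1, 0L)
  rep <- attr(f, "filter_report")
  expect_equal(unname(rep["self_pair"]), 1L)
  expect_equal(unname(rep["excluded_chrom"]), 1L)
  expect_equal(unname(rep["low_count"]), 1L)

  # min_total = 0 keeps the low row (structural rules only)
  f0 <- filter_contacts(tab, bins, min_total = 0)
  expect_equal(nrow(f0), 2)
  expect_error(filter_contacts(tab, bins, min_total = 1e9), "min_total")
})

test_that("contact table TSV round-trips with metadata", {
  sim <- simulate_hic_counts(
    sim_config(chroms = c("chr7s", "chr17s"), chrom_length = 3e6,
               n_hub_pairs = 2, n_intra_diff = 2), seed = 4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(sim$inter, p)
  back <- read_contact_table(p)
  expect_equal(as.data.frame(back), as.data.frame(sim$inter))
  expect_equal(attr(back, "contact_class"), "inter")
  expect_equal(hubdiff:::contact_samples(back)$group,
               hubdiff:::contact_samples(sim$inter)$group)
})

test_that("ICE balancing equalizes row sums and handles masks", {
  # constant matrix is a fixed point: weights equal, rowsums already flat
  m <- matrix(2, 5, 5)
  b <- ice_balance(m)
  expect_true(b$converged)
  expect_equal(unname(b$weights), rep(b$weights[1], 5))

  # bias-distorted rank-structured matrix balances to equal rowsums
  cb <- checkerboard(n = 40, bias_sd = 0.5)
  bal <- ice_balance(cb$mat, tol = 1e-10)
  expect_true(bal$converged)
  rs <- rowSums(bal$matrix)
  expect_lt(sd(rs) / mean(rs), 1e-6)

  # idempotence: balancing a balanced matrix leaves weights ~ 1
  bal2 <- ice_balance(bal$matrix, tol = 1e-10)
  w <- bal2$weights / mean(bal2$weights)
  expect_lt(max(abs(w - 1)), 1e-4)

  # all-zero row is masked and excluded
  m2 <- cb$mat; m2[3, ] <- 0; m2[, 3] <- 0
  b2 <- ice_balance(m2)
  expect_true(b2$mask[3])
  expect_equal(rowSums(b2$matrix)[3], 0)

  expect_error(ice_balance(matrix(1, 2, 3)), "square")
  expect_error(ice_balance(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("compartment eigenvector recovers planted blocks and orients", {
  cb <- checkerboard(n = 60)
  bal <- ice_balance(cb$mat)
  eg <- compartment_eigenvector(bal, orientation_track = cb$block)
  acc <- mean(sign(eg$E1) == cb$block, na.rm = TRUE)
  expect_gte(acc, 0.95)
  expect_equal(eg$label[eg$E1 > 0][1], "A")

  # flipping the orientation track inverts all labels
  eg2 <- compartment_eigenvector(bal, orientation_track = -cb$block)
  expect_equal(eg2$E1, -eg$E1)

  # E1 invariant to global scaling of the contact matrix
  eg3 <- compartment_eigenvector(ice_balance(cb$mat * 7),
                                 orientation_track = cb$block)
  expect_equal(eg3$E1, eg$E1, tolerance = 1e-6)

  # constant matrix has no O/E variance to decompose
  expect_error(compartment_eigenvector(ice_balance(matrix(1, 10, 10)),
                                       orientation_track = rep(1, 10)),
               "variance")
})
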