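# Valid-pairs ingestion, intra/inter binning, filtering, ICE balancing and
# A/B compartment eigenvectors.

#' Parse a HiC-Pro-style valid-pairs file
#'
#' Expects >= 7 tab-separated columns: readID, chr1, pos1, strand1, chr2,
#' pos2, strand2; extra columns (full allValidPairs dialect) are ignored.
#' Positions are 1-based in the file and converted to 0-based internally.
#'
#' @param path valid-pairs TSV.
#' @param dedup drop exact duplicate read IDs (deduplication is normally done
#'   upstream by the valid-pairs producer).
#' @return data.table read_id, chrom1, pos1, chrom2, pos2 (0-based).
#' @export
parse_valid_pairs <- function(path, dedup = FALSE) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = "character")
  if (nrow(dt) == 0)
    return(data.table(read_id = character(), chrom1 = character(),
                      pos1 = numeric(), chrom2 = character(), pos2 = numeric()))
  if (ncol(dt) < 7) stopf("valid-pairs file %s has %d columns (< 7)",
                          path, ncol(dt))
  p1 <- suppressWarnings(as.numeric(dt[[3]]))
  p2 <- suppressWarnings(as.numeric(dt[[6]]))
  bad <- which(is.na(p1) | is.na(p2))
  if (length(bad))
    stopf("non-integer position on line %d of %s", bad[1], path)
  if (any(p1 < 1) || any(p2 < 1))
    stopf("valid-pairs positions must be >= 1 (1-based dialect): %s", path)
  out <- data.table(read_id = dt[[1]], chrom1 = dt[[2]], pos1 = p1 - 1,
                    chrom2 = dt[[5]], pos2 = p2 - 1)
  if (dedup) out <- unique(out, by = "read_id")
  out[]
}

.sample_table <- function(samples, group, batch) {
  data.table(sample = samples, group = group,
             batch = batch %||% rep("b1", length(samples)))
}

new_contact_table <- function(dt, class_type, bin_width, samples) {
  setattr(dt, "contact_class", class_type)
  setattr(dt, "bin_width", bin_width)
  setattr(dt, "samples", samples)
  setattr(dt, "class", c("contact_table", class(dt)))
  dt[]
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table (%s, %g bp bins): %d bin-pairs x %d sample(s)\n",
              attr(x, "contact_class"), attr(x, "bin_width"), nrow(x),
              nrow(attr(x, "samples"))))
  invisible(x)
}

contact_samples <- function(x) attr(x, "samples")

#' Bin valid pairs into intra- and inter-chromosomal contact tables
#'
#' Each pair increments exactly one row of exactly one table: same-chromosome
#' pairs go to the intra table at `w_intra` (default 100 kb), different
#' chromosomes to the inter table at `w_inter` (default 1 Mb). Bin-pair keys
#' are canonicalized to `bin1 <= bin2` under the global bin order. Pairs on
#' excluded chromosomes are dropped and tallied.
#'
#' @param pairs output of [parse_valid_pairs()].
#' @param sizes a [chrom_sizes()] object.
#' @param w_intra,w_inter bin widths in bp.
#' @param exclude chromosomes dropped from the universe.
#' @param sample_name column name for this sample's counts.
#' @return list(intra, inter, dropped) — two single-sample `contact_table`s
#'   and the dropped-pair tally.
#' @export
bin_contacts <- function(pairs, sizes, w_intra = 1e5, w_inter = 1e6,
                         exclude = c("chrX", "chrY", "chrM"),
                         sample_name = "s1") {
  bins_a <- make_bins(sizes, w_intra, exclude)
  bins_e <- make_bins(sizes, w_inter, exclude)
  one <- function(bins, sub) {
    b1 <- bin_of(bins, sub$chrom1, sub$pos1)
    b2 <- bin_of(bins, sub$chrom2, sub$pos2)
    ok <- !is.na(b1) & !is.na(b2)
    key <- data.table(bin1 = pmin(b1[ok], b2[ok]), bin2 = pmax(b1[ok], b2[ok]))
    cnt <- key[, .(count = .N), by = .(bin1, bin2)]
    setorder(cnt, bin1, bin2)
    list(cnt = cnt, dropped = sum(!ok))
  }
  is_intra <- pairs$chrom1 == pairs$chrom2
  ra <- one(bins_a, pairs[is_intra])
  re <- one(bins_e, pairs[!is_intra])
  st <- .sample_table(sample_name, NA_character_, NULL)
  mk <- function(r, cls, w) {
    dt <- copy(r$cnt)
    setnames(dt, "count", sample_name)
    new_contact_table(dt, cls, w, st)
  }
  list(intra = mk(ra, "intra", w_intra),
       inter = mk(re, "inter", w_inter),
       dropped = ra$dropped + re$dropped)
}

#' Merge single-sample contact tables into a multi-sample table
#'
#' Rows are aligned by canonical bin-pair key with zero fill; all inputs must
#' share class and bin width.
#'
#' @param tables list of single-sample `contact_table`s.
#' @param group per-sample condition labels (e.g. "EE"/"CTL").
#' @param batch optional per-sample batch labels.
#' @return a multi-sample `contact_table`.
#' @export
merge_contact_tables <- function(tables, group, batch = NULL) {
  cls <- unique(vapply(tables, attr, "", "contact_class"))
  ws <- unique(vapply(tables, attr, 0, "bin_width"))
  if (length(cls) != 1 || length(ws) != 1)
    stopf("cannot merge tables of different class/bin width")
  nm <- unlist(lapply(tables, function(t) contact_samples(t)$sample))
  if (anyDuplicated(nm)) stopf("duplicate sample names in merge")
  merged <- Reduce(function(a, b) merge(a, b, by = c("bin1", "bin2"),
                                        all = TRUE),
                   lapply(tables, as.data.table))
  for (s in nm) set(merged, which(is.na(merged[[s]])), s, 0L)
  setorder(merged, bin1, bin2)
  new_contact_table(merged, cls, ws, .sample_table(nm, group, batch))
}

#' Filter a merged contact table
#'
#' Removes intra self-pairs (`bin1 == bin2`), rows whose bins lie on excluded
#' chromosomes, and rows with total count across samples below `min_total`.
#' (Excluded chromosomes normally never enter — binning drops them — but the
#' rule is re-applied for tables built elsewhere.)
#'
#' @param table a merged `contact_table`.
#' @param bins the [make_bins()] universe the table was binned on.
#' @param min_total minimum summed count across samples (default 0: only the
#'   structural rules apply).
#' @return filtered `contact_table` with a `filter_report` attribute.
#' @export
filter_contacts <- function(table, bins, min_total = 0) {
  dt <- as.data.table(table)
  scol <- contact_samples(table)$sample
  keep_bins <- universe_bins(bins)
  on_excl <- !(dt$bin1 %in% keep_bins & dt$bin2 %in% keep_bins)
  selfp <- attr(table, "contact_class") == "intra" & dt$bin1 == dt$bin2
  tot <- rowSums(as.matrix(dt[, ..scol]))
  low <- tot < min_total
  keep <- !(on_excl | selfp | low)
  rep <- c(excluded_chrom = sum(on_excl), self_pair = sum(selfp & !on_excl),
           low_count = sum(low & !selfp & !on_excl))
  if (!any(keep))
    stopf("all contact rows removed; lower min_total (currently %g)", min_total)
  out <- new_contact_table(dt[keep], attr(table, "contact_class"),
                           attr(table, "bin_width"), contact_samples(table))
  setattr(out, "filter_report", rep)
  out
}

#' Write / read a contact table as TSV
#'
#' Format: `#class`/`#bin_width`/`#group`/`#batch` metadata lines, then
#' bin1, bin2 and one count column per sample.
#' @param table a `contact_table`.
#' @param path output path.
#' @export
write_contact_table <- function(table, path) {
  st <- contact_samples(table)
  meta <- c(paste0("#class\t", attr(table, "contact_class")),
            paste0("#bin_width\t", format(attr(table, "bin_width"),
                                          scientific = FALSE)),
            paste0("#group\t", paste(st$group, collapse = "\t")),
            paste0("#batch\t", paste(st$batch, collapse = "\t")))
  writeLines(meta, path)
  fwrite(as.data.table(table), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' @rdname write_contact_table
#' @export
read_contact_table <- function(path) {
  meta <- readLines(path, n = 4)
  val <- function(k) strsplit(grep(paste0("^#", k), meta, value = TRUE)[1],
                              "\t")[[1]][-1]
  dt <- fread(path, skip = 4, header = TRUE, sep = "\t")
  scol <- setdiff(names(dt), c("bin1", "bin2"))
  new_contact_table(dt, val("class"), as.numeric(val("bin_width")),
                    .sample_table(scol, val("group"), val("batch")))
}

#' Dense intra-chromosomal contact matrix for one chromosome
#'
#' @param table an intra `contact_table`.
#' @param bins the binning universe.
#' @param chrom chromosome name.
#' @param sample sample name(s) to sum; default all.
#' @return symmetric square matrix of counts.
#' @export
contact_matrix <- function(table, bins, chrom, sample = NULL) {
  b <- bins$bins[chrom == ..chrom]
  if (nrow(b) == 0) stopf("chromosome %s not in universe", chrom)
  lo <- min(b$bin); n <- nrow(b)
  scol <- sample %||% contact_samples(table)$sample
  dt <- as.data.table(table)[bin1 >= lo & bin1 < lo + n &
                               bin2 >= lo & bin2 < lo + n]
  m <- matrix(0, n, n)
  if (nrow(dt) > 0) {
    v <- rowSums(as.matrix(dt[, ..scol]))
    i <- dt$bin1 - lo + 1L; j <- dt$bin2 - lo + 1L
    m[cbind(i, j)] <- m[cbind(i, j)] + v
    off <- i != j
    m[cbind(j[off], i[off])] <- m[cbind(j[off], i[off])] + v[off]
  }
  m
}

#' ICE matrix balancing (iterative correction)
#'
#' Multiplicative per-bin biases are removed by iterating
#' `w <- w * rowsum(balanced) / mean(rowsum)` until the maximum relative
#' row-sum deviation falls below `tol` or `max_iter` is hit. Bins with zero
#' marginal are masked and excluded from all row-sum statistics.
#'
#' @param mat symmetric nonnegative square matrix.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on relative row-sum deviation.
#' @return list (class `balanced_matrix`): `matrix` (balanced, masked rows
#'   zero), `weights` (per-bin bias; NA for masked), `mask` (logical, TRUE =
#'   masked), `converged`, `n_iter`.
#' @export
ice_balance <- function(mat, max_iter = 200, tol = 1e-8) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stopf("ice_balance needs a square matrix")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat))))
    stopf("ice_balance needs a symmetric matrix")
  n <- nrow(mat)
  mask <- rowSums(mat) == 0
  w <- rep(1, n)
  act <- which(!mask)
  converged <- FALSE; it <- 0
  if (length(act) > 0) {
    sub <- mat[act, act, drop = FALSE]
    ws <- rep(1, length(act))
    for (it in seq_len(max_iter)) {
      bal <- sub / outer(ws, ws)
      rs <- rowSums(bal)
      rel <- rs / mean(rs)
      if (max(abs(rel - 1)) < tol) { converged <- TRUE; break }
      ws <- ws * sqrt(rel)
    }
    w[act] <- ws
  }
  out <- matrix(0, n, n)
  if (length(act) > 0) out[act, act] <- mat[act, act] / outer(w[act], w[act])
  w[mask] <- NA_real_
  structure(list(matrix = out, weights = w, mask = mask,
                 converged = converged, n_iter = it),
            class = "balanced_matrix")
}

#' A/B compartment eigenvector of a balanced intra matrix
#'
#' Observed/expected is computed with a per-diagonal expected (mean of each
#' `|i - j|` diagonal over unmasked entries, no smoothing); the leading
#' eigenvector of the Pearson correlation matrix of O/E columns is the
#' compartment score E1. The sign is flipped so `cor(E1, orientation_track)
#' >= 0`; bins with E1 > 0 are labelled "A", E1 < 0 "B". Zero-variance O/E
#' columns are masked.
#'
#' @param bal a [ice_balance()] result.
#' @param orientation_track per-bin score used only to orient the sign
#'   (conventionally gene density or GC content).
#' @return list (class `eigen_result`): `E1` (NA for masked bins), `label`
#'   ("A"/"B"/NA), `mask`, `eigenvalue`.
#' @export
compartment_eigenvector <- function(bal, orientation_track) {
  stopifnot(inherits(bal, "balanced_matrix"))
  m <- bal$matrix
  mask <- bal$mask
  act <- which(!mask)
  if (length(act) < 4) stopf("need >= 4 unmasked bins for compartments")
  sub <- m[act, act, drop = FALSE]
  n <- nrow(sub)
  d <- abs(row(sub) - col(sub))
  exp_by_d <- vapply(0:(n - 1), function(k) mean(sub[d == k]), 0)
  E <- matrix(exp_by_d[d + 1], n, n)
  oe <- sub / E
  oe[!is.finite(oe)] <- 0
  v <- apply(oe, 2, var)
  good <- v > 1e-12
  if (sum(good) < 4) stopf("fewer than 4 O/E columns with variance (constant matrix?)")
  cc <- suppressWarnings(cor(oe[good, good, drop = FALSE]))
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  e1 <- eg$vectors[, 1]
  full <- rep(NA_real_, length(mask))
  idx <- act[good]
  full[idx] <- e1
  ot <- orientation_track[idx]
  if (length(ot) == length(e1) && sd(ot) > 0 && sd(e1) > 0 &&
      cor(e1, ot) < 0) full <- -full
  lab <- ifelse(is.na(full), NA_character_, ifelse(full > 0, "A", "B"))
  structure(list(E1 = full, label = lab, mask = is.na(full),
                 eigenvalue = eg$values[1]),
            class = "eigen_result")
}
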