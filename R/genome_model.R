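# Genome coordinate system: chromosome sizes, fixed-width bins, regions, BED.
# All internal coordinates are 0-based half-open (BED convention).

#' Construct a chromosome-size table
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive integer lengths in bp.
#' @return A `chrom_sizes` object (data.table with columns `chrom`, `length`).
#'   Row order is preserved and defines the global chromosome ordering.
#' @export
chrom_sizes <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stopf("duplicate chromosome name: %s",
                                  chrom[duplicated(chrom)][1])
  if (any(!nzchar(chrom))) stopf("empty chromosome name")
  if (any(!is.finite(length)) || any(length < 1))
    stopf("chromosome lengths must be positive integers")
  cs <- data.table(chrom = chrom, length = length)
  setattr(cs, "class", c("chrom_sizes", class(cs)))
  cs[]
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two-column TSV (name, length); lines starting with `#` are ignored.
#' File order is preserved; duplicates and non-positive lengths are rejected
#' with the offending line number.
#'
#' @param path file path.
#' @return A [chrom_sizes()] object.
#' @export
load_chrom_sizes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2 || is.na(suppressWarnings(as.numeric(p[2]))))
      stopf("malformed chrom.sizes line %d: %s", idx[i], lines[idx[i]])
    if (as.numeric(p[2]) < 1)
      stopf("non-positive length on line %d: %s", idx[i], lines[idx[i]])
  }
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1]
    stopf("duplicate chromosome '%s' (line %d)", d, idx[which(nm == d)[2]])
  }
  chrom_sizes(nm, vapply(parts, function(p) as.numeric(p[2]), 0))
}

#' Write a chrom.sizes file
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  fwrite(as.data.table(sizes)[, .(chrom, length)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Tile retained chromosomes with fixed-width bins
#'
#' A chromosome of length L yields `ceiling(L / bin_width)` half-open bins
#' `[k*w, min((k+1)*w, L))`; the last bin is truncated. Excluded chromosomes
#' (default: sex chromosomes plus chrM) contribute no bins. Global bin
#' indices are dense `0..B-1` in chromosome-then-position order.
#'
#' @param sizes a [chrom_sizes()] object.
#' @param bin_width bin width in bp (>= 1).
#' @param exclude chromosome names dropped from the universe.
#' @return A `genome_bins` object: list with `bins` (data.table chrom, start,
#'   end, bin), `bin_width`, `excluded`, `sizes`.
#' @export
make_bins <- function(sizes, bin_width,
                      exclude = c("chrX", "chrY", "chrM")) {
  stopifnot(inherits(sizes, "chrom_sizes"))
  if (bin_width < 1) stopf("bin_width must be >= 1")
  keep <- as.data.table(sizes)[!chrom %in% exclude]
  if (nrow(keep) == 0) stopf("no chromosomes retained after exclusion")
  bl <- lapply(seq_len(nrow(keep)), function(i) {
    L <- keep$length[i]
    n <- ceiling(L / bin_width)
    start <- (seq_len(n) - 1) * bin_width
    data.table(chrom = keep$chrom[i], start = start,
               end = pmin(start + bin_width, L))
  })
  bins <- rbindlist(bl)
  bins[, bin := seq_len(.N) - 1L]
  structure(list(bins = bins[], bin_width = bin_width,
                 excluded = exclude, sizes = sizes),
            class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins of %g bp on %d chromosomes (excluded: %s)\n",
              nrow(x$bins), x$bin_width,
              length(unique(x$bins$chrom)),
              paste(x$excluded, collapse = ",")))
  invisible(x)
}

# chromosome -> global index of its first bin (internal lookup)
.bin_offsets <- function(bins) {
  b <- bins$bins
  off <- b[, .(first = min(bin), len = max(end)), by = chrom]
  setkey(off, chrom)
  off
}

#' Map genomic positions to global bin indices
#'
#' @param bins a [make_bins()] object.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer global bin indices; NA where the chromosome is not in the
#'   retained universe or the position exceeds the chromosome length.
#' @export
bin_of <- function(bins, chrom, pos) {
  off <- .bin_offsets(bins)
  .qchrom <- as.character(chrom)   # local name: avoid capture by the join
  m <- off[J(.qchrom)]
  idx <- m$first + as.integer(pos %/% bins$bin_width)
  idx[is.na(m$first) | pos < 0 | pos >= m$len] <- NA_integer_
  idx
}

#' Construct a region set
#'
#' @param chrom,start,end vectors defining 0-based half-open intervals.
#' @param name,score,strand,direction optional per-region annotations;
#'   `direction` is +1 (increased) / -1 (decreased).
#' @param label a set label (e.g. `"ATAC_up"`).
#' @return A `region_set` data.table with a `label` attribute.
#' @export
region_set <- function(chrom, start, end, name = NA_character_,
                       score = NA_real_, strand = NA_character_,
                       direction = NA_integer_, label = "regions") {
  chrom <- as.character(chrom)
  if (length(chrom) > 0) {
    if (any(!nzchar(chrom))) stopf("empty chromosome name in region")
    if (any(start < 0) || any(start >= end))
      stopf("regions must satisfy 0 <= start < end")
  }
  rs <- data.table(chrom = chrom, start = as.numeric(start),
                   end = as.numeric(end), name = name, score = score,
                   strand = strand, direction = as.integer(direction))
  setattr(rs, "label", label)
  setattr(rs, "class", c("region_set", class(rs)))
  rs[]
}

#' @rdname region_set
#' @param x object to test.
#' @export
is_region_set <- function(x) inherits(x, "region_set")

region_label <- function(x) attr(x, "label") %||% "regions"

#' Read a BED3/BED6 file as a region set
#'
#' 0-based half-open coordinates; `#`-prefixed and `track` lines are skipped.
#' The strand column is parsed but ignored by every downstream statistic.
#'
#' @param path BED file path.
#' @param label set label; default is the file base name.
#' @return A [region_set()].
#' @export
read_bed <- function(path, label = sub("\\.bed$", "", basename(path))) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(region_set(character(), numeric(), numeric(), label = label))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  idx <- which(keep)
  nf <- lengths(parts)
  if (any(nf < 3)) stopf("BED line %d has < 3 fields", idx[which(nf < 3)[1]])
  st <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  en <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(st) | is.na(en) | st < 0 | st >= en)
  if (length(bad))
    stopf("invalid BED interval on line %d: %s", idx[bad[1]], lines[idx[bad[1]]])
  get_col <- function(k) ifelse(nf >= k, vapply(parts, function(p)
    if (length(p) >= k) p[k] else NA_character_, ""), NA_character_)
  sc <- suppressWarnings(as.numeric(get_col(5)))
  region_set(vapply(parts, `[`, "", 1L), st, en,
             name = get_col(4), score = sc, strand = get_col(6),
             label = label)
}

#' Write a region set as BED
#'
#' Emits BED6 when name/score/strand are present, BED3 otherwise; direction,
#' when set, is encoded in the name field as `name:+1` / `name:-1`.
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  dt <- as.data.table(regions)
  has6 <- nrow(dt) > 0 && (any(!is.na(dt$name)) || any(!is.na(dt$score)) ||
                             any(!is.na(dt$strand)))
  if (has6) {
    out <- dt[, .(chrom, start, end,
                  name = fifelse(is.na(direction) | is.na(name), fcoalesce(name, "."),
                                 paste0(name, ":", ifelse(direction > 0, "+1", "-1"))),
                  score = fcoalesce(score, 0), strand = fcoalesce(strand, "."))]
  } else out <- dt[, .(chrom, start, end)]
  fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' Assign regions to genome bins
#'
#' `any_overlap` returns every bin a region intersects; `midpoint` returns the
#' single bin containing `floor((start + end) / 2)` (start-inclusive at exact
#' boundaries). Regions on excluded or unknown chromosomes are skipped with a
#' warning and tallied in the `skipped` attribute.
#'
#' @param regions a [region_set()].
#' @param bins a [make_bins()] object.
#' @param mode `"any_overlap"` or `"midpoint"`.
#' @return data.table (`region` row index, `bin` global index); attribute
#'   `skipped` counts dropped regions.
#' @export
assign_regions_to_bins <- function(regions, bins,
                                   mode = c("any_overlap", "midpoint")) {
  mode <- match.arg(mode)
  dt <- as.data.table(regions)
  if (nrow(dt) == 0) {
    out <- data.table(region = integer(), bin = integer())
    setattr(out, "skipped", 0L)
    return(out)
  }
  off <- .bin_offsets(bins)
  m <- off[J(dt$chrom)]
  known <- !is.na(m$first)
  n_skip <- sum(!known)
  if (n_skip > 0)
    warnf("%d region(s) on excluded/unknown chromosomes skipped", n_skip)
  w <- bins$bin_width
  rows <- which(known)
  if (mode == "midpoint") {
    mid <- (dt$start[rows] + dt$end[rows]) %/% 2
    out <- data.table(region = rows,
                      bin = as.integer(m$first[rows] + mid %/% w))
  } else {
    lo <- dt$start[rows] %/% w
    hi <- pmin((dt$end[rows] - 1) %/% w, (m$len[rows] - 1) %/% w)
    out <- rbindlist(lapply(seq_along(rows), function(i) {
      data.table(region = rows[i],
                 bin = as.integer(m$first[rows[i]] + lo[i]:hi[i]))
    }))
    if (nrow(out) == 0) out <- data.table(region = integer(), bin = integer())
  }
  setattr(out, "skipped", n_skip)
  out[]
}

#' Bins of the retained (autosomal) universe
#' @param bins a [make_bins()] object.
#' @return integer vector of all global bin indices.
#' @export
universe_bins <- function(bins) bins$bins$bin

#' Convert global bin indices back to intervals
#' @param bins a [make_bins()] object.
#' @param idx integer global bin indices.
#' @return data.table chrom, start, end, bin.
#' @export
bins_to_regions <- function(bins, idx) {
  b <- bins$bins
  setkey(b, bin)
  b[J(as.integer(idx)), .(chrom, start, end, bin)]
}
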