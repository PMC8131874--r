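# Count container shared by contacts, 1 Mb mark bins and generic counts.

#' Construct a count matrix with sample metadata
#'
#' @param counts integer matrix, features x samples (rownames = feature ids).
#' @param group per-sample condition label ("EE"/"CTL" or any two levels).
#' @param batch optional per-sample batch label.
#' @param lib_size per-sample library size; defaults to column sums.
#' @return A `count_matrix`: list(counts, samples) where `samples` is a
#'   data.table (sample, group, batch, lib_size).
#' @export
count_matrix <- function(counts, group, batch = NULL, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (length(group) != ncol(counts)) stopf("group length != n samples")
  ls <- lib_size %||% colSums(counts)
  st <- data.table(sample = colnames(counts), group = as.character(group),
                   batch = as.character(batch %||% rep("b1", ncol(counts))),
                   lib_size = as.numeric(ls))
  structure(list(counts = counts, samples = st), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$group), collapse = "/")))
  invisible(x)
}

#' Write / read a count matrix TSV with group and batch header lines
#'
#' Format: `#group` and `#batch` comment lines, then a header row
#' (`id` + sample names) and one row per feature.
#' @param cm a [count_matrix()].
#' @param path file path.
#' @export
write_count_matrix <- function(cm, path) {
  st <- cm$samples
  writeLines(c(paste0("#group\t", paste(st$group, collapse = "\t")),
               paste0("#batch\t", paste(st$batch, collapse = "\t"))), path)
  dt <- data.table(id = rownames(cm$counts))
  dt <- cbind(dt, as.data.table(cm$counts))
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  meta <- readLines(path, n = 2)
  val <- function(k) strsplit(grep(paste0("^#", k), meta, value = TRUE)[1],
                              "\t")[[1]][-1]
  dt <- fread(path, skip = 2, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  count_matrix(m, group = val("group"), batch = val("batch"))
}
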