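# Two-contrast proteomic consistency: delta = phi / beta.

#' Read a two-contrast protein ratio table
#'
#' TSV with columns id, phi, beta: phi = EE1/CTL1, beta = EE2/CTL2 (the two
#' biological contrasts of an iTRAQ design). `#` comment lines tolerated.
#'
#' @param path file path.
#' @return data.table (id, phi, beta), class `ratio_table`.
#' @export
read_ratio_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  setnames(dt, tolower(names(dt)))
  if (!all(c("id", "phi", "beta") %in% names(dt)))
    stopf("ratio table needs columns id, phi, beta")
  if (anyDuplicated(dt$id)) stopf("duplicate protein id in ratio table")
  setattr(dt, "class", c("ratio_table", class(dt)))
  dt[]
}

#' Compute the between-contrast discrepancy delta = phi / beta
#'
#' delta is the raw ratio of the two contrast ratios, with no transformation:
#' replicate-consistent proteins have delta near 1. Proteins with
#' non-positive, missing or non-finite ratios are excluded and reported.
#'
#' @param table data.table with columns id, phi, beta (ratios > 0).
#' @return `delta_result` data.table (id, phi, beta, delta) with an
#'   `excluded` attribute listing dropped proteins and the reason.
#' @export
compute_delta <- function(table) {
  dt <- as.data.table(table)[, .(id, phi = as.numeric(phi),
                                 beta = as.numeric(beta))]
  bad <- !is.finite(dt$phi) | !is.finite(dt$beta) | dt$phi <= 0 | dt$beta <= 0
  excl <- dt[bad][, reason := fifelse(!is.finite(phi) | !is.finite(beta),
                                      "missing", "non-positive")]
  out <- dt[!bad][, delta := phi / beta]
  setattr(out, "excluded", excl)
  setattr(out, "class", c("delta_result", class(out)))
  out[]
}

#' Partition proteins by delta-consistency
#'
#' A protein is consistent when `|delta - 1| <= tolerance` (boundary
#' inclusive), default tolerance 0.1. Note the asymmetry of the raw-scale
#' rule under contrast swap: `|1/delta - 1| != |delta - 1|` in general, so a
#' protein can be consistent for (phi, beta) but not (beta, phi). The
#' `log_symmetric` option uses `|log2 delta| <= log2(1 + tolerance)` instead,
#' which is swap-symmetric.
#'
#' @param delta a [compute_delta()] result.
#' @param tolerance consistency half-width on the raw delta scale.
#' @param log_symmetric use the swap-symmetric log-scale rule.
#' @return list: `consistent`, `discrepant` (data.tables), `summary`
#'   (counts), `tolerance`.
#' @export
select_consistent <- function(delta, tolerance = 0.1, log_symmetric = FALSE) {
  if (tolerance <= 0) stopf("tolerance must be > 0")
  dt <- as.data.table(delta)
  eps <- 1e-12   # boundary-inclusive despite floating-point ratios
  ok <- if (log_symmetric) abs(log2(dt$delta)) <= log2(1 + tolerance) + eps
        else abs(dt$delta - 1) <= tolerance + eps
  list(consistent = dt[ok], discrepant = dt[!ok],
       summary = c(consistent = sum(ok), discrepant = sum(!ok),
                   total = nrow(dt)),
       tolerance = tolerance)
}
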