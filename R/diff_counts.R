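# Differential count engine: normalization, RUV factors, NB dispersion,
# batched NB GLM with likelihood-ratio tests, BH-FDR, and the
# select-and-intersect batch strategy.

.effective_lib <- function(cm, norm = NULL) {
  ls <- cm$samples$lib_size
  if (!is.null(norm)) ls <- ls * norm$factors
  ls
}

#' Counts per million / reads per kilobase per million
#'
#' `cpm = count / effective library size * 1e6`; `rpkm = cpm / (length/1e3)`.
#' Effective library size is the raw library size times the TMM factor when
#' `norm` is supplied.
#'
#' @param cm a [count_matrix()].
#' @param norm optional [tmm_factors()] result.
#' @return real matrix, same dimensions as the counts.
#' @export
cpm <- function(cm, norm = NULL) {
  ls <- .effective_lib(cm, norm)
  if (any(ls <= 0)) stopf("zero library size")
  sweep(cm$counts, 2, ls, "/") * 1e6
}

#' @rdname cpm
#' @param lengths per-feature lengths in bp (> 0).
#' @export
rpkm <- function(cm, lengths, norm = NULL) {
  if (any(lengths <= 0)) stopf("feature lengths must be positive")
  cpm(cm, norm) / (lengths / 1e3)
}

# --- TMM -------------------------------------------------------------------

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) < 10) {
    warnf("fewer than 10 usable features for TMM pair; factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  2^f
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Per-sample scaling factors from the weighted trimmed mean of log ratios
#' against a reference sample (the one whose upper-quartile CPM is closest to
#' the mean), trimming 30% of M-values and 5% of A-values, weights equal to
#' the inverse asymptotic (delta-method) variance. Factors are rescaled to
#' geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @param ref_sample optional reference column name or index.
#' @param logratio_trim,sum_trim trim fractions for M and A.
#' @return list (class `norm_factors`): `factors` (named, geometric mean 1),
#'   `ref` (reference sample name).
#' @export
tmm_factors <- function(cm, ref_sample = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  y <- cm$counts
  if (ncol(y) < 2) stopf("TMM needs >= 2 samples")
  ls <- cm$samples$lib_size
  if (is.null(ref_sample)) {
    f75 <- apply(y, 2, function(x) quantile(x, p = 0.75)) / ls
    ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(y)))
           else which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(y))
           else as.integer(ref_sample)
  }
  f <- vapply(seq_len(ncol(y)), function(j)
    if (j == ref) 1 else .tmm_pair(y[, j], y[, ref], ls[j], ls[ref],
                                   logratio_trim, sum_trim), 0)
  f <- f / exp(mean(log(f)))
  structure(list(factors = setNames(f, colnames(y)),
                 ref = colnames(y)[ref]), class = "norm_factors")
}

# --- BH --------------------------------------------------------------------

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j` where m counts only non-NA p-values;
#' NA inputs yield NA outputs and do not enter m.
#'
#' @param p numeric p-values in `[0, 1]` (NAs allowed).
#' @return q-values, same length/order as `p`.
#' @export
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  o <- ok[order(p[ok])]
  q[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q
}

# --- RUV factors -----------------------------------------------------------

.unit_var <- function(W) {
  if (ncol(W) == 0) return(W)
  s <- apply(W, 2, sd)
  if (any(s < 1e-12)) stopf("degenerate (constant) unwanted-variation factor")
  sweep(W, 2, s, "/")
}

new_ruv <- function(W, k, variant, control_ids = NULL) {
  structure(list(W = W, k = k, variant = variant, control_ids = control_ids),
            class = "ruv_factors")
}

#' RUVg: unwanted-variation factors from control features
#'
#' Rows of `log(count + 0.5)` for the control features are centered, and W is
#' the first k left singular vectors on the sample side of the resulting
#' samples x controls matrix, scaled to unit variance.
#'
#' @param cm a [count_matrix()].
#' @param control_ids feature ids assumed unaffected by the condition.
#' @param k number of factors (>= 1; `k = 0` returns an empty W).
#' @return `ruv_factors` list: W (samples x k), k, variant, control_ids.
#' @export
ruv_g <- function(cm, control_ids, k = 1) {
  n <- ncol(cm$counts)
  if (k >= n) stopf("k must be < number of samples")
  if (k == 0) return(new_ruv(matrix(0, n, 0), 0L, "g", control_ids))
  miss <- setdiff(control_ids, rownames(cm$counts))
  if (length(miss)) stopf("unknown control feature: %s", miss[1])
  if (length(control_ids) < k + 1) stopf("need > k control features")
  z <- log(cm$counts[control_ids, , drop = FALSE] + 0.5)
  z <- z - rowMeans(z)
  sv <- svd(t(z))
  if (sv$d[k] < 1e-10)
    stopf("control features are constant across samples (zero singular value)")
  new_ruv(.unit_var(sv$u[, seq_len(k), drop = FALSE]), as.integer(k), "g",
          control_ids)
}

#' RUVr: unwanted-variation factors from first-pass residuals
#'
#' log-CPM is regressed on the group design by least squares; W is the first
#' k sample-side singular vectors of the residual matrix.
#'
#' @inheritParams ruv_g
#' @export
ruv_r <- function(cm, k = 1) {
  n <- ncol(cm$counts)
  g <- as.integer(cm$samples$group == cm$samples$group[1])
  X <- cbind(1, g)
  if (k >= n - qr(X)$rank) stopf("k must be < n_samples - rank(design)")
  if (k == 0) return(new_ruv(matrix(0, n, 0), 0L, "r"))
  L <- log(cpm(cm) + 0.5)
  H <- X %*% solve(crossprod(X), t(X))
  R <- L - L %*% t(H)
  if (max(abs(R)) < 1e-10) stopf("residuals are zero; no estimable factor")
  sv <- svd(t(R))
  new_ruv(.unit_var(sv$u[, seq_len(k), drop = FALSE]), as.integer(k), "r")
}

#' RUVs: unwanted-variation factors from within-group replicate differences
#'
#' `log(count + 0.5)` of the control features (default: all features) is
#' centered within each condition group, removing the condition effect; W is
#' the first k sample-side singular vectors of the centered matrix.
#'
#' @inheritParams ruv_g
#' @export
ruv_s <- function(cm, control_ids = NULL, k = 1) {
  n <- ncol(cm$counts)
  if (k >= n) stopf("k must be < number of samples")
  if (k == 0) return(new_ruv(matrix(0, n, 0), 0L, "s", control_ids))
  ids <- control_ids %||% rownames(cm$counts)
  z <- log(cm$counts[ids, , drop = FALSE] + 0.5)
  for (g in unique(cm$samples$group)) {
    j <- which(cm$samples$group == g)
    z[, j] <- z[, j] - rowMeans(z[, j, drop = FALSE])
  }
  if (max(abs(z)) < 1e-10) stopf("no within-group variation; no estimable factor")
  sv <- svd(t(z))
  new_ruv(.unit_var(sv$u[, seq_len(k), drop = FALSE]), as.integer(k), "s", ids)
}

# --- NB GLM machinery ------------------------------------------------------

# NB deviance, phi per feature (0 => Poisson limit), y/mu are F x S.
.nb_deviance <- function(y, mu, phi) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  pois <- phi < 1e-12
  t2 <- matrix(0, nrow(y), ncol(y))
  if (any(!pois)) {
    ph <- phi[!pois]
    ys <- y[!pois, , drop = FALSE]; ms <- mu[!pois, , drop = FALSE]
    t2[!pois, ] <- (ys + 1 / ph) * log((1 + ph * ys) / (1 + ph * ms))
  }
  if (any(pois)) {
    ys <- y[pois, , drop = FALSE]; ms <- mu[pois, , drop = FALSE]
    t2[pois, ] <- ys - ms
  }
  2 * rowSums(t1 - t2)
}

# Solve per-feature p x p normal equations A b = r, A given as a list of
# F-vectors for the upper triangle. Closed forms for p <= 3, loop otherwise.
.solve_batch <- function(A, r, p) {
  F <- length(r[[1]])
  if (p == 1) return(matrix(r[[1]] / A[["11"]], F, 1))
  if (p == 2) {
    det <- A[["11"]] * A[["22"]] - A[["12"]]^2
    return(cbind((A[["22"]] * r[[1]] - A[["12"]] * r[[2]]) / det,
                 (A[["11"]] * r[[2]] - A[["12"]] * r[[1]]) / det))
  }
  if (p == 3) {
    a <- A[["11"]]; b <- A[["12"]]; c <- A[["13"]]
    d <- A[["22"]]; e <- A[["23"]]; f <- A[["33"]]
    det <- a * (d * f - e * e) - b * (b * f - c * e) + c * (b * e - c * d)
    i11 <- d * f - e * e; i12 <- c * e - b * f; i13 <- b * e - c * d
    i22 <- a * f - c * c; i23 <- b * c - a * e; i33 <- a * d - b * b
    return(cbind((i11 * r[[1]] + i12 * r[[2]] + i13 * r[[3]]) / det,
                 (i12 * r[[1]] + i22 * r[[2]] + i23 * r[[3]]) / det,
                 (i13 * r[[1]] + i23 * r[[2]] + i33 * r[[3]]) / det))
  }
  out <- matrix(NA_real_, F, p)
  for (i in seq_len(F)) {
    M <- matrix(0, p, p)
    for (a in 1:p) for (b in a:p) {
      M[a, b] <- M[b, a] <- A[[paste0(a, b)]][i]
    }
    out[i, ] <- solve(M, vapply(r, `[`, 0, i))
  }
  out
}

# log det(X' W X) per feature, given working weights w (F x S); closed form
# for p <= 3 via the same cross-product vectors used by .solve_batch.
.xtwx_logdet <- function(w, Xcross, p) {
  A <- lapply(Xcross, function(xx) as.vector(w %*% xx) + 1e-10)
  if (p == 1) return(log(pmax(A[["11"]], 1e-300)))
  if (p == 2) return(log(pmax(A[["11"]] * A[["22"]] - A[["12"]]^2, 1e-300)))
  if (p == 3) {
    a <- A[["11"]]; b <- A[["12"]]; c <- A[["13"]]
    d <- A[["22"]]; e <- A[["23"]]; f <- A[["33"]]
    return(log(pmax(a * (d * f - e * e) - b * (b * f - c * e) +
                      c * (b * e - c * d), 1e-300)))
  }
  F <- length(A[["11"]])
  out <- numeric(F)
  for (i in seq_len(F)) {
    M <- matrix(0, p, p)
    for (x in 1:p) for (y in x:p) M[x, y] <- M[y, x] <- A[[paste0(x, y)]][i]
    out[i] <- determinant(M, logarithm = TRUE)$modulus
  }
  out
}

# Batched IRLS fit of NB GLMs with log link and a shared design across
# features. Y: F x S counts; X: S x p design; offset: length-S log effective
# library sizes; phi: length-F dispersions.
.fit_nb_batch <- function(Y, X, offset, phi, max_iter = 50, tol = 1e-8) {
  F <- nrow(Y); S <- ncol(Y); p <- ncol(X)
  offm <- matrix(offset, F, S, byrow = TRUE)
  beta <- matrix(0, F, p)
  beta[, 1] <- log(rowMeans(Y / exp(offm)) + 1e-8)
  Xcross <- list()
  for (a in 1:p) for (b in a:p)
    Xcross[[paste0(a, b)]] <- X[, a] * X[, b]
  converged <- rep(FALSE, F)
  for (it in seq_len(max_iter)) {
    eta <- offm + tcrossprod(beta, X)
    mu <- pmin(pmax(exp(eta), 1e-10), 1e10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offm) + (Y - mu) / mu
    A <- lapply(Xcross, function(xx) as.vector(w %*% xx) + 1e-10)
    r <- lapply(1:p, function(a) as.vector((w * z) %*% X[, a]))
    newb <- .solve_batch(A, r, p)
    step <- abs(newb - beta)
    bad <- !is.finite(newb)
    if (any(bad)) newb[bad] <- beta[bad]
    beta <- newb
    done <- apply(step, 1, max) < tol
    converged <- converged | done
    if (all(done)) break
  }
  eta <- offm + tcrossprod(beta, X)
  mu <- pmin(pmax(exp(eta), 1e-10), 1e10)
  list(beta = beta, mu = mu, deviance = .nb_deviance(Y, mu, phi),
       converged = converged)
}

#' Estimate NB dispersions (common + per-feature shrunk)
#'
#' Fitted means come from a Poisson fit on the full design (group plus any
#' unwanted-variation covariates). The common dispersion maximizes the pooled
#' NB profile likelihood; per-feature dispersions maximize the feature
#' likelihood on a grid and are shrunk toward the common value with a prior
#' weight of `w0` pseudo-samples:
#' `phi_i = (S * phi_opt_i + w0 * phi_common) / (S + w0)`.
#'
#' @param cm a [count_matrix()].
#' @param W optional sample covariate matrix ([ruv_g()]/[ruv_r()] `$W`).
#' @param norm optional [tmm_factors()].
#' @param w0 prior weight (pseudo-samples) for shrinkage toward common.
#' @return list (class `dispersion_fit`): `common`, `phi` (per feature, NA
#'   for all-zero features), `flagged` (ids of all-zero features).
#' @export
estimate_dispersion <- function(cm, W = NULL, norm = NULL, w0 = 20) {
  Y <- cm$counts
  zero <- rowSums(Y) == 0
  ids <- rownames(Y)
  Yt <- Y[!zero, , drop = FALSE]
  g <- as.integer(cm$samples$group == unique(cm$samples$group)[1])
  X <- cbind(1, g)
  if (!is.null(W) && ncol(W) > 0) X <- cbind(X, W)
  offset <- log(.effective_lib(cm, norm))
  S <- ncol(Yt)
  p <- ncol(X)
  Xcross <- list()
  for (a in 1:p) for (b in a:p)
    Xcross[[paste0(a, b)]] <- X[, a] * X[, b]
  # Cox-Reid adjusted profile likelihood: the per-feature means consume
  # p of the S sample df, which the naive profile ignores (it collapses
  # the dispersion toward 0 at S = 4, p = 3); subtracting
  # 0.5 * log det(X'WX) restores an approximately unbiased estimate.
  apl <- function(phi, mu) {
    w <- mu / (1 + phi * mu)
    rowSums(dnbinom(Yt, size = 1 / phi, mu = mu, log = TRUE)) -
      0.5 * .xtwx_logdet(w, Xcross, p)
  }
  fit0 <- .fit_nb_batch(Yt, X, offset, phi = rep(0, nrow(Yt)))
  mu <- fit0$mu
  common <- optimize(function(ph) -sum(apl(ph, mu)), c(1e-6, 5))$minimum
  # one mean refit at the common dispersion, then re-profile
  fit1 <- .fit_nb_batch(Yt, X, offset, phi = rep(common, nrow(Yt)))
  mu <- fit1$mu
  common <- optimize(function(ph) -sum(apl(ph, mu)), c(1e-6, 5))$minimum
  grid <- exp(seq(log(1e-6), log(5), length.out = 31))
  ll <- vapply(grid, function(ph) apl(ph, mu), numeric(nrow(Yt)))
  opt <- grid[max.col(ll, ties.method = "first")]
  phi_t <- (S * opt + w0 * common) / (S + w0)
  phi <- rep(NA_real_, nrow(Y))
  phi[!zero] <- phi_t
  structure(list(common = common, phi = setNames(phi, ids),
                 flagged = ids[zero]), class = "dispersion_fit")
}

#' NB GLM differential test (likelihood-ratio, group coefficient)
#'
#' Per feature, a negative-binomial log-linear model with offset
#' `log(effective library size)` and design `[intercept, group, W]` is fitted
#' by IRLS; the p-value is the chi-square likelihood-ratio test of the group
#' coefficient, and log2FC is the group coefficient on the log2 scale
#' (first condition level vs second). BH-FDR is appended. All-zero and
#' non-converged features get `p = NA` and are excluded from the BH
#' denominator.
#'
#' @param cm a [count_matrix()].
#' @param W optional unwanted-variation covariates (samples x k).
#' @param norm optional [tmm_factors()].
#' @param dispersion optional [estimate_dispersion()] result (estimated
#'   internally when missing).
#' @param contrast character of length 2: (numerator, denominator) condition
#'   levels; default `c("EE", "CTL")` when present, else first vs second
#'   observed level.
#' @return `diff_result` data.table: id, log2FC, p, q, direction, test.
#' @export
nb_glm_test <- function(cm, W = NULL, norm = NULL, dispersion = NULL,
                        contrast = NULL) {
  Y <- cm$counts
  lev <- unique(cm$samples$group)
  if (is.null(contrast))
    contrast <- if (all(c("EE", "CTL") %in% lev)) c("EE", "CTL") else lev[1:2]
  g <- as.integer(cm$samples$group == contrast[1])
  if (length(unique(g)) < 2) stopf("both contrast levels must be present")
  Wm <- if (!is.null(W) && ncol(W) > 0) W else NULL
  Xf <- cbind(1, g); if (!is.null(Wm)) Xf <- cbind(Xf, Wm)
  Xn <- cbind(rep(1, length(g))); if (!is.null(Wm)) Xn <- cbind(Xn, Wm)
  if (qr(Xf)$rank < ncol(Xf)) stopf("design matrix [intercept, group, W] not full rank")
  offset <- log(.effective_lib(cm, norm))
  if (is.null(dispersion)) dispersion <- estimate_dispersion(cm, W = Wm, norm = norm)
  zero <- rowSums(Y) == 0
  Yt <- Y[!zero, , drop = FALSE]
  phi <- dispersion$phi[rownames(Yt)]
  phi[is.na(phi)] <- dispersion$common
  full <- .fit_nb_batch(Yt, Xf, offset, phi)
  null <- .fit_nb_batch(Yt, Xn, offset, phi)
  lrt <- pmax(null$deviance - full$deviance, 0)
  pval <- pchisq(lrt, df = 1, lower.tail = FALSE)
  ok <- full$converged & null$converged
  pval[!ok] <- NA_real_
  lfc <- full$beta[, 2] / log(2)
  res <- data.table(id = rownames(Y), log2FC = NA_real_, p = NA_real_)
  res[!zero, `:=`(log2FC = lfc, p = pval)]
  res[, q := bh_fdr(p)]
  res[, direction := fifelse(is.na(log2FC), NA_integer_,
                             fifelse(log2FC >= 0, 1L, -1L))]
  res[, test := "nb_glm_lrt"]
  setattr(res, "contrast", contrast)
  setattr(res, "class", c("diff_result", class(res)))
  res[]
}

# mean silhouette of the two groups on PC1 of a samples x features matrix
.pc1_silhouette <- function(mat_sf, group) {
  pc1 <- prcomp(mat_sf, center = TRUE, scale. = FALSE)$x[, 1]
  s <- vapply(seq_along(pc1), function(i) {
    same <- setdiff(which(group == group[i]), i)
    a <- mean(abs(pc1[i] - pc1[same]))
    b <- mean(abs(pc1[i] - pc1[group != group[i]]))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Empirically stable features for use as RUVg controls
#'
#' Bin-pairs (or generic features) in the top decile of mean raw count whose
#' log-CPM variance is below the median; falls back to the top-mean decile
#' alone when too few qualify.
#'
#' @param cm a [count_matrix()].
#' @param k minimum number of controls needed downstream.
#' @return character vector of feature ids.
#' @export
stable_controls <- function(cm, k = 1) {
  mu <- rowMeans(cm$counts)
  v <- apply(log(cpm(cm) + 0.5), 1, var)
  top <- mu >= quantile(mu, 0.9)
  ids <- rownames(cm$counts)[top & v <= median(v)]
  if (length(ids) < k + 2) ids <- rownames(cm$counts)[top]
  ids
}

#' Select qualifying RUV variants and intersect their calls
#'
#' Each requested variant (g / r / s) is "qualifying" when, after regressing
#' its W out of log-CPM, the top principal component separates the two
#' conditions (positive mean silhouette of the group split on PC1). The
#' engine is run once per qualifying variant and the final call set is the
#' intersection of features significant at `fdr` in every qualifying variant.
#'
#' @param cm a [count_matrix()].
#' @param strategies subset of `c("g", "r", "s")`.
#' @param k number of unwanted factors per variant.
#' @param fdr BH threshold for the intersection (default 0.1).
#' @param control_ids RUVg/RUVs controls; default [stable_controls()].
#' @return list: `results` (per-variant `diff_result`), `qualified`,
#'   `selected` (intersected ids), `table` (id + per-variant q + selected).
#' @export
select_and_intersect <- function(cm, strategies = c("g", "r", "s"), k = 1,
                                 fdr = 0.1, control_ids = NULL) {
  strategies <- match.arg(strategies, c("g", "r", "s"), several.ok = TRUE)
  ctrl <- control_ids %||% stable_controls(cm, k)
  L <- log(cpm(cm) + 0.5)
  group <- cm$samples$group
  norm <- tmm_factors(cm)
  results <- list(); qualified <- character()
  for (v in strategies) {
    W <- switch(v, g = ruv_g(cm, ctrl, k), r = ruv_r(cm, k),
                s = ruv_s(cm, ctrl, k))$W
    Xw <- cbind(1, W)
    H <- Xw %*% solve(crossprod(Xw) + diag(1e-10, ncol(Xw)), t(Xw))
    resid <- L - L %*% t(H)
    sil <- .pc1_silhouette(t(resid), group)
    if (sil > 0) {
      qualified <- c(qualified, v)
      results[[v]] <- nb_glm_test(cm, W = W, norm = norm)
    }
  }
  if (length(qualified) == 0)
    return(list(results = list(), qualified = character(),
                selected = character(),
                table = data.table(id = rownames(cm$counts))))
  sel <- Reduce(intersect, lapply(results, function(r)
    r[!is.na(q) & q < fdr, id]))
  tab <- data.table(id = rownames(cm$counts))
  for (v in qualified) tab[, (paste0("q_", v)) := results[[v]]$q]
  tab[, selected := id %in% sel]
  list(results = results, qualified = qualified, selected = sel, table = tab)
}

#' Differential contact analysis of a merged, filtered contact table
#'
#' Features are bin-pairs. Intra tables use RUVr covariates, inter tables
#' RUVg with empirically stable bin-pairs as controls (the named upstream
#' convention: residual-based factors for intra, control-based for inter).
#' Counts are TMM-normalized and tested with the NB GLM LRT; calls are split
#' by direction at the stated FDR.
#'
#' @param table multi-sample `contact_table` (after [filter_contacts()]).
#' @param k number of unwanted-variation factors (default 1).
#' @param fdr call threshold (default 0.05).
#' @param control_ids optional explicit RUVg controls (inter only).
#' @return list: `result` (`diff_result` with bin1/bin2 columns),
#'   `increased`, `decreased` (subsets at `q < fdr`), `ruv` (factors used).
#' @export
diff_contact_analysis <- function(table, k = 1, fdr = 0.05,
                                  control_ids = NULL) {
  dt <- as.data.table(table)
  st <- contact_samples(table)
  scol <- st$sample
  Y <- as.matrix(dt[, ..scol])
  rownames(Y) <- paste0(dt$bin1, "_", dt$bin2)
  cm <- count_matrix(Y, group = st$group, batch = st$batch)
  norm <- tmm_factors(cm)
  cls <- attr(table, "contact_class")
  ruv <- if (k == 0) NULL
         else if (cls == "intra") ruv_r(cm, k)
         else ruv_g(cm, control_ids %||% stable_controls(cm, k), k)
  W <- if (is.null(ruv)) NULL else ruv$W
  res <- nb_glm_test(cm, W = W, norm = norm)
  res[, `:=`(bin1 = dt$bin1, bin2 = dt$bin2)]
  list(result = res,
       increased = res[!is.na(q) & q < fdr & log2FC > 0],
       decreased = res[!is.na(q) & q < fdr & log2FC < 0],
       ruv = ruv)
}

#' Differential 1 Mb mark bins
#'
#' The NB GLM engine applied to per-bin coverage counts (feature ids are
#' global bin indices); emits up/down region sets directly consumable by the
#' permutation association, replacing a sliding-window differential caller
#' with the same binned NB test used for contacts.
#'
#' @param cm a [count_matrix()] whose feature ids are global bin indices of
#'   `bins`.
#' @param bins the [make_bins()] universe (at the inter-chromosomal width).
#' @param fdr call threshold (default 0.05).
#' @param k unwanted-variation factors (RUVr); 0 disables.
#' @param label prefix for the emitted region-set labels.
#' @return list: `result` (`diff_result`), `up`, `down` ([region_set()]s of
#'   called bins, direction encoded).
#' @export
diff_mark_bins <- function(cm, bins, fdr = 0.05, k = 0, label = "mark") {
  norm <- tmm_factors(cm)
  W <- if (k > 0) ruv_r(cm, k)$W else NULL
  res <- nb_glm_test(cm, W = W, norm = norm)
  mk <- function(sub, dir, lab) {
    if (nrow(sub) == 0)
      return(region_set(character(), numeric(), numeric(), label = lab))
    reg <- bins_to_regions(bins, as.integer(sub$id))
    region_set(reg$chrom, reg$start, reg$end, name = as.character(sub$id),
               score = -log10(pmax(sub$q, 1e-300)), direction = dir,
               label = lab)
  }
  list(result = res,
       up = mk(res[!is.na(q) & q < fdr & log2FC > 0], 1L,
               paste0(label, "_up")),
       down = mk(res[!is.na(q) & q < fdr & log2FC < 0], -1L,
                 paste0(label, "_down")))
}

#' Write a differential result as TSV
#' @param res a `diff_result`.
#' @param path output path.
#' @export
write_diff_result <- function(res, path) {
  fwrite(as.data.table(res), path, sep = "\t")
  invisible(path)
}
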