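#' Filter genes by minimum count in a minimum number of samples
#'
#' A gene is retained iff its count is at least `min_count` in at least
#' `min_samples` samples.
#'
#' @param counts Count matrix (genes x samples) with rownames.
#' @param min_count Minimum count (default 1).
#' @param min_samples Minimum number of samples meeting it (default 3).
#' @return Character vector of retained gene ids.
#' @export
filter_min_count <- function(counts, min_count = 1, min_samples = 3) {
  keep <- rowSums(counts >= min_count) >= min_samples
  rownames(counts)[keep]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values (Robinson & Oshlack): the reference sample is
#' the one whose 75th-percentile count fraction is closest to the mean of
#' those; per-sample log2 count-fraction ratios (M) against the reference
#' and average log2 abundances (A) are computed over genes positive in both
#' samples, doubly trimmed (30% each tail on M, 5% on A by default), and the
#' factor is two to the precision-weighted mean of the surviving M values
#' (weights from the inverse binomial variance approximation). Factors are
#' finally scaled to geometric mean 1.
#'
#' @param counts Count matrix (genes x samples).
#' @param logratio_trim Two-sided trim fraction on M (default 0.3).
#' @param abs_trim Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) stats::quantile(counts[, j] / lib[j], 0.75,
                                            names = FALSE),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]
  one_factor <- function(j) {
    yk <- counts[, j]
    pos <- yk > 0 & yr > 0
    if (!any(pos)) stop("sample ", j, " shares no positive genes with ",
                        "the reference sample")
    yk <- yk[pos]; yrp <- yr[pos]
    M <- log2((yk / lib[j]) / (yrp / lib[ref]))
    A <- 0.5 * log2((yk / lib[j]) * (yrp / lib[ref]))
    v <- (lib[j] - yk) / (lib[j] * yk) + (lib[ref] - yrp) / (lib[ref] * yrp)
    w <- 1 / v
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    f <- sum(w[keep] * M[keep]) / sum(w[keep])
    if (!is.finite(f)) f <- 0
    2^f
  }
  fac <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(counts))
}

#' log2 counts per million
#'
#' `log2((count + prior) / (library_size * factor + 2 * prior) * 1e6)`.
#'
#' @param counts Count matrix (genes x samples).
#' @param factors Per-sample normalization factors (default all 1).
#' @param prior_count Pseudo-count (default 0.5).
#' @param lib_sizes Optional library sizes (default column sums).
#' @return Matrix of log2 CPM values.
#' @export
logcpm <- function(counts, factors = NULL, prior_count = 0.5,
                   lib_sizes = NULL) {
  lib <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  stopifnot(all(factors > 0))
  eff <- lib * factors
  t(log2(t(counts + prior_count) / (eff + 2 * prior_count) * 1e6))
}

#' Metric MDS coordinates from leading log-fold-change distances
#'
#' The distance between two samples is the root mean square of the `top`
#' largest absolute logCPM differences for that pair (genes selected per
#' pair). Classical (Torgerson) metric MDS of the distance matrix gives the
#' plotting coordinates; the first two principal coordinates are returned.
#'
#' @param y logCPM matrix (genes x samples).
#' @param top Number of top genes per pair (default 500; capped at the
#'   number of genes).
#' @return List with `coords` (samples x 2) and `dist` (distance matrix).
#' @export
mds_coordinates <- function(y, top = 500) {
  n <- ncol(y)
  stopifnot(n >= 3L)
  top <- min(top, nrow(y))
  d <- matrix(0, n, n, dimnames = list(colnames(y), colnames(y)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sq <- (y[, i] - y[, j])^2
      d[i, j] <- d[j, i] <-
        sqrt(mean(sort(sq, decreasing = TRUE)[seq_len(top)]))
    }
  }
  cmd <- stats::cmdscale(stats::as.dist(d), k = 2)
  colnames(cmd) <- c("dim1", "dim2")
  list(coords = cmd, dist = d)
}

#' voom-style precision weights
#'
#' Computes logCPM (prior 0.5, effective library + 1), fits an unweighted
#' linear model per gene, regresses the square-root residual standard
#' deviations on average log2 count with lowess (span 0.5), evaluates the
#' trend at each observation's predicted log2 count, and returns weights
#' equal to the trend to the power -4. Predicted log counts outside the
#' lowess range are clipped to the boundary trend values.
#'
#' @param counts Count matrix (genes x samples).
#' @param factors Normalization factors (default all 1).
#' @param design Design matrix (samples x coefficients), full rank.
#' @param span lowess span (default 0.5).
#' @return List with `logcpm` and `weights` matrices (genes x samples).
#' @export
voom_weights <- function(counts, factors = NULL, design, span = 0.5) {
  lib <- colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  eff <- lib * factors
  if (qr(design)$rank < ncol(design)) stop("design is not full rank")
  y <- t(log2(t(counts + 0.5) / (eff + 1) * 1e6))
  qrX <- qr(design)
  coefs <- t(qr.coef(qrX, t(y)))
  resid <- t(qr.resid(qrX, t(y)))
  df_resid <- nrow(design) - ncol(design)
  if (df_resid < 1L) stop("no residual degrees of freedom")
  sigma <- sqrt(rowSums(resid^2) / df_resid)
  sx <- rowMeans(y) + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- stats::lowess(sx, sy, f = span)
  trend_at <- stats::approxfun(lo, rule = 2, ties = mean)
  fitted_logcpm <- coefs %*% t(design)
  fitted_logcount <- t(t(fitted_logcpm) + log2(eff + 1)) - log2(1e6)
  w <- trend_at(fitted_logcount)^-4
  w <- matrix(w, nrow = nrow(y), dimnames = dimnames(y))
  list(logcpm = y, weights = w)
}

# Inverse of the trigamma function by Newton iteration.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Per-gene linear models with empirical-Bayes variance moderation
#'
#' Weighted least squares per gene, followed by moment-matching estimation
#' of the prior degrees of freedom d0 and prior variance s0^2 from the
#' distribution of log residual variances (digamma/trigamma method), and
#' moderated t-statistics for one contrast with d + d0 degrees of freedom.
#' The moderated variance is `(d0 s0^2 + d s^2) / (d0 + d)`; infinite d0
#' collapses it to s0^2.
#'
#' @param y logCPM matrix (genes x samples).
#' @param weights Observation weights, same shape (NULL for unweighted).
#' @param design Design matrix (samples x p), full rank.
#' @param contrast Numeric vector of length p.
#' @return List of class `dge_fit`: table (data.frame gene, coef, t, p, fdr,
#'   s2, df), d0, s02.
#' @export
fit_and_moderate <- function(y, weights = NULL, design, contrast) {
  n <- ncol(y)
  p <- ncol(design)
  stopifnot(length(contrast) == p)
  if (is.null(weights)) weights <- matrix(1, nrow(y), n)
  G <- nrow(y)
  coef_c <- se_u <- s2 <- numeric(G)
  d <- n - p
  for (g in seq_len(G)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    Xw <- design * sw
    yw <- y[g, ] * sw
    fit <- stats::lm.fit(Xw, yw)
    XtX_inv <- chol2inv(chol(crossprod(Xw)))
    coef_c[g] <- sum(contrast * fit$coefficients)
    se_u[g] <- sqrt(drop(t(contrast) %*% XtX_inv %*% contrast))
    s2[g] <- sum(fit$residuals^2) / d
  }
  if (d < 1L) stop("zero residual degrees of freedom: moderation impossible")
  mm <- moderate_variances(s2, d)
  s2_post <- if (is.infinite(mm$d0)) rep(mm$s02, G)
             else (mm$d0 * mm$s02 + d * s2) / (mm$d0 + d)
  tstat <- coef_c / (se_u * sqrt(s2_post))
  df_total <- d + mm$d0
  pval <- 2 * stats::pt(-abs(tstat),
                        df = if (is.infinite(df_total)) Inf else df_total)
  tab <- data.frame(gene = rownames(y) %||% as.character(seq_len(G)),
                    coef = coef_c, t = tstat, p = pval,
                    fdr = stats::p.adjust(pval, "BH"),
                    s2 = s2, df = d, stringsAsFactors = FALSE)
  structure(list(table = tab, d0 = mm$d0, s02 = mm$s02, df_residual = d),
            class = "dge_fit")
}

#' Moment-matching estimate of the variance prior
#'
#' Fits a scaled inverse-chi-square prior to observed residual variances by
#' matching moments of log s^2: with e = log(s2) - digamma(d/2) + log(d/2),
#' the excess variance of e over trigamma(d/2) determines d0 via the inverse
#' trigamma, and the mean determines s0^2. A non-positive excess yields
#' d0 = Inf (variances fully shrunk to s0^2); with a single gene no
#' moderation is possible and d0 = 0 (ordinary t).
#'
#' @param s2 Per-gene residual variances.
#' @param d Residual degrees of freedom (scalar).
#' @return List with d0 and s02.
#' @export
moderate_variances <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    return(list(d0 = 0, s02 = if (any(ok)) mean(s2[ok]) else NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Call differentially expressed genes at an FDR threshold
#'
#' Benjamini-Hochberg adjusted p-values below `alpha` are significant;
#' significant genes are split by the sign of the contrast estimate.
#'
#' @param fit A `dge_fit` from [fit_and_moderate()].
#' @param alpha FDR threshold (default 0.05).
#' @return List with `up`, `down` (character vectors of gene ids) and
#'   `table` (the fit table restricted to significant genes).
#' @export
call_degs <- function(fit, alpha = 0.05) {
  tab <- fit$table
  sig <- tab$fdr < alpha
  list(up = tab$gene[sig & tab$coef > 0],
       down = tab$gene[sig & tab$coef < 0],
       table = tab[sig, , drop = FALSE])
}

#' Counts of all Venn regions of named gene sets
#'
#' @param sets Named list of character vectors.
#' @return data.frame with one row per non-empty combination of set
#'   memberships: a logical column per set, and `count` of elements falling
#'   exactly in that region.
#' @export
set_overlap <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  all_ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_ids %in% s,
                 logical(length(all_ids)))
  if (length(all_ids) == 1L) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, paste, collapse = "")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  combos$count <- vapply(seq_len(nrow(combos)), function(i) {
    k <- paste(unlist(combos[i, names(sets)]), collapse = "")
    sum(key == k)
  }, numeric(1))
  rownames(combos) <- NULL
  combos
}

#' Flag potential expression outlier samples by hierarchical clustering
#'
#' Average-linkage clustering of Euclidean distances between sample logCPM
#' profiles; a sample is flagged when the height at which it first joins any
#' cluster exceeds the median joining height by `k` MADs. Flag-only: nothing
#' is dropped automatically.
#'
#' @param y logCPM matrix (genes x samples).
#' @param k MAD multiplier (default 2).
#' @return data.frame: sample, join_height, flagged.
#' @export
flag_expression_outliers <- function(y, k = 2) {
  d <- stats::dist(t(y))
  hc <- stats::hclust(d, method = "average")
  n <- ncol(y)
  join <- numeric(n)
  for (i in seq_len(nrow(hc$merge))) {
    for (m in hc$merge[i, ]) {
      if (m < 0) join[-m] <- hc$height[i]
    }
  }
  med <- stats::median(join)
  mad_ <- stats::mad(join)
  data.frame(sample = colnames(y), join_height = join,
             flagged = mad_ > 0 & join > med + k * mad_,
             stringsAsFactors = FALSE)
}
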