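#' Filter genes by minimum FPKM in a minimum number of samples
#'
#' @param fpkm FPKM matrix (genes x samples) with rownames.
#' @param min_value Minimum FPKM (default 1).
#' @param min_samples Minimum number of samples meeting it (default 3).
#' @return Character vector of retained gene ids.
#' @export
filter_fpkm <- function(fpkm, min_value = 1, min_samples = 3) {
  keep <- rowSums(fpkm >= min_value) >= min_samples
  rownames(fpkm)[keep]
}

#' Unsigned coexpression adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with Pearson correlation across samples.
#' Input is expected on the log scale (the workflow uses log2(FPKM + 1)).
#'
#' @param expr Expression matrix (genes x samples).
#' @param beta Soft-thresholding exponent (>= 1).
#' @return Symmetric adjacency matrix with unit diagonal.
#' @export
adjacency_matrix <- function(expr, beta) {
  stopifnot(beta >= 1)
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) stop("zero-variance gene(s): ",
                        paste(utils::head(rownames(expr)[v == 0], 3),
                              collapse = ", "))
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Signed scale-free topology fit index of a connectivity vector
#'
#' Bins connectivities into `nbins` equal-width bins and regresses
#' log10(bin frequency) on log10(mean connectivity per bin); the index is
#' the regression R^2 signed by the negative of the slope sign (positive
#' when frequency decreases with connectivity, as in a scale-free
#' network). Empty bins are dropped.
#'
#' @param k Connectivity vector (non-negative).
#' @param nbins Number of bins (default 10).
#' @return Signed R^2 in \[-1, 1\].
#' @export
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(k) < nbins) return(NA_real_)
  bin <- cut(k, breaks = nbins, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  x <- log10(meank[ok])
  y <- log10(freq[ok] / sum(freq[ok]))
  if (length(unique(x)) < 3) return(NA_real_)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[["x"]]) * r2
}

#' Choose the soft-thresholding exponent by scale-free fit
#'
#' For each candidate exponent the adjacency is computed, connectivities
#' (row sums minus self) derived, and the signed scale-free fit index
#' evaluated. The chosen exponent is the smallest whose fit reaches
#' `target`; if none does, the argmax is returned with a warning.
#'
#' @param expr Expression matrix (genes x samples); zero-variance genes are
#'   excluded with a warning.
#' @param candidates Candidate exponents (default 1:20).
#' @param target Fit index target (default 0.8).
#' @return List with `beta` and `fit_table` (data.frame beta, fit, mean_k).
#' @export
pick_soft_threshold <- function(expr, candidates = 1:20, target = 0.8) {
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded")
    expr <- expr[v > 0, , drop = FALSE]
  }
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit <- mean_k <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    k <- rowSums(ac^candidates[i])
    fit[i] <- scale_free_fit(k)
    mean_k[i] <- mean(k)
  }
  tab <- data.frame(beta = candidates, fit = fit, mean_k = mean_k)
  hit <- which(!is.na(fit) & fit >= target)
  if (length(hit)) beta <- candidates[hit[1]]
  else {
    warning("no candidate exponent reaches the target fit index; ",
            "returning the argmax")
    beta <- candidates[which.max(fit)]
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity k = row sums minus self; the diagonal is 1.
#'
#' @param a Symmetric adjacency matrix with entries in \[0, 1\].
#' @return Symmetric TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut statically at `cut_frac` times the maximum merge height. Clusters
#' smaller than `min_module_size` are set unassigned (module 0). Modules
#' whose eigengenes correlate above `merge_cor` are merged iteratively.
#' Module ids are reassigned in order of decreasing size (1 = largest).
#'
#' @param tom TOM similarity matrix.
#' @param expr Expression matrix (genes x samples) used for eigengene
#'   merging; rows must align with `tom`.
#' @param min_module_size Minimum module size (default 30).
#' @param merge_cor Eigengene correlation above which modules merge
#'   (default 0.85).
#' @param cut_frac Static cut height as a fraction of the maximum merge
#'   height (default 0.995).
#' @return Integer vector of module assignments (0 = unassigned), named by
#'   gene.
#' @export
detect_modules <- function(tom, expr, min_module_size = 30,
                           merge_cor = 0.85, cut_frac = 0.995) {
  n <- nrow(tom)
  ids <- rownames(tom) %||% as.character(seq_len(n))
  if (n < min_module_size)
    return(stats::setNames(rep(0L, n), ids))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_frac * max(hc$height))
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  cl <- merge_close_modules(cl, expr, merge_cor)
  # renumber by decreasing size, 0 stays unassigned
  mods <- setdiff(unique(cl), 0L)
  if (length(mods)) {
    sz <- vapply(mods, function(m) sum(cl == m), numeric(1))
    newid <- stats::setNames(seq_along(mods), mods[order(-sz)])
    cl[cl != 0L] <- as.integer(newid[as.character(cl[cl != 0L])])
  }
  stats::setNames(as.integer(cl), ids)
}

merge_close_modules <- function(cl, expr, merge_cor) {
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2L) return(cl)
    eg <- vapply(mods, function(m)
      module_eigengene(expr[cl == m, , drop = FALSE])$scores,
      numeric(ncol(expr)))
    cc <- stats::cor(eg)
    diag(cc) <- 0
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= merge_cor) return(cl)
    cl[cl == mods[mx[2]]] <- mods[mx[1]]
  }
}

#' Module eigengene
#'
#' Standardizes each gene across samples (mean 0, sd 1), takes the first
#' right singular vector as the per-sample eigengene scores, and fixes the
#' sign so the scores correlate positively with mean module expression.
#' Variance explained is the first squared singular value over the total.
#'
#' @param expr Expression submatrix (module genes x samples), >= 2 genes.
#' @return List with `scores` (per sample) and `variance_explained`.
#' @export
module_eigengene <- function(expr) {
  if (nrow(expr) < 2L) stop("module eigengene needs >= 2 genes")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped from module")
    expr <- expr[v > 0, , drop = FALSE]
    if (nrow(expr) < 2L) stop("module eigengene needs >= 2 varying genes")
  }
  z <- t(scale(t(expr)))
  sv <- svd(z)
  scores <- sv$v[, 1]
  meanexpr <- colMeans(z)
  if (stats::cor(scores, meanexpr) < 0) scores <- -scores
  list(scores = scores,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for all modules
#'
#' @param expr Expression matrix (genes x samples).
#' @param assignments Module assignment vector from [detect_modules()].
#' @return List with `eigengenes` (samples x modules matrix, columns "M1",
#'   ...) and `variance_explained` (per module).
#' @export
module_eigengenes <- function(expr, assignments) {
  mods <- sort(setdiff(unique(assignments), 0L))
  eg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("M", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    me <- module_eigengene(expr[assignments == mods[i], , drop = FALSE])
    eg[, i] <- me$scores
    ve[i] <- me$variance_explained
  }
  list(eigengenes = eg, variance_explained = ve)
}

#' Module-trait association by linear regression
#'
#' Ordinary least squares of each module eigengene on the trait; reports
#' R^2, the two-sided p-value of the slope, and BH-adjusted p-values across
#' modules within the trait.
#'
#' @param eigengenes Samples x modules matrix.
#' @param trait Numeric or binary-codable vector, one value per sample.
#' @param trait_name Label for the output (default "trait").
#' @return data.frame: module, trait, r_squared, p, fdr.
#' @export
module_trait_association <- function(eigengenes, trait,
                                     trait_name = "trait") {
  tr <- if (is.numeric(trait)) trait else as.numeric(factor(trait)) - 1
  if (stats::var(tr) == 0) stop("constant trait")
  res <- apply(eigengenes, 2L, function(e) {
    fit <- stats::lm(e ~ tr)
    sm <- summary(fit)
    c(r2 = sm$r.squared, p = sm$coefficients["tr", "Pr(>|t|)"])
  })
  out <- data.frame(module = colnames(eigengenes), trait = trait_name,
                    r_squared = res["r2", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Whole-network and within-module connectivity
#'
#' `k_total` is the row sum of adjacency excluding self; `k_within`
#' restricts the sum to the gene's own module (0 for unassigned genes).
#' Module membership is the correlation of each gene's profile with each
#' module eigengene.
#'
#' @param a Adjacency matrix.
#' @param assignments Module assignment vector.
#' @param expr Optional expression matrix for module membership.
#' @return data.frame: gene, module, k_total, k_within, plus MM columns
#'   (one per module) when `expr` is given.
#' @export
connectivity <- function(a, assignments, expr = NULL) {
  diag(a) <- 0
  k_total <- rowSums(a)
  n <- nrow(a)
  k_within <- numeric(n)
  for (m in setdiff(unique(assignments), 0L)) {
    idx <- which(assignments == m)
    k_within[idx] <- rowSums(a[idx, idx, drop = FALSE])
  }
  out <- data.frame(gene = rownames(a) %||% as.character(seq_len(n)),
                    module = as.integer(assignments),
                    k_total = k_total, k_within = k_within,
                    stringsAsFactors = FALSE)
  if (!is.null(expr)) {
    me <- module_eigengenes(expr, assignments)
    mm <- stats::cor(t(expr), me$eigengenes)
    colnames(mm) <- paste0("MM_", colnames(me$eigengenes))
    out <- cbind(out, as.data.frame(mm, row.names = NULL))
  }
  out
}
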