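test_that("minimum-count filter applies the >=1-in-3-samples rule", {
  counts <- rbind(kept3 = c(1, 1, 1, 0, 0, 0),
                  kept_all = c(5, 5, 5, 5, 5, 5),
                  only2 = c(9, 9, 0, 0, 0, 0),
                  zero = c(0, 0, 0, 0, 0, 0))
  expect_equal(filter_min_count(counts), c("kept3", "kept_all"))
  expect_equal(filter_min_count(counts, min_count = 2, min_samples = 2),
               c("kept_all", "only2"))
})

test_that("TMM matches a direct formula evaluation on the worked example", {
  counts <- cbind(A = c(100, 100, 100, 700), B = c(100, 100, 100, 100))
  # direct evaluation: reference is A (equal 75th-percentile fractions,
  # first wins); for B the three equal-count genes share M = log2(2.5)
  # and survive the double trim, the composition gene is trimmed out,
  # so the pre-scaling factor is exactly 2.5
  expected <- c(A = 2.5^-0.5, B = 2.5^0.5)
  expect_equal(tmm_factors(counts), expected, tolerance = 1e-12)
  expect_equal(prod(tmm_factors(counts)), 1, tolerance = 1e-12)
})

test_that("TMM is 1 for proportional samples and permutation-stable", {
  set.seed(10)
  base <- rpois(300, 40) + 1
  counts <- cbind(s1 = base, s2 = 3 * base, s3 = round(0.5 * base))
  f <- tmm_factors(cbind(s1 = base, s2 = 3 * base))
  expect_equal(unname(f), c(1, 1), tolerance = 1e-9)
  counts <- matrix(rnbinom(300 * 3, mu = 50, size = 3), 300, 3,
                   dimnames = list(NULL, c("s1", "s2", "s3")))
  f1 <- tmm_factors(counts)
  f2 <- tmm_factors(counts[, c(3, 1, 2)])
  expect_equal(f2[names(f1)], f1, tolerance = 1e-12)
})

test_that("TMM agrees with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  counts <- matrix(rnbinom(500 * 6, mu = 80, size = 2), 500, 6)
  expect_equal(unname(tmm_factors(counts)),
               unname(edgeR::calcNormFactors(counts)),
               tolerance = 1e-10)
})

test_that("logCPM follows its formula and scale invariance", {
  counts <- matrix(1, 1, 1)
  got <- logcpm(counts, factors = 1, prior_count = 0.5, lib_sizes = 2)
  expect_equal(got[1, 1], log2(1.5 / 3 * 1e6))
  zero <- matrix(0, 3, 2)
  z <- logcpm(zero, lib_sizes = c(10, 20))
  expect_equal(unique(z[, 1]), z[1, 1])
  expect_equal(unique(z[, 2]), z[1, 2])
  # doubling counts and library together leaves CPM unchanged as prior -> 0
  c1 <- logcpm(matrix(5, 1, 1), lib_sizes = 100, prior_count = 1e-9)
  c2 <- logcpm(matrix(10, 1, 1), lib_sizes = 200, prior_count = 1e-9)
  expect_equal(c1[1, 1], c2[1, 1], tolerance = 1e-6)
  expect_error(logcpm(matrix(1), factors = -1))
})

test_that("MDS distances follow the leading-logFC closed form", {
  set.seed(8)
  y <- matrix(rnorm(500 * 3), 500, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y[, 2] <- y[, 1]             # identical samples
  y[, 3] <- y[, 1] + 2         # uniform shift of delta = 2
  m <- mds_coordinates(y, top = 500)
  expect_equal(m$dist["a", "b"], 0)
  expect_equal(m$dist["a", "c"], 2, tolerance = 1e-9)
  expect_true(isSymmetric(m$dist))
  expect_true(all(diag(m$dist) == 0))
  # classical MDS reproduces exact Euclidean distances (3 points embed
  # exactly in 2 dimensions)
  emb <- as.matrix(stats::dist(m$coords))
  expect_lt(max(abs(emb - m$dist)), 1e-6)
})

test_that("voom weights are positive, flat under constant CV, and ordering is library-scale invariant", {
  set.seed(5)
  G <- 2000; n <- 24
  mu <- exp(runif(G, log(500), log(5000)))
  counts <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 10), G, n)
  design <- stats::model.matrix(~ rep(0:1, length.out = n))
  vw <- voom_weights(counts, NULL, design)
  expect_true(all(vw$weights > 0))
  # constant coefficient of variation: near-flat trend
  expect_lt(max(vw$weights) / min(vw$weights), 1.2)
  # doubling effective library sizes leaves the weight ordering unchanged
  vw2 <- voom_weights(counts, factors = rep(2, n), design)
  expect_gt(stats::cor(as.vector(vw$weights), as.vector(vw2$weights),
                       method = "spearman"), 0.999)
  expect_error(voom_weights(counts, NULL, cbind(1, 1)), "full rank")
})

test_that("voom weights agree with the limma implementation", {
  skip_if_not_installed("limma")
  sim <- gen_counts(tiny_config(seed = 33, n_genes = 400, n_samples = 12))
  counts <- sim$counts[filter_min_count(sim$counts), ]
  design <- stats::model.matrix(~ site, data = sim$design)
  fac <- tmm_factors(counts)
  vw <- voom_weights(counts, fac, design)
  v <- limma::voom(counts, design, lib.size = colSums(counts) * fac)
  expect_equal(unname(vw$logcpm), unname(v$E), tolerance = 1e-10)
  expect_equal(unname(vw$weights), unname(v$weights), tolerance = 1e-6)
})

test_that("variance moderation matches a bisection oracle on printed variances", {
  s2 <- c(1, 4, 9)
  d <- 4
  mm <- moderate_variances(s2, d)
  # independent oracle: solve the trigamma moment equation by bisection
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  target <- stats::var(e) - trigamma(d / 2)
  expect_gt(target, 0)
  f <- function(x) trigamma(x) - target
  lo <- 0.1; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  d0_oracle <- 2 * lo
  s02_oracle <- exp(mean(e) + digamma(lo) - log(lo))
  expect_equal(mm$d0, d0_oracle, tolerance = 1e-4)
  expect_equal(mm$s02, s02_oracle, tolerance = 1e-4)
})

test_that("moderated fit matches limma and handles degenerate priors", {
  skip_if_not_installed("limma")
  sim <- gen_counts(tiny_config(seed = 44, n_genes = 300, n_samples = 12))
  counts <- sim$counts[filter_min_count(sim$counts), ]
  design <- stats::model.matrix(~ site, data = sim$design)
  fac <- tmm_factors(counts)
  vw <- voom_weights(counts, fac, design)
  fit <- fit_and_moderate(vw$logcpm, vw$weights, design, c(0, 1))
  v <- limma::voom(counts, design, lib.size = colSums(counts) * fac)
  lf <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
  # single gene: no moderation possible, ordinary t (d0 = 0)
  one <- fit_and_moderate(vw$logcpm[1, , drop = FALSE],
                          vw$weights[1, , drop = FALSE], design, c(0, 1))
  expect_equal(one$d0, 0)
  # d0 = Inf limit: moderated variance collapses to s0^2
  s2_post_inf <- moderate_variances(rep(2, 50), 4)
  expect_equal(s2_post_inf$d0, Inf)
  expect_equal(s2_post_inf$s02, exp(mean(log(rep(2, 50)) - digamma(2) +
                                           log(2))))
})

test_that("DEG calling applies BH and splits by sign", {
  fit <- structure(list(table = data.frame(
    gene = paste0("g", 1:4), coef = c(1, -1, 2, -2),
    t = 0, p = c(0.01, 0.02, 0.03, 0.04),
    fdr = stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
    s2 = 1, df = 4)), class = "dge_fit")
  expect_equal(fit$table$fdr, rep(0.04, 4))
  degs <- call_degs(fit, alpha = 0.05)
  expect_setequal(degs$up, c("g1", "g3"))
  expect_setequal(degs$down, c("g2", "g4"))
  fit$table$p <- rep(1, 4)
  fit$table$fdr <- rep(1, 4)
  expect_length(call_degs(fit)$up, 0)
  expect_length(call_degs(fit)$down, 0)
})

test_that("set overlaps enumerate every Venn region", {
  ov <- set_overlap(list(A = c("1", "2"), B = c("2", "3")))
  get <- function(a, b) ov$count[ov$A == a & ov$B == b]
  expect_equal(get(TRUE, TRUE), 1)
  expect_equal(get(TRUE, FALSE), 1)
  expect_equal(get(FALSE, TRUE), 1)
  disj <- set_overlap(list(A = "1", B = "2"))
  expect_equal(disj$count[disj$A & disj$B], 0)
  sub <- set_overlap(list(A = c("1", "2"), B = c("1", "2", "3")))
  expect_equal(sub$count[sub$A & sub$B], 2)
  expect_equal(sub$count[sub$A & !sub$B], 0)
})

test_that("outlier flagging is flag-only and finds a planted outlier", {
  set.seed(20)
  y <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  y[, 8] <- y[, 8] + 6
  fl <- flag_expression_outliers(y)
  expect_true(fl$flagged[fl$sample == "s8"])
  expect_equal(sum(fl$flagged), 1)
  expect_equal(nrow(fl), 8)
})
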