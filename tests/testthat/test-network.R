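test_that("FPKM filter applies the >=1-in-3-samples rule", {
  fpkm <- rbind(keep = c(1, 1, 1, 0), drop = c(1, 1, 0.5, 0),
                zero = c(0, 0, 0, 0))
  expect_equal(filter_fpkm(fpkm), "keep")
  expect_equal(filter_fpkm(fpkm, min_value = 0),
               c("keep", "drop", "zero"))
})

test_that("adjacency is |cor|^beta with contract properties", {
  set.seed(3)
  expr <- matrix(rnorm(10 * 8), 10, 8)
  a <- adjacency_matrix(expr, 14)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diag(a) == 1))
  cc <- abs(stats::cor(t(expr)))
  expect_equal(a[1, 2], cc[1, 2]^14)
  # cor 0.5 at beta 14
  expect_equal(0.5^14, 6.103516e-05, tolerance = 1e-6)
  expr2 <- expr; expr2[2, ] <- expr2[1, ]       # cor = 1
  a2 <- adjacency_matrix(expr2, 7)
  expect_equal(a2[1, 2], 1)
  expr3 <- expr; expr3[1, ] <- 5
  expect_error(adjacency_matrix(expr3, 2), "zero-variance")
})

test_that("TOM matches a brute-force triple loop and closed forms", {
  # two nodes with a = 1 and no other neighbours
  a <- diag(2); a[1, 2] <- a[2, 1] <- 1
  expect_equal(tom_similarity(a)[1, 2], 1)
  # disconnected pair with no shared neighbours
  a0 <- diag(4)
  a0[1, 2] <- a0[2, 1] <- 0
  a0[3, 4] <- a0[4, 3] <- 0.9
  expect_equal(tom_similarity(a0)[1, 2], 0)
  # random 20x20 instance vs brute force
  set.seed(7)
  m <- matrix(stats::runif(400), 20)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  tom <- tom_similarity(a)
  ab <- a; diag(ab) <- 0
  k <- rowSums(ab)
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    if (i == j) { brute[i, j] <- 1; next }
    num <- sum(sapply(1:20, function(u)
      if (u == i || u == j) 0 else ab[i, u] * ab[u, j])) + ab[i, j]
    brute[i, j] <- num / (min(k[i], k[j]) + 1 - ab[i, j])
  }
  expect_equal(tom, brute, tolerance = 1e-12)
  expect_true(all(tom >= 0))
})

test_that("scale-free fit is ~1 on an exact power-law degree sequence", {
  # Pareto(alpha = 2) connectivities: p(k) ~ k^-2 exactly
  set.seed(31)
  k <- 1 / runif(20000)
  k <- k[k < 500]
  expect_gt(scale_free_fit(k), 0.95)
  # an increasing degree-frequency relation gives a negative signed fit
  k_inc <- 500 - k[k < 499]
  expect_lt(scale_free_fit(k_inc), 0)
})

test_that("soft-threshold selection is monotone on noise and never fails", {
  set.seed(12)
  expr <- matrix(rnorm(60 * 20), 60, 20)
  st <- suppressWarnings(pick_soft_threshold(expr, candidates = 1:8))
  expect_true(all(diff(st$fit_table$mean_k) < 0))
  expect_true(st$beta %in% 1:8)
  # unreachable target returns the argmax with a warning
  w1 <- capture_warnings(
    st2 <- pick_soft_threshold(expr, candidates = 1:3, target = 2))
  expect_true(any(grepl("argmax", w1)))
  expect_equal(st2$beta, st2$fit_table$beta[which.max(st2$fit_table$fit)])
  expr[1, ] <- 1
  w2 <- capture_warnings(pick_soft_threshold(expr, candidates = 1:3,
                                             target = 2))
  expect_true(any(grepl("zero-variance", w2)))
})

test_that("module detection recovers two planted blocks and rejects noise", {
  set.seed(5)
  n <- 20
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- rbind(
    t(replicate(100, f1 + rnorm(n, sd = 0.45))),
    t(replicate(100, f2 + rnorm(n, sd = 0.45))))
  rownames(expr) <- paste0("g", 1:200)
  tom <- tom_similarity(adjacency_matrix(expr, 12))
  mods <- detect_modules(tom, expr)
  truth <- rep(1:2, each = 100)
  expect_equal(length(unique(mods[mods > 0])), 2)
  tab <- table(mods, truth)
  expect_gt(sum(apply(tab, 1, max)) / 200, 0.95)
  # min_module_size larger than any block: everything unassigned
  mods0 <- detect_modules(tom, expr, min_module_size = 150)
  expect_true(all(mods0 == 0))
  # pure noise: most genes unassigned
  unassigned <- replicate(5, {
    e <- matrix(rnorm(200 * 20), 200, 20)
    tm <- tom_similarity(adjacency_matrix(e, 12))
    mean(detect_modules(tm, e) == 0)
  })
  expect_gt(mean(unassigned), 0.8)
})

test_that("eigengene matches the SVD closed forms and is order-invariant", {
  v <- c(1, -1, 2, 0)
  expr <- rbind(v, 2 * v + 3, -0.5 * v)   # identical standardized profiles
  eg <- module_eigengene(expr)
  expect_equal(eg$variance_explained, 1.0)
  z <- drop(scale(v))
  expect_equal(abs(stats::cor(eg$scores, z)), 1)
  # sign convention: positive correlation with mean standardized expression
  expect_gt(stats::cor(eg$scores, colMeans(t(scale(t(expr))))), 0)
  # SVD oracle on a fixed 6x4 matrix with two anti-correlated halves
  set.seed(9)
  base <- rnorm(4)
  m <- rbind(t(replicate(4, base + rnorm(4, sd = 0.1))),
             t(replicate(2, -base + rnorm(4, sd = 0.1))))
  eg2 <- module_eigengene(m)
  sv <- svd(t(scale(t(m))))
  expect_equal(eg2$variance_explained, sv$d[1]^2 / sum(sv$d^2))
  expect_equal(abs(stats::cor(eg2$scores, sv$v[, 1])), 1, tolerance = 1e-9)
  # permuting gene order leaves the eigengene unchanged
  eg3 <- module_eigengene(m[sample(6), ])
  expect_equal(eg3$scores, eg2$scores, tolerance = 1e-9)
  expect_error(module_eigengene(m[1, , drop = FALSE]), ">= 2")
})

test_that("module-trait regression gives exact R2 at the extremes", {
  trait <- rep(c(0, 1), each = 6)
  eg <- cbind(M1 = trait, M2 = rep(c(1, -1), 6))
  res <- suppressWarnings(module_trait_association(eg, trait, "site"))
  expect_equal(res$r_squared[res$module == "M1"], 1)
  expect_lt(res$p[res$module == "M1"], 1e-10)
  expect_lt(res$r_squared[res$module == "M2"], 0.1)
  expect_true(all(res$fdr >= res$p))
  expect_error(module_trait_association(eg, rep(1, 12)), "constant")
})

test_that("connectivity matches brute-force sums and the star closed form", {
  # star: centre with 5 unit edges
  a <- matrix(0, 6, 6); a[1, 2:6] <- a[2:6, 1] <- 1; diag(a) <- 1
  k <- connectivity(a, rep(1L, 6))
  expect_equal(k$k_total[1], 5)
  expect_equal(k$k_within, k$k_total)
  # random 15-gene network vs brute force, k_within <= k_total
  set.seed(4)
  m <- matrix(runif(225), 15); am <- (m + t(m)) / 2; diag(am) <- 1
  assign <- rep(c(1L, 2L, 0L), each = 5)
  ck <- connectivity(am, assign)
  for (i in 1:15) {
    expect_equal(ck$k_total[i], sum(am[i, -i]))
    if (assign[i] > 0) {
      idx <- setdiff(which(assign == assign[i]), i)
      expect_equal(ck$k_within[i], sum(am[i, idx]))
    } else expect_equal(ck$k_within[i], 0)
  }
  expect_true(all(ck$k_within <= ck$k_total + 1e-12))
})
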