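test_that("gene filtering drops rare, flat, and non-coding genes", {
  set.seed(30)
  n_s <- 100
  mat <- rbind(
    rare = c(rexp(1, 0.1), rep(0, n_s - 1)),              # 1% of samples
    flat = 2^rep(3, n_s) - 1,                             # sd exactly 0
    lowsd = 2^(5 + rnorm(n_s, 0, 0.3)) - 1,               # sd below floor
    good1 = 2^(5 + rnorm(n_s, 0, 2.5)) - 1,
    good2 = 2^(4 + rnorm(n_s, 0, 3)) - 1,
    noncod = 2^(5 + rnorm(n_s, 0, 2.5)) - 1)
  colnames(mat) <- paste0("s", 1:n_s)
  coding <- setNames(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), rownames(mat))
  kept <- rownames(filter_genes(mat, coding))
  expect_setequal(kept, c("good1", "good2"))
  # a gene whose log2 sd is exactly 1 is removed (strict rule):
  # log2(TPM + 1) = (4, 5, 6) has sample sd exactly 1
  m2 <- rbind(sd1 = 2^c(4, 5, 6) - 1, good = 2^c(1, 5, 9) - 1)
  colnames(m2) <- paste0("t", 1:3)
  expect_identical(sd(log2(m2["sd1", ] + 1)), 1)
  expect_equal(rownames(filter_genes(m2)), "good")
  expect_error(filter_genes(mat[c("rare", "flat"), ]), "no genes")
})

test_that("TOM matches hand-computed values and brute-force triples", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  tom <- tom_similarity(a3)
  expect_equal(tom[1, 2], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(unname(diag(tom)), rep(1, 3))
  a0 <- matrix(0, 3, 3)
  expect_equal(unname(tom_similarity(a0)[1, 2]), 0)
  a1 <- matrix(1, 4, 4); diag(a1) <- 0
  expect_true(all(tom_similarity(a1) == 1))
  # brute force over random 3x3 adjacencies
  set.seed(31)
  for (i in 1:20) {
    v <- runif(3)
    a <- matrix(0, 3, 3)
    a[lower.tri(a)] <- v; a <- a + t(a)
    tom <- tom_similarity(a)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      i1 <- p[1]; j1 <- p[2]; u <- setdiff(1:3, p)
      l <- a[i1, u] * a[u, j1]
      k <- rowSums(a)
      expect_equal(tom[i1, j1],
                   (l + a[i1, j1]) / (min(k[i1], k[j1]) + 1 - a[i1, j1]))
    }
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
  expect_error(tom_similarity(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("module detection separates planted blocks and rejects noise", {
  a <- matrix(0.05, 70, 70)
  a[1:35, 1:35] <- 0.9; a[36:70, 36:70] <- 0.9
  diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:70), paste0("g", 1:70))
  # between-block TOM dissimilarity is ~0.91 here, so cut below it
  mods <- detect_modules(tom_similarity(a), cut_height = 0.5,
                         min_module_size = 30)
  expect_equal(length(unique(mods)), 2)
  expect_equal(adjusted_rand(mods, rep(1:2, each = 35)), 1)
  # near-zero TOM leaves everything unassigned
  a0 <- matrix(0.001, 40, 40); diag(a0) <- 0
  dimnames(a0) <- list(paste0("g", 1:40), paste0("g", 1:40))
  expect_true(all(detect_modules(tom_similarity(a0)) == 0))
})

test_that("eigengene is the unit-variance PC1 oriented with mean expression", {
  set.seed(32)
  f <- rnorm(40)
  mat <- rbind(t(sapply(1:6, function(i) 0.95 * f + 0.3 * rnorm(40))),
               single = rnorm(40))
  rownames(mat) <- c(paste0("g", 1:6), "single")
  colnames(mat) <- paste0("s", 1:40)
  e <- module_eigengene(mat, paste0("g", 1:6))
  expect_equal(sd(e), 1)
  expect_gt(cor(e, f), 0.97)
  z <- t(scale(t(mat[paste0("g", 1:6), ])))
  expect_gt(cor(e, colMeans(z)), 0) # sign convention
  # PC1 explains at least as much standardized variance as any member gene
  var_e <- sapply(1:6, function(i) cor(z[i, ], e)^2)
  var_g <- sapply(1:6, function(i) mean(sapply(1:6, function(j)
    cor(z[j, ], z[i, ])^2)))
  expect_gte(mean(var_e) + 1e-9, max(var_g))
  # single-gene module returns that gene's z-scored profile
  es <- module_eigengene(mat, "single")
  expect_equal(unname(es), unname(scale(mat["single", ])[, 1]))
  # two perfectly correlated genes correlate 1 with the eigengene
  m2 <- rbind(a = f, b = 2 * f + 5)
  colnames(m2) <- paste0("s", 1:40)
  e2 <- module_eigengene(m2, c("a", "b"))
  expect_equal(abs(cor(e2, f)), 1, tolerance = 1e-9)
})

test_that("soft power and annotation behave on planted cohorts", {
  co <- generate_expression(cohort_config(seed = 3))
  lg <- log2(filter_genes(co$expression, coding = co$coding) + 1)
  sp <- pick_soft_power(lg)
  expect_true(sp$power %in% 1:20)
  expect_gte(max(sp$fit_table$r2, na.rm = TRUE), 0.8)
  # fit table is reproducible bit-for-bit
  expect_identical(sp, pick_soft_power(lg))
  mods <- detect_modules(tom_similarity(adjacency_matrix(lg, sp$power)))
  em <- module_eigengenes(lg, mods)
  traits <- cbind(depletion = co$truth$traits$depletion,
                  javelin = co$truth$traits$javelin,
                  angio = co$truth$traits$angio)[match(colnames(lg),
                                                       colnames(co$expression)), ]
  ann <- annotate_modules(em, traits, mods)
  expect_false(is.na(ann$escape_module))
  # the labeled escape module holds the planted depletion-linked genes
  esc_genes <- names(mods)[mods == ann$escape_module]
  planted <- names(co$truth$module)[co$truth$module == co$truth$escape_module]
  expect_gt(mean(planted %in% esc_genes), 0.9)
  # zero-variance trait is skipped with a warning
  expect_warning(annotate_modules(em, cbind(traits, const = 1), mods), "zero variance")
})

test_that("the planted-factor module eigengene tracks its latent factor", {
  co <- generate_expression(cohort_config(seed = 8))
  lg <- log2(co$expression + 1)
  m <- co$truth$escape_module
  genes <- names(co$truth$module)[co$truth$module == m]
  e <- module_eigengene(lg, genes)
  expect_gte(abs(cor(e, co$truth$factors[m, ])), 0.95)
})

test_that("greedy refinement traces the documented path and its guarantee", {
  rho <- matrix(c(1, 0.9, 0.7, 0.2,
                  0.9, 1, 0.65, 0.2,
                  0.7, 0.65, 1, 0.2,
                  0.2, 0.2, 0.2, 1), 4, 4,
                dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  expect_equal(refine_signature(rho), c("g1", "g2", "g3"))
  # all pairs above the floor: whole module returned
  rho_hi <- matrix(0.8, 3, 3); diag(rho_hi) <- 1
  dimnames(rho_hi) <- list(letters[1:3], letters[1:3])
  expect_setequal(refine_signature(rho_hi), letters[1:3])
  # no admissible pair: top gene with a warning
  rho_lo <- matrix(0.1, 3, 3); diag(rho_lo) <- 1
  dimnames(rho_lo) <- list(letters[1:3], letters[1:3])
  expect_warning(out <- refine_signature(rho_lo), "top gene")
  expect_length(out, 1)
  # property: the output always satisfies the pairwise floor
  set.seed(33)
  for (i in 1:15) {
    x <- matrix(rnorm(12 * 30), 12, 30,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:30)))
    x[1:5, ] <- matrix(rep(x[1, ], 5), 5, byrow = TRUE) + rnorm(5 * 30, 0, 0.4)
    sel <- suppressWarnings(refine_signature(x, paste0("g", 1:12), rho_floor = 0.5))
    if (length(sel) > 1) {
      rr <- cor(t(x[sel, ]), method = "spearman")
      expect_gte(min(rr[upper.tri(rr)]), 0.5)
    }
  }
})

test_that("escape scoring plumbs ssGSEA through the median split", {
  set.seed(34)
  sig <- immune_escape_signature()
  mat <- matrix(rexp(length(sig) * 3 * 8, 0.1), length(sig) * 3, 8,
                dimnames = list(c(sig, paste0("o", seq_len(2 * length(sig)))),
                                paste0("s", 1:8)))
  sc <- score_escape(mat)
  expect_equal(nrow(sc), 8)
  expect_equal(sum(sc$label == "high"), 4)
  expect_equal(mean(sc$z), 0, tolerance = 1e-9)
})
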