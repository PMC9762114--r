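test_that("RNA ITH reproduces the worked two-region example", {
  # centered log2 values g1 = (1, -1), g2 = (0, 0), g3 = (0.5, -0.5)
  mat <- matrix(2^c(1, -1, 0, 0, 0.5, -0.5), 3, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sheet <- data.frame(sample = c("s1", "s2"), patient = "p1", tissue = "tumor")
  ri <- rna_ith(mat, sheet, pseudocount = 0)
  expect_equal(unname(ri$gene[c("g1", "g2", "g3")]), c(2, 0, 1))
  expect_equal(unname(ri$patient), 1)
  # identical regions give zero
  ri0 <- rna_ith(cbind(s1 = mat[, 1], s2 = mat[, 1]), sheet, pseudocount = 0)
  expect_equal(unname(ri0$patient), 0)
})

test_that("RNA ITH is invariant to per-gene scaling and sample order", {
  set.seed(4)
  mat <- matrix(rexp(120, 0.1), 12, 10,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  sheet <- data.frame(sample = paste0("s", 1:10),
                      patient = rep(c("p1", "p2"), each = 5), tissue = "tumor")
  base <- rna_ith(mat, sheet)
  scaled <- mat
  scaled["g3", ] <- scaled["g3", ] * 7 # multiplicative gene offset
  # exact invariance holds without the pseudocount (log turns scale into shift)
  expect_equal(rna_ith(scaled, sheet, pseudocount = 0)$patient,
               rna_ith(mat, sheet, pseudocount = 0)$patient)
  perm <- mat[, sample(colnames(mat))]
  expect_equal(rna_ith(perm, sheet)$patient, base$patient)
  # single-region patient flagged NA
  sheet1 <- sheet; sheet1$patient[10] <- "p3"
  ri <- rna_ith(mat, sheet1)
  expect_true("p3" %in% ri$flagged && is.na(ri$patient["p3"]))
})

test_that("DNA ITH applies the less-than-half subclonality rule", {
  sheet <- data.frame(sample = paste0("r", 1:4), patient = "p1", tissue = "tumor")
  mut <- data.frame(
    patient = "p1",
    sample = c(paste0("r", 1:4), "r1", "r2", "r3"),
    alteration = c(rep("VHL", 4), "SETD2", "SETD2", "PBRM1"))
  di <- dna_ith(mut, sheet)
  # VHL 4/4 clonal, SETD2 2/4 clonal (2 is not < 2), PBRM1 1/4 subclonal
  expect_equal(unname(di$patient["p1"]), 0.5)
  expect_equal(di$calls$clonality[di$calls$alteration == "SETD2"], "clonal")
  # all alterations clonal -> 0
  allc <- mut[mut$alteration == "VHL", ]
  expect_equal(unname(dna_ith(allc, sheet)$patient["p1"]), 0)
  # no clonal denominator -> undefined, flagged
  sheet5 <- data.frame(sample = paste0("r", 1:5), patient = "p1", tissue = "tumor")
  solo <- data.frame(patient = "p1", sample = c("r1", "r2"),
                     alteration = c("VHL", "SETD2"))
  di5 <- dna_ith(solo, sheet5)
  expect_true(is.na(di5$patient["p1"]) && "p1" %in% di5$flagged)
  # fewer than three regions is not scored
  di2 <- dna_ith(mut[mut$sample %in% c("r1", "r2"), ],
                 sheet[1:2, , drop = FALSE])
  expect_true(is.na(di2$patient["p1"]))
})

test_that("TCR ITH is one minus the shared-clonotype fraction", {
  sheet <- data.frame(sample = c("r1", "r2"), patient = "p1", tissue = "tumor")
  tab <- clonotab(r1 = c(A = 5, B = 2), r2 = c(B = 4, C = 1))
  ti <- tcr_ith(tab, sheet)
  expect_equal(unname(ti$patient["p1"]), 1 - 1 / 3)
  # identical sets -> 0; disjoint -> 1
  expect_equal(unname(tcr_ith(clonotab(r1 = c(A = 1, B = 2), r2 = c(A = 9, B = 1)),
                              sheet)$patient["p1"]), 0)
  expect_equal(unname(tcr_ith(clonotab(r1 = c(A = 1), r2 = c(B = 1)),
                              sheet)$patient["p1"]), 1)
  # all-regions sharing rule is stricter
  sheet3 <- data.frame(sample = c("r1", "r2", "r3"), patient = "p1", tissue = "tumor")
  tab3 <- clonotab(r1 = c(A = 1, B = 1), r2 = c(A = 1, B = 1), r3 = c(A = 1, C = 1))
  expect_equal(unname(tcr_ith(tab3, sheet3, shared_rule = "any2")$patient), 1 - 2 / 3)
  expect_equal(unname(tcr_ith(tab3, sheet3, shared_rule = "all")$patient), 1 - 1 / 3)
  # region relabeling leaves the score unchanged
  tabr <- tab; tabr$sample_id <- ifelse(tabr$sample_id == "r1", "r2", "r1")
  expect_equal(unname(tcr_ith(tabr, sheet)$patient), unname(ti$patient))
})

test_that("binary-feature clustering separates planted blocks exactly", {
  fm <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 4), 4, byrow = TRUE),
              matrix(rep(c(0, 0, 0, 1, 1, 1), 4), 4, byrow = TRUE))
  dimnames(fm) <- list(paste0("p", 1:8), paste0("f", 1:6))
  ith <- data.frame(patient = paste0("p", 1:8), dna_ith = c(rep(1, 4), rep(0, 4)))
  cl <- cluster_genomic_features(fm, ith)
  expect_equal(adjusted_rand(cl$cluster, rep(c("A", "B"), each = 4)), 1)
  expect_equal(unname(cl$cluster[1:4]), rep("ITH-high", 4))
  expect_error(cluster_genomic_features(matrix(1, 4, 3,
    dimnames = list(paste0("p", 1:4), paste0("f", 1:3))), ith), "degenerate")
})

test_that("feature-independent clusters give uniform Fisher p-values", {
  set.seed(8)
  ps <- replicate(150, {
    f <- rbinom(12, 1, 0.5)
    cl <- rep(c("ITH-low", "ITH-high"), each = 6)
    fisher_exact(table(factor(f, levels = 0:1), cl))$p.value
  })
  # discrete p-values are super-uniform; check no inflation at nominal levels
  expect_lt(mean(ps <= 0.05), 0.08)
  expect_gt(mean(ps > 0.5), 0.4)
})

test_that("planted ITH tiers are recovered from genomic features", {
  acc <- vapply(1:10, function(sd) {
    g <- feature_matrix(cohort_config(seed = sd))
    cl <- cluster_genomic_features(g$fm, g$ith)
    mean((cl$cluster == "ITH-high") == (g$tier == "high"))
  }, 0)
  expect_gte(stats::median(acc), 0.9)
  # the enriched lesions rank among the most significant features
  g <- feature_matrix(cohort_config(seed = 1))
  cl <- cluster_genomic_features(g$fm, g$ith)
  top3 <- cl$feature_tests$feature[order(cl$feature_tests$p.value)][1:3]
  expect_true(all(c("hla_loh", "cdkn2ab") %in% top3))
  expect_true(is.finite(cl$combined_p) && cl$combined_p >= 0 && cl$combined_p <= 1)
})

test_that("neighbor joining reproduces additive metrics exactly", {
  D <- matrix(c(0, 5, 7, 8, 5, 0, 8, 9, 7, 8, 0, 9, 8, 9, 9, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(as.dist(D))
  # four-point condition holds: AB|CD with exact branch lengths
  cp <- stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, D)
  tip_len <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])], tr$tip.label)
  expect_equal(tip_len[LETTERS[1:4]], c(A = 2, B = 3, C = 4, D = 5))
  # agrees with the reference implementation topologically
  expect_equal(as.numeric(ape::dist.topo(tr, ape::nj(as.dist(D)))), 0)
  # 3-leaf closed form
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(as.dist(D3))
  expect_equal(stats::cophenetic(t3)[c("x", "y", "z"), c("x", "y", "z")], D3)
})

test_that("neighbor joining handles presence matrices and input order", {
  set.seed(13)
  pres <- matrix(rbinom(40, 1, 0.4), 5, 8,
                 dimnames = list(paste0("r", 1:5), paste0("a", 1:8)))
  tr <- nj_tree(pres)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), paste0("r", 1:5))
  # permuting taxa yields an isomorphic tree
  perm <- pres[c(3, 1, 5, 2, 4), ]
  expect_equal(as.numeric(ape::dist.topo(tr, nj_tree(perm))), 0)
  # matches ape's NJ on the same Hamming distances
  d <- dist(pres, method = "manhattan")
  expect_equal(as.numeric(ape::dist.topo(tr, ape::nj(d))), 0)
  expect_error(nj_tree(pres[1:2, ]), ">= 3")
  # random (non-additive) metrics still produce a valid serializable tree
  txt <- ape::write.tree(tr)
  expect_match(txt, "^\\(")
})
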