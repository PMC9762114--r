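test_that("configuration invariants are enforced", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(module_sizes = c(900, 900), n_genes = 1000,
                             module_intra_cor = c(0.8, 0.8),
                             module_trait_cor = c(0, 0),
                             module_traits = c("none", "none")), "exceed")
  expect_error(cohort_config(editing_mix = c(elimination = 0.5, evasion_LOH = 0.2,
                                             evasion_expression = 0.2,
                                             ambiguous = 0.2)), "sum to 1")
  expect_error(cohort_config(clonotype_zipf_exponent = -1), "> 0")
  expect_error(cohort_config(regions_per_patient = c(1, 3)), ">= 2")
  expect_error(cohort_config(survival_hr = 0), "> 0")
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_config()
  a <- generate_expression(cfg); b <- generate_expression(cfg)
  expect_identical(a, b)
  expect_identical(generate_mutations(cfg), generate_mutations(cfg))
  expect_identical(generate_clonotypes(cfg), generate_clonotypes(cfg))
  expect_identical(generate_clinical(cfg), generate_clinical(cfg))
  # a different seed changes the data
  expect_false(identical(a$expression,
                         generate_expression(small_config(seed = 12L))$expression))
  # stage substreams are independent of call order
  co <- simulate_cohort(cfg)
  expect_identical(co$clonotypes, generate_clonotypes(cfg)$clonotypes)
})

test_that("a 30-gene module at intra-correlation 0.9 lands in [0.8, 0.95]", {
  cfg <- cohort_config(n_patients = 10, regions_per_patient = c(5, 5),
                       n_genes = 100, module_sizes = 30,
                       module_intra_cor = 0.9, module_trait_cor = 0.8,
                       module_traits = "depletion", seed = 5)
  ex <- generate_expression(cfg)
  expect_gte(ncol(ex$expression), 50)
  lg <- log2(ex$expression + 1)
  genes <- names(ex$truth$module)[ex$truth$module == 1]
  cc <- cor(t(lg[genes, ]))
  m <- mean(cc[upper.tri(cc)])
  expect_gte(m, 0.8); expect_lte(m, 0.95)
})

test_that("null module-trait correlation keeps eigengene-trait rho below 0.4", {
  cfg <- cohort_config(n_patients = 10, regions_per_patient = c(5, 5),
                       n_genes = 200, module_sizes = c(30, 30),
                       module_intra_cor = c(0.8, 0.8),
                       module_trait_cor = c(0, 0),
                       module_traits = c("depletion", "none"), seed = 6)
  ex <- generate_expression(cfg)
  lg <- log2(ex$expression + 1)
  rhos <- sapply(1:2, function(m) {
    e <- module_eigengene(lg, names(ex$truth$module)[ex$truth$module == m])
    abs(cor(e, ex$truth$traits$depletion, method = "spearman"))
  })
  expect_lt(max(rhos), 0.4)
})

test_that("forced generator regimes propagate to the heterogeneity scores", {
  # subclonal_rate = 0: every driver clonal, DNA ITH 0 everywhere defined
  cfg0 <- small_config(seed = 21L, subclonal_rate = 0)
  mut0 <- generate_mutations(cfg0)
  di <- dna_ith(mut0$mutations, mut0$sheet, drivers = names(cfg0$driver_genes))
  expect_true(all(di$patient[!is.na(di$patient)] == 0))
  expect_true(all(di$calls$clonality == "clonal"))
  # region_sharing = 1: identical clonotype sets, TCR ITH 0
  tcr1 <- generate_clonotypes(small_config(seed = 22L, region_sharing = 1))
  ti1 <- tcr_ith(tcr1$clonotypes, tcr1$sheet)
  expect_true(all(ti1$patient == 0))
  # region_sharing = 0: disjoint regions, TCR ITH 1 and zero overlap
  tcr0 <- generate_clonotypes(small_config(seed = 23L, region_sharing = 0))
  ti0 <- tcr_ith(tcr0$clonotypes, tcr0$sheet)
  expect_true(all(ti0$patient == 1))
  sheet <- tcr0$sheet
  p <- sheet$patient[1]
  regs <- sheet$sample[sheet$patient == p & sheet$tissue == "tumor"][1:2]
  expect_equal(morisita_overlap(tcr0$clonotypes, regs[1], regs[2]), 0)
})

test_that("editing_mix = (1,0,0,0) forces pure elimination signatures", {
  cfg <- small_config(seed = 24L,
                      editing_mix = c(elimination = 1, evasion_LOH = 0,
                                      evasion_expression = 0, ambiguous = 0))
  mut <- generate_mutations(cfg)
  dep <- mut$fc[mut$fc$depleted, ]
  expect_gt(nrow(dep), 0)
  expect_true(all(!dep$loh))
  lfc <- purity_corrected_log2fc(dep$tpm_pre, dep$tpm_post,
                                 dep$purity_pre, dep$purity_post)
  expect_true(all(lfc >= 0))
  expect_true(all(classify_editing(data.frame(loh = dep$loh, log2fc = lfc))$class ==
                    "elimination"))
})

test_that("clone abundances follow the configured Zipf law", {
  tcr <- generate_clonotypes(cohort_config(n_clonotypes = 1000, seed = 3))
  anchor <- tcr$sheet$sample[tcr$sheet$tissue == "tumor"][1]
  cnt <- sort(tcr$clonotypes$duplicate_count[tcr$clonotypes$sample_id == anchor],
              decreasing = TRUE)
  fit <- lm(log(cnt) ~ log(seq_along(cnt)))
  expect_lt(abs(unname(coef(fit)[2]) + 1.2), 0.1)
})

test_that("survival generation respects the hazard ratio and censoring", {
  surv <- generate_clinical(cohort_config(censor_rate = 0, seed = 2), n = 2000)
  expect_true(all(surv$event == 1))
  fit <- cox_univariate(surv)
  expect_gt(fit$hr, 1.3); expect_lt(fit$hr, 1.7)
  # censor_rate = 1: everything censored, survival ops refuse to fit
  all_c <- generate_clinical(small_config(censor_rate = 1))
  expect_true(all(all_c$event == 0))
  expect_error(km_logrank(all_c), "no events")
  # intermediate censoring is roughly calibrated
  half <- generate_clinical(cohort_config(censor_rate = 0.4, seed = 5), n = 4000)
  expect_lt(abs(mean(half$event == 0) - 0.4), 0.07)
})

test_that("HR = 1 produces uniform log-rank p-values across seeds", {
  ps <- vapply(1:150, function(sd)
    km_logrank(generate_clinical(cohort_config(survival_hr = 1, seed = sd),
                                 n = 100))$p.value, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort tables round-trip losslessly through the writers", {
  co <- simulate_cohort(small_config())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$expression, co$expression, tolerance = 1e-12)
  expect_equal(back$sheet$sample, co$sheet$sample)
  expect_equal(back$clonotypes$duplicate_count, co$clonotypes$duplicate_count)
  expect_equal(back$clinical$time, co$clinical$time, tolerance = 1e-12)
  expect_equal(nrow(back$mutations), nrow(co$mutations))
  expect_equal(back$neoantigens$percent_rank, co$neoantigens$percent_rank,
               tolerance = 1e-12)
  mods <- co$truth$expression$module
  expect_equal(sort(back$modules_gmt$module_1),
               sort(names(mods)[mods == 1]))
  # GMT round-trip on its own
  gmt_path <- file.path(dir, "x.gmt")
  sets <- list(a = c("g1", "g2"), b = c("g3", "g4", "g5"))
  write_gmt(sets, gmt_path)
  expect_equal(read_gmt(gmt_path), sets)
})

test_that("the sample sheet covers regions, timepoints and purity", {
  sheet <- generate_sample_sheet(cohort_config(seed = 9))
  expect_true(all(table(sheet$patient[sheet$tissue == "tumor" &
                                        sheet$timepoint != "pre"]) >= 3))
  expect_true(all(sheet$purity[sheet$tissue == "tumor"] > 0 &
                    sheet$purity[sheet$tissue == "tumor"] <= 1))
  expect_true(all(c("pre", "post", "untreated") %in% sheet$timepoint))
  expect_true(any(sheet$tissue == "pbmc"))
  expect_false(anyDuplicated(sheet$sample) > 0)
})
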