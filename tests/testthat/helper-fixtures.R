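# shared fixtures built in code

# small cohort for fast end-to-end checks
small_config <- function(seed = 11L, ...) {
  cohort_config(n_patients = 8, n_genes = 300,
                module_sizes = c(40, 30), module_intra_cor = c(0.8, 0.7),
                module_trait_cor = c(0.8, 0), module_traits = c("depletion", "none"),
                n_clonotypes = 60, n_neoantigens_per_patient = 10,
                n_survival = 60, seed = seed, ...)
}

# clonotype table from named count vectors, one element per sample
clonotab <- function(...) {
  lst <- list(...)
  do.call(rbind, lapply(names(lst), function(s) {
    cnt <- lst[[s]]
    data.frame(sample_id = s, cdr3_aa = names(cnt), v_call = "TRBV1",
               j_call = "TRBJ1-1", duplicate_count = unname(cnt),
               stringsAsFactors = FALSE)
  }))
}

# patient x feature matrix + ith table + tier truth from a generated cohort
feature_matrix <- function(cfg) {
  mut <- generate_mutations(cfg)
  sheet <- mut$sheet
  pats <- unique(sheet$patient[sheet$tissue == "tumor"])
  drv <- names(cfg$driver_genes)
  fm <- sapply(drv, function(g)
    as.integer(pats %in% mut$mutations$patient[mut$mutations$alteration == g]))
  fl <- mut$flags[!duplicated(mut$flags$patient), ]
  fm <- cbind(fm, hla_loh = as.integer(fl$hla_loh[match(pats, fl$patient)]),
              cdkn2ab = as.integer(fl$cdkn2ab_loss[match(pats, fl$patient)]))
  rownames(fm) <- pats
  di <- dna_ith(mut$mutations, sheet, drivers = drv)
  list(fm = fm, ith = data.frame(patient = pats, dna_ith = di$patient[pats]),
       tier = sheet$ith_tier[match(pats, sheet$patient)], mut = mut)
}

adjusted_rand <- function(a, b) {
  t <- table(a, b)
  N <- sum(t)
  si <- sum(choose(rowSums(t), 2)); sj <- sum(choose(colSums(t), 2))
  sij <- sum(choose(t, 2))
  e <- si * sj / choose(N, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# per-patient detected neoantigen sets from a generated cohort
detected_sets <- function(co, patient) {
  det <- detect_neoantigens(co$neoantigens, co$mutations)
  sheet <- co$sheet
  pre_s <- sheet$sample[sheet$patient == patient & sheet$timepoint == "pre" &
                          sheet$tissue == "tumor"]
  post_s <- sheet$sample[sheet$patient == patient & sheet$timepoint == "post" &
                           sheet$tissue == "tumor"]
  list(pre = det$neo_id[det$sample == pre_s & det$detected],
       post = lapply(stats::setNames(post_s, post_s),
                     function(s) det$neo_id[det$sample == s & det$detected]))
}
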