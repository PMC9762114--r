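# Synthetic multi-regional cohort with known ground truth.
#
# One global integer seed drives independent per-stage substreams: the
# sample sheet uses seed + 0, expression seed + 1, mutations/neoantigens
# seed + 2, clonotypes seed + 3, and clinical seed + 4, so each stage can
# be regenerated independently of the others.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic multi-regional cohort
#'
#' Defines the study conditions of the generated cohort: cohort size and
#' regions per patient, planted co-expression modules and their trait
#' links, driver alterations and subclonality, neoantigen depletion and
#' its editing-class mix, clonotype abundance law and inter-region
#' sharing, and the survival model.
#'
#' @param n_patients number of patients (default 16).
#' @param regions_per_patient inclusive range of tumor regions sampled per
#'   patient (default c(3, 5)).
#' @param n_genes total genes in the expression matrix (default 1500).
#' @param module_sizes planted module sizes (default 60, 45, 35, 30, 30).
#' @param module_intra_cor per-module target mean intra-module Pearson
#'   correlation (default 0.8, 0.78, 0.75, 0.7, 0.65).
#' @param module_trait_cor per-module target correlation between the
#'   module factor and its linked trait (default c(0.8, 0.7, 0.7, 0, 0)).
#' @param module_traits per-module trait name ("depletion", "javelin",
#'   "angio", or "none").
#' @param driver_genes named per-gene probability that a patient carries
#'   the driver alteration.
#' @param subclonal_rate probability a present alteration is subclonal
#'   (restricted to fewer than half of the regions) in ITH-low patients;
#'   ITH-high patients use \code{min(1, 2.6 * subclonal_rate)}.
#' @param n_neoantigens_per_patient pre-treatment neoantigens per patient.
#' @param depletion_rate planted fraction of pre-treatment neoantigens
#'   depleted in every treated region (clonal depletion; default 0.3).
#' @param editing_mix named proportions (elimination, evasion_LOH,
#'   evasion_expression, ambiguous); must sum to 1.
#' @param n_clonotypes clonotypes per repertoire (default 300).
#' @param clonotype_zipf_exponent Zipf rank-abundance exponent (> 0).
#' @param region_sharing probability a clonotype recurs in another region.
#' @param survival_hr hazard ratio of group 1 versus group 0 (> 0).
#' @param censor_rate fraction of observations censored in [0, 1].
#' @param n_survival subjects in the survival table (default 200).
#' @param seed global integer seed.
#' @return validated object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 16,
                          regions_per_patient = c(3, 5),
                          n_genes = 1500,
                          module_sizes = c(60, 45, 35, 30, 30),
                          module_intra_cor = c(0.8, 0.78, 0.75, 0.7, 0.65),
                          module_trait_cor = c(0.8, 0.7, 0.7, 0, 0),
                          module_traits = c("depletion", "javelin", "angio",
                                            "none", "none"),
                          driver_genes = c(VHL = 0.85, PBRM1 = 0.5,
                                           SETD2 = 0.35, BAP1 = 0.2),
                          subclonal_rate = 0.25,
                          n_neoantigens_per_patient = 30,
                          depletion_rate = 0.3,
                          editing_mix = c(elimination = 0.4,
                                          evasion_LOH = 0.25,
                                          evasion_expression = 0.25,
                                          ambiguous = 0.1),
                          n_clonotypes = 300,
                          clonotype_zipf_exponent = 1.2,
                          region_sharing = 0.5,
                          survival_hr = 1.5,
                          censor_rate = 0.2,
                          n_survival = 200,
                          seed = 17L) {
  assert_count(n_patients, "n_patients")
  assert_count(regions_per_patient, "regions_per_patient", min = 2)
  stop_if(length(regions_per_patient) != 2 ||
            regions_per_patient[1] > regions_per_patient[2],
          "'regions_per_patient' must be an increasing range of length 2")
  assert_count(n_genes, "n_genes")
  assert_count(module_sizes, "module_sizes", min = 3)
  stop_if(sum(module_sizes) > n_genes, "module sizes exceed n_genes")
  k <- length(module_sizes)
  stop_if(length(module_intra_cor) != k || length(module_trait_cor) != k ||
            length(module_traits) != k,
          "module_intra_cor, module_trait_cor, module_traits must match module_sizes")
  assert_prob(module_intra_cor, "module_intra_cor")
  stop_if(any(abs(module_trait_cor) > 1), "module_trait_cor must lie in [-1, 1]")
  assert_prob(driver_genes, "driver_genes")
  stop_if(is.null(names(driver_genes)), "'driver_genes' must be named")
  assert_prob(subclonal_rate, "subclonal_rate")
  assert_count(n_neoantigens_per_patient, "n_neoantigens_per_patient")
  assert_prob(depletion_rate, "depletion_rate")
  assert_prob(editing_mix, "editing_mix")
  stop_if(!setequal(names(editing_mix),
                    c("elimination", "evasion_LOH", "evasion_expression", "ambiguous")),
          "editing_mix must name elimination, evasion_LOH, evasion_expression, ambiguous")
  stop_if(abs(sum(editing_mix) - 1) > 1e-8, "editing_mix must sum to 1")
  assert_count(n_clonotypes, "n_clonotypes", min = 2)
  stop_if(clonotype_zipf_exponent <= 0, "clonotype_zipf_exponent must be > 0")
  assert_prob(region_sharing, "region_sharing")
  stop_if(survival_hr <= 0, "survival_hr must be > 0")
  assert_prob(censor_rate, "censor_rate")
  assert_count(n_survival, "n_survival", min = 4)
  assert_count(seed, "seed", min = 0)
  stop_if(seed > 2^31 - 10, "seed too large")
  structure(list(n_patients = n_patients,
                 regions_per_patient = regions_per_patient,
                 n_genes = n_genes, module_sizes = module_sizes,
                 module_intra_cor = module_intra_cor,
                 module_trait_cor = module_trait_cor,
                 module_traits = module_traits,
                 driver_genes = driver_genes, subclonal_rate = subclonal_rate,
                 n_neoantigens_per_patient = n_neoantigens_per_patient,
                 depletion_rate = depletion_rate, editing_mix = editing_mix,
                 n_clonotypes = n_clonotypes,
                 clonotype_zipf_exponent = clonotype_zipf_exponent,
                 region_sharing = region_sharing, survival_hr = survival_hr,
                 censor_rate = censor_rate, n_survival = n_survival,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Synthetic sample sheet
#'
#' Registry of patients, tumor regions, timepoints, tissue classes, and
#' tumor purity. Three quarters of patients are ICI-treated (one
#' pre-treatment biopsy "BX" plus post-treatment regions and two
#' peripheral PBMC timepoints); the rest are untreated multi-region cases.
#' Patients alternate between planted ITH-high and ITH-low tiers.
#'
#' @param config \code{\link{cohort_config}}.
#' @return data frame with columns \code{sample}, \code{patient},
#'   \code{region}, \code{timepoint} ("pre"/"post"/"untreated"),
#'   \code{tissue} ("tumor"/"pbmc"), \code{purity}, \code{ith_tier}.
#' @export
generate_sample_sheet <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  .with_seed(config$seed, {
    pats <- sprintf("P%02d", seq_len(config$n_patients))
    treated <- seq_len(config$n_patients) <= ceiling(0.75 * config$n_patients)
    tier <- ifelse(seq_len(config$n_patients) %% 2 == 1, "high", "low")
    rows <- list()
    region_range <- seq(config$regions_per_patient[1],
                        config$regions_per_patient[2])
    for (i in seq_along(pats)) {
      p <- pats[i]
      nreg <- region_range[sample.int(length(region_range), 1)]
      if (treated[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = paste0(p, "_BX"), patient = p, region = "BX",
          timepoint = "pre", tissue = "tumor",
          purity = round(stats::runif(1, 0.4, 0.9), 3),
          ith_tier = tier[i], stringsAsFactors = FALSE)
        tp <- "post"
      } else tp <- "untreated"
      for (r in seq_len(nreg)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_R%d", p, r), patient = p,
          region = sprintf("R%d", r), timepoint = tp, tissue = "tumor",
          purity = round(stats::runif(1, 0.4, 0.9), 3),
          ith_tier = tier[i], stringsAsFactors = FALSE)
      }
      if (treated[i]) {
        for (t in 1:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sprintf("%s_PBMC%d", p, t), patient = p,
            region = sprintf("PBMC%d", t), timepoint = "post",
            tissue = "pbmc", purity = NA_real_, ith_tier = tier[i],
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Synthetic multi-region expression with planted co-expression modules
#'
#' Latent-factor model on the log2 scale: a gene of module m with loading
#' l follows l * factor_m + sqrt(1 - l^2) * noise, with per-gene loadings
#' jittered around sqrt(rho_m) (mean pairwise intra-module correlation
#' rho_m) and per-gene location and scale offsets added so that
#' median-centering is exercised. Each module's factor is tied to its
#' configured trait at the configured correlation. The background
#' emulates the sub-threshold co-expression of a real transcriptome:
#' roughly 45\% of background genes sit in weak "mini-modules" (3-25
#' genes, mean correlation 0.1-0.85) too small for module detection,
#' giving the soft-thresholded network the heavy-tailed connectivity
#' spectrum of real data; the rest are independent noise. Samples of
#' ITH-high patients carry inflated idiosyncratic noise (x1.5), raising
#' their RNA ITH. A small set of rarely-expressed and low-variance genes
#' exercises the network filters; 10\% of background genes are flagged
#' non-coding.
#'
#' @param config \code{\link{cohort_config}}.
#' @return list with \code{expression} (raw TPM-scale matrix, genes x
#'   tumor samples), \code{coding} (named logical), \code{sheet}, and
#'   \code{truth} (module labels, factors, traits, designated escape
#'   module, tier noise factors).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sheet <- generate_sample_sheet(config)
  tum <- sheet[sheet$tissue == "tumor", , drop = FALSE]
  .with_seed(config$seed + 1L, {
    n_s <- nrow(tum)
    n_g <- config$n_genes
    k <- length(config$module_sizes)
    genes <- sprintf("G%04d", seq_len(n_g))
    module <- integer(n_g)
    idx <- 1L
    for (m in seq_len(k)) {
      module[idx:(idx + config$module_sizes[m] - 1L)] <- m
      idx <- idx + config$module_sizes[m]
    }
    names(module) <- genes
    factors <- matrix(stats::rnorm(k * n_s), k, n_s)
    traits <- list()
    for (m in seq_len(k)) {
      tr <- config$module_traits[m]
      if (tr == "none") next
      cc <- config$module_trait_cor[m]
      traits[[tr]] <- cc * factors[m, ] +
        sqrt(max(0, 1 - cc^2)) * stats::rnorm(n_s)
    }
    # traits configured on modules labeled "none" are independent noise
    for (tr in c("depletion", "javelin", "angio"))
      if (is.null(traits[[tr]])) traits[[tr]] <- stats::rnorm(n_s)
    tau <- ifelse(tum$ith_tier == "high", 1.5, 1) # idiosyncratic noise scale
    mu <- stats::runif(n_g, 3, 8)
    s <- stats::runif(n_g, 1.5, 2.5)
    x <- matrix(0, n_g, n_s, dimnames = list(genes, tum$sample))
    # loading jitter keeps the mean pairwise correlation at rho while
    # spreading per-gene connectivity (E[u] = 1 so E[l_g l_h] = rho)
    loading <- function(rho, n) {
      w <- min(0.11, 0.998 / sqrt(rho) - 1)
      sqrt(rho) * stats::runif(n, 1 - w, 1 + w)
    }
    for (m in seq_len(k)) {
      gi <- which(module == m)
      l <- loading(config$module_intra_cor[m], length(gi))
      for (j in seq_along(gi)) {
        g <- gi[j]
        x[g, ] <- mu[g] + s[g] * (l[j] * factors[m, ] +
                                    sqrt(1 - l[j]^2) * stats::rnorm(n_s) * tau)
      }
    }
    ## background: weak sub-threshold mini-modules plus independent noise
    bg <- which(module == 0)
    n_low_expr <- min(length(bg), max(2L, round(0.01 * n_g)))
    n_low_var <- max(2L, round(0.02 * n_g))
    low_expr <- bg[seq_len(n_low_expr)]
    low_var <- bg[n_low_expr + seq_len(n_low_var)]
    free_bg <- setdiff(bg, c(low_expr, low_var))
    n_mini <- round(0.45 * length(free_bg))
    mini_pool <- free_bg
    assigned <- 0L
    while (assigned < n_mini && length(mini_pool) >= 3) {
      sz <- min(sample(3:25, 1, prob = (25:3)^1.5), length(mini_pool))
      gi <- mini_pool[seq_len(sz)]
      mini_pool <- mini_pool[-seq_len(sz)]
      assigned <- assigned + sz
      f <- stats::rnorm(n_s)
      l <- loading(0.1 + 0.75 * stats::rbeta(1, 1.2, 2.2), sz)
      for (j in seq_along(gi)) {
        g <- gi[j]
        x[g, ] <- mu[g] + s[g] * (l[j] * f +
                                    sqrt(1 - l[j]^2) * stats::rnorm(n_s) * tau)
      }
    }
    for (g in c(mini_pool, low_expr)) # independent background genes
      x[g, ] <- mu[g] + s[g] * stats::rnorm(n_s) * tau
    for (g in low_var) x[g, ] <- mu[g] + 0.3 * stats::rnorm(n_s)
    raw <- pmax(2^x - 1, 0)
    for (g in low_expr) {
      on <- stats::runif(n_s) < 0.02
      raw[g, !on] <- 0
    }
    coding <- stats::setNames(rep(TRUE, n_g), genes)
    noncod <- utils::tail(setdiff(bg, c(low_expr, low_var)),
                          round(0.1 * length(bg)))
    coding[noncod] <- FALSE
    names(traits$depletion) <- names(traits$javelin) <- names(traits$angio) <- tum$sample
    list(expression = raw, coding = coding, sheet = sheet,
         truth = list(module = module,
                      factors = `dimnames<-`(factors, list(NULL, tum$sample)),
                      traits = traits,
                      escape_module = {
                        cand <- which(config$module_traits == "depletion")
                        if (length(cand)) cand[which.max(abs(config$module_trait_cor[cand]))]
                        else NA_integer_
                      },
                      low_expressed = genes[low_expr],
                      low_variance = genes[low_var]))
  })
}

#' Synthetic driver mutations, immune-evasion flags, and neoantigens
#'
#' Drivers are present per patient with the configured probabilities and
#' assigned clonal (all regions, including the pre-treatment biopsy) or
#' subclonal (a random subset covering fewer than half of the regions).
#' ITH-high patients receive a higher subclonal rate and are enriched for
#' SETD2 mutation, HLA LOH, and CDKN2A/B loss. Each patient carries
#' passenger-mutation-supported pre-treatment neoantigens (random 17-mer
#' context, mutant residue central, 9-mer peptide, binding \%Rank drawn at
#' or below 2) plus non-binder decoys straddling the threshold. A fixed
#' fraction of neoantigens is depleted clonally (absent from every treated
#' region); each depleted neoantigen draws an editing class from
#' \code{editing_mix}, with HLA-LOH flags and purity-corrected fold
#' changes consistent with its class.
#'
#' @param config \code{\link{cohort_config}}.
#' @return list with \code{mutations} (patient, sample, alteration,
#'   mutation_id, class), \code{flags} (per-region HLA-LOH and CDKN2A/B
#'   flags), \code{neoantigens} (candidate table with \%Rank), \code{fc}
#'   (per depleted (neoantigen, region): TPM and purity before/after,
#'   LOH), \code{sheet}, and \code{truth}.
#' @export
generate_mutations <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  stop_if(config$regions_per_patient[1] < 2, "regions_per_patient must be >= 2")
  sheet <- generate_sample_sheet(config)
  .with_seed(config$seed + 2L, {
    tum <- sheet[sheet$tissue == "tumor", , drop = FALSE]
    mut_rows <- list(); neo_rows <- list(); fc_rows <- list(); flag_rows <- list()
    clonality <- list(); editing_truth <- list()
    eps <- 0.1
    for (p in unique(tum$patient)) {
      ps <- tum[tum$patient == p, , drop = FALSE]
      tier <- ps$ith_tier[1]
      regions <- ps$sample # includes the pre-treatment biopsy when present
      pre <- ps$sample[ps$timepoint == "pre"]
      post <- ps$sample[ps$timepoint %in% c("post", "untreated")]
      nreg <- length(regions)
      # multiplicative tier effect so forced regimes (rate 0) stay forced
      sub_rate <- if (tier == "high") min(1, config$subclonal_rate * 2.6)
                  else config$subclonal_rate
      pur <- stats::setNames(ps$purity, ps$sample)

      ## driver alterations; ITH-high tumors are enriched for SETD2 and
      ## (more weakly) PBRM1 driver events
      pdrv <- config$driver_genes
      if (tier == "high") {
        if ("SETD2" %in% names(pdrv))
          pdrv["SETD2"] <- min(1, pdrv["SETD2"] + 0.55)
        if ("PBRM1" %in% names(pdrv))
          pdrv["PBRM1"] <- min(1, pdrv["PBRM1"] + 0.25)
      } else {
        if ("SETD2" %in% names(pdrv)) pdrv["SETD2"] <- pdrv["SETD2"] * 0.3
      }
      for (g in names(pdrv)) {
        if (stats::runif(1) > pdrv[g]) next
        # VHL is the truncal ccRCC event: always clonal when present
        subclonal <- g != "VHL" && stats::runif(1) < sub_rate && nreg >= 3
        carry <- if (subclonal) {
          kmax <- ceiling(nreg / 2) - 1L
          sample(regions, sample(seq_len(max(1L, kmax)), 1))
        } else regions
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          patient = p, sample = carry, alteration = g,
          mutation_id = paste0(p, "_", g), class = "driver",
          stringsAsFactors = FALSE)
        clonality[[length(clonality) + 1L]] <- data.frame(
          patient = p, alteration = g,
          clonality = if (subclonal) "subclonal" else "clonal",
          stringsAsFactors = FALSE)
      }

      ## per-region immune-evasion flags (patient-level lesions, all regions)
      p_loh <- if (tier == "high") 0.9 else 0.05
      p_cdkn <- if (tier == "high") 0.8 else 0.05
      has_loh <- stats::runif(1) < p_loh
      has_cdkn <- stats::runif(1) < p_cdkn
      flag_rows[[length(flag_rows) + 1L]] <- data.frame(
        patient = p, sample = regions, hla_loh = has_loh,
        cdkn2ab_loss = has_cdkn, stringsAsFactors = FALSE)

      ## neoantigens (treated patients only: need a pre-treatment baseline)
      if (length(pre) != 1) next
      n_neo <- config$n_neoantigens_per_patient
      n_dep <- round(config$depletion_rate * n_neo)
      dep_idx <- if (n_dep > 0) sample.int(n_neo, n_dep) else integer(0)
      classes <- rep(NA_character_, n_neo)
      if (n_dep > 0)
        classes[dep_idx] <- sample(names(config$editing_mix), n_dep,
                                   replace = TRUE, prob = config$editing_mix)
      for (i in seq_len(n_neo)) {
        nid <- sprintf("%s_NEO%03d", p, i)
        mid <- paste0(nid, "_mut")
        ctx <- paste(sample(.AA, 17, replace = TRUE), collapse = "")
        pep <- substr(ctx, 5, 13) # 9-mer containing the central mutant residue
        rank_a <- stats::runif(1, 0.05, 2)      # binder allele
        rank_b <- stats::runif(1, 2.001, 12)    # non-binder allele
        gene <- sprintf("G%04d", sample(config$n_genes, 1))
        depleted <- i %in% dep_idx
        carry <- if (depleted) pre else c(pre, post)
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          patient = p, sample = carry, alteration = gene,
          mutation_id = mid, class = "passenger", stringsAsFactors = FALSE)
        neo_rows[[length(neo_rows) + 1L]] <- data.frame(
          neo_id = nid, patient = p, mutation_id = mid, gene = gene,
          context17 = ctx, mutant_index = 9L, peptide = pep,
          hla_allele = c("HLA-A*02:01", "HLA-B*07:02"),
          percent_rank = c(rank_a, rank_b), stringsAsFactors = FALSE)
        tpm_pre <- stats::runif(1, 2, 50)
        for (r in post) {
          cls <- classes[i]
          lfc <- if (is.na(cls)) stats::runif(1, -0.5, 0.5)
            else switch(cls,
                        elimination = stats::runif(1, 0.05, 1.5),
                        evasion_LOH = stats::runif(1, -2, 1),
                        evasion_expression = stats::runif(1, -3, -1.1),
                        ambiguous = stats::runif(1, -0.9, -0.1))
          tpm_post <- pur[r] * ((tpm_pre / pur[pre] + eps) * 2^lfc - eps)
          fc_rows[[length(fc_rows) + 1L]] <- data.frame(
            neo_id = nid, patient = p, region = r, depleted = depleted,
            tpm_pre = tpm_pre, tpm_post = max(tpm_post, 0),
            purity_pre = unname(pur[pre]), purity_post = unname(pur[r]),
            loh = !is.na(cls) && cls == "evasion_LOH",
            stringsAsFactors = FALSE)
        }
        if (depleted)
          editing_truth[[length(editing_truth) + 1L]] <- data.frame(
            neo_id = nid, patient = p, class = classes[i],
            stringsAsFactors = FALSE)
      }
      ## non-binder decoy candidates (exercise the %Rank filter)
      for (i in seq_len(max(2L, round(0.2 * n_neo)))) {
        nid <- sprintf("%s_DEC%03d", p, i)
        ctx <- paste(sample(.AA, 17, replace = TRUE), collapse = "")
        neo_rows[[length(neo_rows) + 1L]] <- data.frame(
          neo_id = nid, patient = p, mutation_id = paste0(nid, "_mut"),
          gene = sprintf("G%04d", sample(config$n_genes, 1)),
          context17 = ctx, mutant_index = 9L,
          peptide = substr(ctx, 5, 13),
          hla_allele = c("HLA-A*02:01", "HLA-B*07:02"),
          percent_rank = stats::runif(2, 2.001, 15), stringsAsFactors = FALSE)
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          patient = p, sample = c(pre, post), alteration = "decoy",
          mutation_id = paste0(nid, "_mut"), class = "passenger",
          stringsAsFactors = FALSE)
      }
    }
    list(mutations = do.call(rbind, mut_rows),
         flags = do.call(rbind, flag_rows),
         neoantigens = do.call(rbind, neo_rows),
         fc = if (length(fc_rows)) do.call(rbind, fc_rows) else NULL,
         sheet = sheet,
         truth = list(clonality = do.call(rbind, clonality),
                      editing = if (length(editing_truth))
                        do.call(rbind, editing_truth) else NULL,
                      depletion_rate = config$depletion_rate))
  })
}

#' Synthetic TCR repertoires with Zipf abundances and controlled sharing
#'
#' Clone abundances follow a Zipf law (count of rank i proportional to
#' i^-exponent). The first region of each patient draws its clonotypes
#' from a patient-specific pool; each clonotype recurs in every other
#' region independently with probability \code{region_sharing} (counts
#' resampled with lognormal jitter), topped up with private clones.
#' Treated patients also receive a pre-treatment repertoire whose dominant
#' clone contracts tenfold in treated regions, and two peripheral PBMC
#' timepoints.
#'
#' @param config \code{\link{cohort_config}}.
#' @return list with \code{clonotypes} (AIRR-style table), \code{sheet},
#'   and \code{truth} (per-clonotype sharing pattern, planted contraction).
#' @export
generate_clonotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sheet <- generate_sample_sheet(config)
  .with_seed(config$seed + 3L, {
    nc <- config$n_clonotypes
    s_exp <- config$clonotype_zipf_exponent
    base_counts <- pmax(1, round(5 * nc^s_exp * seq_len(nc)^(-s_exp)))
    rows <- list(); share_truth <- list()
    rand_cdr3 <- function(n) vapply(seq_len(n), function(i)
      paste0("CASS", paste(sample(.AA, sample(6:10, 1), replace = TRUE),
                           collapse = ""), "F"), "")
    for (p in unique(sheet$patient)) {
      ps <- sheet[sheet$patient == p, , drop = FALSE]
      tum <- ps$sample[ps$tissue == "tumor"]
      pbmc <- ps$sample[ps$tissue == "pbmc"]
      pre <- ps$sample[ps$timepoint == "pre" & ps$tissue == "tumor"]
      # ITH-high patients share fewer clonotypes across regions
      sharing <- if (ps$ith_tier[1] == "high" && config$region_sharing > 0 &&
                     config$region_sharing < 1)
        max(0.05, config$region_sharing - 0.25) else config$region_sharing
      pool_n <- nc * (length(tum) + length(pbmc) + 1L)
      j_genes <- sprintf("TRBJ%d-%d", rep(1:2, each = 7), rep(1:7, 2))
      pool <- data.frame(cdr3_aa = rand_cdr3(pool_n),
                         v_call = sample(sprintf("TRBV%d", 1:30), pool_n, TRUE),
                         j_call = sample(j_genes, pool_n, TRUE),
                         stringsAsFactors = FALSE)
      used <- 0L
      take <- function(n) {
        out <- pool[(used + 1L):(used + n), , drop = FALSE]
        used <<- used + n
        out
      }
      anchor <- take(nc) # region-1 repertoire, defines the shared pool
      anchor$duplicate_count <- base_counts
      emit <- function(df, smp) {
        df$sample_id <- smp
        rows[[length(rows) + 1L]] <<- df[, c("sample_id", "cdr3_aa", "v_call",
                                             "j_call", "duplicate_count")]
      }
      first <- TRUE
      shared_flags <- matrix(FALSE, nc, length(tum),
                             dimnames = list(NULL, tum))
      for (r in tum) {
        if (first) {
          emit(anchor, r)
          shared_flags[, r] <- TRUE
          first <- FALSE
          next
        }
        keep <- if (sharing >= 1) rep(TRUE, nc)
          else if (sharing <= 0) rep(FALSE, nc)
          else stats::runif(nc) < sharing
        # the dominant pre-treatment clone stays observable in treated
        # regions so its planted contraction can be tracked
        if (length(pre) == 1 && sharing > 0) keep[1] <- TRUE
        shared_flags[, r] <- keep
        reg <- anchor[keep, , drop = FALSE]
        if (nrow(reg) > 0) {
          reg$duplicate_count <- pmax(1, round(reg$duplicate_count *
                                                 exp(stats::rnorm(nrow(reg), 0, 0.3))))
          if (length(pre) == 1 && r != pre && nrow(reg) > 0 && keep[1]) {
            # planted tenfold contraction of the dominant pre-treatment clone
            reg$duplicate_count[1] <- max(1, round(anchor$duplicate_count[1] * 0.1))
          }
        }
        n_priv <- nc - nrow(reg)
        if (n_priv > 0) {
          priv <- take(n_priv)
          priv$duplicate_count <- pmax(1, round(
            base_counts[seq_len(n_priv)] * exp(stats::rnorm(n_priv, 0, 0.3))))
          reg <- rbind(reg, priv)
        }
        emit(reg, r)
      }
      for (b in pbmc) {
        keep <- stats::runif(nc) < 0.5
        reg <- anchor[keep, , drop = FALSE]
        if (nrow(reg) > 0)
          reg$duplicate_count <- pmax(1, round(reg$duplicate_count *
                                                 exp(stats::rnorm(nrow(reg), 0, 0.4))))
        n_priv <- nc - nrow(reg)
        if (n_priv > 0) {
          priv <- take(n_priv)
          priv$duplicate_count <- pmax(1, round(
            base_counts[seq_len(n_priv)] * exp(stats::rnorm(n_priv, 0, 0.4))))
          reg <- rbind(reg, priv)
        }
        emit(reg, b)
      }
      share_truth[[p]] <- shared_flags
    }
    list(clonotypes = do.call(rbind, rows), sheet = sheet,
         truth = list(sharing = share_truth, contraction = 0.1,
                      zipf_exponent = s_exp))
  })
}

#' Synthetic survival table
#'
#' Exponential event times with baseline hazard 0.1 per time unit for
#' group 0 and hazard ratio \code{survival_hr} for group 1; independent
#' exponential censoring calibrated so roughly \code{censor_rate} of
#' observations are censored (\code{censor_rate = 1} censors everything at
#' the event time).
#'
#' @param config \code{\link{cohort_config}}.
#' @param n number of subjects (default \code{config$n_survival}).
#' @return data frame with columns \code{subject}, \code{time},
#'   \code{event}, \code{group} (0/1).
#' @export
generate_clinical <- function(config, n = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- n %||% config$n_survival
  assert_count(n, "n", min = 4)
  .with_seed(config$seed + 4L, {
    group <- rep(0:1, length.out = n)
    lambda0 <- 0.1
    rate <- lambda0 * config$survival_hr^group
    t_event <- stats::rexp(n, rate)
    if (config$censor_rate >= 1) {
      time <- t_event; event <- rep(0L, n)
    } else if (config$censor_rate <= 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      rate_c <- lambda0 * config$censor_rate / (1 - config$censor_rate)
      t_cens <- stats::rexp(n, rate_c)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    data.frame(subject = sprintf("S%04d", seq_len(n)), time = time,
               event = event, group = group, stringsAsFactors = FALSE)
  })
}

#' Generate the full synthetic cohort
#'
#' Runs every stage (sample sheet, expression, mutations/neoantigens,
#' clonotypes, clinical) under the per-stage seed substreams.
#'
#' @param config \code{\link{cohort_config}} (default configuration when
#'   omitted).
#' @return object of class \code{synthetic_cohort}: list with
#'   \code{config}, \code{sheet}, \code{expression}, \code{mutations},
#'   \code{clonotypes}, \code{clinical}, and the per-stage \code{truth}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  expr <- generate_expression(config)
  mut <- generate_mutations(config)
  tcr <- generate_clonotypes(config)
  clin <- generate_clinical(config)
  structure(list(config = config, sheet = expr$sheet,
                 expression = expr$expression, coding = expr$coding,
                 mutations = mut$mutations, flags = mut$flags,
                 neoantigens = mut$neoantigens, fc = mut$fc,
                 clonotypes = tcr$clonotypes, clinical = clin,
                 truth = list(expression = expr$truth, mutations = mut$truth,
                              clonotypes = tcr$truth)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-regional cohort\n")
  cat(sprintf("  %d patients, %d samples (%d tumor)\n",
              length(unique(x$sheet$patient)), nrow(x$sheet),
              sum(x$sheet$tissue == "tumor")))
  cat(sprintf("  expression: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  %d mutation calls, %d neoantigen records, %d clonotype rows\n",
              nrow(x$mutations), nrow(x$neoantigens), nrow(x$clonotypes)))
  cat(sprintf("  survival: %d subjects, HR %.2f\n", nrow(x$clinical),
              x$config$survival_hr))
  invisible(x)
}
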