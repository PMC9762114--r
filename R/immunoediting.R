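#' Enumerate candidate MHC-I peptides from a mutant 17-mer context
#'
#' Sliding-window enumeration of all 8-11 amino-acid substrings of the
#' mutant context that contain the mutant residue. Contexts shorter than 17
#' residues (mutations near protein termini) are allowed and flagged with a
#' warning. A full 17-mer with the mutant residue central (position 9)
#' yields 8 + 9 + 8 + 7 = 32 candidates.
#'
#' @param context17 amino-acid string (ideally 17-mer, mutant central).
#' @param mutant_index 1-based position of the mutant residue within
#'   \code{context17}.
#' @return data frame with columns \code{peptide}, \code{length},
#'   \code{start} (offset in the context) and \code{mutant_pos} (position of
#'   the mutant residue within the peptide).
#' @export
enumerate_peptides <- function(context17, mutant_index) {
  stop_if(!is.character(context17) || length(context17) != 1,
          "'context17' must be a single string")
  L <- nchar(context17)
  stop_if(mutant_index < 1 || mutant_index > L,
          "mutant residue lies outside the context string")
  if (L < 17) warning(sprintf("context is %d < 17 residues (protein terminus?)", L))
  rows <- list()
  for (len in 8:11) {
    if (len > L) next
    starts <- max(1, mutant_index - len + 1):min(mutant_index, L - len + 1)
    starts <- starts[starts >= 1 & starts + len - 1 <= L]
    for (st in starts) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(context17, st, st + len - 1), length = len,
        start = st, mutant_pos = mutant_index - st + 1L,
        stringsAsFactors = FALSE)
    }
  }
  stop_if(length(rows) == 0, "no 8-11-mer window fits the context")
  do.call(rbind, rows)
}

#' Per-sample neoantigen detection
#'
#' A candidate neoantigen is detected in a sample iff its supporting
#' mutation is called in that sample and its best (minimum) binding
#' percentile rank over the patient's HLA alleles is at or below
#' \code{rank_cut} (boundary inclusive: \%Rank = 2 is a binder at the
#' default cutoff). The "expressed" sub-flag additionally requires the
#' source-gene TPM strictly above \code{tpm_cut} in that sample.
#'
#' @param records neoantigen table: one row per (neoantigen, allele) with
#'   columns \code{neo_id}, \code{mutation_id}, \code{gene},
#'   \code{percent_rank}; rows of one \code{neo_id} share the mutation.
#' @param mutations mutation calls: columns \code{sample},
#'   \code{mutation_id}.
#' @param expression optional gene x sample TPM matrix for the expressed
#'   flag.
#' @param rank_cut binding threshold on \%Rank (default 2, inclusive).
#' @param tpm_cut expression threshold (default 1, strict).
#' @param require_expressed when TRUE, detection additionally requires the
#'   expressed flag (expression-level detection variant).
#' @return data frame with columns \code{neo_id}, \code{sample},
#'   \code{detected}, \code{expressed} (NA when no expression given).
#' @export
detect_neoantigens <- function(records, mutations, expression = NULL,
                               rank_cut = 2, tpm_cut = 1,
                               require_expressed = FALSE) {
  assert_cols(records, c("neo_id", "mutation_id", "percent_rank"), "records")
  assert_cols(mutations, c("sample", "mutation_id"), "mutations")
  bad <- records$neo_id[is.na(records$percent_rank)]
  stop_if(length(bad) > 0,
          paste("missing %Rank for:", paste(unique(bad), collapse = ", ")))
  stop_if(any(records$percent_rank <= 0), "percent_rank must be positive")
  best <- tapply(records$percent_rank, records$neo_id, min)
  meta <- records[!duplicated(records$neo_id),
                  intersect(c("neo_id", "mutation_id", "gene"), names(records)),
                  drop = FALSE]
  meta$binder <- best[meta$neo_id] <= rank_cut
  samples <- unique(mutations$sample)
  if (!is.null(expression)) samples <- union(samples, colnames(expression))
  grid <- expand.grid(neo_id = meta$neo_id, sample = samples,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, meta, by = "neo_id", sort = FALSE)
  called <- paste(grid$mutation_id, grid$sample) %in%
    paste(mutations$mutation_id, mutations$sample)
  grid$detected <- called & grid$binder
  grid$expressed <- NA
  if (!is.null(expression) && "gene" %in% names(grid)) {
    assert_matrix_named(expression)
    ok <- grid$gene %in% rownames(expression) & grid$sample %in% colnames(expression)
    grid$expressed[ok] <- expression[cbind(grid$gene[ok], grid$sample[ok])] > tpm_cut
    if (require_expressed) grid$detected <- grid$detected & grid$expressed %in% TRUE
  }
  grid[order(grid$neo_id, grid$sample), c("neo_id", "sample", "detected", "expressed")]
}

#' Fraction of pre-treatment neoantigens depleted per treated region
#'
#' For each treated region r, the depletion fraction is
#' |pre \ post_r| / |pre| — the share of neoantigens detected before
#' therapy that are undetectable in that region afterwards. The patient
#' value is the mean over treated regions.
#'
#' @param pre character vector of neoantigen identifiers detected
#'   pre-treatment.
#' @param post_sets named list: per treated region, the identifiers
#'   detected after treatment.
#' @return list with \code{per_region} (named vector) and \code{patient}
#'   (mean fraction); both NA with a warning when \code{pre} is empty.
#' @export
depletion_fraction <- function(pre, post_sets) {
  stop_if(!is.list(post_sets) || is.null(names(post_sets)),
          "'post_sets' must be a named list of per-region detected sets")
  if (length(pre) == 0) {
    warning("empty pre-treatment neoantigen set; depletion undefined")
    return(list(per_region = stats::setNames(rep(NA_real_, length(post_sets)),
                                             names(post_sets)),
                patient = NA_real_))
  }
  pre <- unique(pre)
  fr <- vapply(post_sets, function(p) length(setdiff(pre, p)) / length(pre), 0)
  list(per_region = fr, patient = mean(fr))
}

#' Purity-corrected expression fold change
#'
#' FC = (TPM_post / purity_post + eps) / (TPM_pre / purity_pre + eps), with
#' a small pseudo-floor eps (default 0.1 TPM) guarding against division by
#' zero. Returned on the log2 scale.
#'
#' @param tpm_pre,tpm_post source-gene TPM before/after treatment.
#' @param purity_pre,purity_post tumor purity in (0, 1].
#' @param eps pseudo-floor in TPM units.
#' @return log2 fold change.
#' @export
purity_corrected_log2fc <- function(tpm_pre, tpm_post, purity_pre, purity_post,
                                    eps = 0.1) {
  stop_if(anyNA(c(purity_pre, purity_post)), "missing tumor purity")
  stop_if(any(purity_pre <= 0 | purity_pre > 1 | purity_post <= 0 | purity_post > 1),
          "purity must lie in (0, 1]")
  log2((tpm_post / purity_post + eps) / (tpm_pre / purity_pre + eps))
}

#' Classify depleted neoantigens: elimination vs evasion
#'
#' Applies the immunoediting accounting rules to each depleted
#' (neoantigen, region) pair: HLA LOH affecting the presenting allele
#' implies evasion by antigen-presentation loss; otherwise a
#' purity-corrected log2 fold change below -1 implies evasion by
#' expression loss; a non-negative log2 fold change implies immune
#' elimination (clone contraction); fold changes in [-1, 0) are left
#' ambiguous.
#'
#' @param calls data frame with one row per depleted (neoantigen, region)
#'   pair and columns \code{loh} (logical) and \code{log2fc} (numeric,
#'   purity-corrected; see \code{\link{purity_corrected_log2fc}}).
#' @return the input with a \code{class} column in
#'   \{"evasion_LOH", "evasion_expression", "elimination", "ambiguous"\}.
#' @export
classify_editing <- function(calls) {
  assert_cols(calls, c("loh", "log2fc"), "calls")
  stop_if(anyNA(calls$loh) || anyNA(calls$log2fc),
          "loh and log2fc must be complete")
  calls$class <- ifelse(calls$loh, "evasion_LOH",
                 ifelse(calls$log2fc < -1, "evasion_expression",
                 ifelse(calls$log2fc >= 0, "elimination", "ambiguous")))
  calls
}

#' Clonality of neoantigen depletion
#'
#' Counts, for each pre-treatment neoantigen, in how many treated regions
#' it is depleted; depletion in every region is flagged clonal.
#'
#' @param pre pre-treatment detected neoantigen identifiers.
#' @param post_sets named list of per-region detected sets (>= 2 regions).
#' @return list with \code{counts} (named per-neoantigen region counts),
#'   \code{clonal} (logical flags), and \code{histogram} (table of counts
#'   0..n_regions).
#' @export
depletion_clonality <- function(pre, post_sets) {
  stop_if(length(post_sets) < 2, "need >= 2 treated regions")
  pre <- unique(pre)
  nreg <- length(post_sets)
  counts <- vapply(pre, function(nn)
    sum(vapply(post_sets, function(p) !(nn %in% p), TRUE)), 0L)
  hist <- table(factor(counts, levels = 0:nreg))
  list(counts = counts, clonal = counts == nreg, histogram = hist)
}

#' Residue-level selection between depleted and preserved neoantigens
#'
#' For each of the 20 amino acids, builds the 2x2 table of mutant-residue
#' membership among depleted versus preserved neoantigens and reports the
#' odds ratio, two-sided Fisher exact p, and Benjamini-Hochberg q.
#'
#' @param depleted,preserved character vectors of single-letter mutant
#'   residues of depleted / preserved neoantigens.
#' @return data frame with one row per residue: counts, \code{odds_ratio},
#'   \code{p.value}, \code{q.value}.
#' @export
aa_selection <- function(depleted, preserved) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(unique(c(depleted, preserved)), aa)
  stop_if(length(bad) > 0,
          paste("residues outside the 20-letter alphabet:", paste(bad, collapse = ", ")))
  rows <- lapply(aa, function(r) {
    a <- sum(depleted == r); b <- length(depleted) - a
    c_ <- sum(preserved == r); d <- length(preserved) - c_
    p <- fisher_exact(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))$p.value
    or <- if (b * c_ == 0) {
      if (a * d == 0) 1 else Inf
    } else (a * d) / (b * c_)
    data.frame(residue = r, depleted_with = a, depleted_without = b,
               preserved_with = c_, preserved_without = d,
               odds_ratio = or, p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q.value <- bh_adjust(out$p.value)
  out
}

#' Immunogenic HERV loci
#'
#' A HERV locus is immunogenic when its expression correlates positively
#' with TIL abundance at Benjamini-Hochberg FDR below \code{fdr}. TIL
#' abundance defaults to an immune/T-effector ssGSEA score computed
#' upstream.
#'
#' @param hervs HERV locus x sample expression matrix (>= 5 samples).
#' @param til named per-sample TIL abundance score aligned to the matrix
#'   columns.
#' @param fdr FDR threshold (default 0.05).
#' @return data frame per testable locus: \code{locus}, \code{rho},
#'   \code{p.value}, \code{q.value}, \code{immunogenic}.
#' @export
herv_immunogenic <- function(hervs, til, fdr = 0.05) {
  assert_matrix_named(hervs)
  stop_if(ncol(hervs) < 5, "need >= 5 samples")
  stop_if(any(hervs < 0), "HERV expression must be non-negative")
  til <- til[colnames(hervs)]
  stop_if(anyNA(til), "TIL score missing for some samples")
  keep <- apply(hervs, 1, function(x) stats::sd(x) > 0)
  if (any(!keep)) warning(sprintf("skipping %d constant locus/loci", sum(!keep)))
  loci <- rownames(hervs)[keep]
  res <- lapply(loci, function(l) {
    sp <- spearman(hervs[l, ], til)
    data.frame(locus = l, rho = sp$rho, p.value = sp$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q.value <- bh_adjust(out$p.value)
  out$immunogenic <- out$q.value < fdr & out$rho > 0
  out
}

#' HERV editing after therapy
#'
#' Per treated region, HERV editing is the median over immunogenic loci of
#' the purity-corrected log2 expression change relative to the matched
#' pre-treatment sample. Also reports the per-sample median expression over
#' all loci (median HERV) with iterated Grubbs outlier flags.
#'
#' @param hervs HERV locus x sample expression matrix.
#' @param sheet sample sheet with columns \code{sample}, \code{patient},
#'   \code{timepoint}, \code{tissue}, \code{purity}.
#' @param immunogenic character vector of immunogenic locus names (e.g.,
#'   from \code{\link{herv_immunogenic}}).
#' @param eps TPM pseudo-floor in the fold change (default 0.1).
#' @param alpha Grubbs significance level (default 0.05).
#' @return list with \code{editing} (data frame: patient, region sample,
#'   editing score), \code{median_herv} (named per-sample medians), and
#'   \code{outliers} (samples flagged by the Grubbs test).
#' @export
herv_editing <- function(hervs, sheet, immunogenic, eps = 0.1, alpha = 0.05) {
  assert_matrix_named(hervs)
  assert_cols(sheet, c("sample", "patient", "timepoint", "tissue", "purity"), "sheet")
  immunogenic <- intersect(immunogenic, rownames(hervs))
  med <- apply(hervs, 2, stats::median)
  gr <- if (length(med) >= 3) grubbs_test(med, alpha = alpha) else list(index = integer(0))
  outliers <- names(med)[gr$index]
  if (length(immunogenic) == 0) {
    warning("no immunogenic loci; HERV editing undefined")
    return(list(editing = data.frame(patient = character(0), sample = character(0),
                                     editing = numeric(0)),
                median_herv = med, outliers = outliers))
  }
  sheet <- sheet[sheet$sample %in% colnames(hervs), , drop = FALSE]
  rows <- list()
  for (p in unique(sheet$patient)) {
    ps <- sheet[sheet$patient == p, , drop = FALSE]
    pre <- ps$sample[ps$timepoint == "pre" & ps$tissue == "tumor"]
    post <- ps$sample[ps$timepoint == "post" & ps$tissue == "tumor"]
    if (length(pre) != 1 || length(post) == 0) next
    pur <- stats::setNames(ps$purity, ps$sample)
    for (r in post) {
      lfc <- log2((hervs[immunogenic, r] / pur[r] + eps) /
                    (hervs[immunogenic, pre] / pur[pre] + eps))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, sample = r, editing = stats::median(lfc),
        stringsAsFactors = FALSE)
    }
  }
  list(editing = if (length(rows)) do.call(rbind, rows) else
         data.frame(patient = character(0), sample = character(0),
                    editing = numeric(0)),
       median_herv = med, outliers = outliers)
}
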