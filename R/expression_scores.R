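#' The 12-gene immune-escape signature
#'
#' Refined transcriptional signature of immune escape in clear cell renal
#' cell carcinoma, derived from the co-expression module most correlated
#' with the fraction of neoantigens depleted after checkpoint therapy.
#'
#' @return character vector of 12 gene symbols.
#' @export
immune_escape_signature <- function() {
  c("TIMP1", "PXDN", "COL15A1", "OLFML2B", "COL5A2", "DLX5",
    "SOX11", "KLHDC8A", "UNC5A", "ADAMTS14", "MMP11", "FN1")
}

# resolve a signature to its member genes present in the matrix
.resolve_signature <- function(mat, genes, name = "signature") {
  stop_if(length(genes) == 0, sprintf("gene set '%s' is empty", name))
  genes <- unique(genes)
  hit <- genes[genes %in% rownames(mat)]
  if (length(hit) == 0)
    stop(sprintf("no genes of signature '%s' found in the expression matrix", name),
         call. = FALSE)
  if (length(hit) < length(genes)) {
    if (length(hit) < 0.5 * length(genes))
      stop(sprintf("fewer than 50%% of signature '%s' genes found (%d of %d)",
                   name, length(hit), length(genes)), call. = FALSE)
    warning(sprintf("signature '%s': dropping %d gene(s) absent from the matrix",
                    name, length(genes) - length(hit)))
  }
  hit
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' For each sample, genes are ranked by decreasing expression (ties broken
#' deterministically by gene identifier) and the enrichment score is the sum
#' over the ranked list of the difference between the weighted cumulative
#' fraction of in-set genes and the uniform cumulative fraction of out-of-set
#' genes. The gene at descending position j carries weight
#' (N - j + 1)^\code{weight_exponent}, so the most highly expressed gene
#' weighs most. Scores depend only on within-sample ranks, hence are
#' invariant to any strictly increasing transform of one sample's expression.
#'
#' @param mat expression matrix, genes x samples, non-negative abundances
#'   (TPM/FPKM); ranks are taken on the raw scale.
#' @param signature character vector of gene identifiers (or a named list
#'   element from \code{\link{read_gmt}}).
#' @param weight_exponent rank weight exponent alpha (default 0.25).
#' @param name label used in error messages.
#' @return named numeric vector of per-sample enrichment scores.
#' @export
ssgsea_score <- function(mat, signature, weight_exponent = 0.25,
                         name = "signature") {
  assert_matrix_named(mat)
  stop_if(nrow(mat) < 2, "need at least 2 genes")
  genes <- .resolve_signature(mat, signature, name)
  n <- nrow(mat)
  m <- length(genes)
  stop_if(m >= n, "signature covers the whole matrix; no out-of-set genes")
  w_pos <- (n:1)^weight_exponent # weight by descending-rank position
  es <- vapply(seq_len(ncol(mat)), function(s) {
    ord <- order(-mat[, s], rownames(mat))
    inset <- rownames(mat)[ord] %in% genes
    w_in <- w_pos * inset
    p_in <- cumsum(w_in) / sum(w_in)
    p_out <- cumsum(!inset) / (n - m)
    sum(p_in - p_out)
  }, 0)
  names(es) <- colnames(mat)
  es
}

#' Cohort Z-scores of signature scores
#'
#' Centers and scales per-sample scores over the cohort using the sample
#' (n - 1) standard deviation.
#'
#' @param scores named numeric vector of per-sample enrichment scores.
#' @return Z-scores with mean 0 and unit variance.
#' @export
zscore_signatures <- function(scores) {
  assert_numeric(scores)
  stop_if(length(scores) < 2, "need at least 2 samples")
  s <- stats::sd(scores)
  stop_if(s == 0, "degenerate signature: zero variance across the cohort")
  (scores - mean(scores)) / s
}

#' Median high/low split
#'
#' Values strictly above the median are "high"; values at or below the
#' median are "low" (ties at the median classify low, keeping "high"
#' strictly above threshold).
#'
#' @param values numeric vector (length >= 2), names preserved.
#' @return character vector of "high"/"low" labels.
#' @export
classify_high_low <- function(values) {
  assert_numeric(values)
  stop_if(length(values) < 2, "need at least 2 values")
  out <- ifelse(values > stats::median(values), "high", "low")
  names(out) <- names(values)
  out
}

#' Per-patient consistency of region-level high/low labels
#'
#' Collapses region labels to a patient class: all-high regions give "high",
#' all-low give "low", otherwise "mixed". Pre-treatment regions of treated
#' patients are excluded before tallying, and patients left with a single
#' eligible region are flagged and excluded from the class tally.
#'
#' @param labels named character vector of "high"/"low" region labels
#'   (names are sample identifiers).
#' @param sheet sample sheet data frame with columns \code{sample},
#'   \code{patient}, \code{timepoint} ("pre"/"post"/"untreated"),
#'   \code{tissue}.
#' @return data frame with one row per patient: \code{patient},
#'   \code{class} ("high"/"low"/"mixed", NA when excluded),
#'   \code{n_regions}, and \code{excluded} flag ("single-region" or "").
#' @export
patient_consistency <- function(labels, sheet) {
  assert_cols(sheet, c("sample", "patient", "timepoint", "tissue"), "sheet")
  unknown <- setdiff(names(labels), sheet$sample)
  stop_if(length(unknown) > 0,
          paste("labels contain unknown sample(s):", paste(unknown, collapse = ", ")))
  sub <- sheet[sheet$sample %in% names(labels) & sheet$tissue == "tumor" &
                 sheet$timepoint != "pre", , drop = FALSE]
  pats <- unique(sheet$patient[sheet$sample %in% names(labels)])
  res <- lapply(pats, function(p) {
    smp <- sub$sample[sub$patient == p]
    lab <- labels[smp]
    n <- length(lab)
    if (n < 2)
      return(data.frame(patient = p, class = NA_character_, n_regions = n,
                        excluded = "single-region", stringsAsFactors = FALSE))
    cls <- if (all(lab == "high")) "high" else if (all(lab == "low")) "low" else "mixed"
    data.frame(patient = p, class = cls, n_regions = n, excluded = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Score a cohort against a collection of gene signatures
#'
#' Runs \code{\link{ssgsea_score}} for every signature, attaches cohort
#' Z-scores and median high/low labels.
#'
#' @param mat expression matrix, genes x samples.
#' @param signatures named list of gene identifier vectors (e.g., from
#'   \code{\link{read_gmt}}).
#' @param weight_exponent passed to \code{\link{ssgsea_score}}.
#' @return data frame with columns \code{sample}, \code{signature},
#'   \code{es}, \code{z}, \code{label}.
#' @export
score_signatures <- function(mat, signatures, weight_exponent = 0.25) {
  stop_if(is.null(names(signatures)) || any(names(signatures) == ""),
          "'signatures' must be a named list")
  out <- lapply(names(signatures), function(nm) {
    es <- ssgsea_score(mat, signatures[[nm]], weight_exponent, name = nm)
    data.frame(sample = names(es), signature = nm, es = unname(es),
               z = unname(zscore_signatures(es)),
               label = unname(classify_high_low(es)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
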