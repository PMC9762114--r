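# Weighted co-expression network analysis: soft-thresholded correlation
# network, topological overlap, average-linkage module detection with a
# static cut, eigengenes, trait annotation, and greedy signature refinement.

#' Filter genes for network analysis
#'
#' Keeps genes that are expressed (raw abundance > 0) in at least
#' \code{min_frac_expressed} of samples, have a log2 standard deviation
#' strictly above \code{sd_floor}, and are flagged protein-coding.
#'
#' @param mat raw expression matrix (TPM), genes x samples.
#' @param coding optional named logical protein-coding flag per gene
#'   (default: all considered coding).
#' @param min_frac_expressed minimum expressed fraction (default 0.05).
#' @param sd_floor genes with sd(log2(TPM + 1)) <= this are removed
#'   (default 1).
#' @param pseudocount log2 pseudocount (default 1).
#' @return filtered raw matrix.
#' @export
filter_genes <- function(mat, coding = NULL, min_frac_expressed = 0.05,
                         sd_floor = 1, pseudocount = 1) {
  assert_matrix_named(mat)
  frac <- rowMeans(mat > 0)
  sds <- apply(log2(mat + pseudocount), 1, stats::sd)
  keep <- frac >= min_frac_expressed & sds > sd_floor
  if (!is.null(coding)) {
    cod <- coding[rownames(mat)]
    cod[is.na(cod)] <- FALSE
    keep <- keep & cod
  }
  stop_if(sum(keep) == 0, "no genes survive filtering")
  mat[keep, , drop = FALSE]
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted adjacency a_ij = |cor(x_i, x_j)|^power with zero
#' diagonal, Pearson correlation on the log2 scale.
#'
#' @param x log2 expression matrix (genes x samples) or a precomputed
#'   gene x gene correlation matrix (square, symmetric, unit diagonal).
#' @param power soft-thresholding exponent beta.
#' @return adjacency matrix in [0, 1], zero diagonal.
#' @export
adjacency_matrix <- function(x, power) {
  x <- as.matrix(x)
  cors <- if (nrow(x) == ncol(x) && isTRUE(all.equal(unname(diag(x)), rep(1, nrow(x)))) &&
              isSymmetric(unname(x))) x else stats::cor(t(x))
  stop_if(anyNA(cors), "correlations undefined (constant gene?)")
  a <- abs(cors)^power
  diag(a) <- 0
  a
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the unsigned adjacency, computes the
#' connectivity k_i = sum_j a_ij, bins k into \code{n_bins} equal-width
#' bins and takes the scale-free fit R^2 as the squared correlation of
#' log10(bin frequency) against log10(mean bin connectivity). Returns the
#' smallest power whose R^2 reaches \code{r2_target}; if none does, the
#' argmax R^2 with a warning.
#'
#' @param mat log2 expression matrix, genes x samples (>= 20 genes,
#'   >= 8 samples).
#' @param powers candidate grid (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins equal-width connectivity bins (default 10).
#' @return list with \code{power} and \code{fit_table} (power, r2,
#'   mean_connectivity).
#' @export
pick_soft_power <- function(mat, powers = 1:20, r2_target = 0.8, n_bins = 10) {
  assert_matrix_named(mat)
  stop_if(nrow(mat) < 20, "need >= 20 genes")
  stop_if(ncol(mat) < 8, "need >= 8 samples")
  stop_if(length(powers) == 0, "empty power grid")
  cors <- stats::cor(t(mat))
  stop_if(anyNA(cors), "correlations undefined (constant gene?)")
  stop_if(all(abs(cors[upper.tri(cors)]) < 1e-12), "degenerate (all-zero) correlations")
  fit <- vapply(powers, function(b) {
    a <- abs(cors)^b
    diag(a) <- 0
    k <- rowSums(a)
    if (diff(range(k)) < 1e-12) return(c(NA_real_, mean(k)))
    bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(ok) < 3) return(c(NA_real_, mean(k)))
    r <- stats::cor(log10(freq[ok]), log10(kmean[ok]))
    # a scale-free topology requires p(k) to *decay* in k: only a
    # negative log-log slope counts as fit
    c(if (r < 0) r^2 else 0, mean(k))
  }, c(0, 0))
  tab <- data.frame(power = powers, r2 = fit[1, ], mean_connectivity = fit[2, ])
  hit <- which(!is.na(tab$r2) & tab$r2 >= r2_target)
  if (length(hit) > 0) {
    power <- tab$power[hit[1]]
  } else {
    power <- tab$power[which.max(tab$r2)]
    warning(sprintf("no power reaches scale-free R^2 >= %.2f; using argmax (%d)",
                    r2_target, power))
  }
  list(power = power, fit_table = tab)
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_u a_iu a_uj and k_i the node connectivity; the diagonal is
#' set to 1. Measures shared network neighborhood beyond the direct edge.
#'
#' @param a adjacency matrix: symmetric, zero diagonal, entries in [0, 1].
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  stop_if(!isSymmetric(unname(a)), "adjacency must be symmetric")
  stop_if(any(diag(a) != 0), "adjacency must have zero diagonal")
  stop_if(any(a < 0 | a > 1), "adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  L <- a %*% a
  tom <- (L + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut at a static height; clusters smaller than \code{min_module_size}
#' are left unassigned (module 0). Modules are labeled 1, 2, ... in
#' decreasing size order.
#'
#' @param tom TOM similarity matrix.
#' @param cut_height static tree-cut height on the 1 - TOM scale
#'   (default 0.95).
#' @param min_module_size smallest admissible module (default 30).
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, cut_height = 0.95, min_module_size = 30) {
  tom <- as.matrix(tom)
  stop_if(!isSymmetric(unname(tom)), "TOM must be symmetric")
  stop_if(cut_height <= 0 || cut_height >= 1, "cut_height must lie in (0, 1)")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # average linkage is monotone; exact ties can leave float-noise
  # inversions that cutree rejects
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_ids <- names(sizes)[sizes >= min_module_size]
  out <- integer(length(cl))
  names(out) <- names(cl) %||% rownames(tom)
  if (length(keep_ids) > 0) {
    ord <- keep_ids[order(-sizes[keep_ids])]
    for (i in seq_along(ord)) out[cl == as.integer(ord[i])] <- i
  }
  out
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized module
#' submatrix across samples, scaled to unit variance and sign-oriented so
#' its correlation with the module mean expression is non-negative.
#'
#' @param mat log2 expression matrix, genes x samples.
#' @param genes module member gene identifiers.
#' @return named per-sample eigengene vector (unit variance).
#' @export
module_eigengene <- function(mat, genes) {
  assert_matrix_named(mat)
  genes <- intersect(genes, rownames(mat))
  stop_if(length(genes) == 0, "module has no genes present in the matrix")
  x <- mat[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s) from module", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    stop_if(nrow(x) == 0, "all module genes have zero variance")
  }
  z <- t(scale(t(x))) # genes standardized across samples
  if (nrow(z) == 1) {
    e <- z[1, ]
  } else {
    sv <- svd(z)
    e <- sv$v[, 1] * sv$d[1]
  }
  e <- e / stats::sd(e)
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  names(e) <- colnames(mat)
  e
}

#' Eigengenes for all modules
#'
#' @param mat log2 expression matrix.
#' @param modules named module assignment from \code{\link{detect_modules}}.
#' @return sample x module matrix of eigengenes (module 0 excluded).
#' @export
module_eigengenes <- function(mat, modules) {
  ids <- sort(unique(modules[modules > 0]))
  stop_if(length(ids) == 0, "no assigned modules")
  em <- vapply(ids, function(m) module_eigengene(mat, names(modules)[modules == m]),
               numeric(ncol(mat)))
  colnames(em) <- paste0("ME", ids)
  rownames(em) <- colnames(mat)
  em
}

#' Annotate modules by trait correlation
#'
#' Computes the Spearman correlation of every module eigengene with every
#' trait and labels, per trait, the module with the highest correlation
#' (ties broken by module size). The trait named \code{escape_trait}
#' (default "depletion", the fraction of neoantigens depleted) defines the
#' immune-escape module.
#'
#' @param eigengenes sample x module eigengene matrix
#'   (\code{\link{module_eigengenes}}).
#' @param traits sample x trait numeric matrix or data frame, rows aligned
#'   to eigengene rows.
#' @param modules module assignment (used for tie-breaking by size).
#' @param escape_trait trait whose top module is labeled immune escape.
#' @return list with \code{correlations} (module x trait rho matrix),
#'   \code{labels} (named character: trait -> module), and
#'   \code{escape_module} (integer module id or NA).
#' @export
annotate_modules <- function(eigengenes, traits, modules,
                             escape_trait = "depletion") {
  traits <- as.matrix(traits)
  stop_if(nrow(traits) != nrow(eigengenes),
          "traits must be aligned to eigengene samples")
  sizes <- table(modules[modules > 0])
  rho <- matrix(NA_real_, ncol(eigengenes), ncol(traits),
                dimnames = list(colnames(eigengenes), colnames(traits)))
  for (tr in colnames(traits)) {
    v <- traits[, tr]
    if (stats::sd(v) == 0) {
      warning(sprintf("trait '%s' has zero variance; skipped", tr))
      next
    }
    rho[, tr] <- apply(eigengenes, 2, function(e)
      stats::cor(e, v, method = "spearman"))
  }
  labels <- stats::setNames(rep(NA_character_, ncol(traits)), colnames(traits))
  for (tr in colnames(traits)) {
    r <- stats::setNames(rho[, tr], rownames(rho))
    if (all(is.na(r))) next
    best <- which(r == max(r, na.rm = TRUE))
    if (length(best) > 1) { # tie: prefer the larger module
      ids <- as.integer(sub("^ME", "", names(best)))
      best <- best[which.max(sizes[as.character(ids)])]
    }
    labels[tr] <- names(r)[best[1]]
  }
  esc <- if (escape_trait %in% names(labels) && !is.na(labels[escape_trait]))
    as.integer(sub("^ME", "", labels[escape_trait])) else NA_integer_
  list(correlations = rho, labels = labels, escape_module = esc)
}

#' Greedy refinement of a module into a tight signature
#'
#' Orders module genes by mean pairwise Spearman correlation (descending),
#' seeds the signature with the top gene, and adds each subsequent gene
#' only when its correlation with every already-selected gene is at least
#' \code{rho_floor}. The output therefore satisfies min pairwise rho >=
#' \code{rho_floor} by construction.
#'
#' @param x log2 expression matrix (genes x samples) or a precomputed
#'   square symmetric Spearman correlation matrix with unit diagonal.
#' @param genes module member genes (ignored when \code{x} is already a
#'   correlation matrix).
#' @param rho_floor minimum admissible pairwise correlation (default 0.6).
#' @return character vector of selected genes.
#' @export
refine_signature <- function(x, genes = NULL, rho_floor = 0.6) {
  x <- as.matrix(x)
  is_cor <- nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
    isTRUE(all.equal(unname(diag(x)), rep(1, nrow(x)))) && all(abs(x) <= 1 + 1e-12)
  rho <- if (is_cor) x else {
    stop_if(is.null(genes), "supply module genes with an expression matrix")
    genes <- intersect(genes, rownames(x))
    stop_if(length(genes) < 2, "module must have >= 2 genes")
    stats::cor(t(x[genes, , drop = FALSE]), method = "spearman")
  }
  stop_if(nrow(rho) < 2, "module must have >= 2 genes")
  g <- rownames(rho)
  mean_rho <- (rowSums(rho) - 1) / (nrow(rho) - 1)
  ord <- g[order(-mean_rho, g)]
  sel <- ord[1]
  for (cand in ord[-1]) {
    if (all(rho[cand, sel] >= rho_floor)) sel <- c(sel, cand)
  }
  if (length(sel) == 1)
    warning(sprintf("no gene pair meets rho >= %.2f; returning the top gene", rho_floor))
  sel
}

#' End-to-end co-expression module discovery
#'
#' Convenience pipeline: gene filtering, soft-power selection, adjacency,
#' TOM, module detection, eigengenes, trait annotation, and greedy
#' refinement of the immune-escape module.
#'
#' @param mat raw expression matrix (TPM), genes x samples.
#' @param traits sample x trait matrix/data frame (must include the
#'   \code{escape_trait} column for escape annotation).
#' @param coding optional protein-coding flags for
#'   \code{\link{filter_genes}}.
#' @param powers,r2_target soft-power grid and scale-free target.
#' @param cut_height,min_module_size module detection parameters.
#' @param rho_floor refinement floor.
#' @param escape_trait trait defining the immune-escape module.
#' @return object of class \code{escape_modules}: list with the filtered
#'   matrix dimensions, chosen power, module assignment, eigengenes,
#'   annotation, and refined signature.
#' @export
discover_escape_modules <- function(mat, traits, coding = NULL, powers = 1:20,
                                    r2_target = 0.8, cut_height = 0.95,
                                    min_module_size = 30, rho_floor = 0.6,
                                    escape_trait = "depletion") {
  filt <- filter_genes(mat, coding = coding)
  lg <- log2(filt + 1)
  sp <- pick_soft_power(lg, powers = powers, r2_target = r2_target)
  a <- adjacency_matrix(lg, sp$power)
  tom <- tom_similarity(a)
  modules <- detect_modules(tom, cut_height = cut_height,
                            min_module_size = min_module_size)
  stop_if(all(modules == 0), "no modules detected")
  em <- module_eigengenes(lg, modules)
  traits <- as.matrix(traits)[colnames(mat), , drop = FALSE]
  ann <- annotate_modules(em, traits, modules, escape_trait = escape_trait)
  refined <- if (!is.na(ann$escape_module)) {
    esc_genes <- names(modules)[modules == ann$escape_module]
    if (length(esc_genes) >= 2)
      refine_signature(lg, esc_genes, rho_floor = rho_floor) else esc_genes
  } else character(0)
  structure(list(n_genes = nrow(filt), n_samples = ncol(filt),
                 power = sp$power, fit_table = sp$fit_table,
                 modules = modules, eigengenes = em, annotation = ann,
                 refined_signature = refined,
                 network = "unsigned", cut_height = cut_height),
            class = "escape_modules")
}

#' @export
print.escape_modules <- function(x, ...) {
  sizes <- table(x$modules[x$modules > 0])
  cat("Co-expression module set (unsigned network)\n")
  cat(sprintf("  %d genes x %d samples, soft power %d\n",
              x$n_genes, x$n_samples, x$power))
  cat(sprintf("  %d module(s): sizes %s; %d unassigned\n", length(sizes),
              paste(as.integer(sizes), collapse = ", "),
              sum(x$modules == 0)))
  if (!is.na(x$annotation$escape_module))
    cat(sprintf("  immune-escape module: %d; refined signature: %d gene(s)\n",
                x$annotation$escape_module, length(x$refined_signature)))
  invisible(x)
}

#' Score samples with the immune-escape signature
#'
#' ssGSEA score against the (refined or packaged 12-gene) immune-escape
#' signature with cohort Z-scores and the median high/low split used for
#' survival stratification.
#'
#' @param mat expression matrix, genes x samples.
#' @param signature gene identifiers (default the packaged 12-gene set).
#' @param weight_exponent passed to \code{\link{ssgsea_score}}.
#' @return data frame with columns \code{sample}, \code{es}, \code{z},
#'   \code{label}.
#' @export
score_escape <- function(mat, signature = immune_escape_signature(),
                         weight_exponent = 0.25) {
  es <- ssgsea_score(mat, signature, weight_exponent, name = "immune_escape")
  data.frame(sample = names(es), es = unname(es),
             z = unname(zscore_signatures(es)),
             label = unname(classify_high_low(es)), stringsAsFactors = FALSE)
}
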