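#' RNA intratumoral heterogeneity score
#'
#' Expression is log2-transformed (pseudocount 1) and median-centered per
#' gene over the cohort to remove gene-level bias. For each gene and each
#' patient with at least two tumor regions, the median absolute difference
#' over all region pairs is taken; the patient score is the median of these
#' over genes (the expected absolute log2 fold change of a randomly chosen
#' gene between two regions of that tumor) and the gene score is the median
#' over patients.
#'
#' @param mat expression matrix, genes x samples, raw abundances (TPM/FPKM)
#'   unless \code{log_transformed = TRUE}.
#' @param sheet sample sheet with columns \code{sample}, \code{patient},
#'   \code{tissue}.
#' @param pseudocount added before log2 (default 1).
#' @param log_transformed set TRUE when \code{mat} is already on the log2
#'   scale.
#' @return list with \code{patient} (named scores), \code{gene} (named
#'   scores), and \code{flagged} (patients with < 2 tumor regions, scored
#'   NA).
#' @export
rna_ith <- function(mat, sheet, pseudocount = 1, log_transformed = FALSE) {
  assert_matrix_named(mat)
  assert_cols(sheet, c("sample", "patient", "tissue"), "sheet")
  sheet <- sheet[sheet$tissue == "tumor" & sheet$sample %in% colnames(mat), ,
                 drop = FALSE]
  stop_if(nrow(sheet) < 2, "need at least 2 tumor samples")
  x <- mat[, sheet$sample, drop = FALSE]
  if (!log_transformed) x <- log2(x + pseudocount)
  x <- x - apply(x, 1, stats::median) # gene-level median centering
  pats <- unique(sheet$patient)
  per_gene <- matrix(NA_real_, nrow(x), length(pats),
                     dimnames = list(rownames(x), pats))
  flagged <- character(0)
  for (p in pats) {
    smp <- sheet$sample[sheet$patient == p]
    if (length(smp) < 2) { flagged <- c(flagged, p); next }
    pairs <- utils::combn(smp, 2)
    d <- abs(x[, pairs[1, ], drop = FALSE] - x[, pairs[2, ], drop = FALSE])
    per_gene[, p] <- apply(d, 1, stats::median)
  }
  patient <- apply(per_gene, 2, stats::median)
  gene <- apply(per_gene, 1, stats::median, na.rm = TRUE)
  list(patient = patient, gene = gene, flagged = flagged)
}

#' DNA intratumoral heterogeneity score
#'
#' Ratio of subclonal to clonal driver genomic alterations per patient. An
#' alteration is subclonal when present in fewer than half of that
#' patient's sampled tumor regions. Patients with fewer than
#' \code{min_regions} regions, or with no clonal alteration (zero
#' denominator), are scored NA and flagged.
#'
#' @param mutations mutation table with columns \code{patient},
#'   \code{sample}, \code{alteration} (driver gene or alteration
#'   identifier).
#' @param sheet sample sheet with columns \code{sample}, \code{patient},
#'   \code{tissue} (tumor regions define the denominator).
#' @param drivers optional driver identifiers to restrict to.
#' @param min_regions minimum tumor regions per scored patient (default 3).
#' @return list with \code{patient} (named scores), \code{calls} (per
#'   alteration clonal/subclonal labels), and \code{flagged}.
#' @export
dna_ith <- function(mutations, sheet, drivers = NULL, min_regions = 3) {
  assert_cols(mutations, c("patient", "sample", "alteration"), "mutations")
  assert_cols(sheet, c("sample", "patient", "tissue"), "sheet")
  if (!is.null(drivers))
    mutations <- mutations[mutations$alteration %in% drivers, , drop = FALSE]
  tum <- sheet[sheet$tissue == "tumor", , drop = FALSE]
  pats <- unique(tum$patient)
  scores <- stats::setNames(rep(NA_real_, length(pats)), pats)
  flagged <- character(0)
  calls <- list()
  for (p in pats) {
    regions <- tum$sample[tum$patient == p]
    nreg <- length(regions)
    mut <- mutations[mutations$patient == p & mutations$sample %in% regions, ,
                     drop = FALSE]
    if (nreg < min_regions || nrow(mut) == 0) { flagged <- c(flagged, p); next }
    cnt <- tapply(mut$sample, mut$alteration, function(s) length(unique(s)))
    subclonal <- cnt < nreg / 2
    calls[[p]] <- data.frame(patient = p, alteration = names(cnt),
                             n_regions = as.integer(cnt),
                             clonality = ifelse(subclonal, "subclonal", "clonal"),
                             stringsAsFactors = FALSE)
    if (sum(!subclonal) == 0) { flagged <- c(flagged, p); next }
    scores[p] <- sum(subclonal) / sum(!subclonal)
  }
  list(patient = scores,
       calls = if (length(calls)) do.call(rbind, calls) else NULL,
       flagged = flagged)
}

#' TCR intratumoral heterogeneity score
#'
#' One minus the fraction of clonotypes shared across tumor regions:
#' 1 - |shared| / |union|, where a clonotype (CDR3 amino-acid sequence + V
#' gene) is shared when detected in at least two regions
#' (\code{shared_rule = "any2"}, default) or in every region
#' (\code{shared_rule = "all"}).
#'
#' @param clonotypes clonotype table (AIRR-style).
#' @param sheet sample sheet with columns \code{sample}, \code{patient},
#'   \code{tissue}.
#' @param shared_rule "any2" or "all".
#' @return list with \code{patient} (named scores in [0, 1]) and
#'   \code{flagged} (patients with < 2 non-empty tumor regions).
#' @export
tcr_ith <- function(clonotypes, sheet, shared_rule = c("any2", "all")) {
  shared_rule <- match.arg(shared_rule)
  .check_clonotypes(clonotypes)
  assert_cols(sheet, c("sample", "patient", "tissue"), "sheet")
  tum <- sheet[sheet$tissue == "tumor", , drop = FALSE]
  pats <- unique(tum$patient)
  scores <- stats::setNames(rep(NA_real_, length(pats)), pats)
  flagged <- character(0)
  for (p in pats) {
    regions <- tum$sample[tum$patient == p]
    sets <- lapply(regions, function(s) names(.sample_counts(clonotypes, s)))
    empty <- lengths(sets) == 0
    if (any(empty) && any(!empty))
      warning(sprintf("patient %s: excluding %d empty region(s)", p, sum(empty)))
    sets <- sets[!empty]
    if (length(sets) < 2) { flagged <- c(flagged, p); next }
    all_keys <- unlist(sets)
    uni <- unique(all_keys)
    nshare <- if (shared_rule == "any2") {
      sum(table(all_keys) >= 2)
    } else {
      length(Reduce(intersect, sets))
    }
    scores[p] <- 1 - nshare / length(uni)
  }
  list(patient = scores, flagged = flagged)
}

#' Two-cluster patient stratification on binary genomic features
#'
#' Hierarchically clusters patients on binary driver/immune-evasion
#' features (Hamming distance, Ward linkage: shared wildtype status is
#' informative for feature-sparse patients, and Ward favors the balanced
#' two-group split this stratification asks for), cuts into two clusters,
#' and labels the cluster with the higher median DNA ITH score "ITH-high".
#' Each feature is tested for cluster enrichment with a 2x2 Fisher exact
#' test; per-modality high/low calls (DNA, RNA, TCR) are each tested the
#' same way and the three p-values combined by Fisher's method.
#'
#' @param features patient x feature binary matrix (>= 4 patients). A
#'   patient is wildtype (0) only if all regions are wildtype.
#' @param ith data frame with columns \code{patient}, \code{dna_ith},
#'   \code{rna_ith}, \code{tcr_ith} (NAs allowed).
#' @return list with \code{cluster} (named "ITH-high"/"ITH-low" labels),
#'   \code{feature_tests}, \code{modality_tests}, \code{combined_p}, and
#'   the \code{hclust} object. Metadata records distance and linkage.
#' @export
cluster_genomic_features <- function(features, ith) {
  assert_matrix_named(features)
  stop_if(nrow(features) < 4, "need >= 4 patients")
  stop_if(!all(features %in% c(0, 1)), "features must be binary 0/1")
  stop_if(nrow(unique(as.data.frame(features))) == 1,
          "degenerate clustering: all feature rows identical")
  assert_cols(ith, c("patient", "dna_ith"), "ith")
  d <- stats::dist(features, method = "manhattan") # Hamming distance on 0/1
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  med <- vapply(1:2, function(k) {
    v <- ith$dna_ith[match(names(cl)[cl == k], ith$patient)]
    stats::median(v, na.rm = TRUE)
  }, 0)
  hi <- which.max(med)
  labels <- ifelse(cl == hi, "ITH-high", "ITH-low")
  names(labels) <- names(cl)
  feature_tests <- do.call(rbind, lapply(colnames(features), function(f) {
    tab <- table(factor(features[, f], levels = 0:1),
                 factor(labels, levels = c("ITH-low", "ITH-high")))
    data.frame(feature = f, p.value = fisher_exact(tab)$p.value,
               stringsAsFactors = FALSE)
  }))
  modality_tests <- NULL
  combined_p <- NA_real_
  mods <- intersect(c("dna_ith", "rna_ith", "tcr_ith"), names(ith))
  mt <- lapply(mods, function(m) {
    v <- stats::setNames(ith[[m]], ith$patient)[names(labels)]
    ok <- !is.na(v)
    if (sum(ok) < 4 || stats::sd(v[ok]) == 0) return(NULL)
    hl <- classify_high_low(v[ok])
    tab <- table(factor(hl, levels = c("low", "high")),
                 factor(labels[ok], levels = c("ITH-low", "ITH-high")))
    data.frame(modality = m, p.value = fisher_exact(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  mt <- do.call(rbind, mt)
  if (!is.null(mt) && nrow(mt) > 0) {
    modality_tests <- mt
    combined_p <- fishers_method(mt$p.value)
  }
  structure(list(cluster = labels, feature_tests = feature_tests,
                 modality_tests = modality_tests, combined_p = combined_p,
                 hclust = hc),
            distance = "hamming", linkage = "ward.D2")
}

#' Neighbor-joining tree of tumor regions
#'
#' Standard neighbor-joining agglomeration (Saitou-Nei with the usual
#' Q-criterion) over a region x alteration presence matrix (Hamming
#' distance between presence vectors) or a precomputed distance. The tree
#' reproduces any additive (four-point-satisfying) metric exactly.
#' Implemented in-package; the result is an ape \code{phylo} object and can
#' be serialized to Newick with \code{\link[ape]{write.tree}}.
#'
#' @param x region x alteration binary matrix with row names, or a
#'   \code{dist}/square distance matrix.
#' @return unrooted \code{phylo} tree with branch lengths.
#' @export
nj_tree <- function(x) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    D <- as.matrix(x)
    if (is.null(rownames(D))) rownames(D) <- paste0("R", seq_len(nrow(D)))
    if (!isSymmetric(unname(D)) || any(diag(D) != 0)) {
      # presence/absence matrix: Hamming distance between region vectors
      stop_if(!all(D %in% c(0, 1)), "presence matrix must be binary 0/1")
      lab <- rownames(D)
      D <- as.matrix(stats::dist(D, method = "manhattan"))
      dimnames(D) <- list(lab, lab)
    }
  }
  n <- nrow(D)
  stop_if(n < 3, "neighbor joining needs >= 3 taxa")
  labels <- rownames(D) %||% paste0("R", seq_len(n))

  n_tip <- n
  active <- seq_len(n)         # row indices into D
  node_id <- seq_len(n)        # phylo node ids for active rows
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  internal_next <- n_tip + 1L
  # pre-assign internal ids in creation order
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    new_id <- internal_next; internal_next <- internal_next + 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    lens <- c(lens, li, lj)
    # distances from the new node to remaining taxa
    rest <- setdiff(seq_len(m), c(i, j))
    dnew <- (Dm[i, rest] + Dm[j, rest] - dij) / 2
    keep <- active[rest]
    D <- rbind(cbind(D, 0), 0)
    newrow <- nrow(D)
    D[newrow, keep] <- dnew
    D[keep, newrow] <- dnew
    active <- c(keep, newrow)
    node_id <- c(node_id[rest], new_id)
  }
  # terminal 3-star: closed-form branch lengths
  Dm <- D[active, active, drop = FALSE]
  center <- internal_next
  l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  edges <- rbind(edges, c(center, node_id[1]), c(center, node_id[2]),
                 c(center, node_id[3]))
  lens <- c(lens, l1, l2, l3)
  # renumber internal nodes so the last-created (central) node is the root
  # id n_tip + 1, as the phylo convention expects
  remap <- function(v) ifelse(v > n_tip, n_tip + 1L + (center - v), v)
  edges <- matrix(as.integer(remap(edges)), ncol = 2)
  phy <- list(edge = edges, edge.length = lens, tip.label = labels,
              Nnode = center - n_tip)
  class(phy) <- "phylo"
  ape::read.tree(text = ape::write.tree(phy))
}
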