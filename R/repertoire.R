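# Clonotype tables follow the AIRR rearrangement convention: one row per
# clonotype per sample with columns sample_id, cdr3_aa, v_call, j_call,
# duplicate_count. The clonotype key is CDR3 amino-acid sequence + V gene.

.clonotype_key <- function(tab, use_j = FALSE) {
  if (use_j) paste(tab$cdr3_aa, tab$v_call, tab$j_call, sep = "|")
  else paste(tab$cdr3_aa, tab$v_call, sep = "|")
}

.check_clonotypes <- function(tab) {
  assert_cols(tab, c("sample_id", "cdr3_aa", "v_call", "duplicate_count"), "clonotypes")
  stop_if(any(tab$duplicate_count < 1), "clonotype counts must be >= 1")
  invisible(tab)
}

.sample_counts <- function(tab, sample, use_j = FALSE) {
  sub <- tab[tab$sample_id == sample, , drop = FALSE]
  if (nrow(sub) == 0) return(numeric(0))
  key <- .clonotype_key(sub, use_j)
  tapply(sub$duplicate_count, key, sum)
}

#' Repertoire diversity summary
#'
#' Shannon entropy (natural log) of clonotype frequencies, clonotype
#' richness (distinct clonotypes), and total clone count (total template
#' count) for one sample.
#'
#' @param tab clonotype table (AIRR-style columns \code{sample_id},
#'   \code{cdr3_aa}, \code{v_call}, \code{duplicate_count}).
#' @param sample sample identifier to summarize.
#' @return list with \code{shannon}, \code{richness}, \code{clone_count}.
#' @export
diversity_summary <- function(tab, sample) {
  .check_clonotypes(tab)
  cnt <- .sample_counts(tab, sample)
  stop_if(length(cnt) == 0, sprintf("empty repertoire for sample '%s'", sample))
  p <- cnt / sum(cnt)
  list(shannon = -sum(p * log(p)), richness = length(cnt),
       clone_count = sum(cnt))
}

#' Morisita(-Horn) clonotype overlap between two samples
#'
#' The Morisita-Horn index (default) is
#' 2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y) over the
#' union of clonotypes, bounded in [0, 1] and invariant to proportional
#' scaling of either repertoire. \code{variant = "classic"} gives the
#' original Morisita index with lambda_x = sum x(x-1) / (X(X-1)).
#'
#' @param tab clonotype table.
#' @param a,b sample identifiers.
#' @param variant "horn" (default) or "classic".
#' @return overlap index.
#' @export
morisita_overlap <- function(tab, a, b, variant = c("horn", "classic")) {
  variant <- match.arg(variant)
  .check_clonotypes(tab)
  x <- .sample_counts(tab, a); y <- .sample_counts(tab, b)
  stop_if(length(x) == 0 || length(y) == 0, "empty repertoire")
  keys <- union(names(x), names(y))
  xv <- ifelse(keys %in% names(x), x[keys], 0); xv[is.na(xv)] <- 0
  yv <- ifelse(keys %in% names(y), y[keys], 0); yv[is.na(yv)] <- 0
  X <- sum(xv); Y <- sum(yv)
  num <- 2 * sum(xv * yv)
  if (num == 0) return(0)
  if (variant == "horn") {
    num / ((sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y)
  } else {
    lx <- sum(xv * (xv - 1)) / (X * (X - 1))
    ly <- sum(yv * (yv - 1)) / (Y * (Y - 1))
    num / ((lx + ly) * X * Y)
  }
}

#' Pairwise Morisita-Horn overlap matrix
#'
#' @param tab clonotype table.
#' @param samples sample identifiers (default: all samples in the table).
#' @param variant passed to \code{\link{morisita_overlap}}.
#' @return symmetric matrix with unit diagonal.
#' @export
pairwise_overlap_matrix <- function(tab, samples = NULL,
                                    variant = c("horn", "classic")) {
  variant <- match.arg(variant)
  .check_clonotypes(tab)
  samples <- samples %||% unique(tab$sample_id)
  stop_if(length(samples) < 2, "need at least 2 samples")
  n <- length(samples)
  m <- diag(1, n)
  dimnames(m) <- list(samples, samples)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- morisita_overlap(tab, samples[i], samples[j], variant)
  }
  m
}

#' Track dominant clonotypes of a reference sample across the cohort
#'
#' Takes the \code{top_k} most frequent clonotypes of the reference sample
#' and reports their relative frequency in every sample (0 where absent),
#' in a long table suitable for ribbon/alluvial plots.
#'
#' @param tab clonotype table.
#' @param reference reference sample identifier.
#' @param top_k number of dominant reference clonotypes to track.
#' @param samples samples to track across (default: all; the reference is
#'   always included).
#' @return data frame with columns \code{clonotype}, \code{rank},
#'   \code{sample}, \code{frequency}.
#' @export
track_clonotypes <- function(tab, reference, top_k = 10, samples = NULL) {
  .check_clonotypes(tab)
  ref <- .sample_counts(tab, reference)
  stop_if(length(ref) == 0, sprintf("reference sample '%s' not present", reference))
  if (top_k > length(ref)) {
    warning(sprintf("top_k = %d exceeds reference richness %d; truncated",
                    top_k, length(ref)))
    top_k <- length(ref)
  }
  top <- names(sort(ref, decreasing = TRUE))[seq_len(top_k)]
  samples <- unique(c(reference, samples %||% unique(tab$sample_id)))
  rows <- lapply(samples, function(s) {
    cnt <- .sample_counts(tab, s)
    freq <- if (length(cnt) == 0) rep(0, top_k) else {
      v <- cnt[top] / sum(cnt); v[is.na(v)] <- 0; v
    }
    data.frame(clonotype = top, rank = seq_len(top_k), sample = s,
               frequency = unname(freq), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Downsample a repertoire to fixed depth
#'
#' Optional fixed-depth multinomial downsampling for cross-sample
#' comparability of diversity metrics.
#'
#' @param tab clonotype table.
#' @param depth target template count per sample; samples below depth are
#'   kept as-is with a warning.
#' @param seed RNG seed.
#' @return clonotype table with resampled \code{duplicate_count}.
#' @export
downsample_repertoire <- function(tab, depth, seed = 1L) {
  .check_clonotypes(tab)
  assert_count(depth, "depth")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- lapply(unique(tab$sample_id), function(s) {
    sub <- tab[tab$sample_id == s, , drop = FALSE]
    tot <- sum(sub$duplicate_count)
    if (tot <= depth) {
      if (tot < depth) warning(sprintf("sample '%s' has depth %d < %d; kept as-is",
                                       s, tot, depth))
      return(sub)
    }
    draw <- stats::rmultinom(1, depth, sub$duplicate_count / tot)[, 1]
    sub$duplicate_count <- draw
    sub[sub$duplicate_count > 0, , drop = FALSE]
  })
  do.call(rbind, out)
}
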