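# Plain-text readers and writers for the pipeline's table formats. All
# tables are tab-separated with a header; the expression matrix carries
# gene identifiers in the first column.

#' Read / write an expression matrix TSV
#'
#' Genes x samples, first column holding gene identifiers.
#'
#' @param path file path.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(ncol(df) < 2, "expression TSV needs a gene column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  assert_matrix_named(m)
  stop_if(any(m < 0), "expression values must be non-negative")
  m
}

#' @rdname read_expression_tsv
#' @param mat matrix to write.
#' @export
write_expression_tsv <- function(mat, path) {
  assert_matrix_named(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene sets
#'
#' Standard GMT: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path file path.
#' @return named list of gene identifier vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    stop_if(length(f) < 3, "malformed GMT line (need name, description, >= 1 gene)")
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  sets <- unlist(out, recursive = FALSE)
  stop_if(anyDuplicated(names(sets)) > 0, "duplicate gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene identifier vectors.
#' @export
write_gmt <- function(sets, path) {
  stop_if(is.null(names(sets)), "'sets' must be a named list")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits expression TSV, sample sheet, MAF-like mutation TSV, neoantigen
#' TSV, per-region flag TSV, fold-change TSV, AIRR-style rearrangement
#' TSV, survival TSV, a GMT of the planted modules, and the ground truth
#' as JSON.
#'
#' @param cohort \code{\link{simulate_cohort}} result.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  .write_tsv(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  .write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  .write_tsv(cohort$neoantigens, file.path(dir, "neoantigens.tsv"))
  .write_tsv(cohort$flags, file.path(dir, "region_flags.tsv"))
  if (!is.null(cohort$fc)) .write_tsv(cohort$fc, file.path(dir, "fold_changes.tsv"))
  .write_tsv(cohort$clonotypes, file.path(dir, "clonotypes.tsv"))
  .write_tsv(cohort$clinical, file.path(dir, "survival.tsv"))
  mod <- cohort$truth$expression$module
  sets <- lapply(sort(unique(mod[mod > 0])), function(m) names(mod)[mod == m])
  names(sets) <- paste0("module_", sort(unique(mod[mod > 0])))
  write_gmt(sets, file.path(dir, "planted_modules.gmt"))
  truth <- cohort$truth
  truth$expression$factors <- NULL # large latent matrices stay in-memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read back the plain-text tables written by \code{\link{write_cohort}}
#'
#' @param dir cohort directory.
#' @return list with \code{expression}, \code{sheet}, \code{mutations},
#'   \code{neoantigens}, \code{flags}, \code{fc}, \code{clonotypes},
#'   \code{clinical}, \code{modules_gmt}.
#' @export
read_cohort <- function(dir) {
  fc_path <- file.path(dir, "fold_changes.tsv")
  list(expression = read_expression_tsv(file.path(dir, "expression.tsv")),
       sheet = .read_tsv(file.path(dir, "sample_sheet.tsv")),
       mutations = .read_tsv(file.path(dir, "mutations.tsv")),
       neoantigens = .read_tsv(file.path(dir, "neoantigens.tsv")),
       flags = .read_tsv(file.path(dir, "region_flags.tsv")),
       fc = if (file.exists(fc_path)) .read_tsv(fc_path) else NULL,
       clonotypes = .read_tsv(file.path(dir, "clonotypes.tsv")),
       clinical = .read_tsv(file.path(dir, "survival.tsv")),
       modules_gmt = read_gmt(file.path(dir, "planted_modules.gmt")))
}
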