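# internal validation helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

assert_numeric <- function(x, name = deparse(substitute(x))) {
  stop_if(!is.numeric(x) || anyNA(x), sprintf("'%s' must be numeric without NA", name))
  invisible(x)
}

assert_prob <- function(x, name = deparse(substitute(x))) {
  assert_numeric(x, name)
  stop_if(any(x < 0 | x > 1), sprintf("'%s' must lie in [0, 1]", name))
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 1) {
  stop_if(!is.numeric(x) || anyNA(x) || any(x != floor(x)) || any(x < min),
          sprintf("'%s' must be integer-valued and >= %d", name, min))
  invisible(x)
}

assert_matrix_named <- function(x, name = deparse(substitute(x))) {
  stop_if(!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)),
          sprintf("'%s' must be a matrix with row and column names", name))
  stop_if(anyDuplicated(rownames(x)) > 0, sprintf("duplicate row names in '%s'", name))
  stop_if(anyDuplicated(colnames(x)) > 0, sprintf("duplicate column names in '%s'", name))
  invisible(x)
}

assert_cols <- function(df, cols, name = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  stop_if(length(miss) > 0,
          sprintf("'%s' is missing column(s): %s", name, paste(miss, collapse = ", ")))
  invisible(df)
}
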