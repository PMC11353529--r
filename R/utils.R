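#' @importFrom rlang .data %||%
#' @importFrom stats p.adjust phyper pnorm rexp runif sd setNames cor
#' @importFrom utils head modifyList
NULL

# run expr under a fixed seed when one is given, otherwise with the
# session RNG untouched
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# index of the lexicographically smallest sorted character tuple;
# used to break ties between equal-size components deterministically
lex_min_index <- function(tuples) {
  best <- 1L
  for (i in seq_along(tuples)[-1]) {
    a <- tuples[[i]]
    b <- tuples[[best]]
    k <- which(a != b)
    if (length(k) > 0 && a[k[1]] < b[k[1]]) best <- i
  }
  best
}

# TSV writer with '#'-prefixed header comment lines
write_tsv_commented <- function(x, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  comment = "#", ...)
}

assert_scalar_finite <- function(x, what = "value") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
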