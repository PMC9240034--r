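#' @keywords internal
"_PACKAGE"

#' @importFrom stats p.adjust pbinom phyper pt lm coef rnbinom rpois rlnorm
#'   rnorm runif median t.test quantile setNames var
#' @importFrom utils write.table read.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

#' Write a file atomically (temp-then-rename)
#'
#' The writer callback receives a temporary path in the same directory as
#' `path`; the temporary file is renamed onto `path` only after the writer
#' returns, so readers never observe a half-written file.
#'
#' @param path destination path
#' @param writer function of one argument (the temporary path)
#' @return `path`, invisibly
#' @keywords internal
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tmp-", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move temporary file onto '%s'", path)
  invisible(path)
}

write_tsv <- function(df, path) {
  atomic_write(path, function(p) {
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("input file '%s' does not exist", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, ...)
}
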