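# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

#' Format window identifiers
#'
#' Windows are identified as `chrom:start-end` with 0-based half-open
#' coordinates, so that `end - start` is the window width and block
#' arithmetic (`floor(start / block_bp)`) is exact.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds in bp.
#' @return character vector of window ids.
#' @export
window_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse window identifiers
#'
#' @param ids character vector in `chrom:start-end` form.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_window_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop2("malformed window id(s): ", paste(head(ids[bad]), collapse = ", "))
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

# TSV I/O: plain tab-separated files with a header row; row identifiers in
# the first column.

#' Write a matrix or data.frame as TSV
#'
#' @param x matrix or data.frame; matrix rownames become the first column.
#' @param path output file.
#' @param id_col name for the rowname column when `x` is a matrix.
#' @export
write_tsv_matrix <- function(x, path, id_col = "id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
  } else {
    df <- x
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_matrix()] back as a numeric matrix
#'
#' @param path file path.
#' @return numeric matrix with rownames from the first column.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a TSV as a data.frame
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_df <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
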