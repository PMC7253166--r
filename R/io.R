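# Text I/O for matrices and edge lists.

#' Read a dense matrix from delimited text
#'
#' One row per line, entries separated by whitespace and/or commas.
#'
#' @param path File path.
#' @return A numeric matrix.
#' @export
read_dense_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path, call. = FALSE)
  rows <- lapply(strsplit(gsub(",", " ", lines), "\\s+"), function(x) {
    x <- x[nzchar(x)]
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stop("malformed matrix file: non-numeric entry in ", path, call. = FALSE)
    v
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) stop("malformed matrix file: ragged rows in ", path, call. = FALSE)
  do.call(rbind, rows)
}

#' Write a dense matrix as delimited text
#'
#' @param A Numeric matrix.
#' @param path File path.
#' @param digits Significant digits retained.
#' @export
write_dense_matrix <- function(A, path, digits = 17) {
  lines <- apply(A, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted edge list into a state matrix
#'
#' Three delimited columns: source node id, target node id, weight
#' (header optional). Following the package orientation convention, an
#' edge `j -> i` with weight `w` lands in `A[i, j]`. Duplicate edges are
#' summed. The id-to-index mapping is attached as the dimnames and
#' returned alongside.
#'
#' @param path File path.
#' @return A list with `A` (dense matrix, dimnames = node ids) and
#'   `node_ids`.
#' @export
read_edge_list <- function(path) {
  df <- read_delim_flex(path, c("source", "target", "weight"))
  df$weight <- as.numeric(df$weight)
  if (any(!is.finite(df$weight))) stop("non-finite weight in ", path, call. = FALSE)
  ids <- sort(unique(c(df$source, df$target)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(df))) {
    A[df$target[r], df$source[r]] <- A[df$target[r], df$source[r]] + df$weight[r]
  }
  list(A = A, node_ids = ids)
}
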