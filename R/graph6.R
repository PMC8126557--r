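#' graph6 encoding and decoding
#'
#' graph6 is the standard compact ASCII format for undirected simple graphs,
#' one graph per line.  The order is encoded first (a single byte `n + 63`
#' for `n <= 62`, or a `126`-prefixed 18-bit form up to `n = 258047`),
#' followed by the upper triangle of the adjacency matrix read column by
#' column, packed six bits per byte with offset 63.
#'
#' @name graph6
NULL

.g6_encode_one <- function(g) {
  n <- igraph::vcount(g)
  if (n < 1) stop("graph6 encoding needs at least one vertex")
  if (n <= 62) {
    head <- n + 63L
  } else if (n <= 258047) {
    head <- c(126L, 63L + bitwAnd(bitwShiftR(n, 12L), 63L),
              63L + bitwAnd(bitwShiftR(n, 6L), 63L), 63L + bitwAnd(n, 63L))
  } else {
    stop("graph6 encoding supports at most 258047 vertices")
  }
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  bits <- integer(0)
  if (n >= 2) {
    cols <- unlist(lapply(2:n, function(j) a[seq_len(j - 1), j]))
    bits <- as.integer(cols)
  }
  pad <- (6 - length(bits) %% 6) %% 6
  bits <- c(bits, integer(pad))
  groups <- matrix(bits, nrow = 6)
  vals <- as.integer(2^(5:0) %*% groups) + 63L
  rawToChar(as.raw(c(head, vals)))
}

.g6_decode_one <- function(line, lineno = NA) {
  oops <- function(msg) {
    where <- if (is.na(lineno)) "" else sprintf(" (line %d)", lineno)
    stop(sprintf("malformed graph6%s: %s", where, msg), call. = FALSE)
  }
  v <- as.integer(charToRaw(line))
  if (length(v) == 0) oops("empty record")
  if (any(v < 63 | v > 126)) oops("byte outside printable graph6 range")
  if (v[1] == 126) {
    if (length(v) < 4) oops("truncated order field")
    n <- bitwShiftL(v[2] - 63L, 12L) + bitwShiftL(v[3] - 63L, 6L) + (v[4] - 63L)
    v <- v[-(1:4)]
  } else {
    n <- v[1] - 63L
    v <- v[-1]
  }
  nbits <- n * (n - 1) / 2
  need <- ceiling(nbits / 6)
  if (length(v) != need) oops(sprintf("expected %d payload bytes, found %d",
                                      need, length(v)))
  bits <- integer(0)
  if (need > 0) {
    vals <- v - 63L
    bits <- as.vector(vapply(5:0, function(s) bitwAnd(bitwShiftR(vals, s), 1L),
                             integer(length(vals))))
    bits <- as.vector(t(matrix(bits, nrow = length(vals))))
  }
  if (nbits < length(bits) && any(bits[(nbits + 1):length(bits)] != 0))
    oops("nonzero padding bits")
  a <- matrix(0L, n, n)
  if (n >= 2) {
    ut <- which(upper.tri(a))        # column-major = graph6 bit order
    a[ut] <- bits[seq_len(nbits)]
    a <- a + t(a)
  }
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

#' Write graphs in graph6 format
#'
#' @param graphs a list of igraph objects (or a single igraph object).
#' @param path file path, or `NULL` to return the encoded lines.
#' @return the encoded character vector, invisibly when written to a file.
#' @export
write_graph6 <- function(graphs, path = NULL) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  lines <- vapply(graphs, .g6_encode_one, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read graphs from graph6 format
#'
#' @param x file path or character vector of graph6 lines.
#' @return a list of igraph objects (empty input gives an empty list).
#' @export
read_graph6 <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) .g6_decode_one(lines[i], i))
}

#' Read an edge-list text file
#'
#' Secondary reader: two whitespace-separated integer columns, 0-based
#' vertex ids, one edge per line.
#'
#' @param path file path.
#' @param n number of vertices; defaults to `max(id) + 1`.
#' @return an igraph object.
#' @export
read_edgelist <- function(path, n = NULL) {
  m <- as.matrix(read.table(path, header = FALSE,
                            colClasses = "integer")[, 1:2])
  if (any(m < 0)) stop("edge-list vertex ids must be 0-based nonnegative")
  if (is.null(n)) n <- max(m) + 1L
  graph_from_edges(m + 1L, n)
}
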