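# Reading/writing modification matrices, correlation matrices and networks.

#' Read a binary modification matrix from TSV
#'
#' Expects a UTF-8, tab-delimited file with a header row of mark names; the
#' first column holds exon identifiers and every remaining cell must be `0`
#' or `1`. Row and column order are preserved. Region and splicing class are
#' supplied by the caller (they are dataset-level metadata, not encoded in
#' the file).
#'
#' @param path path to the TSV file.
#' @param region,splicingClass metadata attached to the result; see
#'   [ModificationMatrix()].
#' @return a validated [ModificationMatrix-class].
#' @seealso [writeModificationMatrix()]
#' @export
readModificationMatrix <- function(path, region = "exon",
                                   splicingClass = "mixed") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("format error: file must contain a header and at least one data row: ",
         path)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  mark_names <- header[-1L]
  if (length(mark_names) < 2L) {
    stop("format error: at least two mark columns are required")
  }
  dup <- unique(mark_names[duplicated(mark_names)])
  if (length(dup)) {
    stop("format error: duplicate mark name(s): ", paste(dup, collapse = ", "))
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop(sprintf("format error: row %d has %d fields, expected %d",
                 bad, nf[bad], length(header)))
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  cells <- matrix(unlist(lapply(rows, `[`, -1L)), nrow = length(rows),
                  byrow = TRUE)
  bad <- which(!(cells == "0" | cells == "1"), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "parse error: non-binary value '%s' at row %d (exon '%s'), column '%s'",
      cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
      ids[bad[1L, 1L]], mark_names[bad[1L, 2L]]))
  }
  values <- matrix(as.integer(cells), nrow = nrow(cells),
                   dimnames = list(ids, mark_names))
  ModificationMatrix(values, region = region, splicingClass = splicingClass)
}

#' Write a modification matrix as TSV
#'
#' Inverse of [readModificationMatrix()]: header of mark names with an
#' `exon_id` first column, tab-delimited, no quoting.
#'
#' @param x a [ModificationMatrix-class].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
writeModificationMatrix <- function(x, path) {
  stopifnot(is(x, "ModificationMatrix"))
  m <- as.matrix(x)
  df <- data.frame(exon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Convert a DAGStructure or ConsensusNetwork to an igraph object carrying
# the consensus edge attributes when present.
as_igraph <- function(network) {
  if (is(network, "DAGStructure")) {
    igraph::graph_from_data_frame(network@edges, directed = TRUE,
                                  vertices = network@nodes)
  } else if (is(network, "ConsensusNetwork")) {
    e <- network@edges
    df <- data.frame(from = e$from, to = e$to,
                     stability_count = e$skeleton_count,
                     correlation_sign = e$correlation_sign,
                     correlation_value = ifelse(is.na(e$correlation_value),
                                                NA_real_, e$correlation_value),
                     stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = TRUE,
                                  vertices = network@nodes)
  } else {
    stop("unsupported network class: ", class(network)[1L])
  }
}

#' Serialize a network to GraphML, SIF or DOT
#'
#' GraphML is the canonical format (lossless for the edge attributes
#' `stability_count`, `correlation_sign`, `correlation_value`; read back with
#' [readNetworkGraphML()]). SIF and DOT are conveniences. The SIF dialect is
#' one edge per line, `parent<TAB>relation<TAB>child`, where the relation is
#' the correlation sign (`+`, `-` or `na`) for consensus networks and `->`
#' for plain DAGs.
#'
#' @param network a [DAGStructure-class] or [ConsensusNetwork-class].
#' @param path output file path.
#' @param format `"graphml"`, `"sif"` or `"dot"`.
#' @return `invisible(path)`.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "sif", "dot")) {
  format <- match.arg(format)
  if (format %in% c("graphml", "dot")) {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = format)
    return(invisible(path))
  }
  # SIF
  if (is(network, "ConsensusNetwork")) {
    e <- network@edges
    rel <- ifelse(e$correlation_sign == "undefined", "na", e$correlation_sign)
    lines <- paste(e$from, rel, e$to, sep = "\t")
  } else {
    e <- network@edges
    lines <- paste(e$from, "->", e$to, sep = "\t")
  }
  iso <- setdiff(
    if (is(network, "ConsensusNetwork")) network@nodes else network@nodes,
    c(e$from, e$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read back a GraphML network
#'
#' Returns a [ConsensusNetwork-class] when the file carries the consensus
#' edge attributes written by [writeNetwork()], otherwise a
#' [DAGStructure-class].
#'
#' @param path path to a GraphML file.
#' @return a [ConsensusNetwork-class] or [DAGStructure-class].
#' @export
readNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  attrs <- igraph::edge_attr_names(g)
  if ("stability_count" %in% attrs) {
    e <- data.frame(
      from = el[, 1L], to = el[, 2L],
      skeleton_count = as.integer(igraph::edge_attr(g, "stability_count")),
      directed_count = NA_integer_,
      reverse_count = NA_integer_,
      correlation_sign = as.character(igraph::edge_attr(g, "correlation_sign")),
      correlation_value = as.numeric(igraph::edge_attr(g, "correlation_value")),
      flag = "",
      stringsAsFactors = FALSE
    )
    new("ConsensusNetwork", nodes = nodes, edges = e,
        threshold = min(c(e$skeleton_count, 1L)),
        nNetworks = max(c(e$skeleton_count, 10L)),
        pairCounts = data.frame())
  } else {
    DAGStructure(nodes, data.frame(from = el[, 1L], to = el[, 2L],
                                   stringsAsFactors = FALSE))
  }
}

#' Write a correlation matrix as TSV
#'
#' Marks appear as both header row and first column; undefined coefficients
#' (constant columns) are written as `NA`.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
writeCorrelationMatrix <- function(cm, path) {
  stopifnot(is(cm, "CorrelationMatrix"))
  v <- as.matrix(cm)
  df <- data.frame(mark = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
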