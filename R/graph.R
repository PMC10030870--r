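#' Construct a graph from a symmetric adjacency matrix
#'
#' The central container of the package: an undirected, weighted, simple graph
#' held as a symmetric sparse adjacency matrix with a zero diagonal, plus an
#' ordered vector of node identifiers. All layout, spectral and metric
#' functions index nodes in the order of `node_ids(g)`.
#'
#' @param adjacency square matrix (dense or `Matrix` sparse) of non-negative
#'   link weights. It is symmetrized with `pmax(A, t(A))` and the diagonal is
#'   dropped.
#' @param node_ids character vector of unique node labels, one per row of
#'   `adjacency`. Defaults to `"0" ... "N-1"`.
#' @return an object of class `nl_graph` with elements `node_ids`,
#'   `adjacency` (a `dgCMatrix`), `n_nodes` and `n_links`.
#' @examples
#' g <- graph_from_adjacency(matrix(c(0, 1, 1, 0), 2))
#' n_links(g)
#' @export
graph_from_adjacency <- function(adjacency, node_ids = NULL) {
  adjacency <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square")
  }
  n <- nrow(adjacency)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n) - 1L)
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must match adjacency size")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  if (any(adjacency@x < 0)) stop("link weights must be non-negative")
  # symmetrize and drop the diagonal
  adjacency <- pmax_sparse(adjacency, Matrix::t(adjacency))
  diag(adjacency) <- 0
  adjacency <- Matrix::drop0(adjacency)
  dimnames(adjacency) <- list(node_ids, node_ids)
  g <- structure(
    list(node_ids = node_ids,
         adjacency = adjacency,
         n_nodes = n,
         n_links = as.integer(Matrix::nnzero(adjacency) / 2)),
    class = "nl_graph")
  g
}

# elementwise max of two sparse matrices, keeping the result sparse
pmax_sparse <- function(a, b) {
  d <- a - b
  d@x <- pmax(d@x, 0)
  Matrix::drop0(b + d)
}

#' @export
print.nl_graph <- function(x, ...) {
  w <- x$adjacency@x
  kind <- if (length(w) == 0 || all(w == 1)) "unweighted" else "weighted"
  cat(sprintf("<nl_graph> %d nodes, %d links (%s)\n",
              x$n_nodes, x$n_links, kind))
  invisible(x)
}

#' Graph accessors
#'
#' @param g an `nl_graph`.
#' @return `n_nodes()` and `n_links()` return integer counts, `node_ids()` the
#'   label vector, and `adjacency()` the symmetric sparse adjacency matrix.
#' @name graph-accessors
#' @export
n_nodes <- function(g) g$n_nodes

#' @rdname graph-accessors
#' @export
n_links <- function(g) g$n_links

#' @rdname graph-accessors
#' @export
node_ids <- function(g) g$node_ids

#' @rdname graph-accessors
#' @export
adjacency <- function(g) g$adjacency

#' Convert between igraph and nl_graph
#'
#' @param ig an `igraph` object; edge `weight` attributes are kept, other
#'   attributes dropped. Vertex `name` attributes become node ids.
#' @return an `nl_graph`.
#' @export
graph_from_igraph <- function(ig) {
  ids <- if ("name" %in% igraph::vertex_attr_names(ig)) {
    as.character(igraph::V(ig)$name)
  } else {
    as.character(seq_len(igraph::vcount(ig)) - 1L)
  }
  attrname <- if ("weight" %in% igraph::edge_attr_names(ig)) "weight" else NULL
  adj <- igraph::as_adjacency_matrix(ig, type = "both", attr = attrname,
                                     sparse = TRUE)
  graph_from_adjacency(adj, node_ids = ids)
}

#' @rdname graph_from_igraph
#' @param g an `nl_graph`.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::V(ig)$name <- g$node_ids
  ig
}

# order node labels deterministically: numerically when every label parses as
# a number, lexicographically (C locale) otherwise
order_labels <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids, method = "radix")
}

#' Read a graph from edge-list, GML or GraphML sources
#'
#' Edge lists are `"u v [weight]"` per line with `#` comments; GML and GraphML
#' are parsed by igraph. In all formats the result is simple and undirected:
#' duplicate (parallel) edges collapse to the maximum weight, self-loops are
#' dropped with a warning giving their count, and nodes are reindexed in
#' sorted label order (numeric when all labels are numeric) so that repeated
#' reads are deterministic.
#'
#' @param source path to a file, or (for `format = "edgelist"`) a character
#'   string containing the edge list itself when `text = TRUE`.
#' @param format `"edgelist"`, `"gml"` or `"graphml"`; `"auto"` guesses from
#'   the file extension.
#' @param text logical; treat `source` as literal edge-list text.
#' @param binarize logical; if `TRUE`, set every nonzero weight to 1.
#' @return an `nl_graph`.
#' @examples
#' g <- read_graph_file("0 1\n1 2", format = "edgelist", text = TRUE)
#' n_links(g)
#' @export
read_graph_file <- function(source, format = c("auto", "edgelist", "gml", "graphml"),
                            text = FALSE, binarize = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    if (text) {
      format <- "edgelist"
    } else {
      ext <- tolower(tools::file_ext(source))
      format <- switch(ext, gml = "gml", graphml = "graphml", "edgelist")
    }
  }
  g <- if (format == "edgelist") {
    read_edgelist(source, text = text)
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    ig <- igraph::read_graph(source, format = format)
    n_loops <- sum(igraph::which_loop(ig))
    if (n_loops > 0) {
      warning(sprintf("dropped %d self-loop(s)", n_loops))
    }
    ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE,
                           edge.attr.comb = list(weight = "max", "ignore"))
    reorder_graph(graph_from_igraph(ig))
  }
  if (binarize) {
    a <- g$adjacency
    a@x[] <- 1
    g <- graph_from_adjacency(a, node_ids = g$node_ids)
  }
  g
}

read_edgelist <- function(source, text = FALSE) {
  lines <- if (text) strsplit(source, "\n", fixed = TRUE)[[1]] else {
    if (!file.exists(source)) stop("no such file: ", source)
    readLines(source, warn = FALSE)
  }
  raw <- sub("#.*$", "", lines)
  keep <- grepl("\\S", raw)
  if (!any(keep)) stop("empty edge list input")
  u <- character(0); v <- character(0); w <- numeric(0)
  for (i in which(keep)) {
    tok <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    if (!(length(tok) %in% c(2L, 3L))) {
      stop(sprintf("edge list format error at line %d: expected 'u v [weight]', got %s",
                   i, shQuote(trimws(raw[i]))))
    }
    wt <- 1
    if (length(tok) == 3L) {
      wt <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(wt)) {
        stop(sprintf("edge list format error at line %d: weight %s is not numeric",
                     i, shQuote(tok[3])))
      }
    }
    u <- c(u, tok[1]); v <- c(v, tok[2]); w <- c(w, wt)
  }
  loops <- u == v
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    u <- u[!loops]; v <- v[!loops]; w <- w[!loops]
  }
  ids <- unique(c(u, v))
  ids <- ids[order_labels(ids)]
  if (length(ids) == 0) stop("empty edge list input")
  iu <- match(u, ids); iv <- match(v, ids)
  n <- length(ids)
  # collapse duplicates (either orientation) to max weight
  adj <- Matrix::sparseMatrix(i = c(iu, iv), j = c(iv, iu), x = c(w, w),
                              dims = c(n, n), use.last.ij = FALSE)
  if (length(iu)) {
    key <- paste(pmin(iu, iv), pmax(iu, iv))
    wmax <- tapply(w, key, max)
    ij <- do.call(rbind, strsplit(names(wmax), " "))
    i1 <- as.integer(ij[, 1]); j1 <- as.integer(ij[, 2])
    adj <- Matrix::sparseMatrix(i = c(i1, j1), j = c(j1, i1),
                                x = rep(as.numeric(wmax), 2),
                                dims = c(n, n))
  }
  graph_from_adjacency(adj, node_ids = ids)
}

# reindex a graph into sorted label order
reorder_graph <- function(g) {
  o <- order_labels(g$node_ids)
  graph_from_adjacency(g$adjacency[o, o, drop = FALSE], node_ids = g$node_ids[o])
}

#' Write a graph to edge-list, GML or GraphML
#'
#' @param g an `nl_graph`.
#' @param path output file path.
#' @param format one of `"edgelist"`, `"gml"`, `"graphml"`, or `"auto"` to
#'   guess from the extension.
#' @return the path, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("auto", "edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", graphml = "graphml", "edgelist")
  }
  if (format == "edgelist") {
    tri <- Matrix::which(Matrix::triu(g$adjacency) != 0, arr.ind = TRUE)
    w <- g$adjacency[tri]
    lines <- sprintf("%s %s %.17g", g$node_ids[tri[, 1]], g$node_ids[tri[, 2]], w)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(g), path, format = format)
  }
  invisible(path)
}

#' Graph Laplacian L = D - A
#'
#' Returns the combinatorial Laplacian of the (possibly weighted) graph:
#' `L = D - A` with `D_ii = sum_k A_ik`. It is positive semi-definite and its
#' quadratic form is twice the elastic layout energy,
#' `Tr(X' L X) = sum_{i<j} A_ij |x_i - x_j|^2`.
#'
#' @param g an `nl_graph`.
#' @return a symmetric sparse `Matrix`.
#' @export
graph_laplacian <- function(g) {
  Matrix::Diagonal(g$n_nodes, Matrix::rowSums(g$adjacency)) - g$adjacency
}

#' Check that a coordinate matrix is a valid layout for a graph
#'
#' @param g an `nl_graph`.
#' @param layout numeric matrix with one row per node and 2 or 3 columns.
#' @return the layout, invisibly; errors otherwise.
#' @export
check_layout <- function(g, layout) {
  if (!is.matrix(layout) || !is.numeric(layout)) stop("layout must be a numeric matrix")
  if (nrow(layout) != g$n_nodes) {
    stop(sprintf("layout has %d rows but graph has %d nodes",
                 nrow(layout), g$n_nodes))
  }
  if (!(ncol(layout) %in% c(2L, 3L))) stop("layout dimension must be 2 or 3")
  if (!all(is.finite(layout))) stop("layout contains non-finite coordinates")
  invisible(layout)
}

#' Write node coordinates to CSV or JSON
#'
#' CSV columns are `node_id,x,y[,z]` in node order; JSON maps each node id to
#' its coordinate vector. Full double precision is kept so that a write/read
#' round trip reproduces the layout exactly.
#'
#' @param g an `nl_graph`.
#' @param layout an N x d coordinate matrix.
#' @param path output file, or `NULL` to return the serialized text.
#' @param format `"csv"` or `"json"` (default guessed from extension).
#' @return the serialized text (invisibly when written to a file).
#' @export
write_layout <- function(g, layout, path = NULL, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  check_layout(g, layout)
  if (format == "auto") {
    format <- if (!is.null(path) && tolower(tools::file_ext(path)) == "json")
      "json" else "csv"
  }
  if (format == "csv") {
    hdr <- paste(c("node_id", c("x", "y", "z")[seq_len(ncol(layout))]),
                 collapse = ",")
    rows <- apply(layout, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    txt <- paste(c(hdr, paste(g$node_ids, rows, sep = ",")), collapse = "\n")
  } else {
    coords <- lapply(seq_len(nrow(layout)), function(i) layout[i, ])
    names(coords) <- g$node_ids
    txt <- jsonlite::toJSON(coords, digits = NA, auto_unbox = FALSE)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read node coordinates written by [write_layout()]
#'
#' @param path file path (or literal text via `text = TRUE`).
#' @param format `"csv"` or `"json"`; `"auto"` guesses from the extension.
#' @param text logical; treat `path` as the serialized text itself.
#' @return a coordinate matrix with node ids as row names, ordered as stored.
#' @export
read_layout <- function(path, format = c("auto", "csv", "json"), text = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (!text && tolower(tools::file_ext(path)) == "json") "json" else {
      src <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "\n")
      if (grepl("^\\s*\\{", src)) "json" else "csv"
    }
  }
  if (format == "csv") {
    df <- read.csv(if (text) textConnection(path) else path,
                   colClasses = c(node_id = "character"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$node_id
  } else {
    obj <- jsonlite::fromJSON(if (text) path else paste(readLines(path, warn = FALSE),
                                                        collapse = "\n"))
    m <- do.call(rbind, obj)
    rownames(m) <- names(obj)
  }
  colnames(m) <- c("x", "y", "z")[seq_len(ncol(m))]
  m
}

#' Read a two-column "node_id label" community partition file
#'
#' @param path path to a whitespace-separated two-column text file; `#`
#'   comments allowed.
#' @param text logical; treat `path` as literal text.
#' @return a named character vector mapping node id to community label.
#' @export
read_partition <- function(path, text = FALSE) {
  lines <- if (text) strsplit(path, "\n", fixed = TRUE)[[1]] else
    readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", lines)
  keep <- which(grepl("\\S", raw))
  if (!length(keep)) stop("empty partition file")
  out <- character(0)
  for (i in keep) {
    tok <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    if (length(tok) != 2) {
      stop(sprintf("partition format error at line %d: expected 'node_id label'", i))
    }
    out[tok[1]] <- tok[2]
  }
  out
}

# align a partition (named vector or attr) to a graph's node order; errors on
# missing nodes
align_partition <- function(g, partition) {
  if (is.null(names(partition))) {
    if (length(partition) != g$n_nodes) stop("unnamed partition length must equal n_nodes")
    names(partition) <- g$node_ids
  }
  miss <- setdiff(g$node_ids, names(partition))
  if (length(miss)) {
    stop("partition is missing labels for node(s): ",
         paste(head(miss, 5), collapse = ", "))
  }
  as.character(partition[g$node_ids])
}
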