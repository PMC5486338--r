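#' Adjacency graphs for spatial effects
#'
#' An `adjacency_graph` stores named regions and a symmetric, irreflexive
#' neighbourhood relation.  It is the support of the intrinsic CAR (Besag)
#' prior built by [icar_precision()].
#'
#' @param labels character vector of unique region names.
#' @param edges two-column matrix or data.frame of region labels, one
#'   undirected edge per row.  Duplicate and reversed listings collapse to a
#'   single edge; self-edges are an error.
#' @return an object of class `adjacency_graph`: a list with `labels`,
#'   `neighbors` (a named list of character vectors, sorted), and
#'   `components` (integer component id per region).
#' @examples
#' g <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' n_regions(g)
#' @export
adjacency_graph <- function(labels, edges) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (length(labels) < 1L) stop("graph must have at least one region")
  nb <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(nb)) nb[[i]] <- character(0)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("'edges' must have two columns")
    a <- as.character(edges[, 1]); b <- as.character(edges[, 2])
    if (!all(c(a, b) %in% labels)) {
      bad <- setdiff(unique(c(a, b)), labels)
      stop("edge refers to unknown region(s): ", paste(bad, collapse = ", "))
    }
    if (any(a == b)) stop("self-neighbours are not allowed")
    for (k in seq_along(a)) {
      nb[[a[k]]] <- union(nb[[a[k]]], b[k])
      nb[[b[k]]] <- union(nb[[b[k]]], a[k])
    }
    nb <- lapply(nb, sort)
  }
  g <- structure(list(labels = labels, neighbors = nb),
                 class = "adjacency_graph")
  g$components <- graph_components(g)
  g
}

#' @rdname adjacency_graph
#' @param g an `adjacency_graph`.
#' @export
n_regions <- function(g) length(g$labels)

#' @rdname adjacency_graph
#' @export
n_edges <- function(g) sum(lengths(g$neighbors)) / 2

# breadth-first connected components; integer id per region
graph_components <- function(g) {
  n <- length(g$labels)
  comp <- stats::setNames(rep(NA_integer_, n), g$labels)
  cid <- 0L
  for (s in g$labels) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nxt <- g$neighbors[[v]]
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- cid
      queue <- c(queue, nxt)
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", n_regions(x), "regions,", n_edges(x), "edges,",
      max(x$components), "connected component(s)\n")
  invisible(x)
}

#' Rook-neighbour lattice graph
#'
#' Builds a `rows x cols` lattice whose cells neighbour horizontally and
#' vertically adjacent cells.  A 5 x 6 lattice is the package's stand-in for
#' a 30-district administrative map.
#'
#' @param rows,cols lattice dimensions; `rows * cols >= 2`.
#' @return an [adjacency_graph()] with labels `"R<r>C<c>"`; always connected.
#' @examples
#' g <- make_lattice_graph(5, 6)  # 30 regions, 49 edges
#' @export
make_lattice_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L || rows * cols < 2L) {
    stop("lattice must have at least 2 cells")
  }
  lab <- function(r, c) sprintf("R%dC%d", r, c)
  edges <- NULL
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) edges <- rbind(edges, c(lab(r, c), lab(r, c + 1)))
      if (r < rows) edges <- rbind(edges, c(lab(r, c), lab(r + 1, c)))
    }
  }
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols), lab)))
  adjacency_graph(labels, edges)
}

#' Read and write adjacency graph files
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`edgelist`}{one `regionA<TAB>regionB` pair per line; lines
#'     starting with `#` are comments; duplicate/reversed listings are
#'     symmetrised to single undirected edges.  Isolated regions may be
#'     declared by a line holding a single label.  Region labels are
#'     ordered alphabetically on reading (the file stores no label
#'     order).}
#'   \item{`gra`}{line 1 holds the number of regions N; then for each region
#'     exactly three lines: the region label, its neighbour count k, and k
#'     space-separated neighbour labels (an empty line when k = 0).
#'     Asymmetric neighbour listings are rejected.}
#' }
#'
#' @param path file path.
#' @param dialect `"edgelist"` or `"gra"`.
#' @return `read_graph` returns an [adjacency_graph()]; `write_graph`
#'   invisibly returns `path`.  A write followed by a read round-trips the
#'   graph exactly.
#' @export
read_graph <- function(path, dialect = c("edgelist", "gra")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "edgelist") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) > 2L)) stop("malformed edge list line")
    singles <- unlist(lapply(parts[lengths(parts) == 1L], `[[`, 1L))
    pairs <- parts[lengths(parts) == 2L]
    edges <- if (length(pairs)) do.call(rbind, pairs) else NULL
    labels <- sort(unique(c(if (!is.null(edges)) as.vector(t(edges)),
                            singles)))
    adjacency_graph(labels, edges)
  } else {
    read_gra_lines(lines)
  }
}

read_gra_lines <- function(lines) {
  if (length(lines) < 1L) stop("empty .gra file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("malformed region count on line 1")
  if (length(lines) < 1L + 3L * n) stop("truncated .gra file")
  labels <- character(n)
  nbl <- vector("list", n)
  for (i in seq_len(n)) {
    off <- 1L + 3L * (i - 1L)
    labels[i] <- trimws(lines[off + 1L])
    k <- suppressWarnings(as.integer(trimws(lines[off + 2L])))
    if (is.na(k) || k < 0L) stop("malformed neighbour count for region ",
                                 labels[i])
    nb <- strsplit(trimws(lines[off + 3L]), "[[:space:]]+")[[1L]]
    nb <- nb[nzchar(nb)]
    if (length(nb) != k) {
      stop("region ", labels[i], " declares ", k, " neighbours but lists ",
           length(nb))
    }
    nbl[[i]] <- nb
  }
  if (anyDuplicated(labels)) stop("duplicate region labels in .gra file")
  names(nbl) <- labels
  for (i in seq_len(n)) {
    unknown <- setdiff(nbl[[i]], labels)
    if (length(unknown)) {
      stop("region ", labels[i], " lists unknown neighbour(s): ",
           paste(unknown, collapse = ", "))
    }
    for (j in nbl[[i]]) {
      if (!(labels[i] %in% nbl[[j]])) {
        stop("asymmetric .gra listing: ", labels[i], " lists ", j,
             " but not vice versa")
      }
    }
  }
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in nbl[[i]]) if (labels[i] < j) edges <- rbind(edges, c(labels[i], j))
  }
  adjacency_graph(labels, edges)
}

#' @rdname read_graph
#' @param g an [adjacency_graph()].
#' @export
write_graph <- function(g, path, dialect = c("edgelist", "gra")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "adjacency_graph"))
  if (dialect == "edgelist") {
    out <- character(0)
    for (a in g$labels) {
      nb <- g$neighbors[[a]]
      nb <- nb[nb > a]
      if (length(nb)) out <- c(out, paste(a, nb, sep = "\t"))
      else if (length(g$neighbors[[a]]) == 0L) out <- c(out, a)
    }
    writeLines(out, path)
  } else {
    out <- as.character(length(g$labels))
    for (a in g$labels) {
      nb <- g$neighbors[[a]]
      out <- c(out, a, as.character(length(nb)), paste(nb, collapse = " "))
    }
    writeLines(out, path)
  }
  invisible(path)
}
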