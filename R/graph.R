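## Region adjacency graphs: construction, validation, lattice generator,
## and the BayesX-style .gra / JSON readers and writers.

#' Construct a region adjacency graph
#'
#' A `region_graph` holds an ordered set of region labels and a symmetric
#' adjacency structure ("neighbours share a boundary").  Self-pairs are
#' rejected and the graph must be connected, as required by the intrinsic
#' GMRF spatial prior (whose null space is the constant vector only on a
#' connected graph).
#'
#' @param ids Character vector of unique region labels.
#' @param edges Two-column matrix or data frame of region label pairs;
#'   each row is an unordered adjacency.  Duplicates (in either order)
#'   are collapsed.
#' @return An object of class `region_graph` with elements `ids`,
#'   `edges` (canonical two-column character matrix), `neighbours`
#'   (named list of neighbour labels) and `n_neighbours`.
#' @examples
#' g <- region_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' n_regions(g)
#' @export
region_graph <- function(ids, edges) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate region ids", call. = FALSE)
  if (length(ids) < 2) stop("need at least 2 regions", call. = FALSE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  dimnames(edges) <- NULL
  unknown <- setdiff(c(edges), ids)
  if (length(unknown))
    stop("edge references unknown region(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(edges[, 1] == edges[, 2]))
    stop("self-neighbour pair not allowed", call. = FALSE)
  # canonical order within each pair, drop duplicates
  swap <- match(edges[, 1], ids) > match(edges[, 2], ids)
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  edges <- edges[order(match(edges[, 1], ids), match(edges[, 2], ids)), ,
                 drop = FALSE]
  nbs <- lapply(ids, function(r)
    sort(unique(c(edges[edges[, 1] == r, 2], edges[edges[, 2] == r, 1]))))
  names(nbs) <- ids
  g <- structure(
    list(ids = ids, edges = edges, neighbours = nbs,
         n_neighbours = lengths(nbs)),
    class = "region_graph")
  comp <- .graph_components(g)
  if (max(comp) > 1L) {
    msg <- vapply(seq_len(max(comp)), function(k)
      paste0("{", paste(ids[comp == k], collapse = ","), "}"), "")
    stop("graph is disconnected; components: ",
         paste(msg, collapse = " "), call. = FALSE)
  }
  g
}

# Connected-component labels by breadth-first search.
.graph_components <- function(g) {
  n <- length(g$ids)
  comp <- integer(n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- match(g$neighbours[[v]], g$ids)
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$ids), "regions,", nrow(x$edges),
      "adjacency pairs\n")
  cat("neighbour counts:", paste(range(x$n_neighbours), collapse = "-"), "\n")
  invisible(x)
}

#' Number of regions in a graph
#' @param graph A [region_graph()].
#' @return Integer count.
#' @export
n_regions <- function(graph) length(graph$ids)

#' Neighbours of a region
#' @param graph A [region_graph()].
#' @param id Region label.
#' @return Character vector of neighbouring region labels.
#' @export
region_neighbours <- function(graph, id) {
  if (!id %in% graph$ids) stop("unknown region: ", id, call. = FALSE)
  graph$neighbours[[id]]
}

#' Rook-adjacency lattice graph
#'
#' Regular `rows x cols` grid in which regions sharing an edge (not a
#' corner) are neighbours.  Used as a generic stand-in for an
#' administrative-boundary map in simulations.
#'
#' @param rows,cols Grid dimensions; `rows * cols >= 2`.
#' @param prefix Label prefix (default `"R"`); regions are labelled
#'   row-major `R01, R02, ...`.
#' @return A [region_graph()].
#' @examples
#' make_lattice_graph(3, 4)
#' @export
make_lattice_graph <- function(rows, cols, prefix = "R") {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1 || rows * cols < 2)
    stop("need rows * cols >= 2", call. = FALSE)
  n <- rows * cols
  width <- max(2, nchar(n))
  lab <- sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
  idx <- function(r, c) (r - 1L) * cols + c
  edges <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < rows) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  em <- do.call(rbind, edges)
  region_graph(lab, cbind(lab[em[, 1]], lab[em[, 2]]))
}

#' Read a region adjacency graph from file
#'
#' Two dialects are supported and auto-detected:
#' * **`.gra` text** (BayesX-style): first line the region count `n`; then
#'   for each region two lines — its label, and the space-separated
#'   1-based indices of its neighbours (an empty line for none).
#' * **JSON**: a single object mapping each region label to the array of
#'   its neighbour labels.
#'
#' The adjacency must be symmetric (if A lists B, B must list A), free of
#' self-neighbours, and connected.
#'
#' @param path File path.
#' @return A [region_graph()].
#' @seealso [write_graph()]
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(txt[nzchar(trimws(txt))][1])
  if (startsWith(first, "{")) .read_graph_json(path) else .read_graph_gra(txt)
}

.check_symmetric <- function(ids, nbs) {
  for (r in ids) {
    for (t in nbs[[r]]) {
      if (t == r) stop("region ", r, " lists itself as neighbour",
                       call. = FALSE)
      if (!r %in% nbs[[t]])
        stop("asymmetric adjacency: ", r, " lists ", t,
             " but not vice versa", call. = FALSE)
    }
  }
}

.edges_from_neighbours <- function(ids, nbs) {
  pairs <- do.call(rbind, lapply(ids, function(r) {
    if (!length(nbs[[r]])) return(NULL)
    cbind(r, nbs[[r]])
  }))
  pairs
}

.read_graph_gra <- function(txt) {
  txt <- trimws(txt)
  n <- suppressWarnings(as.integer(txt[1]))
  if (is.na(n) || n < 2) stop("malformed .gra header", call. = FALSE)
  if (length(txt) < 1 + 2 * n) stop("truncated .gra file", call. = FALSE)
  ids <- txt[1 + 2 * seq_len(n) - 1]
  nbs <- lapply(seq_len(n), function(i) {
    line <- txt[1 + 2 * i]
    if (!nzchar(line)) return(character())
    j <- suppressWarnings(as.integer(strsplit(line, "\\s+")[[1]]))
    if (any(is.na(j)) || any(j < 1) || any(j > n))
      stop("invalid neighbour index for region ", ids[i], call. = FALSE)
    ids[j]
  })
  names(nbs) <- ids
  .check_symmetric(ids, nbs)
  region_graph(ids, .edges_from_neighbours(ids, nbs))
}

.read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- names(obj)
  nbs <- lapply(obj, as.character)
  unknown <- setdiff(unlist(nbs), ids)
  if (length(unknown))
    stop("neighbour label(s) not declared as regions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  .check_symmetric(ids, nbs)
  region_graph(ids, .edges_from_neighbours(ids, nbs))
}

#' Write a region adjacency graph to file
#'
#' @param graph A [region_graph()].
#' @param path Output file path.
#' @param format `"gra"` (default) or `"json"`; see [read_graph()] for the
#'   dialects.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("gra", "json")) {
  format <- match.arg(format)
  if (format == "gra") {
    lines <- as.character(length(graph$ids))
    for (r in graph$ids) {
      lines <- c(lines, r,
                 paste(match(graph$neighbours[[r]], graph$ids),
                       collapse = " "))
    }
    writeLines(lines, path)
  } else {
    jsonlite::write_json(graph$neighbours, path)
  }
  invisible(path)
}
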