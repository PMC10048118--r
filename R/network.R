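#' Construct a gene network
#'
#' A `gene_network` holds an ordered set of gene identifiers (nodes) and a
#' set of undirected edges between them. The node order is fixed at
#' construction time and defines the column order of every downstream
#' matrix (expression columns, edge-feature columns), so two networks with
#' the same edges but different node order are distinct objects.
#'
#' Edges are undirected: `(a, b)` and `(b, a)` describe the same edge and
#' are deduplicated. Internally each edge is stored as a pair of node
#' positions `(l, k)` with `l < k`.
#'
#' @param nodes character vector of unique gene identifiers; the order is
#'   preserved.
#' @param edges two-column character matrix or data frame of gene-id pairs
#'   (may be empty). Both endpoints must appear in `nodes`; self-loops are
#'   an error.
#' @param orientation optional two-column character matrix of
#'   `(parent, child)` gene-id pairs giving a generative orientation for a
#'   subset of the edges. Used by [simulate_expression()]; ignored
#'   otherwise.
#' @return an object of class `gene_network` with elements `nodes`
#'   (character) and `edges` (integer matrix, columns `l`, `k`, rows
#'   sorted by `l` then `k`).
#' @seealso [load_network()], [edge_index()], [simulation_network()]
#' @export
#' @examples
#' net <- gene_network(c("g1", "g2", "g3"),
#'                     rbind(c("g1", "g3"), c("g2", "g3")))
#' edge_index(net)
gene_network <- function(nodes, edges = NULL, orientation = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("network must contain at least one node")
  if (anyDuplicated(nodes)) stop("duplicate node identifiers: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (is.null(edges) || NROW(edges) == 0L) {
    emat <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("l", "k")))
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    a <- match(as.character(edges[, 1L]), nodes)
    b <- match(as.character(edges[, 2L]), nodes)
    if (anyNA(a) || anyNA(b)) {
      missing <- unique(c(edges[is.na(a), 1L], edges[is.na(b), 2L]))
      stop("edge endpoints not in node list: ", paste(missing, collapse = ", "))
    }
    if (any(a == b)) stop("self-loop edge on node: ",
                          paste(unique(nodes[a[a == b]]), collapse = ", "))
    l <- pmin(a, b)
    k <- pmax(a, b)
    keep <- !duplicated(cbind(l, k))
    l <- l[keep]; k <- k[keep]
    o <- order(l, k)
    emat <- cbind(l = l[o], k = k[o])
  }
  net <- structure(list(nodes = nodes, edges = emat), class = "gene_network")
  if (!is.null(orientation)) {
    orientation <- as.matrix(orientation)
    p <- match(orientation[, 1L], nodes)
    c_ <- match(orientation[, 2L], nodes)
    if (anyNA(p) || anyNA(c_)) stop("orientation refers to unknown nodes")
    attr(net, "orientation") <- cbind(parent = p, child = c_)
  }
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network: ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  cat("nodes:", paste(utils::head(x$nodes, 10L), collapse = " "),
      if (length(x$nodes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Read a gene network from an edge-list file
#'
#' The file is delimited text (tab or whitespace, auto-detected) with one
#' edge per row as two gene identifiers. Lines starting with `#` are
#' comments. An optional header row `gene_a gene_b` is recognised and
#' skipped. Rows with a single identifier declare isolated nodes. Reversed
#' duplicate rows (`A B` and `B A`) collapse to a single undirected edge.
#' Node order is the order of first appearance in the file.
#'
#' @param path path to the edge-list file.
#' @return a [gene_network()].
#' @export
load_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  if (identical(tolower(toks[[1L]][1:2]), c("gene_a", "gene_b")))
    toks <- toks[-1L]
  if (length(toks) == 0L) stop("network file has a header but no edges: ", path)
  nodes <- character(0)
  from <- character(0)
  to <- character(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 1L) {            # isolated-node declaration
      nodes <- c(nodes, tk)
      next
    }
    if (tk[1L] == tk[2L])
      stop("self-loop at line ", i, " of ", path, ": ", tk[1L])
    nodes <- c(nodes, tk[1:2])
    from <- c(from, tk[1L])
    to <- c(to, tk[2L])
  }
  nodes <- nodes[!duplicated(nodes)]
  gene_network(nodes, if (length(from)) cbind(from, to) else NULL)
}

#' Write a gene network as an edge-list file
#'
#' Writes the canonical form read back identically by [load_network()]:
#' a `gene_a`/`gene_b` header, one row per edge with the
#' lexicographically smaller identifier first, then one single-column row
#' per isolated node.
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene_a\tgene_b", con)
  if (nrow(net$edges)) {
    a <- net$nodes[net$edges[, "l"]]
    b <- net$nodes[net$edges[, "k"]]
    swap <- b < a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    o <- order(a, b)
    writeLines(paste(a[o], b[o], sep = "\t"), con)
  }
  iso <- setdiff(net$nodes, net$nodes[unique(as.vector(net$edges))])
  if (length(iso)) writeLines(iso, con)
  invisible(path)
}

#' Edge index of a network
#'
#' Returns the edges as node-position pairs `(l, k)` with `l < k`, sorted
#' ascending in `l` then `k`. This ordering defines the column order of
#' every edge-feature matrix.
#'
#' @param net a [gene_network()].
#' @return integer matrix with columns `l` and `k`, one row per edge.
#' @export
edge_index <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$edges
}

#' Edge names of a network
#'
#' Names each edge `geneA_geneB` with the genes in edge-index order.
#'
#' @param net a [gene_network()].
#' @return character vector, one name per edge.
#' @export
edge_names <- function(net) {
  ei <- edge_index(net)
  if (nrow(ei) == 0L) return(character(0))
  paste(net$nodes[ei[, "l"]], net$nodes[ei[, "k"]], sep = "_")
}

#' The ten-node, ten-edge simulation network
#'
#' The fixed network used throughout the simulation study: ten nodes
#' `X1..X10` and ten undirected edges shaped like a small signalling
#' pathway — a chain with two branches plus one extra edge closing a
#' cycle. Nine edges carry the shipped generative orientation (parent to
#' child); the cycle-closing edge `X3_X8` has no generative role and
#' behaves as a null edge.
#'
#' @return a [gene_network()] with a generative orientation attached.
#' @export
#' @examples
#' net <- simulation_network()
#' length(net$nodes)      # 10
#' nrow(edge_index(net))  # 10
simulation_network <- function() {
  nodes <- paste0("X", 1:10)
  tree <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                c(6, 7), c(7, 8), c(7, 9), c(9, 10))
  edges <- rbind(tree, c(3, 8))
  gene_network(nodes,
               cbind(nodes[edges[, 1]], nodes[edges[, 2]]),
               orientation = cbind(nodes[tree[, 1]], nodes[tree[, 2]]))
}

# Generative orientation of a network: (parent, child) position pairs for a
# spanning forest. Uses the attached orientation when present, otherwise a
# BFS from the lowest-indexed node of each component. Edges closing a cycle
# are excluded (they get no generative role).
network_orientation <- function(net) {
  ori <- attr(net, "orientation")
  if (!is.null(ori)) return(ori)
  m <- length(net$nodes)
  ei <- edge_index(net)
  adj <- vector("list", m)
  for (r in seq_len(nrow(ei))) {
    adj[[ei[r, 1L]]] <- c(adj[[ei[r, 1L]]], ei[r, 2L])
    adj[[ei[r, 2L]]] <- c(adj[[ei[r, 2L]]], ei[r, 1L])
  }
  visited <- logical(m)
  parent <- integer(0)
  child <- integer(0)
  for (root in seq_len(m)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (!visited[u]) {
          visited[u] <- TRUE
          parent <- c(parent, v)
          child <- c(child, u)
          queue <- c(queue, u)
        }
      }
    }
  }
  cbind(parent = parent, child = child)
}
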