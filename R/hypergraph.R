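#' Construct a hypergraph
#'
#' A hypergraph is a set of `n` nodes together with a collection of
#' hyperedges, each an arbitrary-cardinality subset of the nodes. Nodes are
#' stored internally as the contiguous integers `1..n`; the original input
#' labels (which may be any atomic values) are kept in a label table, mapped
#' in order of first appearance. Hyperedges are stored as sorted integer
#' vectors; two hyperedges that are equal as sets are collapsed to one, and
#' hyperedges with fewer than two distinct members are dropped (a lone node
#' can only re-activate itself under the dynamics, so cardinality-1
#' hyperedges play no role).
#'
#' @param edges list of vectors of node labels, one hyperedge per element.
#' @param n optional total node count; must be at least the number of
#'   distinct labels seen. Useful to carry isolated nodes.
#' @param labels optional vector of node labels fixing the internal order;
#'   defaults to first appearance in `edges`.
#' @param quiet suppress the message reporting dropped/duplicate hyperedges.
#' @return an object of class `hypergraph` with fields `n` (node count),
#'   `edges` (list of sorted integer vectors) and `labels`.
#' @examples
#' H <- hypergraph(list(c(0, 1, 2), c(1, 2)))
#' H$n
#' @export
hypergraph <- function(edges, n = NULL, labels = NULL, quiet = FALSE) {
  stopifnot(is.list(edges))
  if (is.null(labels)) {
    labels <- unique(unlist(edges, use.names = FALSE))
  }
  if (anyNA(labels)) stop("node labels must not be NA")
  idx <- function(e) match(e, labels)
  mapped <- lapply(edges, function(e) {
    i <- idx(e)
    if (anyNA(i)) stop("hyperedge contains a label not in the label table")
    sort(unique(as.integer(i)))
  })
  n_dropped <- sum(vapply(mapped, length, 1L) < 2L)
  mapped <- mapped[vapply(mapped, length, 1L) >= 2L]
  keys <- vapply(mapped, paste, "", collapse = " ")
  n_dup <- sum(duplicated(keys))
  mapped <- mapped[!duplicated(keys)]
  if (!quiet && (n_dropped > 0L || n_dup > 0L)) {
    message(sprintf("hypergraph: dropped %d hyperedge(s) of cardinality < 2, %d duplicate(s)",
                    n_dropped, n_dup))
  }
  n_seen <- length(labels)
  if (is.null(n)) n <- n_seen
  if (n < n_seen) stop("n is smaller than the number of distinct node labels")
  structure(list(n = as.integer(n), edges = mapped, labels = labels),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  card <- hyperedge_cardinalities(x)
  cat(sprintf("Hypergraph: %d nodes, %d hyperedges", x$n, length(x$edges)))
  if (length(card)) {
    cat(sprintf(" (cardinality %d..%d)", min(card), max(card)))
  }
  cat("\n")
  invisible(x)
}

#' Hyperedge cardinalities
#'
#' @param H a `hypergraph`.
#' @return integer vector of hyperedge sizes, in storage order.
#' @export
hyperedge_cardinalities <- function(H) {
  vapply(H$edges, length, 1L)
}

#' Validate hypergraph invariants
#'
#' Checks that all member indices lie in `1..n`, that no hyperedge repeats a
#' node, that no two hyperedges coincide as sets, and that every cardinality
#' is at least 2. Called by the dynamics entry points.
#'
#' @param H a `hypergraph`.
#' @return `H` invisibly; stops on violation.
#' @export
validate_hypergraph <- function(H) {
  if (!inherits(H, "hypergraph")) stop("not a hypergraph")
  for (e in H$edges) {
    if (length(e) < 2L) stop("hyperedge with cardinality < 2")
    if (anyDuplicated(e)) stop("hyperedge with repeated node")
    if (min(e) < 1L || max(e) > H$n) stop("hyperedge member out of range")
  }
  keys <- vapply(H$edges, paste, "", collapse = " ")
  if (anyDuplicated(keys)) stop("duplicate hyperedges")
  invisible(H)
}

#' Read a hypergraph from disk
#'
#' Two plain-text formats are supported. `"edge-list"`: one hyperedge per
#' line, whitespace-separated integer node labels, `#` starts a comment.
#' `"simplex-pair"`: the paired-file convention of the public hypergraph
#' dataset repositories, where `path` holds one cardinality per line and
#' `members_path` the flattened member labels, one per line, consumed in
#' order. Duplicate hyperedges and hyperedges of cardinality < 2 are dropped
#' with a message; labels are remapped to contiguous internal indices in
#' order of first appearance.
#'
#' @param path main input file (edge list, or the cardinalities file).
#' @param format `"edge-list"` or `"simplex-pair"`.
#' @param members_path flattened members file (simplex-pair only).
#' @param quiet passed to [hypergraph()].
#' @return a `hypergraph`.
#' @export
load_hypergraph <- function(path, format = c("edge-list", "simplex-pair"),
                            members_path = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge-list") {
    lines <- readLines(path, warn = FALSE)
    lines_clean <- sub("#.*$", "", lines)
    edges <- vector("list", length(lines_clean))
    kept <- logical(length(lines_clean))
    for (i in seq_along(lines_clean)) {
      toks <- strsplit(trimws(lines_clean[i]), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) next
      vals <- suppressWarnings(as.integer(toks))
      if (anyNA(vals)) {
        stop(sprintf("parse error at line %d of %s: non-integer token", i, path))
      }
      edges[[i]] <- vals
      kept[i] <- TRUE
    }
    hypergraph(edges[kept], quiet = quiet)
  } else {
    if (is.null(members_path)) stop("simplex-pair format needs members_path")
    if (!file.exists(members_path)) stop("file not found: ", members_path)
    nv <- scan(path, what = integer(), quiet = TRUE)
    mem <- scan(members_path, what = integer(), quiet = TRUE)
    if (sum(nv) != length(mem)) {
      stop(sprintf("format error: cardinalities sum to %d but %d members given",
                   sum(nv), length(mem)))
    }
    ends <- cumsum(nv)
    starts <- c(1L, head(ends, -1L) + 1L)
    edges <- mapply(function(s, e) mem[s:e], starts, ends, SIMPLIFY = FALSE)
    hypergraph(edges, quiet = quiet)
  }
}

#' Write a hypergraph as a canonical edge list
#'
#' Emits one hyperedge per line, members as their original labels sorted
#' within the line, lines in lexicographic order.
#'
#' @param H a `hypergraph`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_hypergraph <- function(H, path) {
  validate_hypergraph(H)
  lines <- vapply(H$edges, function(e) {
    paste(sort(as.character(H$labels[e])), collapse = " ")
  }, "")
  writeLines(sort(lines), path)
  invisible(path)
}

#' Weighted projected adjacency matrix
#'
#' Projects the hypergraph onto a weighted graph: the entry for a node pair
#' (i, k), i != k, sums 1/(|e_j| - 1) over all hyperedges containing both,
#' and the diagonal is zero. The result is symmetric and nonnegative.
#'
#' @param H a `hypergraph`.
#' @return a sparse symmetric `Matrix` of dimension n x n.
#' @export
projected_adjacency <- function(H) {
  validate_hypergraph(H)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (e in H$edges) {
    w <- 1 / (length(e) - 1)
    pr <- utils::combn(e, 2L)
    ii <- c(ii, pr[1L, ]); jj <- c(jj, pr[2L, ])
    ww <- c(ww, rep(w, ncol(pr)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(H$n, H$n),
                            symmetric = TRUE)
  A
}

#' Largest connected component
#'
#' At level `"full"` every hyperedge connects all its members; at
#' `"pairwise-only"` only cardinality-2 hyperedges count. Ties between
#' equally large components are broken by the smallest minimum node index.
#'
#' @param H a `hypergraph`.
#' @param level `"full"` or `"pairwise-only"`.
#' @return sorted integer vector of node indices (internal 1..n indexing).
#' @export
giant_component <- function(H, level = c("full", "pairwise-only")) {
  level <- match.arg(level)
  validate_hypergraph(H)
  if (level == "full") {
    m <- length(H$edges)
    if (m == 0L) return(if (H$n) 1L else integer(0))
    # bipartite incidence graph: nodes 1..n, hyperedges n+1..n+m
    from <- unlist(lapply(seq_len(m), function(j) rep(H$n + j, length(H$edges[[j]]))))
    to <- unlist(H$edges)
    g <- igraph::make_graph(rbind(to, from), n = H$n + m, directed = FALSE)
  } else {
    two <- H$edges[hyperedge_cardinalities(H) == 2L]
    if (!length(two)) return(if (H$n) 1L else integer(0))
    em <- do.call(cbind, two)
    g <- igraph::make_graph(em, n = H$n, directed = FALSE)
  }
  comp <- igraph::components(g)
  member <- comp$membership[seq_len(H$n)]
  sizes <- tabulate(member, nbins = comp$no)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(best, function(b) min(which(member == b)), 1L)
    best <- best[which.min(mins)]
  }
  sort(which(member == best))
}

#' Restrict a hypergraph to a node subset
#'
#' Keeps the hyperedges entirely contained in `nodes` and relabels the
#' retained nodes contiguously (original labels preserved in the label
#' table). Intended for restricting to a connected component.
#'
#' @param H a `hypergraph`.
#' @param nodes integer vector of internal node indices to keep.
#' @return a `hypergraph` on `length(nodes)` nodes.
#' @export
restrict_to_nodes <- function(H, nodes) {
  validate_hypergraph(H)
  nodes <- sort(unique(as.integer(nodes)))
  keep <- vapply(H$edges, function(e) all(e %in% nodes), TRUE)
  remap <- match(seq_len(H$n), nodes)
  edges <- lapply(H$edges[keep], function(e) sort(remap[e]))
  structure(list(n = length(nodes), edges = edges, labels = H$labels[nodes]),
            class = "hypergraph")
}
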