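#' Vessel tree objects
#'
#' A `vessel_tree` is a rooted, acyclic, directed graph whose *edges* are
#' vessel segments running between consecutive branch points. Nodes are branch
#' points (or the root stub and terminal tips); edges carry a unique positive
#' integer `segment_id` and, optionally, a length and a mean radius/diameter
#' in micrometres. The root node has out-degree 1: the tree starts just
#' before its first bifurcation, so there is a single root segment.
#'
#' On construction, internal nodes of total degree 2 (one parent, one child,
#' no branching) are collapsed so that every segment really does span the
#' stretch between two bifurcations; the collapsed segment's length is the
#' sum of its constituents' lengths.
#'
#' @param edges data.frame with columns `parent_node`, `child_node`
#'   (character or coercible), optionally `segment_id` (unique positive
#'   integers), `length_um`, `diameter_um`, and arbitrary further per-segment
#'   columns which are carried along (the first constituent's value is kept
#'   when chains are collapsed).
#' @param nodes optional data.frame with column `node` and optional
#'   coordinates `x_um`, `y_um`, `z_um`.
#' @param root optional node name. If omitted, the unique node of in-degree 0
#'   is used; with an undirected edge list, supply `root` and use
#'   [orient_edges()] first.
#' @param collapse collapse degree-2 chains (default `TRUE`; set `FALSE` only
#'   for debugging intermediate skeletons).
#' @return An object of class `vessel_tree`: a list with elements `edges`
#'   (validated edge table), `nodes`, and `root`.
#' @seealso [load_tree()], [write_tree()], [assign_ids()]
#' @export
vessel_tree <- function(edges, nodes = NULL, root = NULL, collapse = TRUE) {
  stopifnot(is.data.frame(edges))
  req <- c("parent_node", "child_node")
  if (!all(req %in% names(edges))) {
    stop("edges must have columns 'parent_node' and 'child_node'")
  }
  if (nrow(edges) == 0L) stop("tree must contain at least one segment")
  edges$parent_node <- as.character(edges$parent_node)
  edges$child_node <- as.character(edges$child_node)
  if (is.null(edges$segment_id)) edges$segment_id <- NA_integer_
  if (is.null(edges$length_um)) edges$length_um <- NA_real_
  edges$segment_id <- as.integer(edges$segment_id)
  edges$length_um <- clean_na(as.numeric(edges$length_um))

  ids <- edges$segment_id[!is.na(edges$segment_id)]
  if (anyDuplicated(ids)) {
    stop("ID collision: duplicate segment IDs ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(ids <= 0)) stop("segment IDs must be positive integers")

  all_nodes <- unique(c(edges$parent_node, edges$child_node))
  indeg <- table(factor(edges$child_node, levels = all_nodes))
  if (any(indeg > 1L)) stop("not a tree: node with multiple parent edges")
  roots <- all_nodes[indeg == 0L]
  if (length(roots) == 0L) stop("not a tree: cycle detected (no root node)")
  if (!is.null(root)) {
    root <- as.character(root)
    if (!root %in% roots) {
      stop("named root '", root, "' is not a node of in-degree 0")
    }
  } else if (length(roots) > 1L) {
    stop("ambiguous root: ", length(roots), " nodes of in-degree 0 (",
         paste(utils::head(roots, 5), collapse = ", "), ")")
  } else {
    root <- roots
  }
  if (length(roots) > 1L) stop("ambiguous root: graph is disconnected")

  # connected + every non-root in-degree 1 + unique root => arborescence,
  # but verify reachability to reject disjoint cycles attached nowhere
  g <- igraph::graph_from_data_frame(edges[, c("parent_node", "child_node")],
                                     directed = TRUE)
  if (!igraph::is_connected(g, mode = "weak")) {
    stop("not a tree: graph is disconnected")
  }
  if (igraph::ecount(g) != igraph::vcount(g) - 1L) {
    stop("not a tree: cycle detected")
  }
  if (sum(edges$parent_node == root) != 1L) {
    stop("root must have out-degree 1 (tree starts just before its first bifurcation)")
  }

  if (is.null(nodes)) {
    nodes <- data.frame(node = all_nodes, stringsAsFactors = FALSE)
  } else {
    nodes$node <- as.character(nodes$node)
    missing_nodes <- setdiff(all_nodes, nodes$node)
    if (length(missing_nodes)) {
      extra <- data.frame(node = missing_nodes, stringsAsFactors = FALSE)
      for (cn in setdiff(names(nodes), "node")) extra[[cn]] <- NA
      nodes <- rbind(nodes[names(nodes)], extra[names(nodes)])
    }
    nodes <- nodes[nodes$node %in% all_nodes, , drop = FALSE]
  }
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  tree <- structure(list(edges = edges, nodes = nodes, root = root),
                    class = "vessel_tree")
  if (collapse) tree <- collapse_chains(tree)
  tree
}

# igraph writes numeric NA as NaN in GraphML; normalize back
clean_na <- function(x) {
  x[is.nan(x)] <- NA_real_
  x
}

#' Collapse degree-2 chains into single segments
#'
#' Internal nodes with exactly one parent and one child (no branching) are
#' removed and their two incident segments merged. The merged segment keeps
#' the most proximal constituent's `segment_id` and auxiliary attributes; its
#' length is the sum of constituent lengths and its diameter the
#' length-weighted mean (plain mean if lengths are absent). Idempotent.
#'
#' @param tree a `vessel_tree`
#' @return a `vessel_tree` in which no non-root internal node has total
#'   degree 2
#' @export
collapse_chains <- function(tree) {
  e <- tree$edges
  repeat {
    outdeg <- table(factor(e$parent_node, levels = unique(c(e$parent_node, e$child_node))))
    # a pass-through node: appears once as child and once as parent, not root
    thru <- intersect(e$child_node, e$parent_node)
    thru <- thru[outdeg[thru] == 1L & thru != tree$root]
    if (length(thru) == 0L) break
    v <- thru[[1L]]
    i <- which(e$child_node == v)   # incoming segment
    j <- which(e$parent_node == v)  # outgoing segment
    li <- e$length_um[i]; lj <- e$length_um[j]
    e$length_um[i] <- if (is.na(li) && is.na(lj)) NA_real_ else sum(li, lj, na.rm = TRUE)
    if (!is.null(e$diameter_um)) {
      di <- e$diameter_um[i]; dj <- e$diameter_um[j]
      w <- c(li, lj)
      e$diameter_um[i] <- if (all(!is.na(w)) && sum(w) > 0) {
        sum(c(di, dj) * w) / sum(w)
      } else {
        mean(c(di, dj), na.rm = TRUE)
      }
    }
    e$child_node[i] <- e$child_node[j]
    e <- e[-j, , drop = FALSE]
  }
  rownames(e) <- NULL
  tree$edges <- e
  keep <- unique(c(e$parent_node, e$child_node))
  tree$nodes <- tree$nodes[tree$nodes$node %in% keep, , drop = FALSE]
  rownames(tree$nodes) <- NULL
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("<vessel_tree> ", n_segments(x), " segments, ",
      nrow(x$nodes), " nodes, root '", x$root, "'\n", sep = "")
  n_leaf <- sum(!x$edges$child_node %in% x$edges$parent_node)
  cat("  terminal segments: ", n_leaf,
      if (all(!is.na(x$edges$length_um))) {
        sprintf("; total length %.1f um", sum(x$edges$length_um))
      } else "", "\n", sep = "")
  invisible(x)
}

#' Number of segments (edges) in a vessel tree
#' @param tree a `vessel_tree`
#' @return integer count
#' @export
n_segments <- function(tree) nrow(tree$edges)

#' Assign unique segment identifiers
#'
#' Attributes a unique positive integer ID to every segment by depth-first
#' preorder from the root, visiting children in ascending order of child-node
#' name (numeric order when all node names are numeric, lexicographic
#' otherwise). The attribution is deterministic: re-running on the same tree
#' reproduces the same IDs.
#'
#' @param tree a `vessel_tree`
#' @param overwrite replace existing IDs (default `TRUE`); with `FALSE`,
#'   trees that already carry a full set of IDs are returned unchanged.
#' @return the tree with `segment_id` set on every edge
#' @export
assign_ids <- function(tree, overwrite = TRUE) {
  e <- tree$edges
  if (!overwrite && !anyNA(e$segment_id)) return(tree)
  kids <- edge_children(tree)
  ord <- node_sort_order(e$child_node)
  ids <- integer(nrow(e))
  nxt <- 1L
  stack <- which(e$parent_node == tree$root)
  while (length(stack)) {
    i <- stack[[1L]]
    stack <- stack[-1L]
    ids[i] <- nxt
    nxt <- nxt + 1L
    ch <- kids[[i]]
    if (length(ch)) stack <- c(ch[order(ord[ch])], stack)
  }
  tree$edges$segment_id <- ids
  tree
}

# ranking of node names: numeric when possible, else C-locale lexicographic
node_sort_order <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(rank(num, ties.method = "first"))
  rank(x, ties.method = "first")
}

# list: for edge i, the integer indices of its child edges
edge_children <- function(tree) {
  e <- tree$edges
  unname(split(seq_len(nrow(e)), factor(e$parent_node, levels = e$child_node)))
}

# indices of root edge(s) — exactly one by the out-degree-1 invariant
root_edge <- function(tree) which(tree$edges$parent_node == tree$root)

# edges ordered root-to-leaves (by generation depth); attr "depth" holds depths
topo_order <- function(tree) {
  kids <- edge_children(tree)
  n <- nrow(tree$edges)
  depth <- integer(n)
  ord <- integer(n)
  frontier <- root_edge(tree)
  depth[frontier] <- 1L
  k <- 0L
  while (length(frontier)) {
    ord[(k + 1L):(k + length(frontier))] <- frontier
    k <- k + length(frontier)
    nxt <- unlist(kids[frontier], use.names = FALSE)
    if (length(nxt)) depth[nxt] <- depth[rep(frontier, lengths(kids[frontier]))] + 1L
    frontier <- nxt
  }
  structure(ord, depth = depth)
}

#' Read a vessel tree from GraphML or an edge-list CSV
#'
#' GraphML edges may carry attributes `segment_id` and `length_um`, nodes
#' `x_um`, `y_um`, `z_um`. The CSV dialect is
#' `segment_id,parent_node,child_node,length_um` (UTF-8, comma-separated,
#' '.' decimal); extra columns are carried along. Undirected GraphML input is
#' oriented away from the supplied `root`.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"graphml"` or `"edge-csv"`
#' @param root optional root node name (required for undirected input)
#' @param collapse collapse degree-2 chains after loading (default `TRUE`)
#' @return a validated `vessel_tree`
#' @export
load_tree <- function(path, format = c("auto", "graphml", "edge-csv"),
                      root = NULL, collapse = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edge-csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!igraph::is_directed(g)) {
      if (is.null(root)) stop("undirected input: a root node must be supplied")
      g <- orient_from_root(g, root)
    }
    ed <- igraph::as_data_frame(g, what = "edges")
    vd <- igraph::as_data_frame(g, what = "vertices")
    names(ed)[names(ed) == "from"] <- "parent_node"
    names(ed)[names(ed) == "to"] <- "child_node"
    vd$id <- NULL  # igraph's internal n0/n1 ids from GraphML
    names(vd)[names(vd) == "name"] <- "node"
    for (cn in intersect(c("x_um", "y_um", "z_um"), names(vd))) {
      vd[[cn]] <- clean_na(vd[[cn]])
    }
    vessel_tree(ed, nodes = vd, root = root, collapse = collapse)
  } else {
    ed <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("segment_id", "parent_node", "child_node")
    if (!all(req %in% names(ed))) {
      stop("edge CSV must have header segment_id,parent_node,child_node[,length_um]")
    }
    vessel_tree(ed, root = root, collapse = collapse)
  }
}

orient_from_root <- function(g, root) {
  if (!as.character(root) %in% igraph::V(g)$name) {
    stop("named root '", root, "' not present in graph")
  }
  bf <- igraph::bfs(g, root = as.character(root), father = TRUE, unreachable = FALSE)
  ed <- igraph::as_data_frame(g, what = "edges")
  father <- igraph::V(g)$name[as.integer(bf$father)]
  names(father) <- igraph::V(g)$name
  # flip an edge when its 'to' endpoint is the BFS parent of its 'from'
  flip <- !is.na(father[ed$from]) & father[ed$from] == ed$to
  tmp <- ed$from[flip]; ed$from[flip] <- ed$to[flip]; ed$to[flip] <- tmp
  g2 <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                      vertices = igraph::as_data_frame(g, what = "vertices"))
  g2
}

#' Write a vessel tree to GraphML or edge-list CSV
#'
#' Inverse of [load_tree()]: a written tree reloads to an isomorphic tree
#' with identical segment IDs, lengths and coordinates.
#'
#' @param tree a `vessel_tree`
#' @param path output path
#' @param format `"auto"` (by extension), `"graphml"` or `"edge-csv"`
#' @return `path`, invisibly
#' @export
write_tree <- function(tree, path, format = c("auto", "graphml", "edge-csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edge-csv"
  }
  e <- tree$edges
  if (format == "graphml") {
    d <- e
    names(d)[match(c("parent_node", "child_node"), names(d))] <- c("from", "to")
    nd <- tree$nodes
    names(nd)[names(nd) == "node"] <- "name"
    g <- igraph::graph_from_data_frame(d, directed = TRUE, vertices = nd)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lead <- intersect(c("segment_id", "parent_node", "child_node", "length_um"),
                      names(e))
    d <- e[, c(lead, setdiff(names(e), lead)), drop = FALSE]
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}
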