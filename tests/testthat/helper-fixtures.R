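# Shared fixtures and independent oracles.

# caterpillar: trunk A-B-C-D-E (4 segments), one leaf lateral at each of the
# three internal junctions B, C, D
make_caterpillar <- function(lengths = c(10, 10, 10, 10, 5, 5, 5)) {
  e <- data.frame(parent_node = c("A", "B", "C", "D", "B", "C", "D"),
                  child_node = c("B", "C", "D", "E", "L1", "L2", "L3"),
                  length_um = lengths)
  assign_ids(vessel_tree(e))
}

# complete binary tree of segment-depth `depth` (2^depth - 1 segments);
# the root edge is the depth-1 segment, every tip bifurcates until `depth`
make_binary <- function(depth) {
  rows <- list()
  nxt <- 1L
  new_node <- function() {
    v <- sprintf("n%03d", nxt)
    nxt <<- nxt + 1L
    v
  }
  grow <- function(parent, d) {
    child <- new_node()
    rows[[length(rows) + 1L]] <<- data.frame(parent_node = parent,
                                             child_node = child,
                                             length_um = 1)
    if (d < depth) {
      grow(child, d + 1L)
      grow(child, d + 1L)
    }
  }
  root <- new_node()
  grow(root, 1L)
  assign_ids(vessel_tree(do.call(rbind, rows)))
}

# root segment whose tip trifurcates into three leaf segments
make_trifurcation <- function() {
  e <- data.frame(parent_node = c("R", "A", "A", "A"),
                  child_node = c("A", "B", "C", "D"),
                  length_um = 1)
  assign_ids(vessel_tree(e))
}

# random tree with n segments: a root edge, then children attached to
# uniformly chosen non-root nodes; multifurcations arise naturally.
# Built with collapse = FALSE first, then collapsed, so pass-through chain
# nodes never survive.
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c("v1", character(n - 1L))
  child <- c("v2", character(n - 1L))
  nodes <- c("v2")
  for (i in seq_len(n - 1L) + 1L) {
    parent[i] <- nodes[sample.int(length(nodes), 1L)]
    child[i] <- paste0("v", i + 1L)
    nodes <- c(nodes, child[i])
  }
  e <- data.frame(parent_node = parent, child_node = child,
                  length_um = stats::runif(n, 1, 10))
  assign_ids(vessel_tree(e))
}

# --- exhaustive enumeration of small trees -------------------------------
# Unordered rooted trees represented as nested lists of child subtrees.
# rooted_tree_shapes(n): all shapes with n nodes (n-1 edges below the root).
rooted_tree_shapes <- local({
  cache <- list()
  shapes <- function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- if (n == 1L) {
      list(list())
    } else {
      res <- list()
      # children as a multiset of smaller shapes, non-increasing in
      # (size, index) to enumerate each multiset exactly once
      build <- function(remaining, max_size, max_index, acc) {
        if (remaining == 0L) {
          res[[length(res) + 1L]] <<- acc
          return(invisible())
        }
        for (s in seq_len(min(remaining, max_size))) {
          subs <- shapes(s)
          idx_max <- if (s == max_size) min(max_index, length(subs)) else length(subs)
          for (i in seq_len(idx_max)) {
            build(remaining - s, s, i, c(acc, list(subs[[i]])))
          }
        }
      }
      build(n - 1L, n - 1L, .Machine$integer.max, list())
      res
    }
    cache[[key]] <<- out
    out
  }
  shapes
})

# every vessel tree with <= max_edges segments: a root edge plus a rooted
# shape of up to max_edges nodes hanging off its tip
all_small_trees <- function(max_edges) {
  out <- list()
  for (n in seq_len(max_edges)) {
    for (shape in rooted_tree_shapes(n)) {
      out[[length(out) + 1L]] <- shape
    }
  }
  out
}

shape_to_tree <- function(shape) {
  rows <- list()
  nxt <- 1L
  new_node <- function() {
    v <- sprintf("m%03d", nxt)
    nxt <<- nxt + 1L
    v
  }
  emit <- function(parent, sh) {
    child <- new_node()
    rows[[length(rows) + 1L]] <<- data.frame(parent_node = parent,
                                             child_node = child)
    for (sub in sh) emit(child, sub)
  }
  root <- new_node()
  emit(root, shape)  # the root edge carries the whole shape below it
  assign_ids(vessel_tree(do.call(rbind, rows), collapse = FALSE))
}

# naive Strahler oracle straight from the recursive definition, computed on
# the nested-list shape (independent of the package's edge-table traversal):
# returns the orders of all edges in the same DFS order the shape is emitted
strahler_oracle <- function(shape) {
  orders <- integer(0)
  rec <- function(sh) {
    if (length(sh) == 0L) {
      orders[length(orders) + 1L] <<- 1L
      return(1L)
    }
    slot <- length(orders) + 1L
    orders[slot] <<- NA_integer_  # reserve preorder slot
    ch <- vapply(sh, rec, integer(1))
    s <- max(ch)
    o <- if (sum(ch == s) >= 2L) s + 1L else s
    orders[slot] <<- o
    o
  }
  rec(shape)
  orders
}

# brute-force Davies-Bouldin oracle: explicit loops, no shared code
db_oracle <- function(X, labels, p = 2, q = 2) {
  X <- as.matrix(X)
  lev <- sort(unique(labels))
  g <- length(lev)
  cent <- list()
  S <- numeric(g)
  for (i in seq_len(g)) {
    rows <- X[labels == lev[i], , drop = FALSE]
    cent[[i]] <- apply(rows, 2, mean)
    acc <- 0
    for (r in seq_len(nrow(rows))) {
      dist <- sum(abs(rows[r, ] - cent[[i]])^p)^(1 / p)
      acc <- acc + dist^q
    }
    S[i] <- (acc / nrow(rows))^(1 / q)
  }
  total <- 0
  for (i in seq_len(g)) {
    worst <- -Inf
    for (j in seq_len(g)) {
      if (i == j) next
      M <- sum(abs(cent[[i]] - cent[[j]])^p)^(1 / p)
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / g
}

# closed-form log-likelihood of a single d-variate Gaussian at the MLE
gaussian_loglik_mle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n
  -n / 2 * (d * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus[1] + d)
}

# adjusted Rand index between two labelings (closed form from the
# pair-counting contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
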