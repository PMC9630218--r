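#' Branching classification schemes
#'
#' Four per-segment grouping schemes for rooted vessel trees:
#'
#' * **generations** — top-down: the root segment is generation 1 and every
#'   daughter at every branch point takes its parent's generation plus one.
#' * **Horsfield orders** — bottom-up: terminal segments are order 1; where
#'   branches meet, the parent takes the highest merging order plus one.
#' * **Strahler orders** — bottom-up like Horsfield, but the order increases
#'   only when two or more branches of equal maximal order meet; otherwise
#'   the parent continues with the highest merging order.
#' * **fractal generations** — trunk-based: the main trunk, root to tip, is
#'   generation 1 along its whole length; every branch leaving a
#'   generation-n trunk is the trunk of generation n+1 from branching point
#'   to tip, recursively.
#'
#' All labels start at 1. For every tree, Strahler order is bounded above by
#' Horsfield order segment-wise, and the order-1 segment sets of the two
#' bottom-up schemes coincide (the terminal segments).
#'
#' @param tree a [vessel_tree()]; segments must carry IDs
#'   (see [assign_ids()]).
#' @return a `scheme_labels` object: named integer vector of group labels
#'   keyed by segment ID, with attribute `scheme`.
#' @name classification
NULL

scheme_labels <- function(scheme, ids, labels) {
  stopifnot(length(ids) == length(labels))
  x <- as.integer(labels)
  names(x) <- as.character(ids)
  structure(x, scheme = scheme, class = "scheme_labels")
}

#' @export
print.scheme_labels <- function(x, ...) {
  cat("<scheme_labels> scheme '", attr(x, "scheme"), "': ",
      length(x), " segments in ", group_counts(x), " groups\n", sep = "")
  print(table(group = as.integer(x)))
  invisible(x)
}

require_ids <- function(tree) {
  if (anyNA(tree$edges$segment_id)) {
    stop("tree segments lack IDs; run assign_ids() first")
  }
  tree$edges$segment_id
}

#' @rdname classification
#' @export
generations <- function(tree) {
  ids <- require_ids(tree)
  ord <- topo_order(tree)
  scheme_labels("generation", ids, attr(ord, "depth"))
}

#' @rdname classification
#' @export
horsfield_orders <- function(tree) {
  ids <- require_ids(tree)
  kids <- edge_children(tree)
  ord <- topo_order(tree)
  lab <- integer(nrow(tree$edges))
  for (i in rev(ord)) {
    ch <- kids[[i]]
    lab[i] <- if (length(ch) == 0L) 1L else max(lab[ch]) + 1L
  }
  scheme_labels("horsfield_order", ids, lab)
}

#' @rdname classification
#' @export
strahler_orders <- function(tree) {
  ids <- require_ids(tree)
  kids <- edge_children(tree)
  ord <- topo_order(tree)
  lab <- integer(nrow(tree$edges))
  for (i in rev(ord)) {
    ch <- kids[[i]]
    if (length(ch) == 0L) {
      lab[i] <- 1L
    } else {
      s <- max(lab[ch])
      lab[i] <- if (sum(lab[ch] == s) >= 2L) s + 1L else s
    }
  }
  scheme_labels("strahler_order", ids, lab)
}

#' @rdname classification
#' @param trunk_rule how the trunk is selected at each branch point when no
#'   override applies: `"max_path_length"` (default) follows the child with
#'   the greatest total downstream path length (edge count when lengths are
#'   absent), `"max_subtree_size"` the child with the most downstream
#'   segments, `"max_diameter"` the child with the largest mean diameter.
#'   Ties break by larger mean diameter (when available), then by smaller
#'   segment ID.
#' @param overrides optional integer vector of segment IDs forced onto
#'   trunks, reproducing manual trunk curation; at any branch point at most
#'   one child may be an override.
#' @export
fractal_generations <- function(tree,
                                trunk_rule = c("max_path_length",
                                               "max_subtree_size",
                                               "max_diameter"),
                                overrides = NULL) {
  trunk_rule <- match.arg(trunk_rule)
  ids <- require_ids(tree)
  kids <- edge_children(tree)
  ord <- topo_order(tree)
  n <- nrow(tree$edges)
  e <- tree$edges
  len <- e$length_um
  if (anyNA(len)) len <- rep(1, n)  # edge-count fallback
  dia <- if (!is.null(e$diameter_um)) e$diameter_um else rep(NA_real_, n)

  score <- numeric(n)
  for (i in rev(ord)) {
    ch <- kids[[i]]
    score[i] <- switch(trunk_rule,
      max_path_length = len[i] + if (length(ch)) max(score[ch]) else 0,
      max_subtree_size = 1 + if (length(ch)) sum(score[ch]) else 0,
      max_diameter = if (is.na(dia[i])) 0 else dia[i])
  }
  if (!is.null(overrides)) {
    overrides <- as.integer(overrides)
    bad <- setdiff(overrides, ids)
    if (length(bad)) {
      stop("invalid trunk override: unknown segment IDs ",
           paste(bad, collapse = ", "))
    }
  }
  is_override <- ids %in% overrides

  pick_trunk <- function(ch) {
    ov <- ch[is_override[ch]]
    if (length(ov) > 1L) {
      stop("invalid trunk override: segments ",
           paste(ids[ov], collapse = ", "),
           " compete for the same trunk (overrides must form root-to-leaf paths)")
    }
    if (length(ov) == 1L) return(ov)
    best <- ch[score[ch] == max(score[ch])]
    if (length(best) > 1L && !all(is.na(dia[best]))) {
      d <- ifelse(is.na(dia[best]), -Inf, dia[best])
      best <- best[d == max(d)]
    }
    best[which.min(ids[best])]
  }

  lab <- integer(n)
  stack_edge <- root_edge(tree)
  stack_lab <- 1L
  while (length(stack_edge)) {
    i <- stack_edge[[1L]]; g <- stack_lab[[1L]]
    stack_edge <- stack_edge[-1L]; stack_lab <- stack_lab[-1L]
    repeat {  # walk one trunk from branching point to tip
      lab[i] <- g
      ch <- kids[[i]]
      if (length(ch) == 0L) break
      tr <- pick_trunk(ch)
      off <- setdiff(ch, tr)
      if (length(off)) {
        stack_edge <- c(off, stack_edge)
        stack_lab <- c(rep(g + 1L, length(off)), stack_lab)
      }
      i <- tr
    }
  }
  scheme_labels("fractal_generation", ids, lab)
}

#' Number of distinct groups used by a labeling
#' @param labels a `scheme_labels` object (or plain integer vector)
#' @return integer: cardinality of the used label set
#' @export
group_counts <- function(labels) {
  if (length(labels) == 0L) stop("labels are empty")
  length(unique(as.integer(labels)))
}

#' Run all four classification schemes
#'
#' @inheritParams fractal_generations
#' @param schemes subset of
#'   `c("generation", "horsfield_order", "strahler_order", "fractal_generation")`
#' @return data.frame with `segment_id` and one integer column per scheme,
#'   one row per segment, ordered by segment ID.
#' @export
classify_all <- function(tree, schemes = c("generation", "horsfield_order",
                                           "strahler_order",
                                           "fractal_generation"),
                         trunk_rule = "max_path_length", overrides = NULL) {
  known <- c("generation", "horsfield_order", "strahler_order",
             "fractal_generation")
  bad <- setdiff(schemes, known)
  if (length(bad)) {
    stop("unknown scheme(s) ", paste(bad, collapse = ", "),
         "; valid schemes are: ", paste(known, collapse = ", "))
  }
  ids <- require_ids(tree)
  out <- data.frame(segment_id = sort(ids))
  key <- as.character(out$segment_id)
  for (s in schemes) {
    lab <- switch(s,
      generation = generations(tree),
      horsfield_order = horsfield_orders(tree),
      strahler_order = strahler_orders(tree),
      fractal_generation = fractal_generations(tree, trunk_rule = trunk_rule,
                                               overrides = overrides))
    out[[s]] <- as.integer(lab[key])
  }
  out
}

#' Write per-segment classification labels to CSV
#'
#' One row per segment; columns `segment_id` then one column per scheme.
#'
#' @param labels data.frame from [classify_all()], or a list of
#'   `scheme_labels`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_labels <- function(labels, path) {
  if (!is.data.frame(labels)) {
    stopifnot(length(labels) > 0)
    key <- sort(as.integer(names(labels[[1]])))
    df <- data.frame(segment_id = key)
    for (lab in labels) {
      df[[attr(lab, "scheme")]] <- as.integer(lab[as.character(key)])
    }
    labels <- df
  }
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
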