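#' Synthetic vessel-tree specification
#'
#' Parameters of the tree generator. The monopodial pattern emulates the
#' small-mammal lung lobe: a central trunk running the lobe's length with
#' smaller laterals leaving it near-perpendicularly at the junctions between
#' trunk segments; each lateral is itself a (shorter) monopodial subtree
#' down to the recursion limit, where laterals are single terminal segments.
#' The dichotomous pattern is a complete binary segment tree, the idealized
#' human-lung architecture.
#'
#' Per-segment ground truth is retained on the generated tree: `true_level`
#' (the branch level: trunk 1, its laterals 2, ...), `true_diameter_um` and
#' `true_wall_um`. Diameters follow a per-level geometric shrink law
#' `root_diameter_um * shrink^(level-1)` with mild multiplicative jitter, so
#' diameter is organized by branch hierarchy rather than by top-down
#' generation — the structure that makes bottom-up orderings morphometrically
#' coherent on monopodial trees. Wall thickness varies only weakly with
#' level (`wall_fraction` of diameter, inflated 5% per level), keeping
#' diameter the dominant separating feature.
#'
#' Defaults emulate a mouse-lung arterial lobe at micro-CT scale: a 40-segment
#' trunk (segment length ~150 um, i.e. a ~6 mm lobe), three branch levels,
#' 150 um root diameter shrinking by half per level to the ~35 um resolution
#' floor of small arterioles.
#'
#' @param pattern `"monopodial"` or `"dichotomous"`
#' @param trunk trunk segment count (monopodial) — the root-to-tip chain
#' @param lateral_prob probability that a trunk junction bears a lateral
#' @param depth maximum branch level (monopodial: laterals at level `depth`
#'   are single segments; dichotomous: segment depth of the binary tree)
#' @param lateral_frac sub-trunk length fraction per level: a level-L trunk
#'   has `max(1, ceiling(trunk * lateral_frac^(L-1)))` segments
#' @param root_diameter_um trunk diameter at the root, micrometres
#' @param shrink per-level diameter shrink factor in (0, 1]
#' @param diameter_jitter lognormal sd of multiplicative diameter noise
#' @param wall_fraction wall thickness as a fraction of diameter
#' @param length_mean_um,length_jitter segment length mean and lognormal sd
#' @param seed integer; fixes the generated tree exactly
#' @return a `tree_spec` list
#' @export
tree_spec <- function(pattern = c("monopodial", "dichotomous"),
                      trunk = 40L, lateral_prob = 0.9, depth = 3L,
                      lateral_frac = 0.25,
                      root_diameter_um = 150, shrink = 0.5,
                      diameter_jitter = 0.08, wall_fraction = 0.08,
                      length_mean_um = 150, length_jitter = 0.25,
                      seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(trunk >= 1L, lateral_prob >= 0, lateral_prob <= 1,
            depth >= 1L, shrink > 0, shrink <= 1,
            root_diameter_um > 0, length_mean_um > 0)
  structure(list(pattern = pattern, trunk = as.integer(trunk),
                 lateral_prob = lateral_prob, depth = as.integer(depth),
                 lateral_frac = lateral_frac,
                 root_diameter_um = root_diameter_um, shrink = shrink,
                 diameter_jitter = diameter_jitter,
                 wall_fraction = wall_fraction,
                 length_mean_um = length_mean_um,
                 length_jitter = length_jitter,
                 seed = as.integer(seed)),
            class = "tree_spec")
}

#' Generate a synthetic vessel tree
#'
#' Deterministic given `spec$seed`. See [tree_spec()] for the construction
#' and the retained per-segment ground truth.
#'
#' @param spec a [tree_spec()]
#' @return a [vessel_tree()] with IDs assigned and truth columns
#'   `true_level`, `true_diameter_um`, `true_wall_um`
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  set.seed(spec$seed)
  env <- new.env()
  env$rows <- list()
  env$next_node <- 0L
  new_node <- function() {
    env$next_node <- env$next_node + 1L
    sprintf("n%04d", env$next_node)
  }
  seg_len <- function() {
    spec$length_mean_um * stats::rlnorm(1, -spec$length_jitter^2 / 2,
                                        spec$length_jitter)
  }
  seg_dia <- function(level) {
    spec$root_diameter_um * spec$shrink^(level - 1) *
      stats::rlnorm(1, -spec$diameter_jitter^2 / 2, spec$diameter_jitter)
  }
  add_edge <- function(parent, child, level, length = seg_len()) {
    d <- seg_dia(level)
    env$rows[[length(env$rows) + 1L]] <- data.frame(
      parent_node = parent, child_node = child,
      length_um = length, diameter_um = d,
      true_level = level, true_diameter_um = d,
      true_wall_um = d * spec$wall_fraction * (1 + 0.05 * (level - 1)),
      stringsAsFactors = FALSE)
  }

  if (spec$pattern == "dichotomous") {
    grow_binary <- function(parent, d) {
      child <- new_node()
      add_edge(parent, child, d)
      if (d < spec$depth) {
        grow_binary(child, d + 1L)
        grow_binary(child, d + 1L)
      }
    }
    root <- new_node()
    grow_binary(root, 1L)
  } else {
    trunk_len <- function(level) {
      if (level >= spec$depth) 1L
      else max(1L, ceiling(spec$trunk * spec$lateral_frac^(level - 1)))
    }
    grow_branch <- function(parent, level) {
      nseg <- trunk_len(level)
      # laterals leave at the junctions *between* trunk units; a junction
      # without a lateral is no branch point, so the trunk continues as the
      # same (longer) segment — segments always run bifurcation to bifurcation
      lat <- if (level < spec$depth && nseg > 1L) {
        stats::runif(nseg - 1L) < spec$lateral_prob
      } else {
        rep(FALSE, max(0L, nseg - 1L))
      }
      node <- parent
      run_len <- 0
      for (s in seq_len(nseg)) {
        run_len <- run_len + seg_len()
        if (s == nseg || lat[s]) {
          nxt <- new_node()
          add_edge(node, nxt, level, length = run_len)
          run_len <- 0
          if (s < nseg) grow_branch(nxt, level + 1L)
          node <- nxt
        }
      }
    }
    root <- new_node()
    grow_branch(root, 1L)
  }
  edges <- do.call(rbind, env$rows)
  if (nrow(edges) == 0L) stop("tree specification implies zero segments")
  tree <- vessel_tree(edges, root = root, collapse = FALSE)
  assign_ids(tree)
}

#' Synthetic measurement specification
#'
#' Emulates per-slice paired diameter measurements on serial sections: one
#' paired inner/outer measurement every `step_um` along each segment (a
#' 20 um step over ~150 um segments gives ~4-8 measurements per segment,
#' the density of sampling every tenth 2-um section), Gaussian measurement
#' noise, and independent per-segment dropout emulating segments lost to
#' section misalignment (default 20.5%, i.e. about 4 segments in 5 retained).
#'
#' @param step_um slice step between successive measurements (default 20)
#' @param noise_sd_um sd of additive Gaussian measurement noise (default 2,
#'   about half the 4.4 um voxel size such imaging resolves)
#' @param dropout probability a segment yields no measurements at all
#'   (default 0.205)
#' @param seed integer seed
#' @return a `measurement_spec` list
#' @export
measurement_spec <- function(step_um = 20, noise_sd_um = 2,
                             dropout = 0.205, seed = 1L) {
  stopifnot(step_um > 0, noise_sd_um >= 0, dropout >= 0, dropout <= 1)
  structure(list(step_um = step_um, noise_sd_um = noise_sd_um,
                 dropout = dropout, seed = as.integer(seed)),
            class = "measurement_spec")
}

#' Generate a per-slice measurement table for a synthetic tree
#'
#' Each retained segment contributes `ceiling(length/step)` rows; per row,
#' inner diameter = true diameter + noise (clipped positive) and outer
#' diameter = inner + 2 x true wall + noise (clipped so outer >= inner).
#' Segments are dropped independently with the dropout probability.
#' Deterministic given `spec$seed`.
#'
#' @param tree a tree from [generate_tree()] (must carry
#'   `true_diameter_um`/`true_wall_um`)
#' @param spec a [measurement_spec()]
#' @return measurement data.frame
#'   (`segment_id,slice_index,inner_diameter_um,outer_diameter_um`)
#' @export
generate_measurements <- function(tree, spec) {
  stopifnot(inherits(spec, "measurement_spec"))
  e <- tree$edges
  if (is.null(e$true_diameter_um) || is.null(e$true_wall_um)) {
    stop("tree lacks ground-truth diameters; use generate_tree()")
  }
  set.seed(spec$seed)
  keep <- stats::runif(nrow(e)) >= spec$dropout
  rows <- lapply(which(keep), function(i) {
    nrow_i <- max(1L, ceiling(e$length_um[i] / spec$step_um))
    inner <- e$true_diameter_um[i] +
      stats::rnorm(nrow_i, 0, spec$noise_sd_um)
    inner <- pmax(inner, 1e-3)
    outer <- inner + 2 * e$true_wall_um[i] +
      stats::rnorm(nrow_i, 0, spec$noise_sd_um)
    outer <- pmax(outer, inner)
    data.frame(segment_id = e$segment_id[i], slice_index = seq_len(nrow_i),
               inner_diameter_um = inner, outer_diameter_um = outer)
  })
  if (length(rows) == 0L) {
    warning("all segments dropped: empty measurement table")
    return(data.frame(segment_id = integer(0), slice_index = integer(0),
                      inner_diameter_um = numeric(0),
                      outer_diameter_um = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample a labeled Gaussian mixture
#'
#' Draws `n` points componentwise according to the mixture weights and
#' returns the generating labels alongside, for use as ground truth in
#' clustering tests. Deterministic given `seed`.
#'
#' @param k number of components
#' @param means k x d matrix (or list) of component means
#' @param covs list of k positive-definite d x d covariance matrices, or a
#'   single matrix recycled for all components
#' @param weights mixture weights (default uniform; must sum to 1)
#' @param n total number of points
#' @param seed integer seed
#' @return list with `X` (n x d matrix) and `labels` (integer vector)
#' @export
generate_mixture <- function(k, means, covs, weights = NULL, n = 200L,
                             seed = 1L) {
  if (is.list(means)) means <- do.call(rbind, means)
  means <- as.matrix(means)
  stopifnot(nrow(means) == k)
  d <- ncol(means)
  if (is.matrix(covs)) covs <- rep(list(covs), k)
  stopifnot(length(covs) == k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  set.seed(as.integer(seed))
  labels <- sample.int(k, n, replace = TRUE, prob = weights)
  X <- matrix(0, n, d)
  for (g in seq_len(k)) {
    idx <- which(labels == g)
    if (length(idx)) {
      sigma <- as.matrix(covs[[g]])
      if (all(sigma == 0)) {
        X[idx, ] <- matrix(means[g, ], length(idx), d, byrow = TRUE)
      } else {
        X[idx, ] <- MASS::mvrnorm(length(idx), mu = means[g, ], Sigma = sigma)
      }
    }
  }
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, labels = labels)
}
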