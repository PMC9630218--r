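#' Build a feature matrix for clustering
#'
#' Selects the morphometric observables used to judge group coherence. The
#' default pair is inner vessel diameter and wall thickness, unscaled (both
#' in micrometres); standardization to unit variance is available for
#' exploration. Unmeasured segments (NA features) are dropped — their group
#' memberships are still accounted for by [rank_schemes()].
#'
#' @param features per-segment features (from [aggregate_measurements()] or
#'   [join_features()])
#' @param columns feature columns, default
#'   `c("inner_diameter_um", "wall_thickness_um")`
#' @param standardize scale each column to zero mean / unit variance
#'   (default `FALSE`: raw micrometre values)
#' @return numeric matrix, rownames = segment IDs
#' @export
feature_matrix <- function(features,
                           columns = c("inner_diameter_um", "wall_thickness_um"),
                           standardize = FALSE) {
  miss <- setdiff(columns, names(features))
  if (length(miss)) stop("feature column(s) not found: ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, columns, drop = FALSE])
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  rownames(X) <- as.character(features$segment_id[keep])
  if (standardize) X <- scale(X)
  X
}

# spec-facing family names -> mclust model codes
FAMILY_CODES <- c("spherical-equal" = "EII", "spherical-variable" = "VII",
                  "diagonal-equal" = "EEI", "diagonal-variable" = "VVI",
                  "tied-full" = "EEE", "full-variable" = "VVV")

as_model_code <- function(family) {
  if (family %in% names(FAMILY_CODES)) return(unname(FAMILY_CODES[family]))
  fam <- toupper(family)
  if (fam %in% mclust::mclust.options("emModelNames")) return(fam)
  stop("unknown covariance family '", family, "'; use one of ",
       paste(names(FAMILY_CODES), collapse = ", "),
       " or an mclust model code")
}

#' Fit a Gaussian mixture model
#'
#' Fits a k-component Gaussian mixture to the feature matrix by EM
#' (via mclust, whose model-based hierarchical initialization is
#' deterministic; `seed` and `restarts` are accepted for interface stability
#' and reproducibility bookkeeping).
#'
#' @param X numeric feature matrix (n rows, d columns)
#' @param k number of mixture components (>= 1, < n)
#' @param family covariance family: one of `"spherical-equal"`,
#'   `"spherical-variable"`, `"diagonal-equal"`, `"diagonal-variable"`,
#'   `"tied-full"`, `"full-variable"`, or any mclust model code (e.g. `"VVE"`)
#' @param seed integer seed recorded in the fit
#' @param restarts recorded restart count (initialization is deterministic)
#' @return object of class `gmm_fit`: component weights, means (d x k),
#'   covariance structure, `loglik`, free-parameter count `df`, `bic`
#'   (maximize convention, `2*logLik - df*log(n)`), per-row responsibilities
#'   `z` and MAP `classification`
#' @export
fit_gmm <- function(X, k, family = "full-variable", seed = 1L, restarts = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k = ", k, " components require more than ", n, " observations")
  code <- as_model_code(family)
  set.seed(as.integer(seed))
  # Mclust() resolves mclustBIC in the calling frame; bind it locally so the
  # call works with the mclust namespace unattached
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(X, G = k, modelNames = code, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$loglik) || is.na(fit$loglik)) {
    stop("GMM fit failed for k = ", k, ", family ", code,
         " (likely a singular/collapsed component); consider a simpler ",
         "covariance family, fewer components, or regularizing the data")
  }
  z <- fit$z
  if (is.null(z)) z <- matrix(1, n, 1L)
  means <- fit$parameters$mean
  if (is.null(dim(means))) means <- matrix(means, ncol = k)
  structure(list(k = k, family = code, n = n, d = ncol(X),
                 weights = fit$parameters$pro,
                 means = means,
                 variance = fit$parameters$variance,
                 loglik = fit$loglik, df = fit$df,
                 bic = 2 * fit$loglik - fit$df * log(n),
                 z = z,
                 classification = as.integer(fit$classification),
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> k = ", x$k, " (", x$family, "), n = ", x$n,
      ", logLik = ", format(x$loglik), ", df = ", x$df,
      ", BIC = ", format(x$bic), "\n", sep = "")
  invisible(x)
}

#' Bayesian information criterion (maximize convention)
#'
#' `BIC = 2*logLik - n_params*log(n_obs)`; larger is better, so the selected
#' model attains the *maximum* BIC. (The equally common negated convention
#' `n_params*log(n_obs) - 2*logLik` is this value times -1.)
#'
#' @param loglik maximized log-likelihood, or a `gmm_fit` (then the other
#'   arguments are taken from the fit)
#' @param n_params number of free parameters
#' @param n_obs number of observations
#' @return numeric BIC value
#' @export
bic_score <- function(loglik, n_params = NULL, n_obs = NULL) {
  if (inherits(loglik, "gmm_fit")) {
    fit <- loglik
    if (is.null(n_obs)) n_obs <- fit$n
    return(2 * fit$loglik - fit$df * log(n_obs))
  }
  2 * loglik - n_params * log(n_obs)
}

#' Select a mixture model over a (k, family) grid by BIC
#'
#' Fits every combination of component count `1..kmax` and covariance
#' family, scores each by BIC, and returns the grid together with the
#' argmax-BIC fit. Failed fits are recorded in the grid with `NA` BIC, never
#' silently dropped.
#'
#' @inheritParams fit_gmm
#' @param kmax largest component count (default 9)
#' @param families character vector of covariance families (default: the six
#'   standard families)
#' @return object of class `model_selection`: `grid` (data.frame `k`,
#'   `family`, `loglik`, `df`, `bic`, `error`), `best` (`gmm_fit`), `kmax`
#' @export
select_model <- function(X, kmax = 9L, families = names(FAMILY_CODES),
                         seed = 1L, restarts = 10L) {
  if (kmax < 1L) stop("kmax must be >= 1")
  if (length(families) == 0L) stop("at least one covariance family required")
  grid <- expand.grid(k = seq_len(kmax), family = families,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$loglik <- NA_real_; grid$df <- NA_real_; grid$bic <- NA_real_
  grid$error <- NA_character_
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(
      fit_gmm(X, k = grid$k[i], family = grid$family[i],
              seed = seed, restarts = restarts),
      error = function(e) e)
    if (inherits(f, "error")) {
      grid$error[i] <- conditionMessage(f)
    } else {
      fits[[i]] <- f
      grid$loglik[i] <- f$loglik; grid$df[i] <- f$df; grid$bic[i] <- f$bic
    }
  }
  if (all(is.na(grid$bic))) stop("all mixture fits failed on the (k, family) grid")
  best <- fits[[which.max(grid$bic)]]
  structure(list(grid = grid, best = best, kmax = kmax, seed = as.integer(seed)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> grid of ", nrow(x$grid), " fits (k = 1..", x$kmax,
      "); best: k = ", x$best$k, " (", x$best$family, "), BIC = ",
      format(x$best$bic), "\n", sep = "")
  invisible(x)
}

#' Davies-Bouldin cluster validity index
#'
#' For groups with centroids \eqn{A_i}, within-group dispersion
#' \eqn{S_i = (\mathrm{mean}_{x \in i}\, d(x, A_i)^q)^{1/q}} and centroid
#' separation \eqn{M_{ij} = \|A_i - A_j\|_p} (Minkowski-p), the index is the
#' mean over groups of \eqn{\max_{j \ne i} (S_i + S_j)/M_{ij}}. Lower values
#' indicate compact, well-separated groups; the index is invariant under
#' group relabeling and rigid translation, and invariant under uniform
#' scaling of the data.
#'
#' @param X numeric matrix of observations
#' @param labels group label per row (vector or factor; unused factor levels
#'   count as empty groups)
#' @param p Minkowski exponent for centroid separation (default 2,
#'   Euclidean); also used for point-to-centroid distances
#' @param q dispersion exponent (default 2, root-mean-square; `q = 1` gives
#'   the mean-distance convention)
#' @param empty_action empty groups are `"drop"`ped (default; the dropped
#'   count is attached as attribute `n_empty`) or raise an `"error"`
#' @return the index (numeric scalar) with attributes `n_groups` (non-empty
#'   groups scored) and `n_empty`
#' @export
davies_bouldin <- function(X, labels, p = 2, q = 2,
                           empty_action = c("drop", "error")) {
  empty_action <- match.arg(empty_action)
  if (p < 1 || q < 1) stop("Minkowski exponents p and q must be >= 1")
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X)) stop("one label per row of X required")
  counts <- table(labels)
  n_empty <- sum(counts == 0L)
  if (n_empty > 0L && empty_action == "error") {
    stop(n_empty, " empty group(s) in labeling")
  }
  lev <- names(counts)[counts > 0L]
  g <- length(lev)
  if (g < 2L) stop("Davies-Bouldin index needs at least 2 non-empty groups")
  centroids <- t(vapply(lev, function(l) colMeans(X[labels == l, , drop = FALSE]),
                        numeric(ncol(X))))
  S <- vapply(lev, function(l) {
    rows <- X[labels == l, , drop = FALSE]
    d <- minkowski_dist(rows, centroids[l, ], p)
    mean(d^q)^(1 / q)
  }, numeric(1))
  R <- matrix(0, g, g)
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      M <- sum(abs(centroids[i, ] - centroids[j, ])^p)^(1 / p)
      if (M == 0) {
        stop("degenerate centroids: groups ", lev[i], " and ", lev[j],
             " have identical centroids")
      }
      R[i, j] <- R[j, i] <- (S[i] + S[j]) / M
    }
  }
  diag(R) <- -Inf
  db <- mean(apply(R, 1L, max))
  structure(db, n_groups = g, n_empty = n_empty)
}

minkowski_dist <- function(rows, center, p) {
  rowSums(abs(sweep(rows, 2L, center))^p)^(1 / p)
}

#' Rank classification schemes by Davies-Bouldin score
#'
#' Scores each classification scheme — and the mixture-model reference
#' clustering — by the Davies-Bouldin index on the measured segments'
#' feature matrix, ascending (lower = better-separated groups). Groups that
#' contain no measured segment are counted as empty and excluded from the
#' score; groups reduced to a single measured point are flagged as
#' singletons since both artificially flatter a scheme's score without
#' adding real separation.
#'
#' @param X feature matrix with segment-ID rownames (see [feature_matrix()])
#' @param schemes named list: scheme name -> `scheme_labels` (or named
#'   integer vector over *all* segments, measured or not)
#' @param gmm_labels optional reference labels, either a `gmm_fit` or an
#'   integer vector aligned with the rows of `X`; reported as scheme `"GMM"`
#' @inheritParams davies_bouldin
#' @return object of class `evaluation_report`: data.frame `ranking` with
#'   columns `algorithm`, `score`, `n_groups`, `n_scored_groups`, `n_empty`,
#'   `n_singleton`, `error`, sorted ascending by score (failed schemes
#'   last), plus the scoring configuration
#' @export
rank_schemes <- function(X, schemes, gmm_labels = NULL, p = 2, q = 2) {
  stopifnot(is.list(schemes), length(schemes) > 0)
  if (is.null(names(schemes)) || any(names(schemes) == "")) {
    names(schemes) <- vapply(schemes, function(s) {
      sc <- attr(s, "scheme"); if (is.null(sc)) "scheme" else sc
    }, character(1))
  }
  key <- rownames(X)
  if (is.null(key)) stop("X must carry segment-ID rownames")
  rows <- lapply(names(schemes), function(nm) {
    full <- schemes[[nm]]
    if (is.null(names(full))) stop("scheme '", nm, "' labels must be named by segment ID")
    if (!all(key %in% names(full))) {
      stop("scheme '", nm, "' does not label every measured segment")
    }
    measured <- factor(as.integer(full[key]),
                       levels = sort(unique(as.integer(full))))
    score_one(nm, X, measured, p, q)
  })
  if (!is.null(gmm_labels)) {
    lab <- if (inherits(gmm_labels, "gmm_fit")) gmm_labels$classification else gmm_labels
    if (length(lab) != nrow(X)) {
      stop("gmm_labels must assign one label per row of X")
    }
    rows <- c(rows, list(score_one("GMM", X, factor(lab), p, q)))
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(is.na(ranking$score), ranking$score), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, p = p, q = q, n_measured = nrow(X)),
            class = "evaluation_report")
}

score_one <- function(nm, X, measured, p, q) {
  counts <- table(measured)
  res <- tryCatch(davies_bouldin(X, measured, p = p, q = q),
                  error = function(e) e)
  if (inherits(res, "error")) {
    data.frame(algorithm = nm, score = NA_real_,
               n_groups = length(counts),
               n_scored_groups = NA_integer_,
               n_empty = sum(counts == 0L),
               n_singleton = sum(counts == 1L),
               error = conditionMessage(res), stringsAsFactors = FALSE)
  } else {
    data.frame(algorithm = nm, score = as.numeric(res),
               n_groups = length(counts),
               n_scored_groups = attr(res, "n_groups"),
               n_empty = attr(res, "n_empty"),
               n_singleton = sum(counts == 1L),
               error = NA_character_, stringsAsFactors = FALSE)
  }
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> Davies-Bouldin scores (p = ", x$p, ", q = ", x$q,
      "; lower is better) on ", x$n_measured, " measured segments\n", sep = "")
  df <- x$ranking
  df$score <- round(df$score, 2)
  print(df[, c("algorithm", "score", "n_groups", "n_empty", "n_singleton")],
        row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON carries the full report (scores, group/empty/singleton counts,
#' configuration, and optionally the BIC model-selection grid); the CSV is
#' the two-column `algorithm,score` summary table.
#'
#' @param report an `evaluation_report`
#' @param json_path,csv_path output paths (either may be `NULL` to skip)
#' @param selection optional `model_selection` to embed (BIC grid and
#'   selected model)
#' @param seed optional seed to echo into the report header
#' @return invisibly, the report as a list
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL,
                         selection = NULL, seed = NULL) {
  out <- list(davies_bouldin = list(p = report$p, q = report$q),
              n_measured = report$n_measured,
              ranking = report$ranking)
  if (!is.null(seed)) out$seed <- seed
  if (!is.null(selection)) {
    out$model_selection <- list(
      kmax = selection$kmax,
      best = list(k = selection$best$k, family = selection$best$family,
                  loglik = selection$best$loglik, df = selection$best$df,
                  bic = selection$best$bic),
      grid = selection$grid[, c("k", "family", "loglik", "df", "bic")])
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$ranking[, c("algorithm", "score")], csv_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
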