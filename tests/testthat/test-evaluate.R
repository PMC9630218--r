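test_that("k = 1 fit recovers the closed-form Gaussian MLE", {
  set.seed(10)
  X <- MASS::mvrnorm(80, mu = c(3, -2), Sigma = matrix(c(4, 1, 1, 2), 2))
  fit <- fit_gmm(X, k = 1, family = "full-variable")
  expect_equal(as.vector(fit$means), colMeans(X), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(gaussian_loglik_mle(X)), tolerance = 1e-6)
  expect_equal(fit$df, 5)  # 2 means + 3 free covariance entries, no weights
  expect_equal(fit$bic, 2 * fit$loglik - 5 * log(80), tolerance = 1e-10)
  expect_equal(sum(fit$weights), 1)
})

test_that("well-separated components are recovered exactly", {
  mix <- generate_mixture(k = 2, means = rbind(c(0, 0), c(100, 100)),
                          covs = diag(2), weights = c(0.5, 0.5),
                          n = 400, seed = 21)
  fit <- fit_gmm(mix$X, k = 2, family = "full-variable", seed = 21)
  expect_equal(adjusted_rand(fit$classification, mix$labels), 1.0)
  # estimated means within 3 standard errors of the truth
  ord <- order(fit$means[1, ])
  truth <- rbind(c(0, 0), c(100, 100))
  for (g in 1:2) {
    n_g <- sum(mix$labels == g)
    expect_true(all(abs(fit$means[, ord[g]] - truth[g, ]) <= 3 / sqrt(n_g)))
  }
})

test_that("degenerate fits raise errors", {
  set.seed(1)
  X <- matrix(rnorm(6), 3, 2)
  expect_error(fit_gmm(X, k = 5), "observations")
  expect_error(fit_gmm(X, k = 0), "k must be")
  expect_error(fit_gmm(matrix(rnorm(40), 20, 2), k = 2, family = "nonsense"),
               "unknown covariance family")
})

test_that("BIC follows the maximize convention 2logL - m log n", {
  expect_equal(bic_score(-100, 5, 100), 2 * -100 - 5 * log(100))
  expect_equal(round(bic_score(-100, 5, 100), 4), -223.0259)
  # larger parameter count strictly lowers BIC at equal likelihood
  expect_true(bic_score(-100, 7, 100) < bic_score(-100, 5, 100))
})

test_that("select_model scans the grid, records failures, picks argmax BIC", {
  set.seed(30)
  X <- MASS::mvrnorm(60, mu = c(0, 0), Sigma = diag(2))
  sel <- select_model(X, kmax = 1, families = "full-variable")
  expect_equal(nrow(sel$grid), 1L)
  expect_equal(sel$best$k, 1L)

  sel3 <- select_model(X, kmax = 3,
                       families = c("spherical-equal", "full-variable"))
  expect_equal(nrow(sel3$grid), 6L)
  ok <- !is.na(sel3$grid$bic)
  expect_true(any(ok))
  expect_equal(sel3$best$bic, max(sel3$grid$bic, na.rm = TRUE))
  # deterministic given (data, seed)
  sel3b <- select_model(X, kmax = 3,
                        families = c("spherical-equal", "full-variable"))
  expect_identical(sel3$grid, sel3b$grid)
  expect_error(select_model(X, kmax = 0), "kmax")
  expect_error(select_model(X, kmax = 2, families = character(0)), "family")
})

test_that("single-Gaussian data selects k = 1 by BIC", {
  hits <- 0L
  for (s in 1:20) {
    X <- generate_mixture(k = 1, means = rbind(c(50, 8)),
                          covs = matrix(c(25, 0, 0, 4), 2), n = 150,
                          seed = 100 + s)$X
    sel <- select_model(X, kmax = 3, families = "full-variable")
    hits <- hits + (sel$best$k == 1L)
  }
  expect_gte(hits, 19L)
})

test_that("Davies-Bouldin matches the hand-computed two-cluster fixture", {
  X <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  lab <- c(1, 1, 2, 2)
  expect_equal(as.numeric(davies_bouldin(X, lab, p = 2, q = 2)), 0.2)
  # all within-group distances are equal here, so q is immaterial
  expect_equal(as.numeric(davies_bouldin(X, lab, p = 2, q = 1)), 0.2)
  expect_error(davies_bouldin(X, rep(1, 4)), "at least 2")
  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 2), c(0, 2), c(0, 0)),
                              c(1, 1, 2, 2)), "degenerate centroids")
  expect_error(davies_bouldin(X, lab, p = 0.5), "exponents")
})

test_that("Davies-Bouldin agrees with the brute-force oracle", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(6:50, 1)
    k <- sample(2:5, 1)
    X <- matrix(rnorm(2 * n, sd = 5), n, 2)
    lab <- sample.int(k, n, replace = TRUE)
    lab[seq_len(k)] <- seq_len(k)  # every group non-empty
    p <- sample(c(1, 2, 3), 1)
    q <- sample(c(1, 2), 1)
    expect_equal(as.numeric(davies_bouldin(X, lab, p = p, q = q)),
                 db_oracle(X, lab, p = p, q = q), tolerance = 1e-10)
  }
})

test_that("Davies-Bouldin is invariant under relabeling, translation, scaling", {
  set.seed(8)
  X <- matrix(rnorm(80), 40, 2)
  lab <- sample.int(3, 40, replace = TRUE)
  base <- as.numeric(davies_bouldin(X, lab))
  perm <- c(3L, 1L, 2L)[lab]
  expect_equal(as.numeric(davies_bouldin(X, perm)), base)
  expect_equal(as.numeric(davies_bouldin(X + 1000, lab)), base)
  expect_equal(as.numeric(davies_bouldin(X * 37.5, lab)), base, tolerance = 1e-12)
  # singleton groups contribute zero dispersion
  lab2 <- lab
  lab2[1] <- 4L
  lab2[-1][lab2[-1] == 4L] <- 3L
  expect_no_error(davies_bouldin(X, lab2))
})

test_that("rank_schemes scores, flags empty and singleton groups, and sorts", {
  set.seed(12)
  mix <- generate_mixture(k = 3, means = rbind(c(0, 0), c(40, 0), c(0, 40)),
                          covs = diag(2), n = 90, seed = 5)
  X <- mix$X
  rownames(X) <- as.character(1:90)
  true_lab <- stats::setNames(mix$labels, rownames(X))
  same <- list(a = true_lab, b = true_lab)
  rep1 <- rank_schemes(X, same)
  expect_equal(rep1$ranking$score[1], rep1$ranking$score[2])

  # scheme with a group made entirely of unmeasured segments: labels cover
  # segments 1..95 but X only has rows 1..90, group 4 lives on 91..95
  full <- stats::setNames(c(mix$labels, rep(4L, 5)), as.character(1:95))
  rep2 <- rank_schemes(X, list(with_empty = full))
  row <- rep2$ranking[rep2$ranking$algorithm == "with_empty", ]
  expect_equal(row$n_groups, 4L)
  expect_equal(row$n_empty, 1L)
  expect_equal(row$n_scored_groups, 3L)

  # generative labels beat a degraded labeling, and ranking sorts ascending
  noisy <- true_lab
  flip <- sample(90, 45)
  noisy[flip] <- sample.int(3, 45, replace = TRUE)
  rep3 <- rank_schemes(X, list(truth = true_lab, noisy = noisy),
                       gmm_labels = mix$labels)
  expect_equal(rep3$ranking$score, sort(rep3$ranking$score))
  expect_lt(rep3$ranking$score[rep3$ranking$algorithm == "truth"],
            rep3$ranking$score[rep3$ranking$algorithm == "noisy"])

  # failures are recorded, not propagated
  rep4 <- rank_schemes(X, list(allsame = stats::setNames(rep(1L, 90), rownames(X)),
                               truth = true_lab))
  bad <- rep4$ranking[rep4$ranking$algorithm == "allsame", ]
  expect_true(is.na(bad$score))
  expect_match(bad$error, "at least 2")
  expect_error(rank_schemes(X, list(short = true_lab[1:10])), "every measured")
})

test_that("write_report emits JSON and the algorithm,score CSV", {
  set.seed(3)
  mix <- generate_mixture(k = 2, means = rbind(c(0, 0), c(30, 30)),
                          covs = diag(2), n = 60, seed = 9)
  X <- mix$X
  rownames(X) <- as.character(1:60)
  rep <- rank_schemes(X, list(truth = stats::setNames(mix$labels, rownames(X))),
                      gmm_labels = mix$labels)
  sel <- select_model(X, kmax = 2, families = "full-variable")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, cp, selection = sel, seed = 9L)
  js <- jsonlite::read_json(jp)
  expect_equal(js$seed, 9L)
  expect_equal(length(js$ranking), 2L)
  expect_equal(js$model_selection$best$k, sel$best$k)
  csv <- utils::read.csv(cp)
  expect_equal(names(csv), c("algorithm", "score"))
  expect_equal(nrow(csv), 2L)
})

test_that("feature_matrix selects, drops unmeasured rows, can standardize", {
  t <- make_caterpillar()
  feats <- aggregate_measurements(data.frame(
    segment_id = c(1L, 2L, 3L), slice_index = 1L,
    inner_diameter_um = c(100, 80, 40), outer_diameter_um = c(120, 95, 48)))
  j <- join_features(feats, classify_all(t))
  X <- feature_matrix(j)
  expect_equal(dim(X), c(3L, 2L))
  expect_equal(rownames(X), c("1", "2", "3"))
  expect_equal(colnames(X), c("inner_diameter_um", "wall_thickness_um"))
  Xs <- feature_matrix(j, standardize = TRUE)
  expect_equal(unname(colMeans(Xs)), c(0, 0))
  expect_error(feature_matrix(j, columns = "no_such"), "not found")
})
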