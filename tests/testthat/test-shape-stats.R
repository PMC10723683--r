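set.seed(303)

flatten_coords_test <- function(m) as.vector(t(m))

# small labelled PC-score dataset with separated groups
make_scores <- function(n_per = 8, G = 3, p = 4, sep = 6) {
  x <- do.call(rbind, lapply(seq_len(G), function(g) {
    mu <- rep(0, p); mu[min(g, p)] <- sep * (g - 1)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, mu, `+`)
  }))
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  list(x = x, g = rep(paste0("g", seq_len(G)), each = n_per))
}

test_that("PCA reproduces the data and matches the covariance-eigen oracle", {
  x <- matrix(rnorm(6 * 9), 6, 9)
  p <- fit_pca(x)
  recon <- sweep(p$scores %*% t(p$eigenvectors), 2, p$mean_vector, `+`)
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(apply(p$scores, 2, var), p$eigenvalues,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(p$eigenvectors), diag(ncol(p$eigenvectors)),
               tolerance = 1e-10, ignore_attr = TRUE)
  ee <- eigen(cov(x), symmetric = TRUE)
  m <- length(p$eigenvalues)
  expect_equal(p$eigenvalues, ee$values[1:m], tolerance = 1e-8)
  for (j in 1:m)   # eigenvectors agree up to sign
    expect_equal(abs(p$eigenvectors[, j]), abs(ee$vectors[, j]),
                 tolerance = 1e-6)
})

test_that("project_pca is the affine map it claims to be", {
  x <- matrix(rnorm(8 * 12), 8, 12)
  p <- fit_pca(x)
  expect_equal(as.vector(project_pca(p, p$mean_vector)),
               rep(0, ncol(p$scores)), tolerance = 1e-10)
  expect_equal(project_pca(p, x), p$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  a <- rnorm(12); b <- rnorm(12)
  lhs <- project_pca(p, a + b)
  rhs <- project_pca(p, a) + project_pca(p, b) -
    project_pca(p, rep(0, 12))
  expect_equal(lhs, rhs, tolerance = 1e-8)
  expect_error(project_pca(p, rnorm(5)), "3K")
})

test_that("CVA satisfies its scaling and dimension invariants", {
  d <- make_scores()
  cv <- fit_cva(d$x, d$g)
  expect_equal(sum(cv$pct_variance), 100, tolerance = 1e-6)
  expect_true(all(cv$eigenvalues >= 0))
  expect_identical(ncol(cv$canonical_vectors),
                   min(length(cv$groups) - 1L, cv$n_pcs))
  # pooled within-group covariance of canonical scores is the identity
  wb <- oracle_wb(cv$cv_scores, d$g)
  expect_equal(wb$W, diag(ncol(cv$cv_scores)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # two groups: single axis carrying 100% of the variance
  two <- fit_cva(d$x[1:16, ], d$g[1:16])
  expect_identical(ncol(two$canonical_vectors), 1L)
  expect_equal(two$pct_variance, 100, tolerance = 1e-10)
  expect_error(fit_cva(d$x[1:16, ], rep("a", 16)), "2 groups")
  expect_error(fit_cva(matrix(rnorm(8 * 7), 8, 7), rep(c("a", "b"), 4)),
               "reduce n_pcs")
})

test_that("CVA eigenvalues match the brute-force generalized eigenproblem", {
  for (rep in 1:5) {
    d <- make_scores(n_per = 7, G = 3, p = 4, sep = 2)
    cv <- fit_cva(d$x, d$g)
    oracle <- oracle_cva_eigenvalues(d$x, d$g)
    expect_equal(cv$eigenvalues, oracle[1:2], tolerance = 1e-8)
  }
})

test_that("canonical scores are invariant to invertible remapping of PCs", {
  d <- make_scores(n_per = 10, G = 3, p = 5, sep = 3)
  cv1 <- fit_cva(d$x, d$g)
  M <- matrix(rnorm(25), 5, 5)
  while (abs(det(M)) < 0.1) M <- matrix(rnorm(25), 5, 5)
  cv2 <- fit_cva(d$x %*% M, d$g)
  expect_equal(abs(cv1$cv_scores), abs(cv2$cv_scores), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("classification agrees with full-Mahalanobis brute force", {
  d <- make_scores(n_per = 12, G = 3, p = 4, sep = 6)
  cv <- fit_cva(d$x, d$g)
  # group means classify to their own group
  for (g in cv$groups)
    expect_identical(classify_cva(cv, cv$group_means[g, ]), g)
  new <- matrix(rnorm(50 * 4, sd = 3), 50, 4)
  expect_identical(classify_cva(cv, new),
                   unname(oracle_mahalanobis_classify(d$x, d$g, new)))
  expect_error(classify_cva(cv, rnorm(2)), "n_pcs")
})

test_that("classification matches brute force on 10 random small datasets", {
  ok <- 0L
  for (rep in 1:10) {
    d <- make_scores(n_per = 6 + rep %% 3, G = 2 + rep %% 2, p = 3,
                     sep = 4)
    cv <- fit_cva(d$x, d$g)
    pred <- classify_cva(cv, d$x)
    oracle <- unname(oracle_mahalanobis_classify(d$x, d$g, d$x))
    expect_identical(pred, oracle)
    ok <- ok + 1L
  }
  expect_identical(ok, 10L)
})

test_that("equidistant points break ties toward the first group", {
  x <- rbind(c(-1, 0), c(-1.5, 0.5), c(-0.5, -0.5),
             c(1, 0), c(1.5, 0.5), c(0.5, -0.5))
  g <- rep(c("first", "second"), each = 3)
  cv <- fit_cva(x, g)
  expect_identical(classify_cva(cv, c(0, 0)), "first")
})

test_that("jackknife classification separates and tabulates correctly", {
  d <- make_scores(n_per = 10, G = 3, p = 4, sep = 10)
  cl <- jackknife_classification(d$x, d$g)
  expect_gte(cl$overall_accuracy, 95)
  expect_equal(unname(rowSums(cl$counts)), rep(10, 3))
  expect_equal(unname(rowSums(cl$percentages)), rep(100, 3),
               tolerance = 0.1)
  expect_equal(cl$overall_accuracy,
               100 * sum(diag(cl$counts)) / sum(cl$counts))
})

test_that("jackknife agrees with an off-the-shelf LOO discriminant oracle", {
  skip_if_not_installed("MASS")
  d <- make_scores(n_per = 9, G = 3, p = 3, sep = 3)
  cl <- jackknife_classification(d$x, d$g)
  ld <- MASS::lda(d$x, grouping = d$g, prior = rep(1 / 3, 3), CV = TRUE)
  agree <- mean(cl$predicted == as.character(ld$class))
  expect_gte(agree, 0.95)
})

test_that("select_pc_count finds where the signal lives", {
  # group signal confined to the first 3 PCs, later PCs pure noise
  n_per <- 10; G <- 3
  sig <- make_scores(n_per = n_per, G = G, p = 3, sep = 8)
  x <- cbind(sig$x, matrix(rnorm(n_per * G * 5, sd = 5), n_per * G, 5))
  k <- select_pc_count(x, sig$g)
  expect_lte(k, 3L)
  acc <- attr(k, "accuracy")
  expect_equal(unname(acc[as.character(k)]), max(acc))
  # pure noise: flat accuracy, tie rule returns k_min
  noise <- matrix(rnorm(30 * 6), 30, 6)
  kn <- select_pc_count(noise, rep(c("a", "b", "c"), each = 10),
                        k_min = 2, k_max = 4)
  accn <- attr(kn, "accuracy")
  expect_identical(as.integer(kn),
                   as.integer(names(accn)[which(accn == max(accn))[1]]))
})

test_that("a posteriori projection reproduces training scores and origin", {
  sim <- simulate_dataset(simulation_spec(n_groups = 3, n_per_group = 9,
                                          seed = 11))
  ds <- mirror_lefts(sim$dataset)
  g <- generalized_procrustes(ds)
  shapes <- as_shape_matrix(g$aligned)
  pca <- fit_pca(shapes)
  cv <- fit_cva(pca$scores[, 1:6], ds$records$group)
  proj <- project_posteriori(cv, pca, shapes)
  expect_equal(proj, cv$cv_scores, tolerance = 1e-8)
  # the grand-mean shape projects to the origin of canonical space
  mean_shape <- pca$mean_vector +
    as.vector(pca$eigenvectors[, 1:6] %*% cv$grand_mean)
  expect_equal(as.vector(project_posteriori(cv, pca, mean_shape)),
               rep(0, ncol(cv$cv_scores)), tolerance = 1e-8)
})

test_that("held-out specimens land nearest their own group centroid", {
  hits <- 0L; total <- 0L
  for (seed in 1:4) {
    sim <- simulate_dataset(simulation_spec(
      n_groups = 4, n_per_group = 14, effect_size = 0.25,
      noise_sd = 0.005, n_posteriori = 8, seed = seed))
    res <- run_pipeline(sim$dataset, n_pcs = 6)
    rec <- res$records
    post <- rec$specimen_id[rec$posteriori_flag]
    pred <- res$cva$groups[apply(
      attr(typicality_probabilities(res$cva, res$posteriori_scores),
           "d2"), 1, which.min)]
    hits <- hits + sum(pred == rec$group[match(post, rec$specimen_id)])
    total <- total + length(post)
  }
  expect_gte(hits / total, 0.9)
})

test_that("typicality behaves like a chi-square upper tail", {
  d <- make_scores(n_per = 10, G = 3, p = 4, sep = 4)
  cv <- fit_cva(d$x, d$g)
  centro <- typicality_probabilities(cv, cv$cv_group_means)
  for (i in seq_along(cv$groups))
    expect_equal(centro[[cv$groups[i]]][i], 1, tolerance = 1e-12)
  # far point is atypical of everything: D2 = 50 on df = 2 axes
  expect_lt(pchisq(50, df = 2, lower.tail = FALSE), 1e-9)
  far <- typicality_probabilities(cv, matrix(c(50, 50), 1))
  expect_true(all(as.matrix(far[, -1]) < 1e-9))
  # strictly decreasing in distance
  along <- typicality_probabilities(
    cv, cbind(seq(0, 5, by = 0.5), 0))
  expect_true(all(diff(along[[cv$groups[1]]][
    order(attr(along, "d2")[, 1])]) < 0))
})

test_that("allometry test matches its closed form and nails exact cases", {
  s <- runif(20, 1, 3)
  cvs <- cbind(2 * s, rnorm(20))
  res <- allometry_test(s, cvs)
  expect_equal(res$r[1], 1, tolerance = 1e-10)
  expect_lt(res$p_value[1], 1e-12)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)
  expect_error(allometry_test(rep(1, 20), cvs), "zero variance")
  # t-distribution p-value from the definition
  r <- res$r[2]; n <- 20
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p_value[2], 2 * pt(-abs(tstat), df = n - 2),
               tolerance = 1e-12)
})

test_that("extreme shapes are linear in the score and match the map composition", {
  sim <- simulate_dataset(simulation_spec(n_groups = 3, n_per_group = 8,
                                          seed = 21))
  res <- run_pipeline(sim$dataset, n_pcs = 5)
  cons <- extreme_shape(res$pca, res$cva, 1, 0)
  expect_equal(flatten_coords_test(cons), res$pca$mean_vector,
               tolerance = 1e-10, ignore_attr = TRUE)
  s1 <- extreme_shape(res$pca, res$cva, 1, 0.02)
  s2 <- extreme_shape(res$pca, res$cva, 1, 0.04)
  expect_equal(s2 - cons, 2 * (s1 - cons), tolerance = 1e-10)
  # brute-force composition of the two linear maps
  dir_oracle <- res$pca$eigenvectors[, 1:res$n_pcs] %*%
    res$cva$canonical_vectors[, 2]
  s <- extreme_shape(res$pca, res$cva, 2, 0.03)
  expect_equal(flatten_coords_test(s - cons),
               0.03 * as.vector(dir_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(extreme_shape(res$pca, res$cva, 99, 0), "axis")
})
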