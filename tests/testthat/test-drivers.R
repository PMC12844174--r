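test_that("Mantel r equals brute-force Pearson on vectorized triangles", {
  m1 <- matrix(c(0, 1, 2, 3, 1, 0, 4, 5, 2, 4, 0, 6, 3, 5, 6, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  m2 <- matrix(c(0, 2, 1, 7, 2, 0, 3, 2, 1, 3, 0, 4, 7, 2, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  res <- mantel_test(m1, m2, n_perm = 99, seed = 1)
  expect_equal(res$r, bf_mantel_r(m1, m2), tolerance = 1e-12)
  expect_equal(mantel_test(m1, m1, n_perm = 99, seed = 1)$r, 1, tolerance = 1e-12)
  expect_identical(res, mantel_test(m1, m2, n_perm = 99, seed = 1))

  const <- matrix(1, 4, 4, dimnames = dimnames(m1)); diag(const) <- 0
  expect_error(mantel_test(m1, const), class = "degenerate_input")
})

test_that("env_distance is the absolute difference of z-scores", {
  v <- c(a = 1, b = 3, c = 5)
  d <- as.matrix(env_distance(v))
  z <- (v - 3) / 2
  expect_equal(d["a", "c"], abs(z["a"] - z["c"]), ignore_attr = TRUE)
  expect_error(env_distance(unname(v)), class = "invalid_argument")
})

test_that("db-RDA recovers noiseless structure and rejects collinearity", {
  withr::with_seed(70, {
    x <- rnorm(20)
    noise <- rnorm(20)
    # community = function of x plus a whisper of noise so the permutation
    # test keeps a residual component
    pts <- cbind(2 * x, -x) + matrix(rnorm(40, sd = 0.02), ncol = 2)
    d <- dist(pts)
    attr(d, "Labels") <- paste0("s", 1:20)
    pred <- data.frame(x = x, noise = noise)
    fit <- dbrda_fit(d, pred, n_perm = 99, seed = 1)
    expect_gte(fit$constrained_proportion, 0.95)
    expect_lte(fit$constrained_proportion, 1 + 1e-10)
    expect_lte(fit$adj_r_squared, fit$r_squared)
    expect_lt(fit$p_value, 0.05)

    dup <- data.frame(x = x, x2 = x)
    expect_error(dbrda_fit(d, dup), class = "collinear_predictors")
    expect_error(dbrda_fit(d, data.frame(k = rep(1, 20))),
                 class = "invalid_argument")
  })
})

test_that("PERMANOVA R2 equals the brute-force sum-of-squares decomposition", {
  # two tight clusters: between-distance 1, within 0
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  res <- permanova_test(m, g, n_perm = 99, seed = 1)
  # SS_total = sum d^2 / n = 4/4 = 1; SS_within = 0 -> R2 = 1
  expect_equal(res$r_squared, 1, tolerance = 1e-10)

  tab <- random_table(8, 20, depth = 100, seed = 71)
  d <- bray_curtis(tab)
  g8 <- setNames(rep(c("A", "B"), 4), rownames(tab))
  res2 <- permanova_test(d, g8, n_perm = 99, seed = 2)
  dm <- as.matrix(d)^2
  n <- 8
  ss_total <- sum(dm[lower.tri(dm)]) / n
  ss_within <- sum(vapply(c("A", "B"), function(k) {
    idx <- names(g8)[g8 == k]
    sub <- dm[idx, idx]
    sum(sub[lower.tri(sub)]) / length(idx)
  }, numeric(1)))
  expect_equal(res2$r_squared, 1 - ss_within / ss_total, tolerance = 1e-10)

  expect_error(permanova_test(m, setNames(rep("A", 4), paste0("s", 1:4))),
               class = "invalid_argument")
})

test_that("ANOSIM matches brute-force rank means and perfect separation", {
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0.1
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  res <- anosim_test(m, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)                     # all between > all within

  tab <- random_table(8, 15, depth = 80, seed = 72)
  d <- as.matrix(bray_curtis(tab))
  g8 <- setNames(rep(c("A", "B"), each = 4), rownames(tab))
  res2 <- anosim_test(d, g8, n_perm = 99, seed = 2)
  expect_equal(res2$R, bf_anosim_r(d, g8[rownames(d)]), tolerance = 1e-10)
})

test_that("permutation tests are calibrated under their nulls", {
  rejections <- withr::with_seed(73, {
    vapply(1:100, function(r) {
      tab <- random_table(10, 25, depth = 150)
      d <- bray_curtis(tab)
      g <- setNames(sample(rep(c("A", "B"), 5)), rownames(tab))
      md <- data.frame(sample_id = rownames(tab),
                       lat = runif(10, -60, 60), lon = runif(10, -150, 150))
      geo <- geographic_distance_matrix(md)
      c(mantel = mantel_test(d, geo, n_perm = 99)$p_value < 0.05,
        permanova = permanova_test(d, g, n_perm = 99)$p_value < 0.05,
        anosim = anosim_test(d, g, n_perm = 99)$p_value < 0.05)
    }, logical(3))
  })
  rates <- rowMeans(rejections)
  expect_true(all(rates <= 0.10), info = paste(names(rates), rates, collapse = "; "))
})

test_that("random-forest importance separates signal from noise deterministically", {
  withr::with_seed(80, {
    x1 <- rnorm(30)
    x2 <- rnorm(30)
    y <- x1 + rnorm(30, sd = 0.1)
  })
  res <- rf_importance(y, data.frame(x1 = x1, x2 = x2), n_trees = 300,
                       n_perm = 49, seed = 4)
  imp <- setNames(res$importance$inc_mse_pct, res$importance$predictor)
  pv <- setNames(res$importance$p_value, res$importance$predictor)
  expect_gt(imp["x1"], imp["x2"])
  expect_lt(pv["x1"], 0.05)
  expect_gt(res$r_squared, 0.5)
  expect_identical(res, rf_importance(y, data.frame(x1 = x1, x2 = x2),
                                      n_trees = 300, n_perm = 49, seed = 4))
  expect_error(rf_importance(rep(1, 30), data.frame(x1 = x1)),
               class = "invalid_argument")
  expect_error(rf_importance(y[1:5], data.frame(x1 = x1[1:5])),
               class = "invalid_argument")
})

test_that("glacier aggregation averages cross-sample dissimilarities", {
  m <- matrix(c(0, .2, .6, .8,
                .2, 0, .4, .6,
                .6, .4, 0, .2,
                .8, .6, .2, 0), 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   glacier_id = c("g1", "g1", "g2", "g2"),
                   continent = "Asia", lat = c(30, 31, 40, 41), lon = 90,
                   hdi = c(0.4, 0.6, 0.8, 0.8),
                   u = 1, msr = 1, mmt = 1, tmp = 1, vp = 1)
  rownames(md) <- md$sample_id
  gl <- aggregate_to_glaciers(m, md)
  gm <- as.matrix(gl$dm)
  expect_equal(gm["g1", "g2"], mean(c(.6, .8, .4, .6)))
  expect_equal(gl$metadata["g1", "hdi"], 0.5)
  expect_equal(gl$metadata["g2", "lat"], 40.5)
  expect_equal(gl$metadata["g1", "continent"], "Asia")
})

test_that("diversity-factor fits recover noiseless generating curves", {
  lat <- seq(20, 70, length.out = 12)
  md <- data.frame(sample_id = paste0("s", 1:12),
                   glacier_id = paste0("g", 1:12), continent = "Asia",
                   lat = lat, lon = 90, hdi = seq(0.1, 0.9, length.out = 12),
                   u = 1, msr = 1, mmt = 1, tmp = 1, vp = 1)
  rownames(md) <- md$sample_id
  alpha <- data.frame(sample_id = md$sample_id,
                      richness = -(lat - 45)^2 + 100,
                      shannon = 1)
  fit <- suppressWarnings(diversity_factor_fits(alpha, md))
  expect_equal(fit$latitude$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$latitude$vertex, 45, tolerance = 1e-8)
  expect_true(fit$latitude$hump)

  alpha2 <- data.frame(sample_id = md$sample_id,
                       richness = 3 * md$hdi + 10, shannon = 1)
  fit2 <- suppressWarnings(diversity_factor_fits(alpha2, md))
  expect_equal(fit2$hdi$slope, 3, tolerance = 1e-8)
  expect_equal(fit2$hdi$r_squared, 1, tolerance = 1e-10)

  bad <- md; bad$hdi <- 0.5
  expect_error(diversity_factor_fits(alpha, bad), class = "invalid_argument")
})
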