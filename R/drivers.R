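#' Environmental distance matrix for a scalar factor
#'
#' Absolute difference of z-standardized values — the pairwise "distance"
#' a scalar covariate contributes to a Mantel test.
#'
#' @param values named numeric vector (names = sample ids).
#' @return `dist` object.
#' @export
env_distance <- function(values) {
  if (is.null(names(values)))
    stop_("values must be named by sample id", class = "invalid_argument")
  s <- sd(values)
  z <- if (s > 0) (values - mean(values)) / s else values * 0
  d <- stats::dist(z, method = "manhattan")
  attr(d, "Labels") <- names(values)
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle vectors; one-sided permutation
#' p-value by shuffling one matrix's sample labels (vegan's convention).
#'
#' @param dm_a,dm_b `dist` objects or symmetric matrices with matching labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 999, seed = NULL) {
  ma <- as.matrix(dm_a); mb <- as.matrix(dm_b)
  if (nrow(ma) < 4L) stop_(">= 4 samples required", class = "invalid_argument")
  if (!is.null(rownames(ma)) && !is.null(rownames(mb))) {
    if (!setequal(rownames(ma), rownames(mb)))
      stop_("matrices must share sample labels", class = "invalid_argument")
    mb <- mb[rownames(ma), rownames(ma)]
  }
  lt <- lower.tri(ma)
  if (sd(ma[lt]) == 0 || sd(mb[lt]) == 0)
    stop_("constant distance vector; Mantel r undefined", class = "degenerate_input")
  res <- with_seed_(seed,
    vegan::mantel(stats::as.dist(ma), stats::as.dist(mb),
                  method = "pearson", permutations = n_perm))
  list(r = unname(res$statistic), p_value = res$signif, n_permutations = n_perm)
}

#' Mantel tests of community dissimilarity against each metadata factor
#'
#' @param community_dm community dissimilarity (`dist` or matrix).
#' @param metadata sample metadata containing the factor columns.
#' @param factors character vector of metadata columns to test.
#' @param n_perm,seed as in [mantel_test()].
#' @return data.frame: factor, r, p_value, n_permutations.
#' @export
mantel_factors <- function(community_dm, metadata,
                           factors = c("lat", "lon", "hdi", "u", "msr",
                                       "mmt", "tmp", "vp"),
                           n_perm = 999, seed = NULL) {
  seeds <- spawn_seeds_(seed, length(factors))
  ids <- rownames(as.matrix(community_dm))
  rows <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    vals <- setNames(metadata[[f]], metadata$sample_id)[ids]
    res <- mantel_test(community_dm, env_distance(vals),
                       n_perm = n_perm, seed = seeds[[i]])
    data.frame(factor = f, r = res$r, p_value = res$p_value,
               n_permutations = n_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# z-standardize predictor columns, refusing constants and collinear sets.
standardize_predictors_ <- function(predictors) {
  x <- as.matrix(predictors)
  if (any(apply(x, 2, sd) == 0))
    stop_("constant predictor(s): %s",
          paste(colnames(x)[apply(x, 2, sd) == 0], collapse = ", "),
          class = "invalid_argument")
  z <- scale(x)
  sv <- svd(z)$d
  if (min(sv) == 0 || max(sv) / min(sv) > 1e10) {
    cc <- stats::cor(z)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
    stop_("collinear predictors (e.g. %s ~ %s)",
          colnames(z)[worst[1L]], colnames(z)[worst[2L]],
          class = "collinear_predictors")
  }
  z
}

#' Distance-based redundancy analysis (db-RDA)
#'
#' Principal coordinates of the community dissimilarity are constrained by
#' the (internally z-standardized) predictors, via `vegan::capscale`.
#' Reports the constrained proportion of (positive) inertia, per-axis
#' proportions, Ezekiel-adjusted R-squared and a permutation p-value for
#' the overall model.
#'
#' @param community_dm community dissimilarity (`dist` or matrix).
#' @param predictors data.frame/matrix of numeric predictors, rows matching
#'   the dissimilarity labels; n samples must exceed n predictors.
#' @param n_perm permutations for the overall-model test.
#' @param seed integer seed.
#' @return list with `site_scores`, `axis_proportion`,
#'   `constrained_proportion`, `r_squared`, `adj_r_squared`, `p_value`.
#' @export
dbrda_fit <- function(community_dm, predictors, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(community_dm)
  z <- standardize_predictors_(predictors)
  if (attr(d, "Size") <= ncol(z))
    stop_("need more samples than predictors", class = "invalid_argument")
  df <- as.data.frame(z)
  fit <- vegan::capscale(d ~ ., data = df)
  total <- fit$tot.chi
  constrained <- if (is.null(fit$CCA)) 0 else fit$CCA$tot.chi
  axis_prop <- if (is.null(fit$CCA)) numeric(0) else fit$CCA$eig / total
  r2 <- vegan::RsquareAdj(fit)
  pval <- with_seed_(seed, {
    stats::anova(fit, permutations = n_perm)[["Pr(>F)"]][1L]
  })
  scores <- vegan::scores(fit, display = "sites",
                          choices = seq_len(max(1L, length(axis_prop))))
  list(site_scores = scores,
       axis_proportion = axis_prop,
       constrained_proportion = constrained / total,
       r_squared = r2$r.squared,
       adj_r_squared = r2$adj.r.squared,
       p_value = pval)
}

#' PERMANOVA (adonis2-style) for group differences
#'
#' @param dm dissimilarity (`dist` or matrix).
#' @param groups named vector of group labels per sample.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `r_squared`, `p_value`.
#' @export
permanova_test <- function(dm, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(dm)
  g <- factor(groups[attr(d, "Labels")])
  if (nlevels(g) < 2L) stop_(">= 2 groups required", class = "invalid_argument")
  if (any(table(g) < 2L))
    warning("group(s) of size 1: test valid but weak")
  res <- with_seed_(seed,
    vegan::adonis2(d ~ g, data = data.frame(g = g), permutations = n_perm))
  list(pseudo_F = res$F[1L], r_squared = res$R2[1L], p_value = res$`Pr(>F)`[1L])
}

#' ANOSIM for group differences
#'
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4).
#'
#' @inheritParams permanova_test
#' @return list with `R`, `p_value`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(dm)
  g <- factor(groups[attr(d, "Labels")])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop_(">= 2 groups with >= 2 members required", class = "invalid_argument")
  res <- with_seed_(seed, vegan::anosim(d, g, permutations = n_perm))
  list(R = unname(res$statistic), p_value = res$signif)
}

#' Random-forest importance of environmental predictors
#'
#' Regression forest of a response (typically the first constrained db-RDA
#' axis) on predictors; importance as %IncMSE (percent increase in
#' out-of-bag MSE upon predictor permutation).  Significance per predictor
#' comes from a null distribution of importances obtained by refitting the
#' forest on permuted responses.
#'
#' @param response named numeric vector.
#' @param predictors data.frame/matrix of numeric predictors (rows matching
#'   response order).
#' @param n_trees trees per forest.
#' @param n_perm response permutations for the importance null.
#' @param seed integer seed.
#' @return list with `importance` (data.frame: predictor, inc_mse_pct,
#'   p_value) sorted by decreasing importance, and `r_squared` (out-of-bag).
#' @export
rf_importance <- function(response, predictors, n_trees = 500, n_perm = 100,
                          seed = NULL) {
  if (length(response) < 10L)
    stop_(">= 10 samples required", class = "invalid_argument")
  if (sd(response) == 0)
    stop_("constant response", class = "invalid_argument")
  x <- as.data.frame(as.matrix(predictors))
  mtry <- max(1L, ceiling(ncol(x) / 3))
  with_seed_(seed, {
    fit <- randomForest::randomForest(x, response, ntree = n_trees,
                                      mtry = mtry, importance = TRUE)
    obs_imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1L]
    null_imp <- matrix(NA_real_, n_perm, ncol(x),
                       dimnames = list(NULL, colnames(x)))
    for (r in seq_len(n_perm)) {
      yp <- sample(response)
      nf <- randomForest::randomForest(x, yp, ntree = n_trees, mtry = mtry,
                                       importance = TRUE)
      null_imp[r, ] <- randomForest::importance(nf, type = 1, scale = TRUE)[, 1L]
    }
    p <- vapply(colnames(x), function(v)
      (1 + sum(null_imp[, v] >= obs_imp[v])) / (n_perm + 1), numeric(1))
    imp <- data.frame(predictor = colnames(x),
                      inc_mse_pct = as.numeric(obs_imp),
                      p_value = as.numeric(p), stringsAsFactors = FALSE)
    imp <- imp[order(-imp$inc_mse_pct), ]
    rownames(imp) <- NULL
    list(importance = imp,
         r_squared = fit$rsq[n_trees])
  })
}

#' Aggregate a sample-level dissimilarity matrix and metadata to glaciers
#'
#' Environmental covariates exist at glacier resolution, so driver analyses
#' run at glacier level: between-glacier dissimilarity is the mean of the
#' cross-sample dissimilarities (diagonal forced to 0) and numeric metadata
#' are averaged per glacier.
#'
#' @param dm sample-level dissimilarity (`dist` or matrix).
#' @param metadata sample metadata with `glacier_id`.
#' @return list with `dm` (glacier-level `dist`) and `metadata` (one row per
#'   glacier; `sample_id` holds the glacier id).
#' @export
aggregate_to_glaciers <- function(dm, metadata) {
  m <- as.matrix(dm)
  md <- metadata[rownames(m), ]
  gl <- unique(md$glacier_id)
  out <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (i in seq_along(gl)) for (j in seq_len(i - 1L)) {
    out[i, j] <- out[j, i] <-
      mean(m[md$glacier_id == gl[i], md$glacier_id == gl[j]])
  }
  num <- vapply(md, is.numeric, logical(1))
  agg <- data.frame(sample_id = gl, stringsAsFactors = FALSE)
  for (v in names(md)[num])
    agg[[v]] <- unname(tapply(md[[v]], md$glacier_id, mean)[gl])
  agg$continent <- unname(tapply(md$continent, md$glacier_id,
                                 function(x) x[1L])[gl])
  rownames(agg) <- gl
  list(dm = stats::as.dist(out), metadata = agg)
}

#' Diversity-factor regressions: richness vs latitude and HDI
#'
#' Quadratic ordinary least squares of richness on absolute latitude
#' (hump detection: negative quadratic coefficient with the vertex inside
#' the observed latitude range) and linear OLS of richness on HDI.
#' Analyses are run at glacier level: per-glacier mean richness, latitude
#' and HDI.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param metadata sample metadata (needs glacier_id, lat, hdi).
#' @return list with `latitude` (coefficients, r_squared, p_value, vertex,
#'   hump) and `hdi` (slope, intercept, r_squared, p_value), plus
#'   `n_glaciers`.
#' @export
diversity_factor_fits <- function(alpha, metadata) {
  md <- metadata[alpha$sample_id, ]
  gl <- data.frame(
    richness = as.numeric(tapply(alpha$richness, md$glacier_id, mean)),
    alat = as.numeric(tapply(abs(md$lat), md$glacier_id, mean)),
    hdi = as.numeric(tapply(md$hdi, md$glacier_id, mean)))
  if (nrow(gl) < 5L)
    stop_(">= 5 glacier-level observations required", class = "invalid_argument")
  if (sd(gl$alat) == 0 || sd(gl$hdi) == 0)
    stop_("constant predictor", class = "invalid_argument")

  qfit <- lm(richness ~ alat + I(alat^2), data = gl)
  qs <- summary(qfit)
  cf <- coef(qfit)
  vertex <- if (cf[3L] != 0) -cf[2L] / (2 * cf[3L]) else NA_real_
  qp <- if (qs$fstatistic[1L] > 0)
    stats::pf(qs$fstatistic[1L], qs$fstatistic[2L], qs$fstatistic[3L],
              lower.tail = FALSE) else 1

  lfit <- lm(richness ~ hdi, data = gl)
  ls <- summary(lfit)

  list(
    latitude = list(coefficients = cf, r_squared = qs$r.squared,
                    p_value = as.numeric(qp), vertex = as.numeric(vertex),
                    hump = is.finite(vertex) && cf[3L] < 0 &&
                      vertex > min(gl$alat) && vertex < max(gl$alat)),
    hdi = list(slope = unname(coef(lfit)[2L]),
               intercept = unname(coef(lfit)[1L]),
               r_squared = ls$r.squared,
               p_value = ls$coefficients[2L, 4L]),
    n_glaciers = nrow(gl))
}
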