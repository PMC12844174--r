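EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius

#' Great-circle distance matrix between sampling sites
#'
#' Haversine distances on a sphere of radius 6371.0088 km (IUGG mean),
#' computed with `geosphere::distm`.
#'
#' @param metadata data.frame with columns `sample_id`, `lat` (degrees,
#'   [-90, 90]) and `lon` (degrees, (-180, 180]).
#' @return `dist` object in kilometres with attribute `kind = "geographic_km"`.
#' @export
geographic_distance_matrix <- function(metadata) {
  need <- c("sample_id", "lat", "lon")
  if (!all(need %in% colnames(metadata)))
    stop_("metadata needs columns %s", paste(need, collapse = ", "),
          class = "invalid_argument")
  if (any(!is.finite(metadata$lat)) || any(abs(metadata$lat) > 90) ||
      any(!is.finite(metadata$lon)) || any(metadata$lon <= -180 | metadata$lon > 180))
    stop_("lat/lon out of range", class = "invalid_argument")
  m <- geosphere::distm(cbind(metadata$lon, metadata$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000))
  m <- m / 1000
  dimnames(m) <- list(metadata$sample_id, metadata$sample_id)
  d <- stats::as.dist(m)
  attr(d, "kind") <- "geographic_km"
  d
}

#' Distance-decay regression of community dissimilarity on geographic distance
#'
#' Ordinary least squares of pairwise community dissimilarity on pairwise
#' great-circle distance, fitted within each group (e.g. continent) and
#' overall.  Because pairs sharing a sample are not independent, significance
#' is assessed by a Mantel-style permutation of sample labels (one-sided, for
#' a positive distance-dissimilarity correlation); the parametric OLS p-value
#' is also reported for comparability with plain linear regression.
#'
#' @param community_dm community dissimilarity (`dist` or matrix).
#' @param geo_dm geographic distance in km (`dist` or matrix), same labels.
#' @param groups named vector of group labels per sample, or NULL for a
#'   single overall fit.
#' @param n_perm label permutations for the Mantel-style p-value.
#' @param seed integer seed for the permutations.
#' @return data.frame with one row per group plus `"overall"`: slope
#'   (dissimilarity per km), intercept, r_squared, p_param, p_perm, n_pairs.
#' @export
distance_decay <- function(community_dm, geo_dm, groups = NULL,
                           n_perm = 999, seed = NULL) {
  cm <- as.matrix(community_dm)
  gm <- as.matrix(geo_dm)
  if (!identical(rownames(cm), rownames(gm)))
    stop_("community and geographic matrices must share sample labels",
          class = "invalid_argument")
  samples <- rownames(cm)
  per_group <- !is.null(groups)
  if (per_group) groups <- groups[samples]

  fit_one <- function(ids, label) {
    if (length(ids) < 3L) {
      warning(sprintf("group '%s' has < 3 samples; skipped", label))
      return(NULL)
    }
    csub <- cm[ids, ids]; gsub <- gm[ids, ids]
    lt <- lower.tri(csub)
    y <- csub[lt]; x <- gsub[lt]
    if (sd(x) == 0 || sd(y) == 0) {
      warning(sprintf("group '%s' has a constant distance vector; skipped", label))
      return(NULL)
    }
    fit <- lm(y ~ x)
    r_obs <- cor(x, y)
    perm_r <- with_seed_(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample(length(ids))
      cp <- csub[p, p]
      cor(x, cp[lt])
    }, numeric(1)))
    data.frame(
      region = label,
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = summary(fit)$r.squared,
      p_param = summary(fit)$coefficients[2L, 4L],
      p_perm = (1 + sum(perm_r >= r_obs)) / (n_perm + 1),
      n_pairs = length(y),
      stringsAsFactors = FALSE)
  }

  rows <- if (per_group)
    lapply(unique(groups), function(g) fit_one(samples[groups == g], g))
  else list()
  rows <- c(rows, list(fit_one(samples, "overall")))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
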