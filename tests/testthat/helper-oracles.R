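# Independent brute-force oracles, deliberately written from the formulas
# rather than reusing any package code path.

bf_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

bf_sorensen <- function(x, y) {
  a <- sum(x > 0 & y > 0)
  b <- sum(x > 0 & y == 0)
  cc <- sum(x == 0 & y > 0)
  1 - 2 * a / (2 * a + b + cc)
}

bf_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Spherical law of cosines, the stated independent check on the haversine.
bf_sloc_km <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  to_rad <- pi / 180
  ang <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  R * acos(pmin(pmax(ang, -1), 1))
}

bf_mantel_r <- function(m_a, m_b) {
  lt <- lower.tri(m_a)
  cor(m_a[lt], m_b[lt])
}

# Kruskal-Wallis H with tie correction, from the rank-sum definition.
bf_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# ANOSIM R from ranked dissimilarities.
bf_anosim_r <- function(m, groups) {
  lt <- lower.tri(m)
  r <- rank(m[lt])
  same <- outer(groups, groups, "==")[lt]
  n <- nrow(m)
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

# Exhaustive abundance-weighted beta-MNTD for one pair.
bf_beta_mntd <- function(x, y, d) {
  fx <- x / sum(x); fy <- y / sum(y)
  ix <- which(x > 0); iy <- which(y > 0)
  t1 <- sum(vapply(ix, function(i) fx[i] * min(d[i, iy]), numeric(1)))
  t2 <- sum(vapply(iy, function(j) fy[j] * min(d[j, ix]), numeric(1)))
  (t1 + t2) / 2
}

# Literal re-implementation of the five-way threshold rule, with the
# documented boundary conventions (|bNTI| = 2 -> selection, |RC| = 0.95 ->
# drift).
bf_classify <- function(bnti, rc) {
  if (bnti <= -2) return("HoS")
  if (bnti >= 2) return("HeS")
  if (rc > 0.95) return("DL")
  if (rc < -0.95) return("HD")
  "DR"
}

# Small random count table (samples x taxa) with no empty sample.
random_table <- function(n, s, depth = 100, seed = NULL) {
  gen <- function() {
    m <- matrix(rmultinom(n, depth, prob = rexp(s)), nrow = n, byrow = TRUE)
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("taxon_", seq_len(s)))
    m
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
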