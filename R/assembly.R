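PROCESS_LEVELS <- c("HoS", "HeS", "DL", "HD", "DR")

# Patristic distance matrix aligned to the table's taxon order.
patristic_ <- function(table, tree) {
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips))
    stop_("taxon missing from tree: %s",
          paste(utils::head(missing_tips, 5), collapse = ", "),
          class = "invalid_argument")
  if (length(tree$tip.label) > ncol(table))
    tree <- ape::keep.tip(tree, colnames(table))
  stats::cophenetic(tree)[colnames(table), colnames(table)]
}

# Rows scaled to relative abundance (weighted) or equal weights over present
# taxa (unweighted).
community_weights_ <- function(table, weighted) {
  if (any(rowSums(table) == 0))
    stop_("all-zero sample(s): %s",
          paste(rownames(table)[rowSums(table) == 0], collapse = ", "),
          class = "degenerate_input")
  m <- if (weighted) table else (table > 0) * 1
  sweep(m, 1, rowSums(m), "/")
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For a pair of communities, the abundance-weighted mean over both
#' communities of each taxon's patristic distance to its nearest taxon in
#' the opposite community:
#' \deqn{\beta MNTD = \tfrac12\left[\sum_i f_i \min_j d(i,j) +
#'   \sum_j f_j \min_i d(j,i)\right]}
#' with f the within-sample relative abundances.  A taxon present in both
#' communities is its own nearest neighbour at distance 0.
#'
#' @param table samples x taxa count matrix.
#' @param tree rooted `phylo` covering the table's taxa.
#' @param pair optional length-2 vector of sample ids; if given, the single
#'   value for that pair is returned instead of the full matrix.
#' @param weighted use relative abundances as weights (default) or equal
#'   weights over present taxa.
#' @return `dist` of beta-MNTD values (or a single number when `pair` is
#'   given), in branch-length units.
#' @export
beta_mntd <- function(table, tree, pair = NULL, weighted = TRUE) {
  validate_feature_table(table)
  D <- patristic_(table, tree)
  comm <- community_weights_(table, weighted)
  M <- beta_mntd_kernel(comm, D)
  dimnames(M) <- list(rownames(table), rownames(table))
  if (!is.null(pair)) {
    if (length(pair) != 2L || !all(pair %in% rownames(table)))
      stop_("pair must name two samples of the table", class = "invalid_argument")
    return(M[pair[1L], pair[2L]])
  }
  stats::as.dist(M)
}

# Shared null machinery: observed beta-MNTD plus n_null taxa-shuffle
# replicates (tip labels permuted across the tree, i.e. rows/columns of the
# patristic matrix permuted; identical permutation for every pair within a
# replicate).  Returns lower-triangle vectors.
beta_mntd_null_ <- function(table, tree, n_null, seed, weighted) {
  D <- patristic_(table, tree)
  comm <- community_weights_(table, weighted)
  obs_m <- beta_mntd_kernel(comm, D)
  lt <- lower.tri(obs_m)
  nulls <- with_seed_(seed, {
    vapply(seq_len(n_null), function(r) {
      p <- sample.int(ncol(D))
      beta_mntd_kernel(comm, D[p, p])[lt]
    }, numeric(sum(lt)))
  })
  if (!is.matrix(nulls)) nulls <- matrix(nulls, nrow = sum(lt))
  idx <- which(lt, arr.ind = TRUE)
  list(sample_a = rownames(table)[idx[, 2L]],
       sample_b = rownames(table)[idx[, 1L]],
       obs = obs_m[lt],
       null_mean = rowMeans(nulls),
       null_sd = apply(nulls, 1, sd))
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardized effect size of beta-MNTD against a taxa-shuffle null: tip
#' labels are permuted across the phylogeny (equivalently, rows and columns
#' of the patristic matrix), community data untouched, and
#' \eqn{\beta NTI = (\beta MNTD_{obs} - \mu_{null}) / \sigma_{null}}.
#' The same shuffle is applied to all pairs within a replicate.  Pairs with
#' zero null standard deviation (e.g. a star phylogeny with equal tip-to-tip
#' distances) get `NA` with a warning.
#'
#' @inheritParams beta_mntd
#' @param n_null number of null shuffles.
#' @param seed integer seed; results are deterministic given it.
#' @return data.frame: sample_a, sample_b, beta_mntd, beta_nti.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = NULL, weighted = TRUE) {
  if (nrow(table) < 2L) stop_(">= 2 samples required", class = "invalid_argument")
  n_null <- check_count_(n_null, "n_null")
  nl <- beta_mntd_null_(table, tree, n_null, seed, weighted)
  bnti <- ifelse(nl$null_sd > 0, (nl$obs - nl$null_mean) / nl$null_sd, NA_real_)
  if (anyNA(bnti))
    warning(sprintf("%d pair(s) have zero null sd; beta-NTI undefined (NA)",
                    sum(is.na(bnti))))
  data.frame(sample_a = nl$sample_a, sample_b = nl$sample_b,
             beta_mntd = nl$obs, beta_nti = bnti, stringsAsFactors = FALSE)
}

# One null metacommunity under the Raup-Crick construction: per sample, draw
# as many taxa as the observed richness with probability proportional to
# occupancy, give each drawn taxon one read (so realized richness equals the
# drawn richness exactly), then allocate the remaining reads multinomially
# with probability proportional to pool relative abundance.
rc_null_table_ <- function(table, occupancy, pool) {
  out <- matrix(0L, nrow(table), ncol(table), dimnames = dimnames(table))
  for (i in seq_len(nrow(table))) {
    rich <- sum(table[i, ] > 0)
    total <- sum(table[i, ])
    taxa <- sample.int(ncol(table), rich, prob = occupancy)
    out[i, taxa] <- 1L
    if (total > rich)
      out[i, taxa] <- out[i, taxa] +
        as.integer(rmultinom(1, total - rich, prob = pool[taxa]))
  }
  out
}

#' Bray-Curtis-based Raup-Crick index (RCbray)
#'
#' Ranks each pair's observed Bray-Curtis dissimilarity within a null
#' distribution of probabilistically assembled communities.  Each null
#' community keeps the sample's observed richness (that many taxa drawn with
#' probability proportional to occupancy, each guaranteed one read) and
#' allocates the remaining reads by pool relative abundance.  Then
#' \eqn{RC = 2[(\#null < obs) + \tfrac12(\#null = obs)]/n_{null} - 1 \in [-1, 1]}.
#' RC near +1 means the pair is more dissimilar than expected by chance,
#' near -1 more similar.
#'
#' @inheritParams beta_nti
#' @param occupancy,pool metacommunity parameters of the null: per-taxon
#'   occupancy weights and pool relative abundances.  By default both are
#'   estimated from `table` (occupancy = number of samples a taxon occurs
#'   in; pool = its share of all reads); supply them explicitly when the
#'   metacommunity is known, e.g. when checking the null's own calibration.
#' @return data.frame: sample_a, sample_b, bray_curtis, rc_bray.
#' @export
rc_bray <- function(table, n_null = 999, seed = NULL,
                    occupancy = NULL, pool = NULL) {
  validate_feature_table(table)
  if (nrow(table) < 2L) stop_(">= 2 samples required", class = "invalid_argument")
  n_null <- check_count_(n_null, "n_null")
  if (is.null(occupancy)) occupancy <- colSums(table > 0)
  if (is.null(pool)) pool <- colSums(table) / sum(table)
  if (length(occupancy) != ncol(table) || length(pool) != ncol(table))
    stop_("occupancy and pool must have one entry per taxon",
          class = "invalid_argument")
  if (sum(occupancy > 0) < 2L)
    stop_("degenerate pool: fewer than two taxa occur", class = "degenerate_input")
  obs_m <- as.matrix(bray_curtis(table))
  lt <- lower.tri(obs_m)
  obs <- obs_m[lt]
  counts_less <- numeric(length(obs))
  counts_equal <- numeric(length(obs))
  with_seed_(seed, {
    for (r in seq_len(n_null)) {
      nt <- rc_null_table_(table, occupancy, pool)
      nb <- as.matrix(vegan::vegdist(nt, method = "bray"))[lt]
      counts_less <- counts_less + (nb < obs)
      counts_equal <- counts_equal + (nb == obs)
    }
  })
  idx <- which(lt, arr.ind = TRUE)
  data.frame(sample_a = rownames(table)[idx[, 2L]],
             sample_b = rownames(table)[idx[, 1L]],
             bray_curtis = obs,
             rc_bray = 2 * (counts_less + 0.5 * counts_equal) / n_null - 1,
             stringsAsFactors = FALSE)
}

#' Classify a sample pair's assembly process
#'
#' Five-way partition of the (beta-NTI, RCbray) plane: homogeneous selection
#' (HoS, beta-NTI <= -2), heterogeneous selection (HeS, beta-NTI >= +2);
#' otherwise dispersal limitation (DL, RC > 0.95), homogenizing dispersal
#' (HD, RC < -0.95) or undominated/drift (DR, |RC| <= 0.95).  Boundary
#' convention: |beta-NTI| = 2 exactly counts as selection and |RC| = 0.95
#' exactly as drift, so the five classes partition the plane.
#'
#' @param beta_nti numeric vector.
#' @param rc_bray numeric vector (recycled against `beta_nti`).
#' @return factor with levels HoS, HeS, DL, HD, DR.
#' @export
classify_process <- function(beta_nti, rc_bray) {
  n <- max(length(beta_nti), length(rc_bray))
  beta_nti <- rep_len(beta_nti, n); rc_bray <- rep_len(rc_bray, n)
  if (any(!is.finite(beta_nti)) || any(!is.finite(rc_bray)))
    stop_("beta_nti and rc_bray must be finite", class = "invalid_argument")
  out <- rep("DR", n)
  out[rc_bray > 0.95] <- "DL"
  out[rc_bray < -0.95] <- "HD"
  out[beta_nti <= -2] <- "HoS"
  out[beta_nti >= 2] <- "HeS"
  factor(out, levels = PROCESS_LEVELS)
}

#' Relative contributions of assembly processes
#'
#' @param pairs data.frame with columns `sample_a`, `sample_b`, `process`
#'   (as produced by [assembly_pairs()]).
#' @param grouping optional named vector of group labels per sample; a pair
#'   belongs to a group only if both members do (within-group pairs).
#'   NULL pools all pairs into one group `"all"`.
#' @return data.frame: group, n_pairs, frac_HoS .. frac_DR (fractions sum
#'   to 1 per group).
#' @export
process_fractions <- function(pairs, grouping = NULL) {
  if (is.null(grouping)) {
    grp <- rep("all", nrow(pairs))
  } else {
    ga <- grouping[pairs$sample_a]; gb <- grouping[pairs$sample_b]
    grp <- ifelse(!is.na(ga) & !is.na(gb) & ga == gb, ga, NA)
  }
  keep <- !is.na(grp)
  if (!all(keep)) pairs <- pairs[keep, , drop = FALSE]
  grp <- grp[keep]
  groups <- unique(grp)
  rows <- lapply(groups, function(g) {
    pr <- factor(pairs$process[grp == g], levels = PROCESS_LEVELS)
    if (!length(pr)) {
      warning(sprintf("group '%s' has no classified pairs; excluded", g))
      return(NULL)
    }
    tab <- table(pr) / length(pr)
    cbind(data.frame(group = g, n_pairs = length(pr), stringsAsFactors = FALSE),
          as.data.frame(setNames(as.list(as.numeric(tab)),
                                 paste0("frac_", PROCESS_LEVELS))))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Per-pair assembly analysis
#'
#' Runs [beta_nti()] and [rc_bray()] on the same table, classifies every
#' pair, and attaches great-circle distances when metadata is supplied.
#' Pairs with undefined beta-NTI are dropped with a warning.
#'
#' @inheritParams beta_nti
#' @param metadata optional sample metadata (for `geo_km` and grouping).
#' @return data.frame: sample_a, sample_b, geo_km (if metadata given),
#'   beta_mntd, beta_nti, rc_bray, process.
#' @export
assembly_pairs <- function(table, tree, metadata = NULL, n_null = 999,
                           seed = NULL, weighted = TRUE) {
  seeds <- spawn_seeds_(seed, 2L)
  bn <- beta_nti(table, tree, n_null = n_null, seed = seeds[[1L]], weighted = weighted)
  rc <- rc_bray(table, n_null = n_null, seed = seeds[[2L]])
  stopifnot(identical(bn$sample_a, rc$sample_a),
            identical(bn$sample_b, rc$sample_b))
  out <- data.frame(sample_a = bn$sample_a, sample_b = bn$sample_b,
                    beta_mntd = bn$beta_mntd, beta_nti = bn$beta_nti,
                    rc_bray = rc$rc_bray, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    geo <- as.matrix(geographic_distance_matrix(metadata))
    out$geo_km <- geo[cbind(out$sample_a, out$sample_b)]
    out <- out[, c("sample_a", "sample_b", "geo_km",
                   "beta_mntd", "beta_nti", "rc_bray")]
  }
  if (anyNA(out$beta_nti)) {
    warning(sprintf("dropping %d pair(s) with undefined beta-NTI",
                    sum(is.na(out$beta_nti))))
    out <- out[!is.na(out$beta_nti), , drop = FALSE]
  }
  out$process <- classify_process(out$beta_nti, out$rc_bray)
  out
}

#' Scale dependence of assembly-process fractions
#'
#' Bins sample pairs into half-open distance units
#' \eqn{[u(k-1), uk)} km (default 60 km), computes process fractions per
#' unit, and fits an ordinary least-squares line of each process's fraction
#' on the unit index.
#'
#' @param pairs data.frame from [assembly_pairs()] with a `geo_km` column.
#' @param unit_km width of a scale unit in km.
#' @param min_pairs minimum classified pairs for a unit to enter the trend.
#' @return list with `units` (unit_index, unit_lo_km, unit_hi_km, n_pairs,
#'   frac_*) and `fits` (process, slope, intercept, r_squared, p_value).
#' @export
scale_trend <- function(pairs, unit_km = 60, min_pairs = 5) {
  if (!"geo_km" %in% colnames(pairs))
    stop_("pairs must carry geo_km (run assembly_pairs with metadata)",
          class = "invalid_argument")
  unit <- floor(pairs$geo_km / unit_km) + 1L
  units <- sort(unique(unit))
  rows <- lapply(units, function(k) {
    sel <- unit == k
    if (sum(sel) < min_pairs) return(NULL)
    fr <- process_fractions(pairs[sel, , drop = FALSE])
    cbind(data.frame(unit_index = k, unit_lo_km = unit_km * (k - 1L),
                     unit_hi_km = unit_km * k),
          fr[, -(1:2), drop = FALSE], n_pairs = fr$n_pairs)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 3L)
    stop_("fewer than 3 populated scale units; trend undefined",
          class = "invalid_argument")
  units_df <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(PROCESS_LEVELS, function(p) {
    y <- units_df[[paste0("frac_", p)]]
    x <- units_df$unit_index
    fit <- lm(y ~ x)
    sm <- summary(fit)
    data.frame(process = p,
               slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = sm$r.squared,
               p_value = if (sd(y) == 0) 1 else sm$coefficients[2L, 4L],
               stringsAsFactors = FALSE)
  }))
  list(units = units_df, fits = fits)
}

#' Phylogenetic normalized stochasticity ratio (pNST)
#'
#' For every within-group pair the observed beta-MNTD is compared with its
#' expectation under the taxa-shuffle null.  The per-pair stochasticity
#' ratio is pinned here as
#' \deqn{ST_{ij} = \min(obs, E) / \max(obs, E) \in [0, 1]}
#' (1 when observed phylogenetic turnover equals the null expectation —
#' fully stochastic; 0 when observation sits at a deterministic extreme,
#' e.g. identical communities with obs = 0).  The group pNST is the mean
#' ratio over its pairs, clamped to [0, 1]; higher = more stochastic.
#'
#' @inheritParams beta_nti
#' @param groups named vector of group labels per sample; groups with < 3
#'   samples are excluded with a warning.
#' @return data.frame: group, n_pairs, pnst.
#' @export
pnst <- function(table, tree, groups, n_null = 999, seed = NULL,
                 weighted = TRUE) {
  groups <- groups[rownames(table)]
  if (anyNA(groups))
    stop_("groups must name every sample", class = "invalid_argument")
  nl <- beta_mntd_null_(table, tree, check_count_(n_null, "n_null"),
                        seed, weighted)
  ga <- groups[nl$sample_a]; gb <- groups[nl$sample_b]
  rows <- lapply(unique(groups), function(g) {
    if (sum(groups == g) < 3L) {
      warning(sprintf("group '%s' has < 3 samples; excluded", g))
      return(NULL)
    }
    sel <- ga == g & gb == g
    obs <- nl$obs[sel]; e <- nl$null_mean[sel]
    # obs = 0 (identical communities) is the deterministic extreme even when
    # the null expectation is also 0, so 0/0 maps to 0, not 1
    st <- ifelse(obs == 0, 0,
                 ifelse(pmax(obs, e) == 0, 0, pmin(obs, e) / pmax(obs, e)))
    data.frame(group = g, n_pairs = sum(sel),
               pnst = min(max(mean(st), 0), 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
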