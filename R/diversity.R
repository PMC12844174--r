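#' Alpha diversity: richness and Shannon index
#'
#' Shannon entropy is computed in natural-log units (nats), the vegan
#' convention: H = -sum p_i ln p_i over taxa with p_i > 0.
#'
#' @param table samples x taxa count (or proportion) matrix; ideally rarefied
#'   to a common depth — a warning is issued when row sums differ.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#'   All-zero samples are excluded with a warning.
#' @export
alpha_diversity <- function(table) {
  validate_feature_table(table)
  totals <- rowSums(table)
  if (any(totals == 0)) {
    warning(sprintf("excluding all-zero sample(s): %s",
                    paste(rownames(table)[totals == 0], collapse = ", ")))
    table <- table[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (length(unique(totals)) > 1L)
    warning("unequal sample depths; consider rarefy() before alpha_diversity()")
  data.frame(
    sample_id = rownames(table),
    richness = as.integer(rowSums(table > 0)),
    shannon = as.numeric(vegan::diversity(table, index = "shannon")),
    row.names = rownames(table), stringsAsFactors = FALSE)
}

# Tag a dist object with the dissimilarity kind and check basic sanity.
as_cryo_dist_ <- function(d, kind) {
  m <- as.matrix(d)
  if (any(!is.finite(m)))
    stop_("undefined %s entries (all-zero sample pair?)", kind,
          class = "degenerate_input")
  attr(d, "kind") <- kind
  d
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i).
#'
#' @param table samples x taxa matrix, >= 2 samples.
#' @return `dist` object with attribute `kind = "bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2L) stop_(">= 2 samples required", class = "invalid_argument")
  if (any(rowSums(table) == 0))
    stop_("all-zero sample(s) make Bray-Curtis undefined: %s",
          paste(rownames(table)[rowSums(table) == 0], collapse = ", "),
          class = "degenerate_input")
  as_cryo_dist_(vegan::vegdist(table, method = "bray"), "bray_curtis")
}

#' Sorensen (presence-absence Bray-Curtis) dissimilarity matrix
#'
#' 1 - 2a / (2a + b + c) with a shared and b, c unique taxon counts;
#' identical to Bray-Curtis on binarized data.
#'
#' @inheritParams bray_curtis
#' @return `dist` object with attribute `kind = "sorensen"`.
#' @export
sorensen <- function(table) {
  if (nrow(table) < 2L) stop_(">= 2 samples required", class = "invalid_argument")
  if (any(rowSums(table) == 0))
    stop_("all-zero sample(s) make Sorensen undefined: %s",
          paste(rownames(table)[rowSums(table) == 0], collapse = ", "),
          class = "degenerate_input")
  as_cryo_dist_(vegan::vegdist(table, method = "bray", binary = TRUE), "sorensen")
}

#' Hellinger transformation of a count or proportion table
#'
#' Square root of within-sample relative abundances.  PCoA on Euclidean
#' distances of the transformed table is the recommended way to run a
#' PCA-style ordination of taxon proportions without letting abundant taxa
#' dominate through scale alone.
#'
#' @param table samples x taxa matrix of counts or proportions.
#' @return matrix of the same shape.
#' @export
hellinger <- function(table) {
  totals <- rowSums(table)
  if (any(totals == 0))
    stop_("all-zero sample(s): %s",
          paste(rownames(table)[totals == 0], collapse = ", "),
          class = "degenerate_input")
  sqrt(sweep(table, 1, totals, "/"))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers the squared-distance (Gower) matrix and eigendecomposes it.
#' Axes are ordered by eigenvalue; the proportion explained divides by the
#' sum of positive eigenvalues only.  Negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported but never
#' used for coordinates; no Lingoes/Cailliez correction is applied.
#'
#' @param dm `dist` object or symmetric matrix.
#' @param k number of axes requested.
#' @return list with `coordinates` (n x k' matrix, k' <= k), `eigenvalues`
#'   (all n - 1), and `proportion_explained` per returned axis.
#' @export
pcoa <- function(dm, k = 2) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  k <- check_count_(k, "k")
  fit <- cmdscale(d, k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > max(eig) * 1e-12)
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes", n_pos, n_pos))
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[seq_len(k)] / sum(eig[eig > 0]))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' The omnibus H statistic uses the standard tie correction.  Pairwise Dunn
#' z statistics are computed from mean ranks of the pooled ranking, with
#' Holm-adjusted two-sided p-values, and summarized as a compact letter
#' display: groups sharing a letter are not significantly different.
#'
#' @param values numeric vector of per-sample values.
#' @param groups factor/character vector of group labels, >= 2 groups with
#'   >= 2 observations each.
#' @param alpha significance level for the letter display.
#' @return list with `H`, `df`, `p_value`, `dunn` (data.frame: group_a,
#'   group_b, z, p_adjusted), and `letters` (named character vector).
#' @export
kruskal_wallis_dunn <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L)
    stop_(">= 2 groups required", class = "invalid_argument")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop_("group(s) with < 2 observations: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "),
          class = "invalid_argument")
  if (sd(values) == 0) {
    # fully tied data carry no rank information: H = 0, p = 1 by convention
    kw <- list(statistic = c(H = 0), parameter = c(df = nlevels(groups) - 1),
               p.value = 1)
  } else {
    kw <- kruskal.test(values, groups)
  }

  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- apply(combs, 2, function(pair) {
    na <- sizes[[pair[1]]]; nb <- sizes[[pair[2]]]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / na + 1 / nb))
    if (se == 0) return(0)
    (mean_ranks[[pair[1]]] - mean_ranks[[pair[2]]]) / se
  })
  p_adj <- p.adjust(2 * pnorm(-abs(z)), method = "holm")
  dunn <- data.frame(group_a = combs[1, ], group_b = combs[2, ],
                     z = as.numeric(z), p_adjusted = pmin(p_adj, 1),
                     stringsAsFactors = FALSE)

  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, dunn = dunn,
       letters = letter_display_(lev, dunn, alpha))
}

# Compact letter display by the insert-and-absorb algorithm: start with one
# letter covering all groups; for every significant pair split the letters
# that contain both, then drop letters whose group set is a subset of another.
letter_display_ <- function(levels, dunn, alpha) {
  absorb <- function(sets) {
    keep <- rep(TRUE, length(sets))
    for (j in seq_along(sets)) {
      for (l in seq_along(sets)) {
        if (j == l || !keep[l]) next
        if (all(sets[[j]] %in% sets[[l]]) &&
            (length(sets[[j]]) < length(sets[[l]]) || j > l)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    sets[keep]
  }
  sets <- list(levels)
  sig <- dunn[dunn$p_adjusted < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    sets <- absorb(new_sets)
  }
  out <- setNames(rep("", length(levels)), levels)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Write a labelled square distance matrix as TSV
#'
#' @param dm `dist` or symmetric matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  out <- cbind(data.frame(sample_id = rownames(m)), as.data.frame(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
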