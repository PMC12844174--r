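toy_tree <- function(txt) ape::read.tree(text = txt)

test_that("beta-MNTD matches hand-worked toy phylogenies", {
  # identical communities: nearest neighbour is self at distance 0
  tr <- toy_tree("((A:1,B:1):1,C:2);")
  tab <- rbind(s1 = c(3L, 1L, 2L), s2 = c(3L, 1L, 2L))
  colnames(tab) <- c("A", "B", "C")
  expect_equal(beta_mntd(tab, tr, pair = c("s1", "s2")), 0)

  # disjoint single taxa at patristic distance 3
  tr2 <- toy_tree("(A:1.5,B:1.5);")
  tab2 <- rbind(s1 = c(5L, 0L), s2 = c(0L, 7L)); colnames(tab2) <- c("A", "B")
  expect_equal(beta_mntd(tab2, tr2, pair = c("s1", "s2")), 3)

  # A,B sisters at distance 1; C at 4 from both; {A} vs {B:1, C:1}
  tr3 <- toy_tree("((A:0.5,B:0.5):1.5,C:2);")
  tab3 <- rbind(s1 = c(1L, 0L, 0L), s2 = c(0L, 1L, 1L))
  colnames(tab3) <- c("A", "B", "C")
  expect_equal(beta_mntd(tab3, tr3, pair = c("s1", "s2")), 1.75)

  expect_error(beta_mntd(rbind(s1 = c(A = 1L, X = 1L), s2 = c(A = 1L, X = 0L)),
                         tr2), "X", class = "invalid_argument")
})

test_that("beta-MNTD equals the exhaustive nearest-taxon brute force", {
  tree <- simulate_tree(10, seed = 31)
  d <- stats::cophenetic(tree)
  tab <- random_table(6, 10, depth = 60, seed = 32)
  colnames(tab) <- tree$tip.label
  d <- d[colnames(tab), colnames(tab)]
  m <- as.matrix(beta_mntd(tab, tree))
  for (i in 2:6) for (j in 1:(i - 1))
    expect_equal(m[i, j], bf_beta_mntd(tab[i, ], tab[j, ], d),
                 tolerance = 1e-12)
})

test_that("beta-MNTD agrees with picante's comdistnt", {
  tree <- simulate_tree(24, seed = 33)
  tab <- random_table(5, 24, depth = 120, seed = 34)
  colnames(tab) <- tree$tip.label
  ours <- as.matrix(beta_mntd(tab, tree))
  ref <- as.matrix(picante::comdistnt(tab, stats::cophenetic(tree),
                                      abundance.weighted = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-10)
})

test_that("beta-NTI is deterministic under a seed and flags degenerate nulls", {
  ds <- simulate_metacommunity(scenario_config(n_sites = 8, n_taxa = 40,
                                               depth = 300, seed = 12))
  b1 <- suppressWarnings(beta_nti(ds$table, ds$tree, n_null = 49, seed = 77))
  b2 <- suppressWarnings(beta_nti(ds$table, ds$tree, n_null = 49, seed = 77))
  expect_identical(b1, b2)

  # star tree: every taxa shuffle yields the same beta-MNTD -> sd 0 -> NA
  star <- toy_tree("(A:1,B:1,C:1,D:1);")
  tabs <- rbind(s1 = c(1L, 1L, 0L, 0L), s2 = c(0L, 0L, 1L, 1L))
  colnames(tabs) <- c("A", "B", "C", "D")
  expect_warning(bs <- beta_nti(tabs, star, n_null = 19, seed = 1), "zero null sd")
  expect_true(is.na(bs$beta_nti))
})

test_that("RCbray sits at the correct extremes and within [-1, 1]", {
  # identical samples are more similar than any probabilistic null pair
  tab <- matrix(rep(c(9L, 7L, 5L, 3L, 1L, 8L, 6L, 4L, 2L, 5L), 2), nrow = 2,
                byrow = TRUE, dimnames = list(c("s1", "s2"), paste0("t", 1:10)))
  tab <- rbind(tab, s3 = c(9L, 7L, 5L, 3L, 1L, 8L, 6L, 4L, 2L, 5L))
  rc <- rc_bray(tab, n_null = 99, seed = 5)
  expect_true(all(rc$rc_bray <= -0.95))

  # disjoint supports are more dissimilar than any null pair
  tabd <- rbind(s1 = c(5L, 5L, 5L, 5L, 0L, 0L, 0L, 0L),
                s2 = c(0L, 0L, 0L, 0L, 5L, 5L, 5L, 5L))
  colnames(tabd) <- paste0("t", 1:8)
  rcd <- rc_bray(tabd, n_null = 99, seed = 6)
  expect_gte(rcd$rc_bray, 0.95)

  rnd <- random_table(6, 30, depth = 150, seed = 41)
  rcr <- rc_bray(rnd, n_null = 49, seed = 7)
  expect_true(all(rcr$rc_bray >= -1 & rcr$rc_bray <= 1))
  expect_identical(rcr, rc_bray(rnd, n_null = 49, seed = 7))

  one <- rbind(s1 = c(4L, 0L), s2 = c(3L, 0L)); colnames(one) <- c("a", "b")
  expect_error(rc_bray(one, n_null = 9, seed = 1), class = "degenerate_input")
})

test_that("process classification matches the published rule table", {
  expect_equal(as.character(classify_process(-2.5, 0.1)), "HoS")
  expect_equal(as.character(classify_process(2.5, 0.1)), "HeS")
  expect_equal(as.character(classify_process(0.5, 0.97)), "DL")
  expect_equal(as.character(classify_process(0.5, -0.97)), "HD")
  expect_equal(as.character(classify_process(0.5, 0.2)), "DR")
  # boundary conventions: |bNTI| = 2 -> selection; |RC| = 0.95 -> drift
  expect_equal(as.character(classify_process(c(-2, 2), c(0.99, -0.99))),
               c("HoS", "HeS"))
  expect_equal(as.character(classify_process(c(0, 0), c(0.95, -0.95))),
               c("DR", "DR"))
  expect_error(classify_process(NaN, 0), class = "invalid_argument")
  expect_error(classify_process(0, NA), class = "invalid_argument")
})

test_that("classification is a total partition agreeing with the rule oracle", {
  pts <- withr::with_seed(50, data.frame(b = runif(10000, -5, 5),
                                         r = runif(10000, -1, 1)))
  got <- classify_process(pts$b, pts$r)
  expect_false(anyNA(got))
  want <- mapply(bf_classify, pts$b, pts$r)
  expect_identical(as.character(got), unname(want))
})

test_that("process fractions count correctly and respect grouping", {
  pairs <- data.frame(sample_a = c("a", "a", "b", "c"),
                      sample_b = c("b", "c", "c", "d"),
                      process = factor(c("DL", "DL", "HeS", "HeS"),
                                       levels = cryoassembly:::PROCESS_LEVELS))
  fr <- process_fractions(pairs)
  expect_equal(fr$frac_DL, 0.5)
  expect_equal(fr$frac_HeS, 0.5)
  expect_equal(fr$n_pairs, 4L)
  expect_equal(fr$frac_HoS + fr$frac_HeS + fr$frac_DL + fr$frac_HD + fr$frac_DR, 1)

  grouping <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  fg <- process_fractions(pairs, grouping)
  expect_equal(fg$group, c("g1", "g2"))
  expect_equal(fg$n_pairs, c(1L, 1L))         # only within-group pairs
  expect_equal(fg$frac_DL, c(1, 0))
})

test_that("scale units use half-open 60-km bins and flat fractions give zero slope", {
  pairs <- data.frame(
    sample_a = "x", sample_b = "y",
    geo_km = c(10, 59.9, 60, 150, rep(c(30, 90, 210), times = c(4, 4, 5))),
    process = factor("DL", levels = cryoassembly:::PROCESS_LEVELS))
  expect_equal(floor(pairs$geo_km[1:4] / 60) + 1, c(1, 1, 2, 3))

  tr <- suppressWarnings(scale_trend(pairs, unit_km = 60, min_pairs = 5))
  expect_equal(tr$units$unit_index, c(1L, 2L, 4L))   # bins with >= 5 pairs
  expect_equal(tr$units$unit_lo_km, c(0, 60, 180))
  dl <- tr$fits[tr$fits$process == "DL", ]
  expect_equal(dl$slope, 0, tolerance = 1e-12)
  expect_equal(dl$r_squared, 0, tolerance = 1e-12)
  expect_equal(dl$p_value, 1)

  expect_error(scale_trend(pairs[1:6, ], min_pairs = 5),
               class = "invalid_argument")
})

test_that("assembly_pairs joins the two null models and attaches distances", {
  ds <- simulate_metacommunity(scenario_config(n_sites = 8, n_taxa = 50,
                                               depth = 300, n_continents = 2,
                                               seed = 19))
  pr <- assembly_pairs(ds$table, ds$tree, ds$metadata, n_null = 49, seed = 3)
  expect_equal(nrow(pr), choose(8, 2))
  expect_true(all(c("geo_km", "beta_mntd", "beta_nti", "rc_bray", "process")
                  %in% colnames(pr)))
  expect_identical(pr, assembly_pairs(ds$table, ds$tree, ds$metadata,
                                      n_null = 49, seed = 3))
  geo <- as.matrix(geographic_distance_matrix(ds$metadata))
  expect_equal(pr$geo_km, geo[cbind(pr$sample_a, pr$sample_b)])
})

test_that("pNST hits the deterministic extreme for identical communities", {
  tr <- simulate_tree(12, seed = 61)
  row <- c(5L, 3L, 2L, 4L, 1L, 2L, 3L, 1L, 2L, 4L, 3L, 2L)
  tab <- rbind(s1 = row, s2 = row, s3 = row)
  colnames(tab) <- tr$tip.label
  res <- pnst(tab, tr, groups = c(s1 = "g", s2 = "g", s3 = "g"),
              n_null = 19, seed = 1)
  expect_equal(res$pnst, 0)
  expect_equal(res$n_pairs, 3L)

  # small groups excluded with warning
  ds <- simulate_metacommunity(scenario_config(n_sites = 8, n_taxa = 40,
                                               depth = 200, seed = 62))
  g <- setNames(c(rep("big", 6), rep("small", 2)), ds$metadata$sample_id)
  expect_warning(r2 <- pnst(ds$table, ds$tree, g, n_null = 19, seed = 2),
                 "small")
  expect_equal(r2$group, "big")
  expect_true(r2$pnst >= 0 && r2$pnst <= 1)
})
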