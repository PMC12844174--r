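# Well-separated continental cluster centres (lat, lon), loosely mimicking the
# five landmass groups cryoconite studies sample (Antarctica, Asia, Europe,
# North America, South America) plus two spares.  All pairwise great-circle
# separations exceed 5000 km by construction — a generator contract, not real
# geography — so within-continent spreads of a few hundred km can never
# overlap between continents.
CONTINENT_CENTERS <- data.frame(
  continent = c("Antarctica", "Asia", "Europe", "NorthAmerica", "SouthAmerica",
                "Oceania", "Africa"),
  lat = c(-72, 36, 47, 48, -32, -40, 2),
  lon = c(20, 92, 11, -120, -70, 150, -18)
)

#' Configuration for a synthetic cryoconite metacommunity
#'
#' Bundles and validates every knob of the generator.  The defaults describe
#' the reference study conditions used throughout the package's tests: a
#' five-continent metacommunity of 40 rarefied samples over 300 ASVs at a
#' depth of 2000 reads.
#'
#' @param n_sites number of sampling sites (= samples), >= 4.
#' @param n_taxa regional pool size, >= 8.
#' @param depth reads per site (exact, multinomial), >= 100.
#' @param regime assembly regime: `"selection"` (environmental filtering along
#'   a latitude-linked gradient), `"dispersal_limitation"` (exponential
#'   distance kernel from per-taxon source sites), `"drift"` (pure multinomial
#'   sampling of a shared pool), or `"mixed"` (filtering and dispersal).
#' @param selection_strength Gaussian niche-filter strength, per squared unit
#'   of the niche-rank axis (see Details of [simulate_metacommunity()]); the
#'   default 200 gives a filter sd of `1/sqrt(2*200)` = 0.05 rank units;
#'   0 disables filtering.
#' @param dispersal_decay_km e-folding distance of the dispersal kernel.
#' @param n_continents number of continental clusters (1..7).
#' @param continent_spread_km half-width of the uniform within-continent
#'   site scatter, in km.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration including this seed.
#' @param hdi_effect strength of the anthropogenic-deposition mixing: a site
#'   with Human Development Index h receives a fraction
#'   `min(hdi_effect * h, 0.6)` of its expected community from a shared
#'   deposition pool (selection and mixed regimes only).
#' @param hump_peak_lat absolute latitude (degrees) at which the regional
#'   richness of the site-available pool peaks.
#' @param hump_width_deg latitudinal e-folding width of the richness hump.
#' @param covariate_continent_sd sd of the continent-level component of the
#'   climatic covariates (u, msr, mmt, tmp, vp); 0 makes them pure site noise.
#' @param covariate_site_sd sd of their site-level noise.
#' @param sites_per_glacier sites grouped under one glacier id.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 40, n_taxa = 300, depth = 2000,
                            regime = c("selection", "dispersal_limitation",
                                       "drift", "mixed"),
                            selection_strength = 200,
                            dispersal_decay_km = 500,
                            n_continents = 5,
                            continent_spread_km = 300,
                            seed = 1,
                            hdi_effect = 0.3,
                            hump_peak_lat = 45,
                            hump_width_deg = 20,
                            covariate_continent_sd = 0.5,
                            covariate_site_sd = 1,
                            sites_per_glacier = 1) {
  regime <- match.arg(regime)
  cfg <- list(
    n_sites = check_count_(n_sites, "n_sites", 4L),
    n_taxa = check_count_(n_taxa, "n_taxa", 8L),
    depth = check_count_(depth, "depth", 100L),
    regime = regime,
    selection_strength = selection_strength,
    dispersal_decay_km = dispersal_decay_km,
    n_continents = check_count_(n_continents, "n_continents", 1L),
    continent_spread_km = continent_spread_km,
    seed = check_count_(seed, "seed", min = -.Machine$integer.max),
    hdi_effect = hdi_effect,
    hump_peak_lat = hump_peak_lat,
    hump_width_deg = hump_width_deg,
    covariate_continent_sd = covariate_continent_sd,
    covariate_site_sd = covariate_site_sd,
    sites_per_glacier = check_count_(sites_per_glacier, "sites_per_glacier", 1L)
  )
  if (cfg$selection_strength < 0)
    stop_("selection_strength must be >= 0", class = "invalid_argument")
  if (cfg$dispersal_decay_km <= 0 || cfg$continent_spread_km <= 0)
    stop_("dispersal_decay_km and continent_spread_km must be > 0",
          class = "invalid_argument")
  if (cfg$n_continents > nrow(CONTINENT_CENTERS))
    stop_("at most %d continents supported", nrow(CONTINENT_CENTERS),
          class = "invalid_argument")
  structure(cfg, class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' @param path YAML file whose keys are `scenario_config()` arguments.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop_("unknown scenario key(s): %s", paste(extra, collapse = ", "),
          class = "format_error")
  do.call(scenario_config, vals)
}

#' Simulate a rooted phylogeny with niche optima
#'
#' A pure-birth (Yule) tree with unit speciation rate is grown to `n_taxa`
#' tips; each tip then receives a niche optimum evolved by Brownian motion
#' (variance 1 per unit branch length) along the tree, so phylogenetically
#' close taxa carry similar niches.  That phylogenetic niche conservatism is
#' what gives the beta-nearest-taxon index its power to detect selection.
#'
#' @param n_taxa number of tips, >= 2.
#' @param seed integer seed.
#' @return `phylo` object with an extra element `niche`: named numeric vector
#'   of tip niche optima (standardized to zero mean, unit sd).
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  n_taxa <- check_count_(n_taxa, "n_taxa", 2L)
  with_seed_(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$tip.label <- sprintf("taxon_%04d", seq_len(n_taxa))
    niche <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    niche <- (niche - mean(niche)) / max(sd(niche), .Machine$double.eps)
    tree$niche <- setNames(as.numeric(niche), tree$tip.label)
    tree
  })
}

# Even split of n_sites over n_continents: first (n %% k) continents get one
# extra site.
split_sites_ <- function(n_sites, n_continents) {
  base <- n_sites %/% n_continents
  extra <- n_sites %% n_continents
  rep(seq_len(n_continents), times = base + (seq_len(n_continents) <= extra))
}

#' Simulate a metacommunity under a known assembly regime
#'
#' Sites are placed as `n_continents` well-separated clusters; each taxon's
#' expected abundance at a site combines the regional pool with, depending on
#' the regime, a Gaussian environmental filter on its niche optimum and/or an
#' exponential dispersal kernel from its source site.  Counts are drawn
#' multinomially so every sample's total equals `depth` exactly.
#'
#' Under the `selection` and `mixed` regimes the environmental optimum of a
#' site is a deterministic linear function of its latitude, the number of
#' pool taxa available to a site is hump-shaped in absolute latitude (peaking
#' at `hump_peak_lat`), and a shared "deposition" pool is mixed in with
#' weight proportional to the site's HDI — so latitude and HDI are genuinely
#' recoverable drivers while the climatic covariates can be kept as noise.
#'
#' @param config a `scenario_config`.
#' @return list of class `cryo_dataset` with elements `table` (samples x taxa
#'   integer matrix), `tree` (`phylo` with `$niche`), `metadata` (data.frame),
#'   and `truth` (generating regime and latent site variables).
#' @export
simulate_metacommunity <- function(config) {
  if (!inherits(config, "scenario_config"))
    stop_("config must come from scenario_config()", class = "invalid_argument")
  with_seed_(config$seed, {
    n <- config$n_sites
    S <- config$n_taxa

    ## --- phylogeny and pool -------------------------------------------------
    tree <- simulate_tree(S, seed = NULL)
    niche <- tree$niche
    # iid lognormal pool abundances: phylogenetic signal enters through the
    # niche optima only, so drift communities are phylogenetically random
    pool <- stats::rlnorm(S, meanlog = 0, sdlog = 1)
    pool <- pool / sum(pool)

    ## --- geography ----------------------------------------------------------
    cont_idx <- split_sites_(n, config$n_continents)
    centers <- CONTINENT_CENTERS[seq_len(config$n_continents), ]
    lat0 <- centers$lat[cont_idx]
    lon0 <- centers$lon[cont_idx]
    km_per_deg <- 6371.0088 * pi / 180
    dlat <- runif(n, -1, 1) * config$continent_spread_km / km_per_deg
    dlon <- runif(n, -1, 1) * config$continent_spread_km /
      (km_per_deg * pmax(cos(lat0 * pi / 180), 0.2))
    lat <- pmin(pmax(lat0 + dlat, -89.5), 89.5)
    lon <- ((lon0 + dlon + 180) %% 360) - 180
    lon[lon <= -180] <- lon[lon <= -180] + 360

    sample_id <- sprintf("site_%03d", seq_len(n))
    glacier_id <- sprintf("%s_gl%02d", centers$continent[cont_idx],
                          stats::ave(seq_len(n), cont_idx,
                                     FUN = function(i) (seq_along(i) - 1L) %/%
                                       config$sites_per_glacier + 1L))

    ## --- covariates ---------------------------------------------------------
    hdi_base <- c(0, runif(max(config$n_continents - 1L, 0L), 0.35, 0.95))
    hdi <- pmin(pmax(hdi_base[cont_idx] + rnorm(n, 0, 0.04), 0), 1)
    clim <- sapply(c("u", "msr", "mmt", "tmp", "vp"), function(v) {
      base <- rnorm(config$n_continents, 0, config$covariate_continent_sd)
      base[cont_idx] + rnorm(n, 0, config$covariate_site_sd)
    })

    ## --- site environment and expected communities ---------------------------
    # Selection acts along the niche-RANK axis: taxa are ordered by their
    # Brownian niche optimum (a monotone transform, so phylogenetic niche
    # conservatism is preserved) and a site's optimum is its latitude mapped
    # linearly onto that axis.  Rank space has uniform taxon density, so the
    # filter alone does not impose a latitudinal richness gradient — richness
    # is governed by the hump-shaped available-pool size below.
    env <- (lat + 90) / 180               # deterministic latitude-linked optimum
    weights <- matrix(rep(pool, each = n), nrow = n)   # n x S

    if (config$regime %in% c("selection", "mixed")) {
      # hump-shaped available-pool size in |lat|
      frac <- 0.3 + 0.7 * exp(-((abs(lat) - config$hump_peak_lat) /
                                  config$hump_width_deg)^2)
      k_pool <- pmax(8L, round(frac * S))
      avail <- matrix(FALSE, n, S)
      for (i in seq_len(n)) avail[i, sample.int(S, k_pool[i])] <- TRUE
      nrank <- rank(niche, ties.method = "first") / S
      filt <- exp(-config$selection_strength *
                    outer(env, nrank, function(e, q) (q - e)^2))
      weights <- weights * filt * avail
    } else {
      k_pool <- rep(S, n)
    }

    if (config$regime %in% c("dispersal_limitation", "mixed")) {
      origin <- sample.int(n, S, replace = TRUE)   # one source site per taxon
      geo <- geographic_distance_matrix(
        data.frame(sample_id = sample_id, lat = lat, lon = lon))
      geo <- as.matrix(geo)
      kern <- exp(-geo[, origin, drop = FALSE] / config$dispersal_decay_km)
      weights <- weights * (1e-4 + kern)
    } else {
      origin <- rep(NA_integer_, S)
    }

    if (config$regime %in% c("selection", "mixed") && config$hdi_effect > 0) {
      # sparse anthropogenic deposition pool: ~10% of taxa, lognormal weights
      depo <- numeric(S)
      supp <- sample.int(S, max(10L, round(0.1 * S)))
      depo[supp] <- stats::rlnorm(length(supp), 0, 1)
      depo <- depo / sum(depo)
      m <- pmin(config$hdi_effect * hdi, 0.6)
      rs <- rowSums(weights)
      rs[rs == 0] <- 1
      weights <- (1 - m) * weights / rs + m * matrix(rep(depo, each = n), nrow = n)
    } else {
      depo <- NULL
    }

    ## --- sampling -----------------------------------------------------------
    counts <- matrix(0L, n, S, dimnames = list(sample_id, tree$tip.label))
    for (i in seq_len(n)) {
      w <- weights[i, ]
      if (sum(w) <= 0)
        stop_("site %s received zero total weight", sample_id[i],
              class = "degenerate_scenario")
      counts[i, ] <- as.integer(rmultinom(1, config$depth, prob = w))
    }

    metadata <- data.frame(
      sample_id = sample_id, glacier_id = glacier_id,
      continent = centers$continent[cont_idx],
      lat = lat, lon = lon, hdi = hdi,
      u = clim[, "u"], msr = clim[, "msr"], mmt = clim[, "mmt"],
      tmp = clim[, "tmp"], vp = clim[, "vp"],
      stringsAsFactors = FALSE)
    rownames(metadata) <- sample_id

    structure(list(
      table = counts, tree = tree, metadata = metadata,
      truth = list(regime = config$regime, config = config, env = env,
                   niche = niche, pool = pool, origin = origin,
                   k_pool = k_pool, deposition = depo)
    ), class = "cryo_dataset")
  })
}

#' Write a synthetic dataset's three files to a directory
#'
#' Feature table as TSV (taxa rows), tree as newick, metadata as CSV.
#'
#' @param dataset a `cryo_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "feature_table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.csv"))
  write_feature_table(dataset$table, paths[["table"]])
  ape::write.tree(dataset$tree, paths[["tree"]])
  write_sample_metadata(dataset$metadata, paths[["metadata"]])
  paths
}
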