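# Synthetic landscape generator. Emulates the statistical structure of the
# study design: 24 landscapes of 500 m radius dominated by arable land
# (mean ~0.70), gradients in preceding and synchronous floral resources, a
# negative correlation between arable proportion and preceding resources
# driven by a shared "agricultural intensification" axis, and a
# landscape-level seed-set response that is linear in the two-SD-standardized
# preceding index and urban proportion with Gaussian noise. Pod counts are
# integer draws from a binomial with 8 ovule slots whose success probability
# is tuned so that the mean over pods with >= 1 seed equals the landscape
# mean (the response is defined over such pods).

#' Configuration for the synthetic landscape generator
#'
#' Defaults follow the study design being emulated: 24 landscapes, intercept
#' 2.5 seeds/pod, standardized preceding-resource effect 0.17 and urban
#' effect 0.18 (single-predictor scale), between-landscape residual sd 0.2
#' seeds/pod, target correlation -0.6 between arable proportion and the
#' preceding index, and 55 pods per landscape.
#'
#' @param n_landscapes Number of landscapes (>= 2).
#' @param n_pre,n_syn Pollen types flowering in the preceding / synchronous
#'   period.
#' @param beta0 Intercept: mean seeds per pod.
#' @param beta_fai_pre Effect of the standardized preceding index.
#' @param beta_urban Effect of the standardized urban proportion.
#' @param sigma Residual sd of the landscape mean seeds/pod (> 0).
#' @param rho_arable_fai Target correlation between arable proportion and
#'   the preceding index (|rho| < 1).
#' @param pods_per_landscape Pods harvested per landscape.
#' @param seed Random seed; all randomness flows from it.
#' @return List of class `fai_syn_config`.
#' @export
synthetic_config <- function(n_landscapes = 24L, n_pre = 8L, n_syn = 6L,
                             beta0 = 2.5, beta_fai_pre = 0.17,
                             beta_urban = 0.18, sigma = 0.2,
                             rho_arable_fai = -0.6,
                             pods_per_landscape = 55L, seed = 1L) {
  stopifnot(n_landscapes >= 2L, n_pre >= 2L, n_syn >= 2L, sigma > 0,
            abs(rho_arable_fai) < 1, pods_per_landscape >= 2L)
  structure(list(n_landscapes = as.integer(n_landscapes),
                 n_pre = as.integer(n_pre), n_syn = as.integer(n_syn),
                 beta0 = beta0, beta_fai_pre = beta_fai_pre,
                 beta_urban = beta_urban, sigma = sigma,
                 rho_arable_fai = rho_arable_fai,
                 pods_per_landscape = as.integer(pods_per_landscape),
                 seed = as.integer(seed)),
            class = "fai_syn_config")
}

# mean of a zero-truncated Binomial(8, p)
truncated_binom_mean <- function(p) 8 * p / (1 - (1 - p)^8)

# invert the truncated mean; mu must lie in (1, 8)
solve_trunc_p <- function(mu) {
  vapply(mu, function(m) {
    stats::uniroot(function(p) truncated_binom_mean(p) - m,
                   lower = 1e-9, upper = 1 - 1e-9, tol = 1e-10)$root
  }, numeric(1L))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate a synthetic input bundle
#'
#' Draws diet volumes, plant annotations, species covers, land-cover
#' composition, distances and pod-level seed counts with the dependence
#' structure described in [synthetic_config()]. The seed-set response is
#' built from the index actually computed from the generated tables, so the
#' full pipeline recovers the configured effects without bias. Deterministic
#' under a fixed seed.
#'
#' @param config `fai_syn_config` (default: [synthetic_config()]).
#' @return A validated `fai_bundle`. Attributes: `"seed"`, and `"truth"`
#'   (list with the generated index, landscape means, achieved
#'   arable-preceding correlation, and the config).
#' @export
generate <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "fai_syn_config"))
  set.seed(config$seed)
  n <- config$n_landscapes
  ids <- sprintf("L%02d", seq_len(n))

  # shared intensification axis: high g = more arable, fewer floral resources
  g <- stats::rnorm(n)

  arable <- stats::plogis(stats::qlogis(0.70) + 1.1 * g)
  rest_alpha <- c(permanent_crop = 1.5, forest = 2, woody_snh = 1.2,
                  herbaceous_snh = 4, urban = 2.5, other = 0.8)
  rest <- t(vapply(seq_len(n), function(i) rdirichlet1(rest_alpha),
                   numeric(length(rest_alpha))))
  colnames(rest) <- names(rest_alpha)
  props <- cbind(arable = arable, rest * (1 - arable))
  landcover <- data.frame(
    landscape_id = rep(ids, each = ncol(props)),
    class = rep(colnames(props), times = n),
    proportion = as.numeric(t(props)), stringsAsFactors = FALSE)

  distances <- data.frame(
    landscape_id = ids,
    dist_forest_m = round(stats::runif(n, 20, 450) * exp(-6 * props[, "forest"]), 1),
    dist_urban_m = round(stats::runif(n, 10, 300) * exp(-6 * props[, "urban"]), 1),
    stringsAsFactors = FALSE)

  # diet: volumes per period, decreasing so the leading types dominate
  pre_types <- sprintf("pre_%02d", seq_len(config$n_pre))
  syn_types <- sprintf("syn_%02d", seq_len(config$n_syn))
  vol_pre <- sort(stats::rgamma(config$n_pre, shape = 1.2), decreasing = TRUE)
  vol_syn <- sort(stats::rgamma(config$n_syn, shape = 1.2), decreasing = TRUE)
  diet <- rbind(
    data.frame(pollen_type = pre_types, period = "preceding",
               volume = round(100 * vol_pre / sum(vol_pre), 4)),
    data.frame(pollen_type = syn_types, period = "synchronous",
               volume = round(100 * vol_syn / sum(vol_syn), 4)))

  # annotations: early resources mostly woody and wild (fruit trees, maple,
  # willow analogues); late resources more mixed; a couple of cultivated
  # types (mass-flowering crop / orchard analogues)
  ann_one <- function(types, woody_k, cultivated_idx) {
    data.frame(pollen_type = types,
               growth_form = ifelse(seq_along(types) <= woody_k,
                                    "woody", "herbaceous"),
               origin = ifelse(seq_along(types) %in% cultivated_idx,
                               "cultivated", "wild"),
               stringsAsFactors = FALSE)
  }
  type_ann <- rbind(
    ann_one(pre_types, woody_k = config$n_pre - 2L,
            cultivated_idx = c(3L, config$n_pre)),
    ann_one(syn_types, woody_k = max(2L, round(config$n_syn / 2)),
            cultivated_idx = config$n_syn))
  # one species per type, two for the leading type of each period (to
  # exercise species -> type aggregation)
  dup <- type_ann$pollen_type %in% c(pre_types[1L], syn_types[1L])
  plants <- rbind(type_ann, type_ann[dup, ])
  plants$species <- make.unique(paste0("sp_", plants$pollen_type), sep = "_v")
  plants <- plants[, c("species", "pollen_type", "growth_form", "origin")]

  # species covers: log-linear in a landscape floral axis that mixes the
  # intensification gradient (weight |rho|) with an independent floral
  # latent (weight sqrt(1 - rho^2)), so the arable-index correlation is set
  # by the mixing ratio rather than averaging out across pollen types.
  # Synchronous types load more weakly than preceding ones.
  rho <- config$rho_arable_fai
  h_pre <- stats::rnorm(n)
  h_syn <- stats::rnorm(n)
  # the 1.15 factor compensates the attenuation from the exp/logit links
  lam <- min(0.98, 1.15 * abs(rho))
  floral_pre <- sign(rho) * lam * g + sqrt(1 - lam^2) * h_pre
  lam_s <- 0.8 * lam
  floral_syn <- sign(rho) * lam_s * g + sqrt(1 - lam_s^2) * h_syn
  base <- stats::runif(nrow(plants), log(50), log(2000))
  is_pre <- grepl("^pre", plants$pollen_type)
  cover <- do.call(rbind, lapply(seq_len(nrow(plants)), function(s) {
    axis <- if (is_pre[s]) floral_pre else floral_syn
    data.frame(landscape_id = ids, species = plants$species[s],
               cover_m2 = round(exp(base[s] + 0.85 * axis +
                                      stats::rnorm(n, 0, 0.45)), 2),
               stringsAsFactors = FALSE)
  }))

  pre_bundle <- structure(list(diet = diet, plants = plants, cover = cover,
                               landscape_ids = ids), class = "fai_bundle")
  fai_pre <- fai_table(pre_bundle, periods = "preceding")$fai

  mu <- config$beta0 +
    config$beta_fai_pre * standardize_2sd(fai_pre, "fai_pre") +
    config$beta_urban * standardize_2sd(props[, "urban"], "urban") +
    stats::rnorm(n, 0, config$sigma)
  mu <- pmin(pmax(mu, 1.05), 7.9)
  p_l <- solve_trunc_p(mu)
  seedset <- data.frame(
    landscape_id = rep(ids, each = config$pods_per_landscape),
    pod_id = rep(sprintf("pod_%03d", seq_len(config$pods_per_landscape)),
                 times = n),
    seeds = stats::rbinom(n * config$pods_per_landscape, size = 8L,
                          prob = rep(p_l, each = config$pods_per_landscape)),
    stringsAsFactors = FALSE)

  bundle <- as_bundle(diet, plants, cover, landcover, distances, seedset)
  rho_hat <- stats::cor(arable, fai_pre)
  if (abs(rho_hat - config$rho_arable_fai) > 0.3) {
    warning("achieved correlation(arable, preceding fai) = ",
            round(rho_hat, 2), " vs target ", config$rho_arable_fai,
            call. = FALSE)
  }
  attr(bundle, "seed") <- config$seed
  attr(bundle, "truth") <- list(fai_pre = stats::setNames(fai_pre, ids),
                                mu = stats::setNames(mu, ids),
                                arable = stats::setNames(arable, ids),
                                rho_arable_fai = rho_hat, config = config)
  bundle
}

#' Two-landscape worked example bundle
#'
#' A hand-computable fixture: two landscapes, two pollen types with diet
#' volumes 80 and 20 (weights 0.8 / 0.2), covers 10/10 m2 for the first
#' type and 0/20 m2 for the second, so the preceding index is exactly
#' `fai = {L1: 0.8, L2: 1.2}` with mean 1. Seed counts are `{2, 3, 1}` and
#' `{3, 0, 3}`, so the mean over pods with at least one developed seed is
#' 2.0 and 3.0.
#'
#' @return A validated `fai_bundle`.
#' @export
fixture_tiny <- function() {
  diet <- data.frame(pollen_type = c("p1", "p2"), period = "preceding",
                     volume = c(80, 20), stringsAsFactors = FALSE)
  plants <- data.frame(species = c("sp1", "sp2"),
                       pollen_type = c("p1", "p2"),
                       growth_form = c("woody", "herbaceous"),
                       origin = c("wild", "cultivated"),
                       stringsAsFactors = FALSE)
  cover <- data.frame(
    landscape_id = c("L1", "L2", "L1", "L2"),
    species = c("sp1", "sp1", "sp2", "sp2"),
    cover_m2 = c(10, 10, 0, 20), stringsAsFactors = FALSE)
  landcover <- data.frame(
    landscape_id = rep(c("L1", "L2"), each = 4L),
    class = rep(c("arable", "forest", "urban", "herbaceous_snh"), times = 2L),
    proportion = c(0.6, 0.1, 0.2, 0.1, 0.4, 0.3, 0.1, 0.2),
    stringsAsFactors = FALSE)
  distances <- data.frame(landscape_id = c("L1", "L2"),
                          dist_forest_m = c(120, 0),
                          dist_urban_m = c(0, 250), stringsAsFactors = FALSE)
  seedset <- data.frame(
    landscape_id = rep(c("L1", "L2"), each = 3L),
    pod_id = rep(c("pod_1", "pod_2", "pod_3"), times = 2L),
    seeds = c(2L, 3L, 1L, 3L, 0L, 3L), stringsAsFactors = FALSE)
  as_bundle(diet, plants, cover, landcover, distances, seedset)
}
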