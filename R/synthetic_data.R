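# Synthetic study generator --------------------------------------------------
#
# Generates complete multi-landscape trapping studies with the statistical
# structure the analyses assume: a landscape tree-cover gradient, trap-scale
# covariates correlated within and across scales, and negative-binomial
# catches declining log-linearly with the urbanization index around a
# landscape random intercept.

#' Configuration for a synthetic trapping study
#'
#' Defaults emulate a 13-landscape, 16-traps-per-landscape survey spanning a
#' 10--80% landscape tree-cover gradient, with trap-scale tree cover
#' tracking landscape cover (target Pearson r of landscape means vs.
#' landscape cover around 0.81) and barrier-free angle tracking trap cover
#' (target per-trap Pearson r around 0.85). Catches follow
#' log(mu) = alpha_s + beta * urbanization_index + u_landscape with a
#' lognormal species-abundance hierarchy and negative-binomial noise.
#'
#' @param n_landscapes number of landscapes.
#' @param traps_per_landscape traps per landscape.
#' @param landscape_cover_range landscape tree-cover range (%), uniform.
#' @param landscape_bias_sd sd of the landscape-level deviation of trap
#'   cover from landscape cover (%); with `within_cover_sd`, sets the
#'   cross-scale correlation.
#' @param within_cover_sd sd of trap-level tree-cover noise (%).
#' @param barrier_latent_weight weight of trap cover in the barrier-free
#'   angle mix (the rest is independent uniform noise); sets the trap-scale
#'   covariate correlation.
#' @param species_pool_size size of the regional species pool.
#' @param total_catch_rate expected total catch per trap (all species
#'   summed) at urbanization index 0, before occupancy thinning and
#'   landscape effects; the community-level rate is partitioned among
#'   species by the lognormal abundance distribution, so a larger pool
#'   means rarer species at fixed sampling effort.
#' @param sad_log_sd lognormal shape (sd of log relative abundance) of the
#'   species abundance distribution.
#' @param beta urbanization slope on the log link (per index unit).
#' @param landscape_sd sd of the landscape random intercept (log scale).
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param occupancy probability a pool species occurs in a given landscape
#'   (occupancy thinning).
#' @param non_native_fraction fraction of the pool labelled non-native
#'   (label only; no distinct dynamics).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_landscapes = 13,
                             traps_per_landscape = 16,
                             landscape_cover_range = c(10, 80),
                             landscape_bias_sd = 14,
                             within_cover_sd = 12,
                             barrier_latent_weight = 0.63,
                             species_pool_size = 150,
                             total_catch_rate = 140,
                             sad_log_sd = 1.2,
                             beta = -0.015,
                             landscape_sd = 0.3,
                             nb_size = 0.8,
                             occupancy = 0.6,
                             non_native_fraction = 0.07) {
  stopifnot(n_landscapes >= 1, traps_per_landscape >= 2,
            length(landscape_cover_range) == 2,
            landscape_cover_range[1] >= 0, landscape_cover_range[2] <= 100,
            landscape_cover_range[1] < landscape_cover_range[2],
            landscape_bias_sd >= 0, within_cover_sd >= 0,
            barrier_latent_weight >= 0, barrier_latent_weight <= 1,
            species_pool_size >= 1, total_catch_rate > 0, nb_size > 0,
            occupancy > 0, occupancy <= 1,
            non_native_fraction >= 0, non_native_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

.clip01 <- function(x) pmin(100, pmax(0, x))

#' Generate landscape and trap covariates
#'
#' Landscape tree cover is uniform on the configured range; trap tree cover
#' is the landscape cover plus a landscape-level bias and trap-level noise,
#' clipped to \[0, 100\]; the barrier-free angle is a weighted mix of trap
#' cover and independent uniform noise, clipped likewise. The urbanization
#' index is then computed with [urbanization_index()]. Clipping slightly
#' attenuates the target correlations; this is accepted and documented.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (mandatory).
#' @return a list with `landscapes` and `traps` tables (trap table carries
#'   `urbanization_index`).
#' @export
generate_covariates <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  .seeded_rng(seed)$run(function() {
    nL <- config$n_landscapes
    nT <- config$traps_per_landscape
    lids <- sprintf("L%02d", seq_len(nL))
    cover2km <- stats::runif(nL, config$landscape_cover_range[1],
                             config$landscape_cover_range[2])
    bias <- stats::rnorm(nL, 0, config$landscape_bias_sd)
    traps <- do.call(rbind, lapply(seq_len(nL), function(i) {
      tc <- .clip01(cover2km[i] + bias[i] +
                      stats::rnorm(nT, 0, config$within_cover_sd))
      w <- config$barrier_latent_weight
      ba <- .clip01(w * tc + (1 - w) * stats::runif(nT, 0, 100))
      data.frame(trap_id = sprintf("%s_T%02d", lids[i], seq_len(nT)),
                 landscape_id = lids[i],
                 tree_cover_250m = tc, barrier_free_angle = ba,
                 stringsAsFactors = FALSE)
    }))
    list(landscapes = data.frame(landscape_id = lids,
                                 tree_cover_2km = cover2km,
                                 stringsAsFactors = FALSE),
         traps = add_urbanization_index(traps))
  })
}

#' Generate capture records for generated covariates
#'
#' The community-level catch rate is partitioned among the pool species by a
#' lognormal species abundance distribution: species s receives log rate
#' alpha_s = log(p_s * total_catch_rate) with p_s the normalized lognormal
#' weights. Expected counts at trap j of landscape l are
#' exp(alpha_s + beta * index_j + u_l) with u_l a Gaussian landscape
#' intercept; realized counts are negative binomial. Occupancy thinning
#' removes each species from each landscape independently with probability
#' 1 - occupancy. A configurable fraction of species is labelled non-native.
#'
#' @param config a [synthetic_config()].
#' @param covariates result of [generate_covariates()].
#' @param seed integer seed (mandatory).
#' @return a capture table (rows only for positive counts).
#' @export
generate_community <- function(config, covariates, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  traps <- covariates$traps
  .seeded_rng(seed)$run(function() {
    nS <- config$species_pool_size
    sids <- sprintf("sp%03d", seq_len(nS))
    w <- exp(stats::rnorm(nS, 0, config$sad_log_sd))
    alpha <- log(w / sum(w) * config$total_catch_rate)
    origin <- ifelse(stats::runif(nS) < config$non_native_fraction,
                     "non_native", "native")
    guild <- sample(c("longhorned", "bark", "ambrosia", "other"), nS,
                    replace = TRUE, prob = c(0.45, 0.3, 0.2, 0.05))
    lids <- unique(traps$landscape_id)
    u <- stats::rnorm(length(lids), 0, config$landscape_sd)
    names(u) <- lids
    present <- matrix(stats::runif(nS * length(lids)) < config$occupancy,
                      nrow = nS, dimnames = list(sids, lids))
    rows <- lapply(seq_len(nrow(traps)), function(j) {
      lid <- traps$landscape_id[j]
      s_here <- which(present[, lid])
      if (!length(s_here)) return(NULL)
      mu <- exp(alpha[s_here] + config$beta * traps$urbanization_index[j] +
                  u[lid])
      cnt <- stats::rnbinom(length(s_here), size = config$nb_size, mu = mu)
      pos <- cnt > 0
      if (!any(pos)) return(NULL)
      data.frame(trap_id = traps$trap_id[j],
                 species_id = sids[s_here[pos]],
                 count = cnt[pos],
                 origin = origin[s_here[pos]],
                 guild = guild[s_here[pos]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
}

#' Generate a complete synthetic study
#'
#' Runs [generate_covariates()] and [generate_community()] and, if `dir` is
#' given, writes `traps.csv`, `landscapes.csv`, `captures.csv` and a
#' `manifest.json` recording the configuration and seed. Distinct seeds for
#' the two stages are derived deterministically from `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (mandatory).
#' @param dir optional output directory (created if needed).
#' @return a list with `traps`, `landscapes`, `captures`, `config`, `seed`.
#' @export
generate_study <- function(config = synthetic_config(), seed, dir = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  cov <- generate_covariates(config, seed = seed)
  caps <- generate_community(config, cov, seed = seed + 1000003L)
  study <- list(traps = cov$traps, landscapes = cov$landscapes,
                captures = caps, config = config, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_trap_table(study$traps, file.path(dir, "traps.csv"))
    write_landscape_table(study$landscapes, file.path(dir, "landscapes.csv"))
    write_capture_table(study$captures, file.path(dir, "captures.csv"))
    manifest <- c(unclass(config), list(seed = seed))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  study
}
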