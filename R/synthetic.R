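#' Configuration of the synthetic two-site connectome generator
#'
#' The generator emulates what multi-site studies of streamline-count
#' connectomes actually look like: a shared anatomical template with denser,
#' heavier intra-hemispheric connectivity; a linear (on the log scale)
#' age-related decline of all weights; a sex effect on a designated random
#' edge subset; a per-site bias that favors intra-hemispheric edges under a
#' fixed total streamline budget (mirroring the intra-hemispheric site
#' differences seen in real two-site averages), optionally with an explicit
#' global gain; per-subject global gain jitter; and edge-level log-normal
#' noise. Weights are rounded to nonnegative integers, as streamline counts
#' are.
#'
#' @param n_nodes node count (default 84, split into two hemisphere blocks).
#' @param n_per_site training subjects per site.
#' @param site_labels two (or more) site labels.
#' @param base_density inter-hemispheric edge probability.
#' @param intra_hemisphere_boost multiplier on the edge probability (and the
#'   template weight scale) within a hemisphere.
#' @param base_log_weight_mean,base_log_weight_sd log-normal template weight
#'   parameters.
#' @param site_effect named list (one entry per site) of
#'   `list(intra = , gain = )` multiplicative biases: `intra` scales
#'   intra-hemispheric edges, `gain` scales everything.
#' @param balance_site_mass if `TRUE` (default) the intra-hemispheric site
#'   bias is renormalized so it redistributes streamlines between intra- and
#'   inter-hemispheric edges without changing the expected total count --
#'   tractography generates a fixed number of streamlines per subject, so
#'   site effects reshape the connectome rather than inflate it. The explicit
#'   `gain` field is applied afterwards and is never balanced away.
#' @param age_range uniform age range in years.
#' @param age_slope per-year multiplicative log-slope applied to all weights
#'   (negative = decline with age), centered at the midpoint of `age_range`.
#' @param sex_effect multiplier applied, for female subjects, to a designated
#'   edge subset (a seeded random fraction `sex_edge_fraction` of all
#'   potential edges, fixed across the cohort).
#' @param sex_edge_fraction fraction of edges carrying the sex effect.
#' @param noise_sd sd of the edge-level log-normal noise.
#' @param subject_gain_sd sd of the per-subject global log-normal gain
#'   (captures head-size/SNR variability that per-edge noise cannot).
#' @param seed integer seed; the whole generator is deterministic given it.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_nodes = 84, n_per_site = 150,
                             site_labels = c("SITE1", "SITE2"),
                             base_density = 0.25, intra_hemisphere_boost = 2.4,
                             base_log_weight_mean = log(30),
                             base_log_weight_sd = 1.5,
                             site_effect = list(
                               SITE1 = list(intra = 1.0, gain = 1.0),
                               SITE2 = list(intra = 1.40, gain = 1.0)),
                             balance_site_mass = TRUE,
                             age_range = c(55, 90), age_slope = -0.015,
                             sex_effect = 1.15, sex_edge_fraction = 0.3,
                             noise_sd = 0.25, subject_gain_sd = 0.06,
                             seed = 42) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              n_per_site = as.integer(n_per_site),
              site_labels = as.character(site_labels),
              base_density = base_density,
              intra_hemisphere_boost = intra_hemisphere_boost,
              base_log_weight_mean = base_log_weight_mean,
              base_log_weight_sd = base_log_weight_sd,
              site_effect = site_effect,
              balance_site_mass = isTRUE(balance_site_mass),
              age_range = age_range,
              age_slope = age_slope, sex_effect = sex_effect,
              sex_edge_fraction = sex_edge_fraction,
              noise_sd = noise_sd, subject_gain_sd = subject_gain_sd,
              seed = as.integer(seed))
  if (cfg$n_nodes < 4 || cfg$n_nodes %% 2 != 0)
    stop("`n_nodes` must be an even integer >= 4", call. = FALSE)
  if (cfg$n_per_site < 2)
    stop("`n_per_site` must be at least 2", call. = FALSE)
  if (cfg$base_density <= 0 || cfg$base_density > 1)
    stop("`base_density` must be in (0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cfg$subject_gain_sd < 0)
    stop("`subject_gain_sd` must be >= 0", call. = FALSE)
  if (cfg$sex_edge_fraction <= 0 || cfg$sex_edge_fraction > 1)
    stop("`sex_edge_fraction` must be in (0, 1]", call. = FALSE)
  if (!all(cfg$site_labels %in% names(cfg$site_effect)))
    stop("`site_effect` must name every entry of `site_labels`",
         call. = FALSE)
  if (diff(cfg$age_range) <= 0)
    stop("`age_range` must be increasing", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

hemisphere_of <- function(n_nodes) rep(c("L", "R"), each = n_nodes / 2)

intra_mask <- function(n_nodes) {
  h <- hemisphere_of(n_nodes)
  outer(h, h, `==`)
}

#' Noiseless template connectome
#'
#' Two hemisphere blocks; an edge is present with probability `base_density`
#' (boosted by `intra_hemisphere_boost` within a hemisphere, capped at 1) and
#' carries a log-normal weight whose scale is also boosted intra-hemisphere.
#' Deterministic given `config$seed`.
#' @param config a [generator_config()].
#' @return a [connectome()].
#' @export
make_template <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_nodes
  im <- intra_mask(n)
  with_seed(config$seed, {
    p <- ifelse(im, pmin(1, config$base_density * config$intra_hemisphere_boost),
                config$base_density)
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    present <- stats::runif(sum(up)) < p[up]
    wts <- exp(stats::rnorm(sum(up), config$base_log_weight_mean,
                            config$base_log_weight_sd))
    wts <- wts * ifelse(im[up], sqrt(config$intra_hemisphere_boost), 1)
    w[up] <- present * wts
    w <- w + t(w)
    connectome(w, node_labels = paste0(hemisphere_of(n), "_",
                                       rep(seq_len(n / 2), 2)))
  })
}

# the edge subset carrying the sex effect, fixed for the whole cohort
sex_effect_mask <- function(config) {
  n <- config$n_nodes
  with_seed(config$seed + 500L, {
    m <- matrix(FALSE, n, n)
    up <- upper.tri(m)
    m[up] <- stats::runif(sum(up)) < config$sex_edge_fraction
    m | t(m)
  })
}

subject_weights <- function(template, age, sex, site, config) {
  n <- config$n_nodes
  im <- intra_mask(n)
  age_ref <- mean(config$age_range)
  se <- config$site_effect[[site]]
  site_mult <- ifelse(im, se$intra, 1)
  if (config$balance_site_mass && se$intra != 1) {
    # redistribute rather than add mass: fixed streamline budget per subject
    r <- sum(template$weights * site_mult) / sum(template$weights)
    site_mult <- site_mult / r
  }
  mult <- site_mult * se$gain * exp(config$age_slope * (age - age_ref))
  if (sex == "female") {
    sm <- sex_effect_mask(config)
    mult <- mult * ifelse(sm, config$sex_effect, 1)
  }
  gain <- exp(stats::rnorm(1, 0, config$subject_gain_sd))
  up <- upper.tri(mult)
  noise <- matrix(1, n, n)
  noise[up] <- exp(stats::rnorm(sum(up), 0, config$noise_sd))
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  w <- round(template$weights * mult * gain * noise)
  w[w < 0] <- 0
  list(weights = w, gain = gain)
}

#' Generate a two-site training cohort with known ground truth
#'
#' Per subject: age uniform on `age_range`, sex Bernoulli(0.5), then the
#' age, sex, site, subject-gain and noise multipliers applied to the shared
#' template and rounded to integer streamline counts.
#' @param config a [generator_config()].
#' @return list: `cohort` (a [cohort()]) and `ground_truth` (list with
#'   `table` -- subject_id, age, sex, site, subject_gain -- and the noiseless
#'   `template` [connectome()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  template <- make_template(config)
  with_seed(config$seed + 1000L, {
    records <- list(); gt <- list()
    for (site in config$site_labels) {
      for (i in seq_len(config$n_per_site)) {
        id <- sprintf("%s_%03d", site, i)
        age <- stats::runif(1, config$age_range[1], config$age_range[2])
        sex <- if (stats::runif(1) < 0.5) "female" else "male"
        sw <- subject_weights(template, age, sex, site, config)
        records[[id]] <- subject_record(
          id, age, sex, site,
          connectome(sw$weights, node_labels = template$node_labels))
        gt[[id]] <- data.frame(subject_id = id, age = age, sex = sex,
                               site = site, subject_gain = sw$gain,
                               stringsAsFactors = FALSE)
      }
    }
    list(cohort = cohort(unname(records),
                         site_vocabulary = config$site_labels),
         ground_truth = list(table = do.call(rbind, c(gt,
                                                      make.row.names = FALSE)),
                             template = template))
  })
}

#' Generate a demographically matched test set
#'
#' Draws `n_pairs` demographic profiles (age, sex) and instantiates one
#' subject per site from each profile, jittering age by at most +/-0.5 year,
#' so that every profile yields an admissible same-sex, within-one-year
#' cross-site pair and [match_cohorts()] recovers all `n_pairs` pairs.
#' @param config a [generator_config()] (first two `site_labels` are used).
#' @param n_pairs number of matched pairs (the motivating study used 77).
#' @return a [cohort()] of `2 * n_pairs` records; the profile table is
#'   attached as attribute `"ground_truth"`.
#' @export
generate_matched_testset <- function(config, n_pairs) {
  stopifnot(inherits(config, "generator_config"))
  if (n_pairs == 0)
    return(cohort(list(), site_vocabulary = config$site_labels))
  template <- make_template(config)
  sites <- config$site_labels[1:2]
  with_seed(config$seed + 2000L, {
    records <- list(); gt <- list()
    for (k in seq_len(n_pairs)) {
      age0 <- stats::runif(1, config$age_range[1] + 0.5,
                           config$age_range[2] - 0.5)
      sex <- if (stats::runif(1) < 0.5) "female" else "male"
      for (site in sites) {
        id <- sprintf("PAIR%03d_%s", k, site)
        age <- age0 + stats::runif(1, -0.5, 0.5)
        sw <- subject_weights(template, age, sex, site, config)
        records[[id]] <- subject_record(
          id, age, sex, site,
          connectome(sw$weights, node_labels = template$node_labels))
        gt[[id]] <- data.frame(subject_id = id, pair = k, age = age,
                               sex = sex, site = site,
                               subject_gain = sw$gain,
                               stringsAsFactors = FALSE)
      }
    }
    out <- cohort(unname(records), site_vocabulary = config$site_labels)
    attr(out, "ground_truth") <- do.call(rbind, c(gt, make.row.names = FALSE))
    out
  })
}
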