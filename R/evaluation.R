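#' Cohen's D (pooled-variance standardized mean difference)
#'
#' \eqn{d = (\bar x_1 - \bar x_2) / s_p} with
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}. By the usual
#' convention |d| < 0.2 is a small effect and |d| > 0.5 medium-to-large.
#' @param sample1,sample2 numeric vectors (each of length at least 2).
#' @return the effect size; `NA` when the pooled variance is zero.
#' @export
cohens_d <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2)
    stop("cohens_d needs at least 2 observations per sample", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(sample1) + (n2 - 1) * stats::var(sample2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(sample1) - mean(sample2)) / sqrt(sp2)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Rank-sum U for sample1 with midranks for ties; the two-sided p-value uses
#' the normal approximation with the tie correction to the variance and a
#' 0.5 continuity correction. When every observation is identical the
#' variance is zero and `p = 1` is returned with `undefined = TRUE`.
#' @param sample1,sample2 numeric vectors (nonempty).
#' @return list: `u` (U statistic for sample1, in `[0, n1*n2]`), `p`
#'   (two-sided), `undefined`.
#' @export
mann_whitney_u <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 1 || n2 < 1) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(sample1, sample2)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0)
    return(list(u = u, p = 1, undefined = TRUE))
  mu <- n1 * n2 / 2
  zval <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  zval <- max(zval, 0)
  list(u = u, p = min(1, 2 * stats::pnorm(-zval)), undefined = FALSE)
}

#' Demographic 1:1 matching across sites
#'
#' Maximum-cardinality bipartite matching between the subjects of two sites,
#' where a pair is admissible when both subjects share the same sex and their
#' ages differ by at most `age_tolerance` years (default 1). Implemented with
#' augmenting paths (Kuhn's algorithm), so the matching is truly maximum, and
#' deterministic given input order.
#'
#' @param site_a,site_b lists of [subject_record()] (or cohorts filtered per
#'   site).
#' @param age_tolerance admissible age gap in years.
#' @return list of class `"matched_pair_set"`: `pairs` (list of
#'   `list(a =, b =)` records), `unmatched` (leftover records), `n_pairs`.
#' @export
match_cohorts <- function(site_a, site_b, age_tolerance = 1.0) {
  recs_a <- if (inherits(site_a, "cohort")) site_a$records else site_a
  recs_b <- if (inherits(site_b, "cohort")) site_b$records else site_b
  na <- length(recs_a); nb <- length(recs_b)
  if (na == 0 || nb == 0)
    return(structure(list(pairs = list(), unmatched = c(recs_a, recs_b),
                          n_pairs = 0L), class = "matched_pair_set"))
  admissible <- lapply(seq_len(na), function(i) {
    ra <- recs_a[[i]]
    which(vapply(recs_b, function(rb)
      ra$sex == rb$sex && abs(ra$age - rb$age) <= age_tolerance,
      logical(1)))
  })
  match_b <- integer(nb)  # 0 = free; else index into recs_a
  try_augment <- function(i, seen) {
    for (j in admissible[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_b[j] == 0L) {
        match_b[j] <<- i
        return(list(ok = TRUE, seen = seen))
      }
      res <- try_augment(match_b[j], seen)
      seen <- res$seen
      if (res$ok) {
        match_b[j] <<- i
        return(list(ok = TRUE, seen = seen))
      }
    }
    list(ok = FALSE, seen = seen)
  }
  for (i in seq_len(na)) try_augment(i, rep(FALSE, nb))
  pairs <- lapply(which(match_b > 0L), function(j)
    list(a = recs_a[[match_b[j]]], b = recs_b[[j]]))
  matched_a <- match_b[match_b > 0L]
  unmatched <- c(recs_a[setdiff(seq_len(na), matched_a)],
                 recs_b[which(match_b == 0L)])
  structure(list(pairs = pairs, unmatched = unmatched,
                 n_pairs = length(pairs)),
            class = "matched_pair_set")
}

#' @export
print.matched_pair_set <- function(x, ...) {
  cat(sprintf("<matched_pair_set> %d pairs, %d unmatched\n", x$n_pairs,
              length(x$unmatched)))
  invisible(x)
}

effect_rows <- function(tab, site_labels, measure, phase, alpha) {
  v1 <- tab[tab$site == site_labels[1], measure]
  v2 <- tab[tab$site == site_labels[2], measure]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 2 || length(v2) < 2) return(NULL)
  d <- cohens_d(v1, v2)
  mw <- mann_whitney_u(v1, v2)
  data.frame(measure = measure, phase = phase, cohens_d = d, U = mw$u,
             p = mw$p, n1 = length(v1), n2 = length(v2),
             significant = mw$p < alpha, stringsAsFactors = FALSE)
}

#' Before/after harmonization effect-size report
#'
#' For each of the 12 network measures, computes the between-site Cohen's D
#' and Mann-Whitney U test in the raw ("before") and harmonized ("after")
#' measure tables. Harmonization of a measure is successful when the
#' post-harmonization |D| is below 0.2 and any significant (p < alpha)
#' median difference present before is no longer significant after.
#'
#' @param measures_before,measures_after data.frames in the
#'   [measures_table()] schema (an `after` table may carry a `route` column;
#'   filter it to one route first). Measures undefined for a subject are
#'   skipped with a warning when too few values remain.
#' @param site_labels the two site labels to compare (defaults to the two
#'   sites observed in `measures_before`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per measure and phase: `measure`, `phase`
#'   (`before`/`after`), `cohens_d`, `U`, `p`, `n1`, `n2`, `significant`,
#'   `success_flag` (on `after` rows only).
#' @export
harmonization_report <- function(measures_before, measures_after,
                                 site_labels = NULL, alpha = 0.05) {
  if (is.null(site_labels))
    site_labels <- sort(unique(measures_before$site))
  if (length(site_labels) != 2)
    stop("harmonization_report compares exactly two sites", call. = FALSE)
  out <- list()
  for (m in measure_names()) {
    rb <- effect_rows(measures_before, site_labels, m, "before", alpha)
    ra <- effect_rows(measures_after, site_labels, m, "after", alpha)
    if (is.null(rb) || is.null(ra)) {
      warning(sprintf("measure %s skipped: too few defined values", m))
      next
    }
    rb$success_flag <- NA
    ra$success_flag <- !is.na(ra$cohens_d) && abs(ra$cohens_d) < 0.2 &&
      (!rb$significant || !ra$significant)
    out[[m]] <- rbind(rb, ra)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Biological-preservation metrics of a trained model
#'
#' Evaluates the age and sex heads on held-out subjects: sex classification
#' accuracy at the 0.5 probability cutoff, age mean absolute error in years
#' (after de-standardization), and age R-squared.
#' @param model a trained `"siteharm_model"`.
#' @param test_cohort a [cohort()] of held-out subjects.
#' @return list: `sex_accuracy`, `age_mae`, `age_r2`, plus the per-subject
#'   predictions (`age_pred`, `sex_prob`).
#' @export
biology_report <- function(model, test_cohort) {
  stopifnot(inherits(model, "siteharm_model"),
            inherits(test_cohort, "cohort"))
  md <- cohort_metadata(test_cohort)
  X <- model_features(model, test_cohort)
  code <- vae_encode(model$params, X, model$config)
  heads <- vae_heads(model$params, code$mu, 1L, model$config)
  age_pred <- heads$age_hat * model$stats$age_sd + model$stats$age_mean
  sex_prob <- sigmoid(heads$sex_logit)
  sex_true <- encode_sex(md$sex)
  acc <- mean((sex_prob >= 0.5) == (sex_true == 1))
  resid <- md$age - age_pred
  r2 <- 1 - sum(resid^2) / sum((md$age - mean(md$age))^2)
  list(sex_accuracy = acc, age_mae = mean(abs(resid)), age_r2 = r2,
       age_pred = age_pred, sex_prob = sex_prob)
}

#' Bootstrap stability of harmonization and biology metrics
#'
#' Retrains the model `n_iter` times, each time on a random `frac` fraction
#' of the training cohort drawn without replacement (iteration `i` uses seed
#' `base seed + i`), evaluating every model against the same fixed test set:
#' post-harmonization effect sizes (recomputed-measure route) and the
#' biology metrics. Summaries are mean +/- SD across iterations.
#'
#' @param cohort training [cohort()].
#' @param measures training measures table.
#' @param config a [vae_config()]; its `seed` is the bootstrap base seed.
#' @param test_cohort fixed held-out [cohort()] (e.g. the matched test set).
#' @param target_site site domain used for projection.
#' @param n_iter bootstrap iterations (the full-scale analysis uses 100;
#'   smaller values give quick stability checks).
#' @param frac subsample fraction (default 0.8, without replacement).
#' @return list: `per_iteration` (data.frame: iteration, max_abs_d,
#'   mean_abs_d, n_significant, sex_accuracy, age_mae, age_r2) and `summary`
#'   (mean and sd per metric).
#' @export
bootstrap_experiments <- function(cohort, measures, config, test_cohort,
                                  target_site = 1, n_iter = 100, frac = 0.8) {
  stopifnot(inherits(cohort, "cohort"))
  if (frac <= 0 || frac >= 1) stop("`frac` must be in (0, 1)", call. = FALSE)
  n <- length(cohort$records)
  m <- floor(frac * n)
  if (m < 2 * config$batch_size)
    stop(sprintf(paste("subsample size %d is below twice the batch size %d;",
                       "reduce batch_size or enlarge the cohort"),
                 m, config$batch_size), call. = FALSE)
  before <- measures_table(test_cohort)
  rows <- lapply(seq_len(n_iter), function(it) {
    idx <- with_seed(config$seed + it, sort(sample.int(n, m)))
    sub <- cohort(cohort$records[idx], site_vocabulary = cohort$site_vocabulary)
    cfg <- config
    cfg$seed <- config$seed + it
    model <- vae_train(sub, measures, cfg)
    proj <- project_cohort(test_cohort, model, target_site)
    after <- proj$measures[proj$measures$route == "recomputed", ]
    rep_tab <- harmonization_report(before, after)
    aft <- rep_tab[rep_tab$phase == "after", ]
    bio <- biology_report(model, test_cohort)
    data.frame(iteration = it, max_abs_d = max(abs(aft$cohens_d)),
               mean_abs_d = mean(abs(aft$cohens_d)),
               n_significant = sum(aft$significant),
               sex_accuracy = bio$sex_accuracy, age_mae = bio$age_mae,
               age_r2 = bio$age_r2)
  })
  per_iter <- do.call(rbind, rows)
  metrics <- setdiff(names(per_iter), "iteration")
  summ <- data.frame(metric = metrics,
                     mean = vapply(metrics, function(k) mean(per_iter[[k]]),
                                   numeric(1)),
                     sd = vapply(metrics, function(k) stats::sd(per_iter[[k]]),
                                 numeric(1)),
                     row.names = NULL)
  list(per_iteration = per_iter, summary = summ)
}
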