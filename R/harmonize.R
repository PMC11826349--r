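#' Project one subject's connectome into a target site domain
#'
#' Runs the deterministic pipeline: preprocess the connectome exactly as in
#' training (threshold, `log(1+w)`, per-feature z-score), encode to the
#' posterior mean (no sampling at test time), decode conditioned on the
#' requested site, invert the feature transform, clip negatives to zero, and
#' rebuild the symmetric matrix. Network measures are produced by both
#' routes: predicted by the model's measure head at the target site, and
#' recomputed from the reconstructed connectome.
#'
#' @param record a [subject_record()] with a connectome matching the model's
#'   parcellation.
#' @param model a trained `"siteharm_model"`.
#' @param target_site site label (in the model's vocabulary) or index.
#' @param recompute_measures compute measures on the reconstruction
#'   (default `TRUE`; skipping saves time when only head predictions are
#'   needed).
#' @param rethreshold apply the model's connection filter to the
#'   reconstruction before recomputing measures (default `TRUE`): decoded
#'   matrices carry many sub-streamline noise edges that would otherwise
#'   dominate topology-sensitive measures such as density; set `FALSE` to
#'   analyze the raw decoder output.
#' @param gamma,seed passed to [all_measures()] for the recomputed route.
#' @return list of class `"harmonized_record"`: `subject_id`, `source_site`,
#'   `target_site`, `x_hat` (a [connectome()]), `measures_pred`,
#'   `measures_recomputed`.
#' @export
project <- function(record, model, target_site, recompute_measures = TRUE,
                    rethreshold = TRUE, gamma = 1, seed = 1) {
  stopifnot(inherits(record, "subject_record"),
            inherits(model, "siteharm_model"))
  tgt <- resolve_site(model, target_site)
  cfg <- model$config
  conn <- threshold_connectome(record$connectome, cfg$total_streamlines,
                               cfg$threshold_fraction)
  v <- log1p(vectorize(conn))
  if (length(v) != cfg$input_dim)
    stop(sprintf("subject %s: %d features but the model expects %d",
                 record$subject_id, length(v), cfg$input_dim), call. = FALSE)
  x <- (v - model$stats$feat_mean) / model$stats$feat_sd
  code <- vae_encode(model$params, x, cfg)
  z <- code$mu
  xh_std <- vae_decode(model$params, z, tgt, cfg)
  xh <- expm1(drop(xh_std) * model$stats$feat_sd + model$stats$feat_mean)
  xh[xh < 0] <- 0
  x_hat <- devectorize(xh, model$n_nodes, node_labels = model$node_labels)

  heads <- vae_heads(model$params, z, tgt, cfg)
  mp <- drop(heads$measures_hat) * model$stats$meas_sd + model$stats$meas_mean
  names(mp) <- cfg$measure_subset
  mr <- NULL
  if (recompute_measures) {
    xm <- if (rethreshold)
      threshold_connectome(x_hat, cfg$total_streamlines,
                           cfg$threshold_fraction)
    else x_hat
    mr <- all_measures(xm, gamma = gamma, seed = seed)
  }
  structure(list(subject_id = record$subject_id, source_site = record$site,
                 target_site = model$site_vocabulary[tgt], x_hat = x_hat,
                 measures_pred = mp, measures_recomputed = mr),
            class = "harmonized_record")
}

resolve_site <- function(model, site) {
  if (is.numeric(site)) {
    site <- as.integer(site)
    if (site < 1 || site > length(model$site_vocabulary))
      stop("target site index out of range", call. = FALSE)
    return(site)
  }
  idx <- match(site, model$site_vocabulary)
  if (is.na(idx))
    stop(sprintf("unknown target site '%s'; model knows: %s", site,
                 paste(model$site_vocabulary, collapse = ", ")), call. = FALSE)
  idx
}

#' Project a whole cohort into one site domain
#'
#' Applies [project()] to every record (stable input order) and assembles a
#' harmonized measures table in the same schema as [measures_table()], with
#' a `route` column distinguishing head-predicted from recomputed measures.
#'
#' @inheritParams project
#' @param x a [cohort()].
#' @return list of class `"harmonized_cohort"`: `records` (list of
#'   `"harmonized_record"`), `measures` (data.frame with `route` column),
#'   `target_site`.
#' @export
project_cohort <- function(x, model, target_site, recompute_measures = TRUE,
                           rethreshold = TRUE, gamma = 1, seed = 1) {
  stopifnot(inherits(x, "cohort"))
  recs <- lapply(x$records, function(r)
    tryCatch(project(r, model, target_site, recompute_measures, rethreshold,
                     gamma, seed),
             error = function(e)
               stop(sprintf("subject %s: %s", r$subject_id,
                            conditionMessage(e)), call. = FALSE)))
  row_of <- function(hr, vals, route) {
    full <- stats::setNames(rep(NA_real_, 12), measure_names())
    full[names(vals)] <- vals
    cbind(data.frame(subject_id = hr$subject_id, site = hr$source_site,
                     route = route, stringsAsFactors = FALSE),
          as.data.frame(as.list(full)))
  }
  tabs <- lapply(recs, function(hr) {
    out <- row_of(hr, hr$measures_pred, "predicted")
    if (!is.null(hr$measures_recomputed))
      out <- rbind(out, row_of(hr, hr$measures_recomputed, "recomputed"))
    out
  })
  structure(list(records = recs, measures = do.call(rbind, tabs),
                 target_site = recs[[1]]$target_site %||%
                   as.character(target_site)),
            class = "harmonized_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Entrywise mean connectome
#'
#' Averages connectome matrices, optionally restricted to one site's
#' subjects. Used to visualize systematic site differences (and their
#' removal) at the edge level.
#'
#' @param x a [cohort()], a `"harmonized_cohort"`, or a list of
#'   [connectome()] objects.
#' @param site optional site label filter (matches `site`/`source_site`).
#' @return a [connectome()] holding the mean weights.
#' @export
average_connectome <- function(x, site = NULL) {
  conns <- if (inherits(x, "cohort")) {
    keep <- if (is.null(site)) x$records
            else Filter(function(r) r$site %in% site, x$records)
    lapply(keep, function(r) r$connectome)
  } else if (inherits(x, "harmonized_cohort")) {
    keep <- if (is.null(site)) x$records
            else Filter(function(r) r$source_site %in% site, x$records)
    lapply(keep, function(r) r$x_hat)
  } else {
    x
  }
  if (!length(conns)) stop("no connectomes selected", call. = FALSE)
  acc <- conns[[1]]$weights
  if (length(conns) > 1)
    for (cn in conns[-1]) acc <- acc + cn$weights
  connectome(acc / length(conns), node_labels = conns[[1]]$node_labels)
}
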