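#' Model configuration for the site-conditional VAE
#'
#' The harmonization model is a variational autoencoder over upper-triangle
#' connectome feature vectors. The encoder (linear-ReLU-linear-ReLU, then two
#' parallel affine maps) produces a posterior mean and log-variance; the
#' decoder and the network-measure prediction head are conditioned on a
#' one-hot site code, while the age and sex heads read the latent code alone
#' (biology must be site-invariant). The composite loss is the weighted sum
#' of conditional reconstruction error, KL divergence to a standard normal
#' (which bounds the site information retained in the latent space), age and
#' sex prediction losses, and site-conditional network-measure prediction
#' error.
#'
#' @param input_dim feature-vector length, `n(n-1)/2` (3486 for 84 nodes).
#' @param n_sites number of acquisition sites (at least 2).
#' @param n_measures width of the network-measure head (12 for co-learning,
#'   1 for an individually learned measure).
#' @param measure_subset names of the measures predicted by the head
#'   (defaults to all of [measure_names()]).
#' @param hidden_dim,latent_dim layer widths.
#' @param w_recon,w_kl,w_age,w_sex,w_B loss-component weights (all default 1,
#'   an unweighted sum).
#' @param learning_rate,epochs,batch_size Adam optimizer settings.
#' @param kl_warmup number of initial epochs over which the KL weight ramps
#'   linearly from 0 to `w_kl` (standard warm-up that lets the heads and the
#'   reconstruction organize the latent space before the bottleneck
#'   tightens); 0 disables.
#' @param total_streamlines,threshold_fraction connection-filter settings
#'   applied to every connectome before feature extraction.
#' @param seed single integer seed controlling initialization, minibatch
#'   shuffling, and reparameterization noise.
#' @return a list of class `"vae_config"`.
#' @export
vae_config <- function(input_dim, n_sites, n_measures = 12,
                       measure_subset = measure_names(),
                       hidden_dim = 256, latent_dim = 16,
                       w_recon = 1, w_kl = 0.5, w_age = 1, w_sex = 1, w_B = 1,
                       learning_rate = 1e-3, epochs = 600, batch_size = 64,
                       kl_warmup = 100, total_streamlines = 1e7,
                       threshold_fraction = 1e-7, seed = 1) {
  cfg <- list(input_dim = as.integer(input_dim), n_sites = as.integer(n_sites),
              n_measures = as.integer(n_measures),
              measure_subset = measure_subset,
              hidden_dim = as.integer(hidden_dim),
              latent_dim = as.integer(latent_dim),
              w_recon = w_recon, w_kl = w_kl, w_age = w_age, w_sex = w_sex,
              w_B = w_B, learning_rate = learning_rate,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              kl_warmup = as.integer(kl_warmup),
              total_streamlines = total_streamlines,
              threshold_fraction = threshold_fraction, seed = as.integer(seed))
  dims <- c("input_dim", "n_sites", "n_measures", "hidden_dim", "latent_dim",
            "epochs", "batch_size")
  for (d in dims) if (cfg[[d]] < 1) stop(sprintf("%s must be positive", d),
                                         call. = FALSE)
  for (w in c("w_recon", "w_kl", "w_age", "w_sex", "w_B"))
    if (cfg[[w]] < 0) stop(sprintf("%s must be nonnegative", w), call. = FALSE)
  if (cfg$n_sites < 2)
    stop("the site-conditional model needs at least 2 sites", call. = FALSE)
  if (length(cfg$measure_subset) != cfg$n_measures)
    stop("length(measure_subset) must equal n_measures", call. = FALSE)
  class(cfg) <- "vae_config"
  cfg
}

#' Initialize model parameters
#'
#' He-scaled Gaussian initialization for the ReLU layers, smaller scaling for
#' output maps; deterministic given `config$seed`.
#' @param config a [vae_config()].
#' @return named list of weight matrices and bias vectors.
#' @export
vae_init <- function(config) {
  d <- config$input_dim; h <- config$hidden_dim; L <- config$latent_dim
  S <- config$n_sites; M <- config$n_measures
  with_seed(config$seed, {
    rmat <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, sd = scale),
                                           nr, nc)
    list(
      enc_W1 = rmat(d, h, sqrt(2 / d)),    enc_b1 = numeric(h),
      enc_W2 = rmat(h, h, sqrt(2 / h)),    enc_b2 = numeric(h),
      enc_Wmu = rmat(h, L, sqrt(1 / h)),   enc_bmu = numeric(L),
      enc_Wlv = rmat(h, L, 0.01),          enc_blv = numeric(L),
      dec_W1 = rmat(L + S, h, sqrt(2 / (L + S))), dec_b1 = numeric(h),
      dec_W2 = rmat(h, d, sqrt(1 / h)),    dec_b2 = numeric(d),
      age_w = rmat(L, 1, sqrt(1 / L)),     age_b = 0,
      sex_w = rmat(L, 1, sqrt(1 / L)),     sex_b = 0,
      meas_W = rmat(L + S, M, sqrt(1 / (L + S))), meas_b = numeric(M))
  })
}

as_row_matrix <- function(x, width = NULL) {
  if (is.matrix(x)) return(x)
  matrix(x, nrow = 1)  # width checks happen at the call sites
}

#' One-hot site encoding
#' @param index integer site index/indices in `1..n_sites`.
#' @param n_sites vocabulary size.
#' @return matrix with one row per index, exactly one 1 per row.
#' @export
site_onehot <- function(index, n_sites) {
  index <- as.integer(index)
  if (any(index < 1L | index > n_sites))
    stop(sprintf("site index out of range 1..%d", n_sites), call. = FALSE)
  out <- matrix(0, length(index), n_sites)
  out[cbind(seq_along(index), index)] <- 1
  out
}

#' Encode connectome features to the latent posterior
#'
#' Deterministic map x -> (mu, log sigma^2) through the two-layer ReLU
#' encoder. Accepts a single feature vector or a matrix with one row per
#' subject.
#' @param params parameter list from [vae_init()] (or a trained model's).
#' @param x feature vector(s), already preprocessed/standardized.
#' @param config the matching [vae_config()].
#' @return object of class `"latent_code"`: `mu`, `log_var` (row matrices)
#'   and `dim`.
#' @export
vae_encode <- function(params, x, config) {
  X <- as_row_matrix(x, config$input_dim)
  if (ncol(X) != config$input_dim)
    stop(sprintf("expected %d input features, got %d", config$input_dim,
                 ncol(X)), call. = FALSE)
  H1 <- pmax(sweep(X %*% params$enc_W1, 2, params$enc_b1, `+`), 0)
  H2 <- pmax(sweep(H1 %*% params$enc_W2, 2, params$enc_b2, `+`), 0)
  structure(list(mu = sweep(H2 %*% params$enc_Wmu, 2, params$enc_bmu, `+`),
                 log_var = sweep(H2 %*% params$enc_Wlv, 2, params$enc_blv, `+`),
                 dim = config$latent_dim),
            class = "latent_code")
}

#' Reparameterization: sample the latent code
#'
#' `z = mu + exp(log_var / 2) * eps` with `eps` a standard-normal draw.
#' Supply `eps` explicitly for deterministic use (`eps = 0` gives `z = mu`),
#' or a `seed` to draw it reproducibly.
#' @param code a `"latent_code"` from [vae_encode()].
#' @param eps standard-normal noise, recycled to the shape of `mu`; mutually
#'   exclusive with `seed`.
#' @param seed integer seed used to draw `eps` when it is not supplied.
#' @return matrix `z` with the shape of `mu`.
#' @export
reparameterize <- function(code, eps = NULL, seed = NULL) {
  mu <- code$mu
  if (is.null(eps)) {
    if (is.null(seed)) stop("supply either `eps` or `seed`", call. = FALSE)
    eps <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  }
  if (length(eps) == 1) eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + exp(code$log_var / 2) * eps
}

#' Decode a latent code in a chosen site domain
#'
#' Concatenates `z` with the one-hot site code and maps through the two-layer
#' decoder (ReLU between); the same `z` decoded under different sites yields
#' the reconstruction "as if acquired" at each site.
#' @param params,config as in [vae_encode()].
#' @param z latent code row matrix (or vector).
#' @param site integer site index/indices (length 1, recycled, or one per row).
#' @return reconstructed feature matrix, `input_dim` columns.
#' @export
vae_decode <- function(params, z, site, config) {
  Z <- as_row_matrix(z, config$latent_dim)
  if (ncol(Z) != config$latent_dim)
    stop("latent dimension mismatch", call. = FALSE)
  C <- site_onehot(rep_len(site, nrow(Z)), config$n_sites)
  Din <- cbind(Z, C)
  G1 <- pmax(sweep(Din %*% params$dec_W1, 2, params$dec_b1, `+`), 0)
  sweep(G1 %*% params$dec_W2, 2, params$dec_b2, `+`)
}

#' Prediction heads: age, sex, and site-conditional network measures
#'
#' Age and sex are affine in `z` alone; the measure head is affine in
#' `(z, site)` because network measures are evaluated in a site domain.
#' @inheritParams vae_decode
#' @return list: `age_hat` (standardized scale), `sex_logit`,
#'   `measures_hat` (standardized scale, `n_measures` columns).
#' @export
vae_heads <- function(params, z, site, config) {
  Z <- as_row_matrix(z, config$latent_dim)
  C <- site_onehot(rep_len(site, nrow(Z)), config$n_sites)
  Din <- cbind(Z, C)
  list(age_hat = drop(Z %*% params$age_w + params$age_b),
       sex_logit = drop(Z %*% params$sex_w + params$sex_b),
       measures_hat = sweep(Din %*% params$meas_W, 2, params$meas_b, `+`))
}

#' KL divergence of the latent posterior from the standard normal
#'
#' Closed form for diagonal Gaussians:
#' \eqn{\tfrac12 \sum_d (e^{\ell_d} + \mu_d^2 - 1 - \ell_d)} with
#' \eqn{\ell = \log\sigma^2}. This is the variational penalty that bounds the
#' mutual information between the latent code and the site variable.
#' @param code a `"latent_code"` (or list with `mu`, `log_var`).
#' @return nonnegative scalar (one sample) or vector (one per row).
#' @export
kl_divergence <- function(code) {
  mu <- as_row_matrix(code$mu, length(code$mu))
  lv <- as_row_matrix(code$log_var, length(code$log_var))
  drop(0.5 * rowSums(exp(lv) + mu^2 - 1 - lv))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable mean binary cross entropy of logits vs labels in {0,1}
bce_mean <- function(logit, y) {
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

#' Composite training loss (and, optionally, its gradients)
#'
#' Evaluates the five-part loss on a batch: reconstruction of the connectome
#' features decoded at each record's true site, KL divergence, squared error
#' of standardized age, binary cross entropy of sex, and squared error of the
#' standardized network-measure targets predicted at the true site (targets
#' with an undefined measure are masked out of the mean). The total is the
#' configured weighted sum.
#'
#' @param params parameter list.
#' @param batch list with `X` (standardized features, row per subject), `age`
#'   (standardized), `sex` (0/1), `site` (integer index), `B` (standardized
#'   measure targets, `n_measures` columns), `B_mask` (1 where the target is
#'   defined).
#' @param config a [vae_config()].
#' @param eps reparameterization noise matrix (shape of `mu`); 0 uses the
#'   posterior mean.
#' @param grads if `TRUE`, also return analytic gradients for every
#'   parameter (hand-derived backpropagation).
#' @return list with `breakdown` (class `"loss_breakdown"`: `recon`, `kl`,
#'   `age`, `sex`, `measures`, `total`) and optionally `grads`.
#' @export
vae_loss <- function(params, batch, config, eps = 0, grads = FALSE) {
  X <- batch$X
  B <- nrow(X)
  a <- batch$age; s <- batch$sex
  Ct <- site_onehot(batch$site, config$n_sites)
  Bt <- as_row_matrix(batch$B, config$n_measures)
  Bm <- if (is.null(batch$B_mask)) matrix(1, B, config$n_measures)
        else as_row_matrix(batch$B_mask, config$n_measures) * 1

  # ---- forward ----
  A1 <- sweep(X %*% params$enc_W1, 2, params$enc_b1, `+`); H1 <- pmax(A1, 0)
  A2 <- sweep(H1 %*% params$enc_W2, 2, params$enc_b2, `+`); H2 <- pmax(A2, 0)
  MU <- sweep(H2 %*% params$enc_Wmu, 2, params$enc_bmu, `+`)
  LV <- sweep(H2 %*% params$enc_Wlv, 2, params$enc_blv, `+`)
  LV <- pmin(pmax(LV, -30), 30)  # numerical guard, inactive in normal training
  E <- if (length(eps) == 1) matrix(eps, B, config$latent_dim) else eps
  SD <- exp(LV / 2)
  Z <- MU + SD * E
  Din <- cbind(Z, Ct)
  A3 <- sweep(Din %*% params$dec_W1, 2, params$dec_b1, `+`); G1 <- pmax(A3, 0)
  Xhat <- sweep(G1 %*% params$dec_W2, 2, params$dec_b2, `+`)
  agehat <- drop(Z %*% params$age_w + params$age_b)
  sexlogit <- drop(Z %*% params$sex_w + params$sex_b)
  Mhat <- sweep(Din %*% params$meas_W, 2, params$meas_b, `+`)

  Rz <- Xhat - X
  l_recon <- sum(Rz^2) / length(Rz)
  l_kl <- mean(0.5 * rowSums(exp(LV) + MU^2 - 1 - LV))
  l_age <- mean((agehat - a)^2)
  l_sex <- bce_mean(sexlogit, s)
  denomB <- max(1, sum(Bm))
  l_meas <- sum(Bm * (Mhat - Bt)^2) / denomB
  total <- config$w_recon * l_recon + config$w_kl * l_kl +
    config$w_age * l_age + config$w_sex * l_sex + config$w_B * l_meas
  breakdown <- structure(list(recon = l_recon, kl = l_kl, age = l_age,
                              sex = l_sex, measures = l_meas, total = total),
                         class = "loss_breakdown")
  if (!grads) return(list(breakdown = breakdown))

  # ---- backward ----
  L <- config$latent_dim
  g <- list()
  dXhat <- config$w_recon * 2 * Rz / length(Rz)
  g$dec_b2 <- colSums(dXhat)
  g$dec_W2 <- crossprod(G1, dXhat)
  dA3 <- (dXhat %*% t(params$dec_W2)) * (A3 > 0)
  g$dec_b1 <- colSums(dA3)
  g$dec_W1 <- crossprod(Din, dA3)
  dDin <- dA3 %*% t(params$dec_W1)
  dZ <- dDin[, seq_len(L), drop = FALSE]

  dage <- config$w_age * 2 * (agehat - a) / B
  g$age_w <- crossprod(Z, matrix(dage)); g$age_b <- sum(dage)
  dZ <- dZ + matrix(dage) %*% t(params$age_w)

  dlog <- config$w_sex * (sigmoid(sexlogit) - s) / B
  g$sex_w <- crossprod(Z, matrix(dlog)); g$sex_b <- sum(dlog)
  dZ <- dZ + matrix(dlog) %*% t(params$sex_w)

  dMhat <- config$w_B * 2 * Bm * (Mhat - Bt) / denomB
  g$meas_b <- colSums(dMhat)
  g$meas_W <- crossprod(Din, dMhat)
  dDm <- dMhat %*% t(params$meas_W)
  dZ <- dZ + dDm[, seq_len(L), drop = FALSE]

  dMU <- dZ + config$w_kl * MU / B
  dLV <- dZ * E * 0.5 * SD + config$w_kl * 0.5 * (exp(LV) - 1) / B

  g$enc_bmu <- colSums(dMU); g$enc_Wmu <- crossprod(H2, dMU)
  g$enc_blv <- colSums(dLV); g$enc_Wlv <- crossprod(H2, dLV)
  dH2 <- dMU %*% t(params$enc_Wmu) + dLV %*% t(params$enc_Wlv)
  dA2 <- dH2 * (A2 > 0)
  g$enc_b2 <- colSums(dA2); g$enc_W2 <- crossprod(H1, dA2)
  dA1 <- (dA2 %*% t(params$enc_W2)) * (A1 > 0)
  g$enc_b1 <- colSums(dA1); g$enc_W1 <- crossprod(X, dA1)

  grads_out <- list(enc_W1 = g$enc_W1, enc_b1 = g$enc_b1, enc_W2 = g$enc_W2,
                    enc_b2 = g$enc_b2, enc_Wmu = g$enc_Wmu,
                    enc_bmu = g$enc_bmu, enc_Wlv = g$enc_Wlv,
                    enc_blv = g$enc_blv, dec_W1 = g$dec_W1, dec_b1 = g$dec_b1,
                    dec_W2 = g$dec_W2, dec_b2 = g$dec_b2, age_w = g$age_w,
                    age_b = g$age_b, sex_w = g$sex_w, sex_b = g$sex_b,
                    meas_W = g$meas_W, meas_b = g$meas_b)
  list(breakdown = breakdown, grads = grads_out)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.4f (recon %.4f, kl %.4f, age %.4f, sex %.4f, measures %.4f)\n",
    x$total, x$recon, x$kl, x$age, x$sex, x$measures))
  invisible(x)
}

# ---- data preparation -------------------------------------------------------

log1p_features <- function(cohort, config) {
  t(vapply(cohort$records, function(r) {
    conn <- threshold_connectome(r$connectome, config$total_streamlines,
                                 config$threshold_fraction)
    log1p(vectorize(conn))
  }, numeric(config$input_dim)))
}

standardize_cols <- function(X, center, scale) {
  sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
}

safe_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-8) 1 else s
}

# Assemble standardized training arrays + the statistics needed to invert them.
prepare_training_data <- function(cohort, measures, config) {
  md <- cohort_metadata(cohort)
  sites <- cohort$site_vocabulary
  if (length(unique(md$site)) < 2)
    stop(paste("training cohort covers a single site; site disentanglement",
               "is undefined without at least two sites"), call. = FALSE)
  Xraw <- log1p_features(cohort, config)
  feat_mean <- colMeans(Xraw)
  feat_sd <- apply(Xraw, 2, safe_sd)
  X <- standardize_cols(Xraw, feat_mean, feat_sd)

  age_mean <- mean(md$age); age_sd <- safe_sd(md$age)
  rows <- match(md$subject_id, measures$subject_id)
  if (anyNA(rows))
    stop(sprintf("measures table is missing subject(s): %s",
                 paste(md$subject_id[is.na(rows)], collapse = ", ")),
         call. = FALSE)
  Bt <- as.matrix(measures[rows, config$measure_subset, drop = FALSE])
  meas_mean <- apply(Bt, 2, function(x) mean(x, na.rm = TRUE))
  meas_mean[!is.finite(meas_mean)] <- 0
  meas_sd <- apply(Bt, 2, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-8) 1 else s
  })
  Bmask <- 1 * !is.na(Bt)
  Bstd <- standardize_cols(Bt, meas_mean, meas_sd)
  Bstd[is.na(Bstd)] <- 0

  list(X = X, age = (md$age - age_mean) / age_sd, sex = encode_sex(md$sex),
       site = match(md$site, sites), B = Bstd, B_mask = Bmask,
       stats = list(feat_mean = feat_mean, feat_sd = feat_sd,
                    age_mean = age_mean, age_sd = age_sd,
                    meas_mean = meas_mean, meas_sd = meas_sd),
       site_vocabulary = sites)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the site-conditional VAE
#'
#' Minibatch gradient descent (Adam) on the composite loss. Connectome
#' features are transformed as `log(1 + w)` and z-scored per feature on the
#' training set; age and measure targets are z-scored likewise. All
#' standardization statistics are stored with the model and applied to any
#' later input. Fully deterministic given `config$seed`.
#'
#' @param cohort training [cohort()] spanning at least two sites.
#' @param measures measures table ([measures_table()]) covering every
#'   training subject; these site-biased measures are the ground-truth
#'   targets of the measure head.
#' @param config a [vae_config()].
#' @param verbose print a progress line every 25 epochs.
#' @return object of class `"siteharm_model"`: `params`, `config`, `stats`,
#'   `site_vocabulary`, `n_nodes`, `node_labels`, and `history` (per-epoch
#'   mean loss breakdown).
#' @export
vae_train <- function(cohort, measures, config, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "vae_config"))
  dat <- prepare_training_data(cohort, measures, config)
  n <- nrow(dat$X)
  if (length(dat$site_vocabulary) != config$n_sites)
    stop(sprintf("config declares %d sites but the cohort has %d",
                 config$n_sites, length(dat$site_vocabulary)), call. = FALSE)

  params <- vae_init(config)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  hist <- matrix(NA_real_, config$epochs, 6,
                 dimnames = list(NULL, c("recon", "kl", "age", "sex",
                                         "measures", "total")))
  t_step <- 0
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      cfg_ep <- config
      if (config$kl_warmup > 0 && ep <= config$kl_warmup)
        cfg_ep$w_kl <- config$w_kl * ep / config$kl_warmup
      # step decay for the final third of training sharpens convergence
      lr_ep <- config$learning_rate * if (ep > 2 * config$epochs / 3) 0.3 else 1
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      acc <- numeric(6); wt <- 0
      for (st in starts) {
        idx <- ord[st:min(st + config$batch_size - 1, n)]
        bs <- length(idx)
        eps <- matrix(stats::rnorm(bs * config$latent_dim), bs,
                      config$latent_dim)
        batch <- list(X = dat$X[idx, , drop = FALSE], age = dat$age[idx],
                      sex = dat$sex[idx], site = dat$site[idx],
                      B = dat$B[idx, , drop = FALSE],
                      B_mask = dat$B_mask[idx, , drop = FALSE])
        res <- vae_loss(params, batch, cfg_ep, eps = eps, grads = TRUE)
        t_step <- t_step + 1
        upd <- adam_step(params, res$grads, state, lr_ep, t_step)
        params <- upd$params; state <- upd$state
        b <- res$breakdown
        acc <- acc + bs * c(b$recon, b$kl, b$age, b$sex, b$measures, b$total)
        wt <- wt + bs
      }
      hist[ep, ] <- acc / wt
      if (verbose && (ep %% 25 == 0 || ep == 1))
        message(sprintf("epoch %4d  total %.4f  recon %.4f  kl %.4f", ep,
                        hist[ep, "total"], hist[ep, "recon"], hist[ep, "kl"]))
    }
  })

  conn0 <- cohort$records[[1]]$connectome
  structure(list(params = params, config = config, stats = dat$stats,
                 site_vocabulary = dat$site_vocabulary,
                 sex_encoding = c(female = 1, male = 0),
                 n_nodes = conn0$n, node_labels = conn0$node_labels,
                 history = as.data.frame(hist)),
            class = "siteharm_model")
}

#' @export
print.siteharm_model <- function(x, ...) {
  cat(sprintf(
    "<siteharm_model> %d -> %d -> %d latent; sites: %s; measures head: %s\n",
    x$config$input_dim, x$config$hidden_dim, x$config$latent_dim,
    paste(x$site_vocabulary, collapse = ", "),
    paste(x$config$measure_subset, collapse = ", ")))
  if (nrow(x$history))
    cat(sprintf("trained %d epochs; final total loss %.4f\n",
                nrow(x$history), x$history$total[nrow(x$history)]))
  invisible(x)
}

#' Train under the co-learning or individual learning scheme
#'
#' Co-learning fits one model whose measure head predicts all 12 network
#' measures simultaneously; individual learning fits 12 separate models, one
#' per measure (head width 1). The encoder architecture is identical in both.
#'
#' @inheritParams vae_train
#' @param scheme `"colearn"` or `"individual"`.
#' @return list of class `"siteharm_scheme"`: `scheme` and `models` (length
#'   1 for co-learning, 12 for individual, named by measure).
#' @export
train_scheme <- function(cohort, measures, config,
                         scheme = c("colearn", "individual"),
                         verbose = FALSE) {
  scheme <- match.arg(scheme)
  if (scheme == "colearn") {
    cfg <- config
    cfg$n_measures <- 12L
    cfg$measure_subset <- measure_names()
    models <- list(colearn = vae_train(cohort, measures, cfg, verbose))
  } else {
    models <- lapply(measure_names(), function(mn) {
      cfg <- config
      cfg$n_measures <- 1L
      cfg$measure_subset <- mn
      vae_train(cohort, measures, cfg, verbose)
    })
    names(models) <- measure_names()
  }
  structure(list(scheme = scheme, models = models),
            class = "siteharm_scheme")
}

# Standardized feature matrix for any cohort, using a trained model's stats.
model_features <- function(model, cohort) {
  Xraw <- log1p_features(cohort, model$config)
  standardize_cols(Xraw, model$stats$feat_mean, model$stats$feat_sd)
}

#' Persist / restore a trained model
#'
#' Writes the parameter blob (`params.rds`) plus a JSON sidecar with the
#' architecture, loss weights, standardization statistics, seed, site
#' vocabulary and measure order. Reloading reproduces encode/decode outputs
#' bitwise.
#' @param model a `"siteharm_model"`.
#' @param dir model directory (created if needed).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "siteharm_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  side <- list(config = unclass(model$config), stats = model$stats,
               site_vocabulary = model$site_vocabulary,
               sex_encoding = as.list(model$sex_encoding),
               n_nodes = model$n_nodes, node_labels = model$node_labels)
  jsonlite::write_json(side, file.path(dir, "model.json"), digits = NA,
                       auto_unbox = TRUE)
  saveRDS(model$history, file.path(dir, "history.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @param dir model directory written by [save_model()].
#' @export
load_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- side$config
  config <- vae_config(
    input_dim = cfg$input_dim, n_sites = cfg$n_sites,
    n_measures = cfg$n_measures, measure_subset = cfg$measure_subset,
    hidden_dim = cfg$hidden_dim, latent_dim = cfg$latent_dim,
    w_recon = cfg$w_recon, w_kl = cfg$w_kl, w_age = cfg$w_age,
    w_sex = cfg$w_sex, w_B = cfg$w_B, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    kl_warmup = cfg$kl_warmup,
    total_streamlines = cfg$total_streamlines,
    threshold_fraction = cfg$threshold_fraction, seed = cfg$seed)
  stats <- side$stats
  # JSON arrays drop names; restore the measure naming of the training run
  names(stats$meas_mean) <- config$measure_subset
  names(stats$meas_sd) <- config$measure_subset
  structure(list(params = readRDS(file.path(dir, "params.rds")),
                 config = config, stats = stats,
                 site_vocabulary = side$site_vocabulary,
                 sex_encoding = unlist(side$sex_encoding),
                 n_nodes = side$n_nodes, node_labels = side$node_labels,
                 history = readRDS(file.path(dir, "history.rds"))),
            class = "siteharm_model")
}
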