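tiny_cfg <- function(...) {
  vae_config(input_dim = 6, n_sites = 2, n_measures = 2,
             measure_subset = c("m1", "m2"), hidden_dim = 5, latent_dim = 3,
             ...)
}

zero_params <- function(cfg) {
  p <- vae_init(cfg)
  lapply(p, function(x) x * 0)
}

random_batch <- function(cfg, B = 4) {
  list(X = matrix(rnorm(B * cfg$input_dim), B, cfg$input_dim),
       age = rnorm(B), sex = rbinom(B, 1, 0.5),
       site = sample(1:cfg$n_sites, B, replace = TRUE),
       B = matrix(rnorm(B * cfg$n_measures), B, cfg$n_measures),
       B_mask = matrix(rbinom(B * cfg$n_measures, 1, 0.8), B,
                       cfg$n_measures))
}

test_that("encoder is deterministic and zero maps to zero", {
  cfg <- tiny_cfg()
  p0 <- zero_params(cfg)
  code <- vae_encode(p0, numeric(6), cfg)
  expect_equal(as.numeric(code$mu), rep(0, 3))
  expect_equal(as.numeric(code$log_var), rep(0, 3))

  set.seed(1)
  p <- vae_init(cfg)
  x <- rnorm(6)
  c1 <- vae_encode(p, x, cfg)
  c2 <- vae_encode(p, x, cfg)
  expect_identical(c1, c2)
  expect_error(vae_encode(p, rnorm(5), cfg), "features")
})

test_that("reparameterization has the prescribed mean and scale", {
  code <- structure(list(mu = matrix(c(0.3, -1), 1), log_var = matrix(0, 1, 2),
                         dim = 2), class = "latent_code")
  expect_equal(reparameterize(code, eps = 0), code$mu)
  code0 <- structure(list(mu = matrix(0, 1, 2), log_var = matrix(0, 1, 2),
                          dim = 2), class = "latent_code")
  expect_equal(as.numeric(reparameterize(code0, eps = matrix(c(1, -1), 1))),
               c(1, -1))
  # Monte-Carlo: empirical variance of z matches exp(log_var) within 3 SE
  lv <- log(0.49)
  codev <- structure(list(mu = matrix(2, 1e5, 1),
                          log_var = matrix(lv, 1e5, 1), dim = 1),
                     class = "latent_code")
  z <- reparameterize(codev, seed = 99)
  v <- var(as.numeric(z))
  se <- 0.49 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(v - 0.49), 3 * se)
  expect_lt(abs(mean(z) - 2), 3 * 0.7 / sqrt(1e5))
})

test_that("decoder and heads are wired site-conditionally", {
  cfg <- tiny_cfg()
  expect_equal(as.numeric(vae_decode(zero_params(cfg), numeric(3), 1, cfg)),
               rep(0, 6))
  set.seed(2)
  p <- vae_init(cfg)
  z <- rnorm(3)
  x1 <- vae_decode(p, z, 1, cfg)
  x2 <- vae_decode(p, z, 2, cfg)
  expect_false(isTRUE(all.equal(x1, x2)))  # conditioning matters
  expect_error(vae_decode(p, z, 3, cfg), "out of range")
  expect_length(as.numeric(x1), 6)

  h1 <- vae_heads(p, z, 1, cfg)
  h2 <- vae_heads(p, z, 2, cfg)
  expect_equal(h1$age_hat, h2$age_hat)        # biology heads unconditioned
  expect_equal(h1$sex_logit, h2$sex_logit)
  expect_false(isTRUE(all.equal(h1$measures_hat, h2$measures_hat)))
  expect_true(all(siteharm:::sigmoid(h1$sex_logit) > 0 &
                  siteharm:::sigmoid(h1$sex_logit) < 1))

  hz <- vae_heads(zero_params(cfg), numeric(3), 1, cfg)
  expect_equal(hz$age_hat, 0)
  expect_equal(siteharm:::sigmoid(hz$sex_logit), 0.5)
  expect_equal(as.numeric(hz$measures_hat), c(0, 0))

  # decoded feature length for the 84-node atlas
  cfg84 <- vae_config(input_dim = 84 * 83 / 2, n_sites = 2, hidden_dim = 8,
                      latent_dim = 2)
  p84 <- vae_init(cfg84)
  expect_length(as.numeric(vae_decode(p84, rnorm(2), 2, cfg84)), 3486)
})

test_that("KL divergence matches its closed form and is nonnegative", {
  expect_equal(kl_divergence(list(mu = 0, log_var = 0)), 0)
  expect_equal(kl_divergence(list(mu = 1, log_var = 0)), 0.5)
  expect_equal(kl_divergence(list(mu = 0, log_var = log(2))),
               0.5 * (2 - log(2) - 1))
  set.seed(31)
  for (i in 1:1000) {
    d <- sample(1:6, 1)
    mu <- rnorm(d); lv <- rnorm(d)
    expect_equal(kl_divergence(list(mu = mu, log_var = lv)),
                 0.5 * sum(exp(lv) + mu^2 - 1 - lv), tolerance = 1e-12)
    expect_gte(kl_divergence(list(mu = mu, log_var = lv)), 0)
  }
})

test_that("loss breakdown obeys the weighting contract", {
  cfg <- tiny_cfg()
  set.seed(5)
  p <- vae_init(cfg)
  batch <- random_batch(cfg)
  # all weights zero except KL: total equals the KL component
  cfg_kl <- tiny_cfg(w_recon = 0, w_kl = 1, w_age = 0, w_sex = 0, w_B = 0)
  bd <- vae_loss(p, batch, cfg_kl, eps = 0)$breakdown
  expect_equal(bd$total, bd$kl)
  # general: total is the weighted sum of components
  cfg_w <- tiny_cfg(w_recon = 2, w_kl = 0.5, w_age = 3, w_sex = 0.1, w_B = 7)
  bd2 <- vae_loss(p, batch, cfg_w, eps = 0)$breakdown
  expect_equal(bd2$total,
               2 * bd2$recon + 0.5 * bd2$kl + 3 * bd2$age + 0.1 * bd2$sex +
                 7 * bd2$measures, tolerance = 1e-9)
  # perfect reconstruction/prediction with collapsed posterior: zero loss
  p0 <- zero_params(cfg)
  b0 <- list(X = matrix(0, 2, 6), age = c(0, 0), sex = NULL, site = c(1, 2),
             B = matrix(0, 2, 2), B_mask = matrix(1, 2, 2))
  b0$sex <- c(0.5, 0.5)  # BCE of logit 0 vs "0.5" label = log(2): check parts
  bd0 <- vae_loss(p0, b0, cfg, eps = 0)$breakdown
  expect_equal(bd0$recon, 0)
  expect_equal(bd0$kl, 0)
  expect_equal(bd0$age, 0)
  expect_equal(bd0$measures, 0)
})

test_that("single-record loss matches hand arithmetic on a minimal network", {
  cfg <- vae_config(input_dim = 3, n_sites = 2, n_measures = 1,
                    measure_subset = "m", hidden_dim = 2, latent_dim = 2)
  p <- zero_params(cfg)
  p$enc_W1 <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)   # picks x1, x2
  p$enc_Wmu <- diag(2)
  p$dec_W2 <- matrix(1, 2, 3)
  x <- c(1, 2, 0.5)
  batch <- list(X = matrix(x, 1), age = 0.5, sex = 1, site = 1,
                B = matrix(0.25, 1), B_mask = matrix(1, 1))
  bd <- vae_loss(p, batch, cfg, eps = 0)$breakdown
  # forward by hand: H1 = relu([1,2]) = [1,2]; H2 = relu(0) = 0... enc_W2 = 0
  # so mu = 0, lv = 0, z = 0; decoder: Din = [0,0,1,0]; all params 0 -> xhat 0
  expect_equal(bd$recon, mean(x^2))
  expect_equal(bd$kl, 0)
  expect_equal(bd$age, 0.25)
  expect_equal(bd$sex, -log(0.5))
  expect_equal(bd$measures, 0.0625)
  expect_equal(bd$total, mean(x^2) + 0.25 - log(0.5) + 0.0625)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg()
  set.seed(8)
  p <- vae_init(cfg)
  batch <- random_batch(cfg, B = 5)
  eps <- matrix(rnorm(5 * 3), 5, 3)
  res <- vae_loss(p, batch, cfg, eps = eps, grads = TRUE)
  h <- 1e-5
  worst <- 0
  for (nm in names(p)) {
    for (i in seq_along(p[[nm]])) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (vae_loss(pp, batch, cfg, eps = eps)$breakdown$total -
               vae_loss(pm, batch, cfg, eps = eps)$breakdown$total) / (2 * h)
      err <- abs(fd - res$grads[[nm]][i]) /
        max(abs(fd), abs(res$grads[[nm]][i]), 1e-6)
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training is reproducible and reduces the loss on synthetic data", {
  dat <- tiny_trained()
  hist <- dat$model$history
  n_ep <- nrow(hist)
  expect_lt(mean(tail(hist$total, 10)), mean(head(hist$total, 10)))

  # bitwise-identical loss history under the same seed and data
  m2 <- vae_train(dat$gen$cohort, dat$meas, tiny_vae_config())
  expect_identical(dat$model$history, m2$history)
  expect_identical(dat$model$params, m2$params)

  # single-site cohort is refused
  s1 <- cohort_subset(dat$gen$cohort, "SITE1")
  s1$site_vocabulary <- "SITE1"
  expect_error(vae_train(s1, dat$meas, tiny_vae_config()), "single site")
})

test_that("KL regularization raises training reconstruction error", {
  dat <- tiny_trained()
  cfg_ae <- tiny_vae_config(epochs = 25, w_kl = 0, w_age = 0, w_sex = 0,
                            w_B = 0)
  cfg_vae <- tiny_vae_config(epochs = 25, w_kl = 1, w_age = 0, w_sex = 0,
                             w_B = 0)
  m_ae <- vae_train(dat$gen$cohort, dat$meas, cfg_ae)
  m_vae <- vae_train(dat$gen$cohort, dat$meas, cfg_vae)
  expect_lt(tail(m_ae$history$recon, 1), tail(m_vae$history$recon, 1))
})

test_that("training schemes produce the promised model sets", {
  dat <- tiny_trained()
  cfg <- tiny_vae_config(epochs = 4)
  co <- train_scheme(dat$gen$cohort, dat$meas, cfg, "colearn")
  expect_length(co$models, 1)
  expect_equal(ncol(co$models[[1]]$params$meas_W), 12)

  ind <- train_scheme(dat$gen$cohort, dat$meas, cfg, "individual")
  expect_length(ind$models, 12)
  expect_named(ind$models, measure_names())
  expect_true(all(vapply(ind$models,
                         function(m) ncol(m$params$meas_W) == 1, logical(1))))
  # same encoder architecture in both schemes
  expect_equal(dim(ind$models[[1]]$params$enc_W1),
               dim(co$models[[1]]$params$enc_W1))
  expect_error(train_scheme(dat$gen$cohort, dat$meas, cfg, "both"))
})

test_that("model persistence round-trips bitwise", {
  dat <- tiny_trained()
  dir <- withr::local_tempdir()
  save_model(dat$model, dir)
  m2 <- load_model(dir)
  expect_identical(m2$params, dat$model$params)
  expect_equal(m2$stats, dat$model$stats)
  X <- siteharm:::model_features(dat$model, dat$test)
  c1 <- vae_encode(dat$model$params, X, dat$model$config)
  c2 <- vae_encode(m2$params, X, m2$config)
  expect_identical(c1$mu, c2$mu)
  expect_identical(vae_decode(dat$model$params, c1$mu, 2, dat$model$config),
                   vae_decode(m2$params, c2$mu, 2, m2$config))
})
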