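# shared small simulated scene: focal food trait Yo, mediator X acting on it
make_mediation_scene <- function(seed, n = 50000L, beta_xy = 0.3,
                                 n_gy = 20L, n_gx = 20L, var_gx = 0.35) {
  cfg <- sim_config(n_individuals = n, n_gy = n_gy, n_gx = n_gx,
                    var_gx = var_gx, beta_xy = beta_xy, seed = seed)
  sims <- simulate_sumstats(cfg, traits = c("Yo", "X"))
  list(focal = sims$Yo, med = sims$X, truth = sims$truth)
}

test_that("CUR classification applies the 1 +/- 0.05 window to signed CUR", {
  expect_equal(classify_cur(1.04), "non-mediated")
  expect_equal(classify_cur(1.0), "non-mediated")
  expect_equal(classify_cur(0.95), "non-mediated")
  expect_equal(classify_cur(0.80), "uncertain")
  expect_equal(classify_cur(-1.0), "uncertain")   # sign flip is never direct
  expect_equal(classify_cur(NaN), "uncertain")
  expect_equal(classify_cur(c(1.02, 2, Inf)),
               c("non-mediated", "uncertain", "uncertain"))
  expect_equal(classify_cur(1.2, window = 0.25), "non-mediated")
})

test_that("the prior mediated effect is the theta-weighted combination with
           propagated uncertainty", {
  model <- structure(list(focal_trait = "y",
                          mediators = data.frame(trait = c("m1", "m2"),
                                                 theta = c(0.5, -0.2),
                                                 se_theta = c(0.05, 0.04))),
                     class = "mediator_model")
  pm <- predict_mediated_effect(list(beta = c(m1 = 0.2, m2 = 0),
                                     se = c(m1 = 0.01, m2 = 0.02)), model)
  expect_equal(pm$mu, 0.1)
  # all mediator betas zero: mu = 0, se from the theta-level terms only
  pm0 <- predict_mediated_effect(list(beta = c(m1 = 0, m2 = 0),
                                      se = c(m1 = 0.01, m2 = 0.02)), model)
  expect_equal(pm0$mu, 0)
  expect_equal(pm0$se_mu, sqrt(0.5^2 * 0.01^2 + 0.2^2 * 0.02^2))
  expect_error(predict_mediated_effect(list(beta = c(m1 = 0.2, m2 = NA),
                                            se = c(m1 = 0.01, m2 = 0.02)),
                                       model),
               "not correctable")

  # Monte-Carlo check of the independence-propagated SE
  set.seed(71)
  b <- c(0.15, -0.1); se_b <- c(0.02, 0.03)
  th <- c(0.5, -0.2); se_th <- c(0.05, 0.04)
  draws <- replicate(1e5,
    sum(rnorm(2, th, se_th) * rnorm(2, b, se_b)))
  pm2 <- predict_mediated_effect(list(beta = c(m1 = b[1], m2 = b[2]),
                                      se = c(m1 = se_b[1], m2 = se_b[2])),
                                 model)
  expect_equal(pm2$se_mu, sd(draws), tolerance = 0.05)
})

test_that("a null mediator model leaves the statistics untouched with CUR
           exactly 1", {
  focal <- make_sumstats(30L, seed = 73)
  null_model <- structure(list(focal_trait = "t",
                               mediators = data.frame(trait = character(0),
                                                      theta = numeric(0),
                                                      se_theta = numeric(0)),
                               selection_path = NULL,
                               instruments = character(0), prior_r2 = 0),
                          class = "mediator_model")
  ce <- correct_effects(focal, null_model, list())
  expect_identical(ce$corr_beta, focal$beta)
  expect_identical(ce$corr_se, focal$se)
  expect_true(all(ce$cur == 1))
  # classification guard: weak variants stay uncertain even at CUR = 1
  weak <- abs(focal$beta) < 2 * focal$se
  expect_true(all(ce$type[weak] == "uncertain"))
  expect_true(all(ce$type[!weak] == "non-mediated"))
})

test_that("corrected standard errors never shrink and missing mediator data
           flags variants as uncertain", {
  scene <- make_mediation_scene(75)
  model <- fit_prior(scene$focal, list(X = scene$med))
  med_short <- scene$med[-(1:3), ]
  class(med_short) <- class(scene$med)
  attr(med_short, "trait") <- "X"
  ce <- correct_effects(scene$focal, model, list(X = med_short))
  expect_true(all(ce$corr_se >= ce$se, na.rm = TRUE))
  miss <- ce$variant_id %in% scene$med$variant_id[1:3]
  expect_true(all(ce$type[miss] == "uncertain"))
  expect_true(all(ce$reason[miss] == "missing mediator estimate"))
  expect_true(all(is.na(ce$corr_beta[miss])))
})

test_that("a sample-overlap correlation shrinks the corrected variance", {
  scene <- make_mediation_scene(76)
  model <- fit_prior(scene$focal, list(X = scene$med))
  ce0 <- correct_effects(scene$focal, model, list(X = scene$med))
  ce_ov <- correct_effects(scene$focal, model, list(X = scene$med),
                           overlap_rho = 0.5)
  th <- model$mediators$theta
  expect_true(all(ce_ov$corr_se * sign(th) <= ce0$corr_se * sign(th)))
  expect_equal(ce_ov$corr_beta, ce0$corr_beta)
})

test_that("the stepwise prior keeps the null model when no mediation is
           simulated", {
  # four candidate mediators, none with any causal effect on the focal
  # trait: the model should stay empty in nearly every replicate
  n_rep <- 200L
  picked <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_individuals = 50000L, n_gy = 15, n_gx = 15,
                      var_gx = 0.3, beta_xy = 0, seed = 1000L + r)
    sims <- simulate_sumstats(cfg, traits = c("Yo", "X", "U"))
    # candidates: the true (but null-effect) trait X plus permuted decoys
    decoy <- function(s, k) {
      d <- s
      d$beta <- s$beta[(seq_len(nrow(s)) + k) %% nrow(s) + 1L]
      attr(d, "trait") <- paste0("decoy", k)
      d
    }
    model <- fit_prior(sims$Yo,
                       list(X = sims$X, d1 = decoy(sims$X, 3),
                            d2 = decoy(sims$X, 7), d3 = decoy(sims$X, 11)))
    picked[r] <- nrow(model$mediators)
  }
  expect_gte(mean(picked == 0L), 0.95)
})

test_that("the stepwise prior recovers a single true mediator and its
           effect", {
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    scene <- make_mediation_scene(2000L + r, beta_xy = 0.3)
    decoy <- scene$med
    decoy$beta <- rnorm(nrow(decoy), 0, 0.002)
    decoy$pval <- pmax(2 * pnorm(-abs(decoy$beta / decoy$se)), 1e-300)
    attr(decoy, "trait") <- "decoy"
    model <- fit_prior(scene$focal,
                       list(X = scene$med, d1 = decoy))
    if (nrow(model$mediators) >= 1L && "X" %in% model$mediators$trait) {
      hits <- hits + 1L
      # theta is the X -> Yo effect on the observed standardized scale
      d <- 1
      sd_y <- sqrt(1 + 0.3^2)
      theta_true <- sqrt(0.7) * 0.3 / sd_y
      row <- model$mediators[model$mediators$trait == "X", ]
      expect_lt(abs(row$theta - theta_true), 4 * row$se_theta)
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("variance explained is 0 under the null model, near 1 under
           saturated mediation, and always a proportion", {
  scene <- make_mediation_scene(77)
  null_model <- structure(list(focal_trait = "Yo",
                               mediators = data.frame(trait = character(0),
                                                      theta = numeric(0),
                                                      se_theta = numeric(0)),
                               selection_path = NULL,
                               instruments = character(0), prior_r2 = 0),
                          class = "mediator_model")
  expect_equal(variance_explained(scene$focal, null_model, list()), 0)

  # saturated mediation: every focal variant acts through X
  cfg <- sim_config(n_individuals = 200000L, n_gy = 0, n_gx = 40,
                    var_gx = 0.4, beta_xy = 0.5, retest_r = 1, seed = 79)
  sims <- simulate_sumstats(cfg, traits = c("Yo", "X"))
  model <- fit_prior(sims$Yo, list(X = sims$X))
  ve <- variance_explained(sims$Yo, model, list(X = sims$X))
  expect_gt(ve, 0.9)
  expect_lte(ve, 1)
  expect_error(variance_explained(scene$focal, null_model, list(),
                                  variants = scene$focal$variant_id[1:3]),
               "insufficient data")
})

test_that("CUR separates direct from mediated variants when reverse
           causation is absent", {
  scene <- make_mediation_scene(81, n = 100000L, beta_xy = 0.3)
  model <- fit_prior(scene$focal, list(X = scene$med))
  ce <- correct_effects(scene$focal, model, list(X = scene$med))
  m <- merge(as.data.frame(ce), scene$truth[c("variant_id", "class")])
  sig <- m[m$pval <= 5e-8, ]
  gy <- sig[sig$class == "Gy", ]
  gx <- sig[sig$class == "Gx", ]
  expect_gt(nrow(gy), 10)
  expect_gt(nrow(gx), 10)
  expect_gt(mean(gy$type == "non-mediated"), 0.8)
  expect_gt(mean(gx$type == "uncertain"), 0.8)
  expect_gt(median(abs(gx$cur - 1)), 0.05)
})

test_that("CUR filtering reduces confounding bias of downstream IVW", {
  # confounded scenario: Gu acts on both the food trait and the health
  # outcome, true food -> outcome effect zero; IVW on all significant
  # instruments is biased, IVW on non-mediated instruments is not
  n_rep <- 60L
  bias_raw <- bias_flt <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_individuals = 100000L, n_gy = 30, n_gx = 0,
                      n_gu = 30, var_gu = 0.3, var_gy = 0.1,
                      beta_ux = 0.3, beta_uy = 0.3, seed = 3000L + r)
    sims <- simulate_sumstats(cfg, traits = c("Yo", "X", "U"))
    model <- fit_prior(sims$Yo, list(U = sims$U))
    ce <- correct_effects(sims$Yo, model, list(U = sims$U))
    instruments <- ce$variant_id[ce$pval <= 5e-8]
    keep <- intersect(instruments,
                      ce$variant_id[ce$type == "non-mediated"])
    h <- harmonize(sims$Yo, sims$X)
    if (length(instruments) >= 2L)
      bias_raw[r] <- mr_ivw(mr_input(h, variants = instruments))$b
    if (length(keep) >= 2L)
      bias_flt[r] <- mr_ivw(mr_input(h, variants = keep))$b
  }
  ok <- !is.na(bias_raw) & !is.na(bias_flt)
  expect_gt(mean(ok), 0.9)
  expect_lt(median(abs(bias_flt[ok])), median(abs(bias_raw[ok])))
})
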