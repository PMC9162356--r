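#' Pipeline configuration and derived thresholds
#'
#' Holds the study-wide thresholds. The genome-wide significance threshold
#' for food-trait instrument discovery is derived by Bonferroni correction of
#' the conventional `gw_p = 5e-8` over the number of independent food-trait
#' groups (default 5), giving 1e-8.
#'
#' @param n_food_groups number of independent food-trait families used for
#'   the Bonferroni derivation (default 5).
#' @param gw_p conventional genome-wide threshold (default 5e-8); also the
#'   instrument threshold for health-trait exposures and mediators.
#' @param r2_max LD pruning threshold (default 0.001).
#' @param cur_window CUR classification half-width (default 0.05).
#' @param q_target q-value significance target (default 0.05).
#' @param het_q_p heterogeneity p threshold for stepwise pruning and flags
#'   (default 0.05).
#' @param palindrome_eaf_limit see [harmonize()].
#' @param seed integer seed driving every stochastic step of [run_study()].
#' @return A `pipeline_config` with the derived `food_instrument_p`.
#' @export
pipeline_config <- function(n_food_groups = 5L, gw_p = 5e-8,
                            r2_max = 0.001, cur_window = 0.05,
                            q_target = 0.05, het_q_p = 0.05,
                            palindrome_eaf_limit = 0.08, seed = 1L) {
  for (v in c(gw_p, r2_max, q_target, het_q_p))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  if (gw_p > 5e-8 + 1e-20)
    stop("gw_p must not exceed the 5e-8 family default")
  if (n_food_groups < 1L) stop("n_food_groups must be >= 1")
  structure(list(n_food_groups = as.integer(n_food_groups), gw_p = gw_p,
                 food_instrument_p = gw_p / n_food_groups,
                 r2_max = r2_max, cur_window = cur_window,
                 q_target = q_target, het_q_p = het_q_p,
                 palindrome_eaf_limit = palindrome_eaf_limit,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline config\n",
      "  food instrument threshold: ", format(x$food_instrument_p),
      " (", format(x$gw_p), " / ", x$n_food_groups, " groups)\n",
      "  LD r2 < ", x$r2_max, ", CUR window 1 ± ", x$cur_window,
      ", q < ", x$q_target, "\n", sep = "")
  invisible(x)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid
#' `#{p > lambda} / (m (1 - lambda))`, smooths it with a cubic smoothing
#' spline and evaluates the smoother at the largest lambda; q-values are the
#' pi0-scaled step-up quantities, monotonized so q is non-decreasing in p and
#' capped at 1. With fewer than 20 p-values pi0 cannot be estimated stably
#' and the function falls back to Benjamini-Hochberg with a warning.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param lambda grid for pi0 estimation (default 0.05 to 0.95 by 0.05).
#' @return q-values in the order of `pvals`; the pi0 estimate is attached as
#'   attribute `"pi0"`.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("all p-values must lie in (0, 1]")
  m <- length(p)
  if (m < 20L) {
    warning("fewer than 20 p-values: falling back to Benjamini-Hochberg")
    q <- stats::p.adjust(p, method = "BH")
    attr(q, "pi0") <- 1
    return(q)
  }
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Direction concordance between discovery and replication effects
#'
#' Fraction of shared variants whose discovery and replication effects agree
#' in sign, with an exact two-sided binomial test against 0.5, plus the
#' fraction reaching nominal significance in replication with an exact
#' binomial test against 0.05.
#'
#' @param discovery data.frame with columns `variant_id` (or `variant`) and
#'   `beta`.
#' @param replication data.frame with columns `variant_id`/`variant`, `beta`
#'   and `pval` (or `p`).
#' @return list: `n_shared`, `concordant_fraction`, `concordance_p`,
#'   `nominal_fraction`, `nominal_p`.
#' @export
replication_concordance <- function(discovery, replication) {
  idcol <- function(d) if ("variant_id" %in% names(d)) "variant_id" else "variant"
  pcol <- if ("pval" %in% names(replication)) "pval" else "p"
  shared <- intersect(discovery[[idcol(discovery)]],
                      replication[[idcol(replication)]])
  if (length(shared) == 0L)
    stop("no shared variants between discovery and replication")
  bd <- discovery$beta[match(shared, discovery[[idcol(discovery)]])]
  br <- replication$beta[match(shared, replication[[idcol(replication)]])]
  pr <- replication[[pcol]][match(shared, replication[[idcol(replication)]])]
  k_conc <- sum(sign(bd) == sign(br))
  k_nom <- sum(pr < 0.05)
  n <- length(shared)
  list(n_shared = n,
       concordant_fraction = k_conc / n,
       concordance_p = stats::binom.test(k_conc, n, 0.5)$p.value,
       nominal_fraction = k_nom / n,
       nominal_p = stats::binom.test(k_nom, n, 0.05)$p.value)
}

# one exposure -> outcome reverse-direction fit with the Egger-intercept
# switch rule
.reverse_pair <- function(exposure, outcome, config, ld) {
  instruments <- if (is.null(ld)) {
    exposure$variant_id[exposure$pval <= config$gw_p]
  } else {
    ld_prune(exposure, ld, config$r2_max, config$gw_p)$variant_id
  }
  base <- data.frame(exposure = attr(exposure, "trait"),
                     outcome = attr(outcome, "trait"),
                     method = NA_character_, nsnp = 0L,
                     b = NA_real_, se = NA_real_, pval = NA_real_,
                     het_p = NA_real_, egger_pleio = NA_real_,
                     n_pruned = 0L, reason = NA_character_,
                     stringsAsFactors = FALSE)
  if (length(instruments) < 2L) {
    base$reason <- "fewer than 2 instruments"
    return(base)
  }
  h <- tryCatch(harmonize(exposure, outcome, config$palindrome_eaf_limit),
                error = function(e) NULL)
  if (is.null(h) || sum(h$pairs$variant_id %in% instruments) < 2L) {
    base$reason <- "fewer than 2 instruments after harmonization"
    return(base)
  }
  input <- mr_input(h, variants = instruments)
  n_pruned <- 0L
  if (nrow(input$data) >= 3L) {
    pruned <- tryCatch(stepwise_het_prune(input, config$het_q_p),
                       error = function(e) input)
    n_pruned <- nrow(input$data) - nrow(pruned$data)
    input <- pruned
  }
  fit <- mr_ivw(input, mode = "auto")
  egger_p <- NA_real_
  if (nrow(input$data) >= 3L) {
    eg <- tryCatch(mr_egger(input), error = function(e) NULL)
    if (!is.null(eg)) {
      egger_p <- eg$egger_intercept_p
      if (egger_p < 0.05) fit <- eg  # the directional-pleiotropy switch
    }
  }
  base$method <- fit$method
  base$nsnp <- fit$nsnp
  base$b <- fit$b
  base$se <- fit$se
  base$pval <- fit$pval
  base$het_p <- fit$q_pval
  base$egger_pleio <- egger_p
  base$n_pruned <- n_pruned
  base
}

#' Reverse-direction MR screen: health exposures on food outcomes
#'
#' For every exposure/outcome pair: instrument selection at the conventional
#' genome-wide threshold (LD-pruned when a matrix is supplied), stepwise
#' heterogeneity pruning, IVW with automatic fixed/random-effects choice,
#' and the switch rule by which the MR-Egger estimate replaces IVW when the
#' Egger intercept differs from zero at p < 0.05. q-values are computed
#' across all testable pairs.
#'
#' @param health_exposures,food_outcomes named lists of [sumstats].
#' @param config a [pipeline_config].
#' @param ld optional [ld_matrix].
#' @return data.frame, one row per pair, with estimate, diagnostics and
#'   `qval` (class `study_section`).
#' @export
reverse_mr_screen <- function(health_exposures, food_outcomes, config,
                              ld = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- list()
  for (ex in health_exposures) for (out in food_outcomes)
    rows[[length(rows) + 1L]] <- .reverse_pair(ex, out, config, ld)
  res <- do.call(rbind, rows)
  ok <- !is.na(res$pval)
  res$qval <- NA_real_
  if (sum(ok) >= 2L)
    res$qval[ok] <- suppressWarnings(storey_qvalues(res$pval[ok]))
  class(res) <- c("study_section", "data.frame")
  res
}

# one forward pair: radial outliers, IVW auto, Egger / median / RAPS as
# sensitivity analyses
.forward_pair <- function(exposure, outcome, instruments, config, seed,
                          mode) {
  base <- data.frame(exposure = attr(exposure, "trait"),
                     outcome = attr(outcome, "trait"),
                     method = NA_character_, nsnp = 0L,
                     b = NA_real_, se = NA_real_, pval = NA_real_,
                     type = if (mode == "raw") "Uncorrected" else "Corrected",
                     outliers = 0L, egger_pleio = NA_real_,
                     beta_egger = NA_real_, se_egger = NA_real_,
                     beta_median = NA_real_, se_median = NA_real_,
                     mr_raps_beta = NA_real_, mr_raps_se = NA_real_,
                     het_p = NA_real_, reason = NA_character_,
                     stringsAsFactors = FALSE)
  if (length(instruments) < 1L) {
    base$reason <- "no instruments"
    return(base)
  }
  h <- tryCatch(harmonize(exposure, outcome, config$palindrome_eaf_limit),
                error = function(e) NULL)
  if (is.null(h) || sum(h$pairs$variant_id %in% instruments) < 1L) {
    base$reason <- "no instruments after harmonization"
    return(base)
  }
  input <- mr_input(h, variants = instruments)
  outliers <- character(0)
  if (nrow(input$data) >= 3L) {
    rad <- tryCatch(radial_outliers(input, alpha = 0.05),
                    error = function(e) NULL)
    if (!is.null(rad)) {
      outliers <- rad$outliers
      input <- rad$input
    }
  }
  fit <- mr_ivw(input, mode = "auto")
  base$method <- fit$method
  base$nsnp <- fit$nsnp
  base$b <- fit$b
  base$se <- fit$se
  base$pval <- fit$pval
  base$het_p <- fit$q_pval
  base$outliers <- length(outliers)
  if (nrow(input$data) >= 3L) {
    eg <- tryCatch(mr_egger(input), error = function(e) NULL)
    if (!is.null(eg)) {
      base$egger_pleio <- eg$egger_intercept_p
      base$beta_egger <- eg$b
      base$se_egger <- eg$se
    }
    wm <- tryCatch(mr_weighted_median(input, n_boot = 500L, seed = seed),
                   error = function(e) NULL)
    if (!is.null(wm)) {
      base$beta_median <- wm$b
      base$se_median <- wm$se
    }
    rp <- tryCatch(mr_raps(input), error = function(e) NULL)
    if (!is.null(rp)) {
      base$mr_raps_beta <- rp$b
      base$mr_raps_se <- rp$se
    }
  }
  base
}

#' Forward MR of food exposures on health outcomes, raw or CUR-filtered
#'
#' Instrument selection uses the uncorrected p-values at the derived
#' food-trait threshold; in `cur_filtered` mode only variants labelled
#' non-mediated by the mediation correction are retained as instruments.
#' Exposure weights are always the uncorrected effects. Each pair goes
#' through radial outlier removal, IVW (automatic fixed/random effects),
#' and MR-Egger, weighted-median and MR-RAPS sensitivity analyses; Storey
#' q-values are computed across all testable pairs.
#'
#' @param food_exposures named list of [sumstats] (including projected PC
#'   traits).
#' @param outcomes named list of [sumstats].
#' @param config a [pipeline_config].
#' @param mode `"raw"` or `"cur_filtered"`.
#' @param corrected named list (matching `food_exposures`) of
#'   [correct_effects()] results or of projected stats carrying a `type`
#'   column; required in `cur_filtered` mode.
#' @param ld optional [ld_matrix].
#' @param seed seed for the bootstrap SEs.
#' @return data.frame, one row per pair (class `study_section`).
#' @export
forward_mr <- function(food_exposures, outcomes, config,
                       mode = c("raw", "cur_filtered"), corrected = NULL,
                       ld = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  if (mode == "cur_filtered" && is.null(corrected))
    stop("cur_filtered mode requires the corrected effects")
  rows <- list()
  i <- 0L
  for (en in names(food_exposures)) {
    ex <- food_exposures[[en]]
    instruments <- if (is.null(ld)) {
      ex$variant_id[ex$pval <= config$food_instrument_p]
    } else {
      ld_prune(ex, ld, config$r2_max,
               config$food_instrument_p)$variant_id
    }
    if (mode == "cur_filtered") {
      ce <- corrected[[en]]
      if (is.null(ce)) stop("no corrected effects for exposure '", en, "'")
      ce <- as.data.frame(ce)
      keep <- ce$variant_id[ce$type == "non-mediated"]
      instruments <- intersect(instruments, keep)
    }
    for (out in outcomes) {
      i <- i + 1L
      rows[[length(rows) + 1L]] <-
        .forward_pair(ex, out, instruments, config, seed + i, mode)
    }
  }
  res <- do.call(rbind, rows)
  ok <- !is.na(res$pval)
  res$qval <- NA_real_
  if (sum(ok) >= 2L)
    res$qval[ok] <- suppressWarnings(storey_qvalues(res$pval[ok]))
  # heterogeneous pairs are flagged (multiple-testing corrected), never
  # dropped
  res$het_flag <- FALSE
  okh <- !is.na(res$het_p)
  if (sum(okh) >= 2L)
    res$het_flag[okh] <-
      suppressWarnings(storey_qvalues(res$het_p[okh])) <= 0.05
  class(res) <- c("study_section", "data.frame")
  res
}

#' Configuration for a multi-trait synthetic study
#'
#' Defines an acyclic multi-trait system for pipeline-level simulation: a
#' (possibly unobserved) confounder U, `n_health` health-determinant traits
#' influenced by U and influencing every food trait (`theta_hf`), `n_food`
#' reported food traits with their own direct variants and questionnaire
#' noise, and `n_outcome` downstream outcome traits receiving `theta_fo`
#' from every food. Every trait has exactly unit variance by construction
#' (residual noise absorbs the remainder); summary statistics for each trait
#' are drawn from the asymptotic sampling distribution in independent
#' samples (two-sample design). For the bidirectional single-food system use
#' [sim_config()]/[simulate_cohort()].
#'
#' @param n_food,n_health,n_outcome trait counts.
#' @param n_gy,n_gh,n_go,n_gu variants per food/health/outcome trait and for
#'   the confounder.
#' @param var_gy,var_gh,var_go,var_gu variance explained by each trait's own
#'   variants.
#' @param theta_hf effect of each health trait on each food (scalar or
#'   `n_health` x `n_food` matrix).
#' @param theta_fo causal effect of each food on each outcome (scalar or
#'   `n_food` x `n_outcome` matrix).
#' @param b_uh,b_uf,b_uo confounder effects on health, food and outcome
#'   traits.
#' @param retest_r questionnaire test-retest reliability of the observed
#'   food traits.
#' @param n GWAS sample size per trait.
#' @param maf_range minor-allele-frequency range.
#' @param observe_u emit summary statistics for U as a trait (`"U"`).
#' @param seed integer seed.
#' @return A `study_config`.
#' @export
study_config <- function(n_food = 4L, n_health = 2L, n_outcome = 2L,
                         n_gy = 25L, n_gh = 30L, n_go = 30L, n_gu = 25L,
                         var_gy = 0.1, var_gh = 0.3, var_go = 0.3,
                         var_gu = 0.3,
                         theta_hf = 0.2, theta_fo = 0,
                         b_uh = 0.3, b_uf = 0.3, b_uo = 0.3,
                         retest_r = 0.7, n = 100000L,
                         maf_range = c(0.05, 0.5), observe_u = FALSE,
                         seed = 1L) {
  cfg <- list(n_food = as.integer(n_food), n_health = as.integer(n_health),
              n_outcome = as.integer(n_outcome),
              n_gy = as.integer(n_gy), n_gh = as.integer(n_gh),
              n_go = as.integer(n_go), n_gu = as.integer(n_gu),
              var_gy = var_gy, var_gh = var_gh, var_go = var_go,
              var_gu = var_gu,
              theta_hf = theta_hf, theta_fo = theta_fo,
              b_uh = b_uh, b_uf = b_uf, b_uo = b_uo,
              retest_r = retest_r, n = as.integer(n),
              maf_range = as.numeric(maf_range),
              observe_u = isTRUE(observe_u), seed = as.integer(seed))
  if (cfg$n_food < 1L) stop("need at least one food trait")
  if (retest_r <= 0 || retest_r > 1) stop("retest_r must lie in (0, 1]")
  cfg$theta_hf <- matrix(theta_hf, cfg$n_health, cfg$n_food)
  cfg$theta_fo <- matrix(theta_fo, cfg$n_food, cfg$n_outcome)
  structure(cfg, class = "study_config")
}

#' Simulate summary statistics for a multi-trait study
#'
#' @param config a [study_config].
#' @return list with `stats` (named list of [sumstats]: health traits, then
#'   observed food traits, then outcomes, plus `"U"` when observed),
#'   `truth` (per-variant table: class, owner trait, maf, true standardized
#'   beta on every trait) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  set.seed(cfg$seed)
  food_names <- paste0("food", seq_len(cfg$n_food))
  health_names <- if (cfg$n_health) paste0("health", seq_len(cfg$n_health))
  else character(0)
  outcome_names <- if (cfg$n_outcome)
    paste0("outcome", seq_len(cfg$n_outcome)) else character(0)

  owner <- c(rep("U", cfg$n_gu),
             rep(health_names, each = cfg$n_gh),
             rep(food_names, each = cfg$n_gy),
             rep(outcome_names, each = cfg$n_go))
  n_var <- length(owner)
  cls <- ifelse(owner == "U", "Gu",
                ifelse(owner %in% health_names, "Gh",
                       ifelse(owner %in% food_names, "Gy", "Go")))
  maf <- stats::runif(n_var, cfg$maf_range[1], cfg$maf_range[2])
  v <- 2 * maf * (1 - maf)
  sgn <- sample(c(-1, 1), n_var, replace = TRUE)
  per_var <- c(Gu = if (cfg$n_gu) cfg$var_gu / cfg$n_gu else 0,
               Gh = if (cfg$n_gh) cfg$var_gh / cfg$n_gh else 0,
               Gy = if (cfg$n_gy) cfg$var_gy / cfg$n_gy else 0,
               Go = if (cfg$n_go) cfg$var_go / cfg$n_go else 0)
  b_own <- sgn * sqrt(per_var[cls] / v)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- sample.int(4L, n_var, replace = TRUE)
  vtab <- data.frame(variant_id = sprintf("rs%05d", seq_len(n_var)),
                     class = cls, owner = owner, maf = maf,
                     effect_allele = pairs[pick, 1],
                     other_allele = pairs[pick, 2],
                     stringsAsFactors = FALSE)

  # each trait is a linear combination of independent primitives: the
  # centered dosages (variance v) plus one unit-variance noise primitive per
  # generated trait; variances and true betas are then exact
  prim_var <- v
  rows <- list()
  add_trait <- function(name, genetic_owner, parents = character(0),
                        parent_coefs = numeric(0), noise_scale = 1) {
    coef <- rep(0, length(prim_var))
    if (!is.null(genetic_owner))
      coef[seq_len(n_var)][owner == genetic_owner] <-
        b_own[owner == genetic_owner]
    for (i in seq_along(parents)) {
      pr <- rows[[parents[i]]]
      coef[seq_along(pr)] <- coef[seq_along(pr)] + parent_coefs[i] * pr
    }
    var_sofar <- sum(coef^2 * prim_var)
    if (var_sofar > 1 + 1e-10)
      stop("trait '", name, "' over-determined: structural variance ",
           format(var_sofar, digits = 4), " exceeds 1")
    prim_var <<- c(prim_var, 1)
    coef <- c(coef, sqrt(max(1 - var_sofar, 0)) * noise_scale)
    rows[[name]] <<- coef
    invisible(NULL)
  }
  add_trait("U", "U")
  for (j in seq_len(cfg$n_health))
    add_trait(health_names[j], health_names[j], "U", cfg$b_uh)
  for (i in seq_len(cfg$n_food)) {
    add_trait(paste0(food_names[i], "_true"), food_names[i],
              c(health_names, "U"), c(cfg$theta_hf[, i], cfg$b_uf))
    # questionnaire measurement: shrink the true trait and add item noise
    coef_true <- rows[[paste0(food_names[i], "_true")]]
    prim_var <- c(prim_var, 1)
    rows[[food_names[i]]] <- c(sqrt(cfg$retest_r) * coef_true,
                               rep(0, length(prim_var) - 1L -
                                     length(coef_true)),
                               sqrt(1 - cfg$retest_r))
  }
  for (l in seq_len(cfg$n_outcome))
    add_trait(outcome_names[l], outcome_names[l],
              c(paste0(food_names, "_true"), "U"),
              c(cfg$theta_fo[, l], cfg$b_uo))

  emit <- c(health_names, food_names, outcome_names,
            if (cfg$observe_u) "U")
  beta_true <- vapply(emit, function(tn) {
    rows[[tn]][seq_len(n_var)]
  }, numeric(n_var))
  stats <- list()
  for (tn in emit) {
    bt <- beta_true[, tn]
    se <- sqrt(pmax(1 - bt^2 * v, 0.01) / (cfg$n * v))
    bh <- stats::rnorm(n_var, bt, se)
    p <- pmax(2 * stats::pnorm(-abs(bh / se)), .Machine$double.xmin)
    stats[[tn]] <- sumstats(data.frame(variant_id = vtab$variant_id,
                                       effect_allele = vtab$effect_allele,
                                       other_allele = vtab$other_allele,
                                       eaf = maf, beta = bh, se = se,
                                       pval = p, n = cfg$n,
                                       stringsAsFactors = FALSE),
                            trait = tn, quiet = TRUE)
  }
  truth <- cbind(vtab, as.data.frame(beta_true))
  names(truth)[seq.int(ncol(vtab) + 1L, length.out = length(emit))] <-
    paste0("beta_", emit)
  list(stats = stats, truth = truth, config = cfg,
       trait_groups = list(health = health_names, food = food_names,
                           outcome = outcome_names))
}

#' Run the full synthetic study: screen, correct, classify, project, MR
#'
#' Orchestrates the complete analysis on a simulated multi-trait study:
#' reverse MR screen (health on food), mediator-model fitting and mediation
#' correction per food trait, CUR classification tallies, clustering of the
#' corrected food z-score correlation matrix, leading-PC dietary-pattern
#' construction with per-variant projection of both original and corrected
#' effects, and forward MR of foods (and PC traits) on the outcome traits in
#' both raw and CUR-filtered modes. Deterministic under the pipeline seed.
#'
#' @param config a [study_config].
#' @param pconfig a [pipeline_config].
#' @return A `study_report`: sections `reverse`, `forward_raw`,
#'   `forward_filtered`, `classification`, `mediator_models`, `clusters`,
#'   `pc_traits`, plus the configs.
#' @export
run_study <- function(config, pconfig = pipeline_config()) {
  stopifnot(inherits(config, "study_config"),
            inherits(pconfig, "pipeline_config"))
  sim <- simulate_study(config)
  health <- sim$stats[sim$trait_groups$health]
  foods <- sim$stats[sim$trait_groups$food]
  outcomes <- sim$stats[sim$trait_groups$outcome]

  reverse <- if (length(health) && length(foods))
    reverse_mr_screen(health, foods, pconfig) else NULL

  models <- list()
  corrected <- list()
  classification <- list()
  for (fn in names(foods)) {
    models[[fn]] <- if (length(health))
      fit_prior(foods[[fn]], health, p_instr = pconfig$gw_p)
    else structure(list(focal_trait = fn,
                        mediators = data.frame(trait = character(0),
                                               theta = numeric(0),
                                               se_theta = numeric(0)),
                        selection_path = NULL, instruments = character(0),
                        prior_r2 = 0), class = "mediator_model")
    corrected[[fn]] <- correct_effects(foods[[fn]], models[[fn]], health,
                                       window = pconfig$cur_window)
    sig <- corrected[[fn]][corrected[[fn]]$pval <=
                             pconfig$food_instrument_p, ]
    classification[[fn]] <- data.frame(
      exposure = fn, n_significant = nrow(sig),
      non_mediated = sum(sig$type == "non-mediated"),
      uncertain = sum(sig$type == "uncertain"),
      prior_r2 = models[[fn]]$prior_r2, stringsAsFactors = FALSE)
  }
  classification <- do.call(rbind, classification)
  rownames(classification) <- NULL

  clusters <- NULL
  pcs <- list()
  proj <- list()
  proj_corr_info <- list()
  if (length(foods) >= 2L) {
    Z <- sapply(names(foods), function(fn) {
      ce <- corrected[[fn]]
      z <- ce$corr_beta / ce$corr_se
      z[!is.finite(z)] <- 0
      z
    })
    rg <- stats::cor(Z)
    clusters <- cluster_traits(trait_cor_matrix(rg))
    corr <- trait_cor_matrix(rg)
    groups <- Filter(function(g) length(g) >= 2L, clusters$groups)
    if (length(groups) == 0L ||
        !any(vapply(groups, length, 0L) == length(foods)))
      groups <- c(groups, list(names(foods)))  # overall dietary pattern
    for (gi in seq_along(groups)) {
      nm <- if (length(groups[[gi]]) == length(foods)) "all_foods_pc"
      else paste0("pc_group", gi)
      pcs[[nm]] <- pc_rotation(corr, groups[[gi]], name = nm)
      proj[[nm]] <- project_effects(foods, pcs[[nm]],
                                    corrected = corrected,
                                    window = pconfig$cur_window)
      proj_corr_info[[nm]] <- proj[[nm]]
    }
  }
  exposures <- c(foods, proj)
  cur_info <- c(corrected, proj_corr_info)
  forward_raw <- forward_mr(exposures, outcomes, pconfig, mode = "raw",
                            seed = pconfig$seed)
  forward_filtered <- forward_mr(exposures, outcomes, pconfig,
                                 mode = "cur_filtered",
                                 corrected = cur_info,
                                 seed = pconfig$seed)
  structure(list(reverse = reverse, forward_raw = forward_raw,
                 forward_filtered = forward_filtered,
                 classification = classification,
                 mediator_models = models, clusters = clusters,
                 pc_traits = pcs, config = config, pconfig = pconfig),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat("Synthetic diet-health MR study report\n")
  if (!is.null(x$reverse))
    cat("  reverse screen: ", sum(!is.na(x$reverse$pval)), " testable pairs, ",
        sum(x$reverse$qval < x$pconfig$q_target, na.rm = TRUE),
        " significant at q < ", x$pconfig$q_target, "\n", sep = "")
  cat("  classification of significant food variants:\n")
  print.data.frame(format(x$classification, digits = digits))
  for (sec in c("forward_raw", "forward_filtered")) {
    s <- x[[sec]]
    cat("  ", sec, ": ", sum(!is.na(s$pval)), " testable pairs, ",
        sum(s$qval < x$pconfig$q_target, na.rm = TRUE),
        " significant at q < ", x$pconfig$q_target, "\n", sep = "")
  }
  invisible(x)
}
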