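#' Classify a corrected-to-uncorrected ratio
#'
#' A variant is `"non-mediated"` iff its CUR lies inside the window
#' `[1 - window, 1 + window]`, and `"uncertain"` otherwise. The window is
#' applied to the signed CUR, so sign flips after correction (CUR < 0) are
#' always uncertain. Non-finite CUR values (e.g. an observed beta of zero)
#' are uncertain.
#'
#' @param cur numeric vector of corrected-to-uncorrected ratios.
#' @param window half-width of the non-mediated window (default 0.05).
#' @return character vector of labels.
#' @export
classify_cur <- function(cur, window = 0.05) {
  stopifnot(is.numeric(window), window >= 0)
  out <- rep("uncertain", length(cur))
  ok <- is.finite(cur) & cur >= 1 - window & cur <= 1 + window
  out[ok] <- "non-mediated"
  out
}

# align a mediator's per-variant (beta, se) to the focal trait's allele
# coding; NA where the variant is absent or the alleles are irreconcilable
.align_to_focal <- function(focal, med) {
  i <- match(focal$variant_id, med$variant_id)
  beta <- med$beta[i]
  se <- med$se[i]
  same <- med$effect_allele[i] == focal$effect_allele &
    med$other_allele[i] == focal$other_allele
  swap <- med$effect_allele[i] == focal$other_allele &
    med$other_allele[i] == focal$effect_allele
  beta[which(swap)] <- -beta[which(swap)]
  bad <- !is.na(i) & !(same | swap)
  beta[bad] <- NA_real_
  se[bad] <- NA_real_
  list(beta = beta, se = se)
}

# per-variant prior mediated effect and its SE for a whole sumstats table;
# returns NA rows where any mediator estimate is unavailable
.prior_components <- function(focal, model, mediator_stats) {
  k <- nrow(model$mediators)
  nv <- nrow(focal)
  if (k == 0L)
    return(list(mu = rep(0, nv), se_mu = rep(0, nv),
                complete = rep(TRUE, nv)))
  missing_med <- setdiff(model$mediators$trait, names(mediator_stats))
  if (length(missing_med) > 0L)
    stop("mediator_stats lacks trait(s): ",
         paste(missing_med, collapse = ", "))
  B <- SEB <- matrix(NA_real_, nv, k)
  for (j in seq_len(k)) {
    al <- .align_to_focal(focal, mediator_stats[[model$mediators$trait[j]]])
    B[, j] <- al$beta
    SEB[, j] <- al$se
  }
  th <- model$mediators$theta
  se_th <- model$mediators$se_theta
  mu <- drop(B %*% th)
  se_mu <- sqrt(drop(SEB^2 %*% th^2) + drop(B^2 %*% se_th^2))
  complete <- rowSums(is.na(B)) == 0L
  list(mu = mu, se_mu = se_mu, complete = complete)
}

#' Prior mediated effect of one variant under a mediator model
#'
#' `mu = sum_k theta_k * b_k`, with variance propagated as
#' `se_mu^2 = sum_k (theta_k^2 se_bk^2 + b_k^2 se_thetak^2)` treating the
#' terms as independent.
#'
#' @param variant list with numeric vectors `beta` and `se`, named by
#'   mediator trait, giving the variant's effect on each mediator in `model`.
#' @param model a [fit_prior()] result.
#' @return list with `mu` and `se_mu`.
#' @export
predict_mediated_effect <- function(variant, model) {
  stopifnot(inherits(model, "mediator_model"))
  k <- nrow(model$mediators)
  if (k == 0L) return(list(mu = 0, se_mu = 0))
  traits <- model$mediators$trait
  b <- variant$beta[traits]
  se_b <- variant$se[traits]
  if (anyNA(b) || anyNA(se_b))
    stop("variant not correctable: missing mediator estimate for ",
         paste(traits[is.na(b) | is.na(se_b)], collapse = ", "))
  th <- model$mediators$theta
  se_th <- model$mediators$se_theta
  list(mu = sum(th * b),
       se_mu = sqrt(sum(th^2 * se_b^2 + b^2 * se_th^2)))
}

#' Fit the mediator model for a focal trait (modified-bGWAS prior)
#'
#' Forward stepwise selection of mediator traits whose causal effects on the
#' focal trait build the per-variant prior. For each candidate, instruments
#' are selected at `p_instr` (and LD-pruned at `r2_max` when an LD matrix is
#' supplied). Starting from the empty model, each step adds the candidate
#' that (a) has a Bonferroni-significant multivariable effect
#' (`p < entry_p / n_candidates`) and (b) most improves the K-fold
#' cross-validated prediction of the focal z-scores, measured as the mean
#' held-out correlation between prior and observed z-scores (causal effects
#' refit within each fold excluding the held-out instruments); the held-out
#' correlation must be positive and exceed the current model's, since an
#' anti-correlated prior is not predictive. Selection stops when no
#' candidate qualifies. Final causal
#' effects come from multivariable MR on the union instrument set of the
#' retained mediators; `prior_r2` is the squared prior/observed z-score
#' correlation across all shared variants.
#'
#' @param focal [sumstats] for the focal (food) trait.
#' @param mediators named list of candidate mediator [sumstats].
#' @param ld optional [ld_matrix] for instrument pruning.
#' @param p_instr instrument p-value threshold (default 5e-8).
#' @param r2_max LD pruning threshold (default 0.001).
#' @param k_folds folds for cross-validation (default 5).
#' @param entry_p base entry significance level, Bonferroni-corrected over
#'   the candidate pool (default 0.05).
#' @param min_instruments minimum usable instruments per candidate
#'   (default 3).
#' @return A `mediator_model`: focal trait label, retained `mediators`
#'   (data.frame `trait`, `theta`, `se_theta`), `selection_path`,
#'   `instruments`, `prior_r2` and the null-model flag. An empty retained set
#'   is the null model (all priors zero) and is returned with a warning when
#'   no candidate has valid instruments.
#' @export
fit_prior <- function(focal, mediators, ld = NULL,
                      p_instr = 5e-8, r2_max = 0.001,
                      k_folds = 5L, entry_p = 0.05,
                      min_instruments = 3L) {
  stopifnot(inherits(focal, "sumstats"), is.list(mediators),
            length(mediators) >= 1L)
  if (is.null(names(mediators)) || any(names(mediators) == ""))
    stop("mediators must be a named list")
  null_model <- function(path) {
    structure(list(focal_trait = attr(focal, "trait"),
                   mediators = data.frame(trait = character(0),
                                          theta = numeric(0),
                                          se_theta = numeric(0)),
                   selection_path = path, instruments = character(0),
                   prior_r2 = 0),
              class = "mediator_model")
  }
  instr <- lapply(mediators, function(m) {
    ids <- if (is.null(ld)) m$variant_id[m$pval <= p_instr] else
      ld_prune(m, ld, r2_max = r2_max, p_max = p_instr)$variant_id
    intersect(ids, focal$variant_id)
  })
  usable <- vapply(instr, length, 0L) >= min_instruments
  if (!any(usable)) {
    warning("no candidate mediator has >= ", min_instruments,
            " valid instruments; returning the null model")
    return(null_model(data.frame(step = integer(0), added = character(0),
                                 cv_r2 = numeric(0), pval = numeric(0))))
  }
  cands <- names(mediators)[usable]
  n_cands <- length(cands)
  gate_p <- entry_p / n_cands

  # evaluation set: variants shared by the focal trait and every usable
  # candidate, with deterministic fold assignment
  eval_ids <- focal$variant_id
  for (cn in cands) {
    al <- .align_to_focal(focal, mediators[[cn]])
    eval_ids <- eval_ids[!is.na(al$beta[match(eval_ids,
                                              focal$variant_id)])]
  }
  fold_of <- (seq_along(eval_ids) - 1L) %% k_folds + 1L
  names(fold_of) <- eval_ids
  z_obs <- focal$beta / focal$se
  names(z_obs) <- focal$variant_id

  fit_theta <- function(sel, ids) {
    mr_mvmr(mediators[sel], focal, ids)
  }
  # mean held-out correlation between prior and observed z-scores; the sign
  # matters: an anti-correlated prior is not predictive, so the squared
  # summary alone would reward chance entries
  cv_cor <- function(sel) {
    ids <- unique(unlist(instr[sel]))
    cors <- numeric(0)
    for (kf in seq_len(k_folds)) {
      test_ids <- eval_ids[fold_of == kf]
      train_ids <- setdiff(ids, test_ids)
      if (length(train_ids) < length(sel) + 1L || length(test_ids) < 3L)
        next
      th <- tryCatch(fit_theta(sel, train_ids), error = function(e) NULL)
      if (is.null(th)) next
      model_k <- structure(list(mediators = data.frame(
        trait = th$exposure, theta = th$theta, se_theta = th$se)),
        class = "mediator_model")
      sub <- focal[match(test_ids, focal$variant_id), , drop = FALSE]
      class(sub) <- class(focal)
      pc <- .prior_components(sub, model_k, mediators)
      z_prior <- pc$mu / sub$se
      cors <- c(cors, if (stats::sd(z_prior) == 0) 0 else
        stats::cor(z_prior, z_obs[test_ids]))
    }
    if (length(cors) == 0L) return(NA_real_)
    mean(cors)
  }

  selected <- character(0)
  best_cor <- 0
  path <- list()
  repeat {
    remaining <- setdiff(cands, selected)
    if (length(remaining) == 0L) break
    scores <- data.frame(cand = remaining, cv = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(scores))) {
      sel <- c(selected, scores$cand[i])
      ids <- unique(unlist(instr[sel]))
      th <- tryCatch(fit_theta(sel, ids), error = function(e) NULL)
      if (is.null(th)) next
      scores$p[i] <- th$pval[th$exposure == scores$cand[i]]
      scores$cv[i] <- cv_cor(sel)
    }
    ok <- !is.na(scores$cv) & !is.na(scores$p) &
      scores$p < gate_p & scores$cv > best_cor
    if (!any(ok)) break
    pick <- scores[ok, ][which.max(scores$cv[ok]), ]
    selected <- c(selected, pick$cand)
    best_cor <- pick$cv
    path[[length(path) + 1L]] <- data.frame(step = length(selected),
                                            added = pick$cand,
                                            cv_r2 = pick$cv^2,
                                            pval = pick$p,
                                            stringsAsFactors = FALSE)
  }
  path <- if (length(path)) do.call(rbind, path) else
    data.frame(step = integer(0), added = character(0),
               cv_r2 = numeric(0), pval = numeric(0))
  if (length(selected) == 0L) return(null_model(path))
  ids <- unique(unlist(instr[selected]))
  th <- fit_theta(selected, ids)
  model <- structure(list(focal_trait = attr(focal, "trait"),
                          mediators = data.frame(trait = th$exposure,
                                                 theta = th$theta,
                                                 se_theta = th$se,
                                                 pval = th$pval),
                          selection_path = path, instruments = ids,
                          prior_r2 = 0),
                     class = "mediator_model")
  model$prior_r2 <- variance_explained(focal, model, mediators)
  model
}

#' @export
print.mediator_model <- function(x, digits = 3, ...) {
  cat("Mediator model for '", x$focal_trait, "'\n", sep = "")
  if (nrow(x$mediators) == 0L) {
    cat("  null model: no mediators retained\n")
  } else {
    cat("  retained mediators (", length(x$instruments),
        " instruments):\n", sep = "")
    print.data.frame(format(x$mediators, digits = digits))
  }
  cat("  prior r2 (prior vs observed z-scores): ",
      format(x$prior_r2, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Correct per-variant effects for mediated components
#'
#' Subtracts the prior mediated effect from the observed effect of every
#' variant: `beta_corr = beta_obs - mu`, `se_corr = sqrt(se_obs^2 + se_mu^2)`
#' (variance is added, never removed), with a two-sided normal p-value, and
#' computes the corrected-to-uncorrected ratio `cur = beta_corr / beta_obs`.
#' Labels come from [classify_cur()], with two guards: variants whose
#' observed effect is indistinguishable from zero (`|beta_obs| < 2 se_obs`)
#' are labelled uncertain regardless of CUR (the ratio is noise-dominated),
#' and variants with any missing mediator estimate are not correctable and
#' are labelled uncertain with a reason.
#'
#' @param focal [sumstats] for the focal trait.
#' @param model a [fit_prior()] result (a null model leaves the statistics
#'   unchanged and every CUR exactly 1).
#' @param mediator_stats named list of [sumstats] supplying each retained
#'   mediator's per-variant effects.
#' @param window CUR classification half-width (default 0.05).
#' @param overlap_rho correlation between the focal estimate's error and
#'   each mediator estimate's error induced by sample overlap between the
#'   GWAS; 0 (the default) assumes non-overlapping samples. A non-zero
#'   value subtracts `2 * sum_k theta_k * rho * se_obs * se_bk` from the
#'   corrected variance (floored at the observed variance ratio 1e-6).
#' @return A `corrected_effects` object: data.frame with columns
#'   `variant_id`, `beta`, `se`, `pval`, `mu`, `se_mu`, `corr_beta`,
#'   `corr_se`, `corr_p`, `cur`, `type`, `reason`.
#' @export
correct_effects <- function(focal, model, mediator_stats, window = 0.05,
                            overlap_rho = 0) {
  stopifnot(inherits(focal, "sumstats"), inherits(model, "mediator_model"),
            abs(overlap_rho) <= 1)
  pc <- .prior_components(focal, model, mediator_stats)
  mu <- pc$mu
  se_mu <- pc$se_mu
  corr_beta <- focal$beta - mu
  cov_term <- if (overlap_rho != 0 && nrow(model$mediators) > 0L) {
    tot <- rep(0, nrow(focal))
    for (j in seq_len(nrow(model$mediators))) {
      al <- .align_to_focal(focal,
                            mediator_stats[[model$mediators$trait[j]]])
      tot <- tot + model$mediators$theta[j] * overlap_rho *
        focal$se * al$se
    }
    tot
  } else 0
  corr_se <- sqrt(pmax(focal$se^2 + se_mu^2 - 2 * cov_term,
                       1e-6 * focal$se^2))
  corr_p <- 2 * stats::pnorm(-abs(corr_beta / corr_se))
  cur <- ifelse(focal$beta == 0, NA_real_,
                ifelse(mu == 0, 1, corr_beta / focal$beta))
  type <- classify_cur(cur, window)
  reason <- rep(NA_character_, nrow(focal))
  weak <- abs(focal$beta) < 2 * focal$se
  type[weak] <- "uncertain"
  reason[weak] <- "observed effect within 2 SE of zero"
  reason[focal$beta == 0] <- "undefined CUR: observed beta is zero"
  nc <- !pc$complete
  type[nc] <- "uncertain"
  mu[nc] <- NA_real_
  se_mu[nc] <- NA_real_
  corr_beta[nc] <- NA_real_
  corr_se[nc] <- NA_real_
  corr_p[nc] <- NA_real_
  cur[nc] <- NA_real_
  reason[nc] <- "missing mediator estimate"
  out <- data.frame(variant_id = focal$variant_id,
                    beta = focal$beta, se = focal$se, pval = focal$pval,
                    mu = mu, se_mu = se_mu,
                    corr_beta = corr_beta, corr_se = corr_se,
                    corr_p = corr_p, cur = cur, type = type,
                    reason = reason, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("corrected_effects", "data.frame"),
            trait = attr(focal, "trait"), window = window,
            model = model)
}

#' @export
print.corrected_effects <- function(x, ...) {
  cat("Mediation-corrected effects for '", attr(x, "trait"), "' (",
      nrow(x), " variants, CUR window 1 ± ", attr(x, "window"),
      ")\n", sep = "")
  print(table(x$type))
  invisible(x)
}

#' @export
summary.corrected_effects <- function(object, p_sig = 5e-8, ...) {
  sig <- object[object$pval <= p_sig, , drop = FALSE]
  out <- list(trait = attr(object, "trait"),
              window = attr(object, "window"),
              n = nrow(object), n_sig = nrow(sig),
              counts = table(factor(object$type,
                                    c("non-mediated", "uncertain"))),
              counts_sig = table(factor(sig$type,
                                        c("non-mediated", "uncertain"))),
              cur_quartiles_sig = if (nrow(sig))
                stats::quantile(sig$cur, c(.25, .5, .75), na.rm = TRUE)
              else NULL)
  class(out) <- "summary.corrected_effects"
  out
}

#' @export
print.summary.corrected_effects <- function(x, ...) {
  cat("Corrected effects for '", x$trait, "': ", x$n, " variants (",
      x$n_sig, " significant)\n", sep = "")
  cat("  all variants:        non-mediated ", x$counts[1],
      ", uncertain ", x$counts[2], "\n", sep = "")
  cat("  significant variants: non-mediated ", x$counts_sig[1],
      ", uncertain ", x$counts_sig[2], "\n", sep = "")
  if (!is.null(x$cur_quartiles_sig))
    cat("  CUR quartiles (significant): ",
        paste(format(x$cur_quartiles_sig, digits = 3), collapse = " / "),
        "\n", sep = "")
  invisible(x)
}

#' @export
plot.corrected_effects <- function(x, p_sig = 5e-8, ...) {
  sig <- x$pval <= p_sig
  col <- ifelse(x$type == "non-mediated", "forestgreen", "firebrick")
  graphics::plot(x$beta, x$cur, col = ifelse(sig, col, "grey70"),
                 pch = ifelse(sig, 19, 1),
                 xlab = "observed beta", ylab = "CUR", ...)
  w <- attr(x, "window")
  graphics::abline(h = c(1 - w, 1 + w), lty = 2, col = "grey40")
  invisible(x)
}

#' Proportion of genetic signal explained by the mediator model
#'
#' The squared correlation between the prior z-scores (`mu / se_obs`) and the
#' observed z-scores across a variant set, i.e. the fraction of the focal
#' trait's per-variant association signal attributable to mediation through
#' the model's traits. Zero for the null model; in \[0, 1\] by construction.
#'
#' @param focal [sumstats] for the focal trait.
#' @param model a [fit_prior()] result.
#' @param mediator_stats named list of [sumstats] for the model's mediators.
#' @param variants optional variant-id subset (e.g. an LD-pruned genome-wide
#'   set); defaults to all focal variants with complete mediator data.
#' @param min_variants minimum usable variants (default 10).
#' @return A proportion in \[0, 1\].
#' @export
variance_explained <- function(focal, model, mediator_stats,
                               variants = NULL, min_variants = 10L) {
  stopifnot(inherits(focal, "sumstats"), inherits(model, "mediator_model"))
  if (!is.null(variants)) {
    focal <- focal[match(intersect(variants, focal$variant_id),
                         focal$variant_id), , drop = FALSE]
    class(focal) <- c("sumstats", "data.frame")
  }
  if (nrow(model$mediators) == 0L) {
    if (nrow(focal) < min_variants)
      stop("insufficient data: fewer than ", min_variants, " variants")
    return(0)
  }
  pc <- .prior_components(focal, model, mediator_stats)
  use <- pc$complete
  if (sum(use) < min_variants)
    stop("insufficient data: fewer than ", min_variants,
         " variants with complete mediator estimates")
  z_prior <- pc$mu[use] / focal$se[use]
  z_obs <- focal$beta[use] / focal$se[use]
  if (stats::sd(z_prior) == 0) return(0)
  stats::cor(z_prior, z_obs)^2
}
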