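#' Assemble instrument-level data for two-sample MR
#'
#' @param x a `harmonized_set` from [harmonize()], or a data.frame with
#'   columns `variant_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @param exposure,outcome labels.
#' @param variants optional subset of variant ids (the selected instruments).
#' @return An `mr_input` object.
#' @export
mr_input <- function(x, exposure = NULL, outcome = NULL, variants = NULL) {
  if (inherits(x, "harmonized_set")) {
    if (is.null(exposure)) exposure <- x$exposure
    if (is.null(outcome)) outcome <- x$outcome
    x <- x$pairs
  }
  need <- c("variant_id", "beta_exposure", "se_exposure",
            "beta_outcome", "se_outcome")
  stopifnot(is.data.frame(x), all(need %in% names(x)))
  x <- x[need]
  if (!is.null(variants)) x <- x[x$variant_id %in% variants, , drop = FALSE]
  if (nrow(x) < 1L) stop("mr_input requires at least one instrument")
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0))
    stop("all standard errors must be positive")
  if (anyDuplicated(x$variant_id)) stop("duplicate instrument variant_id")
  rownames(x) <- NULL
  structure(list(data = x,
                 exposure = if (is.null(exposure)) "exposure" else exposure,
                 outcome = if (is.null(outcome)) "outcome" else outcome),
            class = "mr_input")
}

#' @export
print.mr_input <- function(x, ...) {
  cat("MR input: ", x$exposure, " -> ", x$outcome, " (",
      nrow(x$data), " instruments)\n", sep = "")
  invisible(x)
}

.new_mr_result <- function(method, input, b, se, nsnp,
                           q_stat = NA_real_, q_df = NA_real_,
                           egger_intercept = NA_real_,
                           egger_intercept_se = NA_real_,
                           outliers_removed = character(0), extra = list()) {
  res <- list(method = method,
              exposure = input$exposure, outcome = input$outcome,
              nsnp = nsnp, b = b, se = se,
              pval = max(2 * stats::pnorm(-abs(b / se)),
                         .Machine$double.xmin),
              q_stat = q_stat, q_df = q_df,
              q_pval = if (is.na(q_stat)) NA_real_ else
                stats::pchisq(q_stat, q_df, lower.tail = FALSE),
              egger_intercept = egger_intercept,
              egger_intercept_se = egger_intercept_se,
              egger_intercept_p = if (is.na(egger_intercept)) NA_real_ else
                2 * stats::pnorm(-abs(egger_intercept / egger_intercept_se)),
              outliers_removed = outliers_removed)
  structure(c(res, extra), class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat("Two-sample MR: ", x$exposure, " -> ", x$outcome, "\n",
      "  method: ", x$method, "  (", x$nsnp, " instruments)\n",
      "  b = ", format(x$b, digits = digits),
      "  se = ", format(x$se, digits = digits),
      "  p = ", format(x$pval, digits = digits), "\n", sep = "")
  if (!is.na(x$q_stat))
    cat("  heterogeneity: Q = ", format(x$q_stat, digits = digits),
        " (df ", x$q_df, ", p = ", format(x$q_pval, digits = digits),
        ")\n", sep = "")
  if (!is.na(x$egger_intercept))
    cat("  Egger intercept = ", format(x$egger_intercept, digits = digits),
        " (p = ", format(x$egger_intercept_p, digits = digits), ")\n",
        sep = "")
  if (length(x$outliers_removed))
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  stats::setNames(object$b, paste0(object$exposure, "->", object$outcome))
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$b - z * object$se, object$b + z * object$se), 1L,
              dimnames = list(paste0(object$exposure, "->", object$outcome),
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' @export
plot.mr_result <- function(x, input, ...) {
  if (missing(input) || !inherits(input, "mr_input"))
    stop("plot.mr_result needs the mr_input the fit was computed from")
  d <- input$data
  graphics::plot(d$beta_exposure, d$beta_outcome,
                 xlab = paste("effect on", x$exposure),
                 ylab = paste("effect on", x$outcome),
                 pch = 19, col = "grey30", ...)
  graphics::segments(d$beta_exposure, d$beta_outcome - 1.96 * d$se_outcome,
                     d$beta_exposure, d$beta_outcome + 1.96 * d$se_outcome,
                     col = "grey70")
  graphics::abline(a = if (is.na(x$egger_intercept)) 0 else x$egger_intercept,
                   b = x$b, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Wald ratio estimate from a single variant
#'
#' `estimate = by / bx`, with first-order delta-method standard error
#' `sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)`.
#'
#' @param bx,se_x variant effect on the exposure and its SE.
#' @param by,se_y variant effect on the outcome and its SE.
#' @return list with `estimate` and `se`.
#' @export
wald_ratio <- function(bx, se_x, by, se_y) {
  if (any(bx == 0)) stop("undefined ratio: bx = 0")
  list(estimate = by / bx,
       se = sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4))
}

# Cochran's Q on per-variant ratio estimates with first-order weights
.ratio_q <- function(d, b) {
  w <- d$beta_exposure^2 / d$se_outcome^2
  r <- d$beta_outcome / d$beta_exposure
  w * (r - b)^2
}

#' Inverse-variance-weighted MR
#'
#' Fixed-effect estimate `b = sum(bx by / se_y^2) / sum(bx^2 / se_y^2)` with
#' `se = 1 / sqrt(sum(bx^2 / se_y^2))` (weighted least squares through the
#' origin). Heterogeneity is Cochran's Q on the per-variant ratios. The
#' random-effects flavour is multiplicative: the SE is inflated by
#' `sqrt(Q / (nsnp - 1))` when that exceeds 1; the point estimate is
#' unchanged. `mode = "auto"` selects random effects iff the heterogeneity
#' p-value is below 0.05. A single instrument falls back to the Wald ratio.
#'
#' @param input an [mr_input].
#' @param mode `"auto"`, `"FE"` or `"RE"`.
#' @return An `mr_result`.
#' @export
mr_ivw <- function(input, mode = c("auto", "FE", "RE")) {
  mode <- match.arg(mode)
  stopifnot(inherits(input, "mr_input"))
  d <- input$data
  n <- nrow(d)
  if (n == 1L) {
    w <- wald_ratio(d$beta_exposure, d$se_exposure,
                    d$beta_outcome, d$se_outcome)
    return(.new_mr_result("Wald ratio", input, w$estimate, w$se, 1L))
  }
  if (any(d$beta_exposure == 0)) stop("instrument with zero exposure effect")
  wt <- d$beta_exposure^2 / d$se_outcome^2
  b <- sum(d$beta_exposure * d$beta_outcome / d$se_outcome^2) / sum(wt)
  se_fe <- 1 / sqrt(sum(wt))
  q <- sum(.ratio_q(d, b))
  q_df <- n - 1L
  q_p <- stats::pchisq(q, q_df, lower.tail = FALSE)
  infl <- max(1, sqrt(q / q_df))
  use_re <- switch(mode, FE = FALSE, RE = TRUE, auto = q_p < 0.05)
  .new_mr_result(if (use_re) "IVW (RE)" else "IVW (FE)", input,
                 b, if (use_re) se_fe * infl else se_fe, n,
                 q_stat = q, q_df = q_df)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept, weights `1 / se_y^2`, after orienting instruments so every
#' exposure beta is positive (the standard InSIDE convention). The slope is
#' the causal estimate; a non-zero intercept indicates directional
#' pleiotropy. Standard errors are inflated multiplicatively by
#' `max(1, sqrt(Q / (nsnp - 2)))`.
#'
#' @param input an [mr_input] with at least 3 instruments.
#' @return An `mr_result` with `egger_intercept` fields populated.
#' @export
mr_egger <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  d <- input$data
  n <- nrow(d)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  if (stats::sd(bx) < 1e-12 * max(abs(bx), 1))
    stop("collinear design: all exposure betas equal after orientation")
  w <- 1 / d$se_outcome^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X * sqrt(w))
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - drop(X %*% coefs)
  q <- sum(w * resid^2)
  q_df <- n - 2L
  infl <- max(1, sqrt(q / q_df))
  vc <- solve(xtwx) * infl^2
  .new_mr_result("MR-Egger", input, coefs["slope", 1],
                 sqrt(vc["slope", "slope"]), n,
                 q_stat = q, q_df = q_df,
                 egger_intercept = coefs["intercept", 1],
                 egger_intercept_se = sqrt(vc["intercept", "intercept"]))
}

# weighted median of x with weights w (Bowden et al. interpolation)
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(x)])
  k <- max(which(s < 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median MR
#'
#' Weighted median of the per-variant ratio estimates with inverse-variance
#' weights (first-order ratio variances); consistent when at least half the
#' weight comes from valid instruments. The SE is estimated by parametric
#' bootstrap: instrument effects are redrawn from their sampling
#' distributions and the weighted median recomputed.
#'
#' @param input an [mr_input] with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap; the caller's RNG state is restored on
#'   exit.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(input, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(input, "mr_input"))
  d <- input$data
  n <- nrow(d)
  if (n < 3L) stop("weighted median requires at least 3 instruments")
  if (any(d$beta_exposure == 0)) stop("instrument with zero exposure effect")
  ratio <- d$beta_outcome / d$beta_exposure
  w <- d$beta_exposure^2 / d$se_outcome^2
  est <- .weighted_median(ratio, w)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  boots <- replicate(n_boot, {
    bx <- stats::rnorm(n, d$beta_exposure, d$se_exposure)
    by <- stats::rnorm(n, d$beta_outcome, d$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    .weighted_median(by / bx, bx^2 / d$se_outcome^2)
  })
  .new_mr_result("Weighted median", input, est, stats::sd(boots), n,
                 extra = list(n_boot = n_boot))
}

#' MR-RAPS: maximum adjusted profile likelihood with overdispersion
#'
#' Errors-in-variables model `by_j ~ N(beta * gamma_j, se_y^2)`,
#' `bx_j ~ N(gamma_j, se_x^2)`; profiling out the true instrument strengths
#' gives residuals `by - beta * bx` with variance
#' `omega^2 * (se_y^2 + beta^2 * se_x^2)` under multiplicative
#' overdispersion `omega^2`. The estimate maximizes the profile likelihood in
#' `beta`; the SE comes from the observed information of the two-parameter
#' model, with `omega^2` floored at 1 (no deflation below the fixed-effect
#' SE). In the limit of error-free exposure betas the point estimate equals
#' the IVW estimate.
#'
#' @param input an [mr_input] with at least 3 instruments.
#' @return An `mr_result` with `omega2` in the extra fields.
#' @export
mr_raps <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  d <- input$data
  n <- nrow(d)
  if (n < 3L) stop("MR-RAPS requires at least 3 instruments")
  by <- d$beta_outcome; bx <- d$beta_exposure
  sy2 <- d$se_outcome^2; sx2 <- d$se_exposure^2
  prof_nll <- function(beta) {
    v <- sy2 + beta^2 * sx2
    r2v <- (by - beta * bx)^2 / v
    n * log(mean(r2v)) + sum(log(v))
  }
  ratios <- by / ifelse(bx == 0, .Machine$double.eps, bx)
  centre <- stats::median(ratios)
  span <- max(10 * stats::mad(ratios, constant = 1.4826), 10, diff(range(ratios)))
  opt <- stats::optimize(prof_nll, interval = c(centre - span, centre + span),
                         tol = 1e-10)
  beta_hat <- opt$minimum
  if (!is.finite(opt$objective) ||
      min(abs(beta_hat - (centre + c(-span, span)))) < 1e-6 * span)
    stop("MR-RAPS did not converge: optimum at the search boundary (centre ",
         format(centre), ", span ", format(span), ")")
  v <- sy2 + beta_hat^2 * sx2
  omega2_hat <- mean((by - beta_hat * bx)^2 / v)
  nll2 <- function(par) {
    beta <- par[1]; lo <- par[2]
    v <- sy2 + beta^2 * sx2
    0.5 * sum((by - beta * bx)^2 / (exp(lo) * v) + lo + log(v))
  }
  H <- stats::optimHess(c(beta_hat, log(omega2_hat)), nll2)
  vc <- tryCatch(solve(H), error = function(e)
    stop("MR-RAPS did not converge: singular information matrix"))
  se <- sqrt(vc[1, 1])
  if (omega2_hat < 1) se <- se * 1 / sqrt(omega2_hat)  # floor omega2 at 1
  .new_mr_result("MR-RAPS", input, beta_hat, se, n,
                 extra = list(omega2 = omega2_hat))
}

# radial (modified second-order) weights for the ratio estimates
.radial_weights <- function(d) {
  1 / (d$se_outcome^2 / d$beta_exposure^2 +
         d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
}

#' Radial-MR outlier detection
#'
#' Fits the radial IVW model with modified second-order weights, compares
#' each variant's contribution to Cochran's Q against the chi-square(1)
#' distribution, flags variants whose Bonferroni-adjusted (over the current
#' number of instruments) contribution p-value falls below `alpha`, removes
#' them, and iterates until no variant is flagged.
#'
#' @param input an [mr_input] with at least 3 instruments.
#' @param alpha significance level for the Bonferroni-adjusted per-variant Q
#'   test (default 0.05).
#' @return list with `outliers` (variant ids, in removal order) and `input`
#'   (the reduced [mr_input]).
#' @export
radial_outliers <- function(input, alpha = 0.05) {
  stopifnot(inherits(input, "mr_input"))
  d <- input$data
  if (nrow(d) < 3L) stop("radial outlier detection requires >= 3 instruments")
  removed <- character(0)
  repeat {
    w <- .radial_weights(d)
    r <- d$beta_outcome / d$beta_exposure
    b <- sum(w * r) / sum(w)
    qj <- w * (r - b)^2
    pj <- stats::pchisq(qj, 1, lower.tail = FALSE)
    flagged <- pj < alpha / nrow(d)
    if (!any(flagged)) break
    if (all(flagged))
      stop("degenerate input: every instrument flagged as a radial outlier")
    removed <- c(removed, d$variant_id[flagged])
    d <- d[!flagged, , drop = FALSE]
    if (nrow(d) < 2L)
      stop("degenerate input: fewer than 2 instruments left after removal")
  }
  list(outliers = removed,
       input = mr_input(d, exposure = input$exposure,
                        outcome = input$outcome))
}

#' Stepwise heterogeneity pruning of instruments
#'
#' While the global Cochran's Q p-value is below `q_p_threshold`, removes the
#' single instrument with the largest Q contribution and refits. Errors if
#' pruning would leave fewer than 2 instruments.
#'
#' @param input an [mr_input] with at least 3 instruments.
#' @param q_p_threshold stop once the heterogeneity p-value is at or above
#'   this (default 0.05).
#' @return The pruned [mr_input]; removed ids in attribute `"removed"`.
#' @export
stepwise_het_prune <- function(input, q_p_threshold = 0.05) {
  stopifnot(inherits(input, "mr_input"))
  d <- input$data
  if (nrow(d) < 3L) stop("stepwise pruning requires >= 3 instruments")
  removed <- character(0)
  repeat {
    wt <- d$beta_exposure^2 / d$se_outcome^2
    b <- sum(d$beta_exposure * d$beta_outcome / d$se_outcome^2) / sum(wt)
    qj <- .ratio_q(d, b)
    q_p <- stats::pchisq(sum(qj), nrow(d) - 1L, lower.tail = FALSE)
    if (q_p >= q_p_threshold) break
    if (nrow(d) <= 2L)
      stop("degenerate input: heterogeneity pruning would leave < 2 ",
           "instruments")
    worst <- which.max(qj)
    removed <- c(removed, d$variant_id[worst])
    d <- d[-worst, , drop = FALSE]
  }
  out <- mr_input(d, exposure = input$exposure, outcome = input$outcome)
  attr(out, "removed") <- removed
  out
}

#' Multivariable MR from summary statistics
#'
#' Weighted multiple regression without intercept of the outcome betas on the
#' matrix of exposure betas at the instrument variants, weights
#' `1 / se_outcome^2`. Exposure effects are aligned to the outcome's effect
#' alleles (swapped alleles flip the sign); mismatched alleles are an error.
#'
#' @param exposures named list of [sumstats], one per exposure.
#' @param outcome a [sumstats].
#' @param instruments character vector of instrument variant ids; must number
#'   at least `length(exposures) + 1` and be present in every input.
#' @return data.frame (class `mvmr_result`) with one row per exposure:
#'   `exposure`, `theta`, `se`, `pval`.
#' @export
mr_mvmr <- function(exposures, outcome, instruments) {
  stopifnot(is.list(exposures), length(exposures) >= 1L,
            inherits(outcome, "sumstats"))
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- paste0("exposure", seq_along(exposures))
  k <- length(exposures)
  if (length(instruments) < k + 1L)
    stop("need at least ", k + 1L, " instruments for ", k, " exposure(s)")
  oi <- match(instruments, outcome$variant_id)
  if (anyNA(oi)) stop("instrument(s) missing from outcome: ",
                      paste(instruments[is.na(oi)][1:min(5, sum(is.na(oi)))],
                            collapse = ", "))
  B <- matrix(NA_real_, length(instruments), k,
              dimnames = list(instruments, names(exposures)))
  for (j in seq_len(k)) {
    ex <- exposures[[j]]
    ei <- match(instruments, ex$variant_id)
    if (anyNA(ei)) stop("instrument(s) missing from exposure '",
                        names(exposures)[j], "'")
    same <- ex$effect_allele[ei] == outcome$effect_allele[oi] &
      ex$other_allele[ei] == outcome$other_allele[oi]
    swap <- ex$effect_allele[ei] == outcome$other_allele[oi] &
      ex$other_allele[ei] == outcome$effect_allele[oi]
    if (any(!same & !swap))
      stop("allele mismatch between exposure '", names(exposures)[j],
           "' and outcome at instrument(s): ",
           paste(instruments[!same & !swap][1:min(5, sum(!same & !swap))],
                 collapse = ", "))
    B[, j] <- ifelse(swap, -ex$beta[ei], ex$beta[ei])
  }
  by <- outcome$beta[oi]
  w <- 1 / outcome$se[oi]^2
  qrB <- qr(B * sqrt(w))
  if (qrB$rank < k) {
    dep <- colnames(B)[qrB$pivot[(qrB$rank + 1L):k]]
    stop("collinear exposures: ", paste(dep, collapse = ", "),
         " linearly dependent on the others")
  }
  xtwx <- crossprod(B * sqrt(w))
  theta <- solve(xtwx, crossprod(B, w * by))
  vc <- solve(xtwx)
  se <- sqrt(diag(vc))
  out <- data.frame(exposure = names(exposures), theta = drop(theta),
                    se = se, pval = 2 * stats::pnorm(-abs(drop(theta) / se)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "vcov") <- vc
  attr(out, "nsnp") <- length(instruments)
  class(out) <- c("mvmr_result", "data.frame")
  out
}
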