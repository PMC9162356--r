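#' Configuration for the structural simulation model
#'
#' Defines the linear structural equation model used to generate synthetic
#' cohorts: a focal (food) trait Y, a causally connected trait X with possibly
#' bidirectional effects X->Y (`beta_xy`) and Y->X (`beta_yx`), and a
#' confounder U acting on both (`beta_uy`, `beta_ux`). Three classes of
#' independent biallelic variants act additively: `Gy` directly on Y, `Gx` on
#' X, `Gu` on U. The observed trait `Yo` is the true trait `Yt` plus
#' measurement noise calibrated so replicate observations correlate at
#' `retest_r`, emulating food-frequency-questionnaire test-retest reliability.
#'
#' Structural residual variances are chosen so each structural input (U, and
#' the pre-feedback components of X and Y) has unit variance; the resulting
#' traits are then standardized by their closed-form standard deviations, so
#' every simulated trait has (theoretical) variance 1.
#'
#' @param n_individuals cohort size.
#' @param n_gy,n_gx,n_gu counts of direct-on-Y, X-acting and confounder
#'   variants.
#' @param maf_range minor-allele-frequency interval, a sub-interval of
#'   (0, 0.5].
#' @param var_gy,var_gx,var_gu variance fractions of Y, X and U explained by
#'   their variant sets (per-SD trait scale).
#' @param beta_xy,beta_yx simultaneous causal effects X->Y and Y->X (SD
#'   units).
#' @param beta_uy,beta_ux confounder effects U->Y and U->X (SD units).
#' @param retest_r test-retest correlation of the observed trait, in (0, 1].
#' @param seed integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_individuals = 100000L,
                       n_gy = 50L, n_gx = 50L, n_gu = 0L,
                       maf_range = c(0.05, 0.5),
                       var_gy = 0.1, var_gx = 0.35, var_gu = 0.3,
                       beta_xy = 0, beta_yx = 0,
                       beta_uy = 0, beta_ux = 0,
                       retest_r = 0.7, seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_gy = as.integer(n_gy), n_gx = as.integer(n_gx),
              n_gu = as.integer(n_gu),
              maf_range = as.numeric(maf_range),
              var_gy = var_gy, var_gx = var_gx, var_gu = var_gu,
              beta_xy = beta_xy, beta_yx = beta_yx,
              beta_uy = beta_uy, beta_ux = beta_ux,
              retest_r = retest_r, seed = as.integer(seed))
  if (cfg$n_individuals < 2L) stop("n_individuals must be >= 2")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      diff(cfg$maf_range) < 0)
    stop("maf_range must be an interval within (0, 0.5]")
  if (retest_r <= 0 || retest_r > 1) stop("retest_r must lie in (0, 1]")
  if (abs(beta_xy * beta_yx - 1) < 1e-12)
    stop("beta_xy * beta_yx = 1: singular simultaneous system")
  if (var_gu < 0 || var_gu >= 1 + 1e-12)
    stop("var_gu must lie in [0, 1)")
  if (var_gy + beta_uy^2 > 1 + 1e-12)
    stop("var_gy + beta_uy^2 exceeds 1: no residual variance left for Y")
  if (var_gx + beta_ux^2 > 1 + 1e-12)
    stop("var_gx + beta_ux^2 exceeds 1: no residual variance left for X")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: n =", x$n_individuals,
      "| Gy/Gx/Gu =", x$n_gy, x$n_gx, x$n_gu,
      "| X->Y =", x$beta_xy, "Y->X =", x$beta_yx,
      "| U->Y =", x$beta_uy, "U->X =", x$beta_ux,
      "| retest r =", x$retest_r, "| seed =", x$seed, "\n")
  invisible(x)
}

# draw variant metadata (maf, per-score effect, class, alleles) for a config;
# must be called under the config's RNG stream
.draw_variants <- function(cfg) {
  n_var <- cfg$n_gy + cfg$n_gx + cfg$n_gu
  classes <- rep(c("Gy", "Gx", "Gu"), c(cfg$n_gy, cfg$n_gx, cfg$n_gu))
  maf <- stats::runif(n_var, cfg$maf_range[1], cfg$maf_range[2])
  sign <- sample(c(-1, 1), n_var, replace = TRUE)
  per_var <- c(Gy = if (cfg$n_gy) cfg$var_gy / cfg$n_gy else 0,
               Gx = if (cfg$n_gx) cfg$var_gx / cfg$n_gx else 0,
               Gu = if (cfg$n_gu) cfg$var_gu / cfg$n_gu else 0)
  v_dos <- 2 * maf * (1 - maf)
  b <- sign * sqrt(per_var[classes] / v_dos)
  # non-palindromic allele pairs keep downstream harmonization unambiguous
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- sample.int(4L, n_var, replace = TRUE)
  data.frame(variant_id = sprintf("rs%04d", seq_len(n_var)),
             class = classes, maf = maf, b = b,
             effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
             stringsAsFactors = FALSE)
}

# closed-form reduced-form effects of every variant on U, X, Yt, Yo
# (standardized trait scale) plus the theoretical trait SDs
.reduced_form <- function(cfg, variants) {
  d <- 1 - cfg$beta_xy * cfg$beta_yx
  # pre-feedback components x0, y0 have unit variance by construction;
  # their covariance flows only through the shared confounder
  cov_xy0 <- cfg$beta_ux * cfg$beta_uy
  var_x <- (1 + cfg$beta_yx^2 + 2 * cfg$beta_yx * cov_xy0) / d^2
  var_y <- (1 + cfg$beta_xy^2 + 2 * cfg$beta_xy * cov_xy0) / d^2
  sd_x <- sqrt(var_x)
  sd_y <- sqrt(var_y)
  b <- variants$b
  bu <- ifelse(variants$class == "Gu", b, 0)
  bx0 <- ifelse(variants$class == "Gx", b, 0) + cfg$beta_ux * bu
  by0 <- ifelse(variants$class == "Gy", b, 0) + cfg$beta_uy * bu
  beta_x <- (bx0 + cfg$beta_yx * by0) / d
  beta_y <- (by0 + cfg$beta_xy * bx0) / d
  list(sd_x = sd_x, sd_y = sd_y,
       beta = cbind(U = bu,
                    X = beta_x / sd_x,
                    Yt = beta_y / sd_y,
                    Yo = sqrt(cfg$retest_r) * beta_y / sd_y))
}

#' Simulate an individual-level cohort under the structural model
#'
#' Genotype dosages are drawn independently as Binomial(2, maf). The
#' simultaneous system X = beta_yx * Y + ..., Y = beta_xy * X + ... is solved
#' through its reduced form, so bidirectional effects are generated exactly
#' rather than by iteration. Traits are standardized by their closed-form
#' standard deviations; the observed trait is
#' `Yo = sqrt(retest_r) * Yt + sqrt(1 - retest_r) * noise`, which keeps unit
#' variance and gives replicate observations test-retest correlation
#' `retest_r`.
#'
#' @param config a [sim_config].
#' @return A `sim_cohort`: list with `genotypes` (individuals x variants
#'   dosage matrix), `traits` (data.frame U, X, Yt, Yo), `truth` (per-variant
#'   class, maf, alleles and true standardized effects on each trait) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  variants <- .draw_variants(cfg)
  n <- cfg$n_individuals
  n_var <- nrow(variants)
  G <- matrix(stats::rbinom(n * n_var, 2L,
                            rep(variants$maf, each = n)),
              nrow = n, ncol = n_var,
              dimnames = list(NULL, variants$variant_id))
  Gc <- sweep(G, 2L, 2 * variants$maf)  # centered dosages
  score <- function(cls) {
    idx <- variants$class == cls
    if (!any(idx)) return(numeric(n))
    drop(Gc[, idx, drop = FALSE] %*% variants$b[idx])
  }
  vgu <- if (cfg$n_gu) cfg$var_gu else 0
  vgx <- if (cfg$n_gx) cfg$var_gx else 0
  vgy <- if (cfg$n_gy) cfg$var_gy else 0
  U <- score("Gu") + stats::rnorm(n, sd = sqrt(1 - vgu))
  x0 <- cfg$beta_ux * U + score("Gx") +
    stats::rnorm(n, sd = sqrt(1 - vgx - cfg$beta_ux^2))
  y0 <- cfg$beta_uy * U + score("Gy") +
    stats::rnorm(n, sd = sqrt(1 - vgy - cfg$beta_uy^2))
  d <- 1 - cfg$beta_xy * cfg$beta_yx
  X <- (x0 + cfg$beta_yx * y0) / d
  Yt <- (y0 + cfg$beta_xy * x0) / d
  rf <- .reduced_form(cfg, variants)
  X <- X / rf$sd_x
  Yt <- Yt / rf$sd_y
  Yo <- sqrt(cfg$retest_r) * Yt +
    sqrt(1 - cfg$retest_r) * stats::rnorm(n)
  truth <- cbind(variants, as.data.frame(rf$beta))
  names(truth)[match(c("U", "X", "Yt", "Yo"), names(truth))] <-
    c("beta_U", "beta_X", "beta_Yt", "beta_Yo")
  structure(list(genotypes = G,
                 traits = data.frame(U = U, X = X, Yt = Yt, Yo = Yo),
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: n =", nrow(x$genotypes),
      "individuals,", ncol(x$genotypes), "variants",
      "(", paste(table(x$truth$class), names(table(x$truth$class)),
                 collapse = ", "), ")\n")
  invisible(x)
}

#' Per-variant association scan of a simulated cohort
#'
#' Simple linear regression of the selected trait on each dosage column,
#' returning beta, standard error, two-sided p (t-distribution with n-2 df)
#' and n as a [sumstats] object. Monomorphic variants cannot be tested and are
#' dropped with a message.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param trait one of `"U"`, `"X"`, `"Yo"` (`Yt` is latent and not
#'   scannable).
#' @return A [sumstats] object; effect-allele frequency is the observed
#'   dosage frequency.
#' @export
gwas_scan <- function(cohort, trait = c("Yo", "X", "U")) {
  stopifnot(inherits(cohort, "sim_cohort"))
  trait <- match.arg(trait)
  y <- cohort$traits[[trait]]
  G <- cohort$genotypes
  n <- length(y)
  mono <- apply(G, 2L, function(g) length(unique(g)) == 1L)
  if (any(mono))
    message("gwas_scan: dropped ", sum(mono), " monomorphic variant(s): ",
            paste(colnames(G)[mono], collapse = ", "))
  G <- G[, !mono, drop = FALSE]
  gm <- colMeans(G)
  Gc <- sweep(G, 2L, gm)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- drop(crossprod(Gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  pval <- pmax(pval, .Machine$double.xmin)
  truth <- cohort$truth[!mono, , drop = FALSE]
  sumstats(data.frame(variant_id = colnames(G),
                      effect_allele = truth$effect_allele,
                      other_allele = truth$other_allele,
                      eaf = gm / 2, beta = beta, se = se, pval = pval,
                      n = n, stringsAsFactors = FALSE),
           trait = trait, quiet = TRUE)
}

#' Draw summary statistics directly from their asymptotic distribution
#'
#' Fast alternative to [simulate_cohort()] plus [gwas_scan()]: for each trait
#' the estimated effect is drawn as
#' `beta_hat ~ N(beta_true, se^2)` with
#' `se = sqrt((1 - beta_true^2 * v) / (n * v))`, `v = 2 maf (1 - maf)`,
#' where `beta_true` is the closed-form reduced-form effect on the
#' standardized trait. Draws are independent across traits, which corresponds
#' to each trait being measured in a separate (two-sample) cohort. The
#' individual-level path is the ground truth; this generator exists for
#' cheap large replication grids.
#'
#' @param config a [sim_config].
#' @param traits which traits to emit.
#' @return List with one [sumstats] per trait plus `truth` (as in
#'   [simulate_cohort()]).
#' @export
simulate_sumstats <- function(config, traits = c("Yo", "X", "U")) {
  stopifnot(inherits(config, "sim_config"))
  traits <- match.arg(traits, c("Yo", "X", "U", "Yt"), several.ok = TRUE)
  cfg <- config
  set.seed(cfg$seed)
  variants <- .draw_variants(cfg)
  rf <- .reduced_form(cfg, variants)
  v <- 2 * variants$maf * (1 - variants$maf)
  n <- cfg$n_individuals
  out <- list()
  for (tr in traits) {
    bt <- rf$beta[, tr]
    se <- sqrt(pmax(1 - bt^2 * v, 0.01) / (n * v))
    bh <- stats::rnorm(length(bt), mean = bt, sd = se)
    p <- pmax(2 * stats::pnorm(-abs(bh / se)), .Machine$double.xmin)
    out[[tr]] <- sumstats(data.frame(variant_id = variants$variant_id,
                                     effect_allele = variants$effect_allele,
                                     other_allele = variants$other_allele,
                                     eaf = variants$maf, beta = bh, se = se,
                                     pval = p, n = n,
                                     stringsAsFactors = FALSE),
                          trait = tr, quiet = TRUE)
  }
  truth <- cbind(variants, as.data.frame(rf$beta))
  names(truth)[match(c("U", "X", "Yt", "Yo"), names(truth))] <-
    c("beta_U", "beta_X", "beta_Yt", "beta_Yo")
  out$truth <- truth
  out
}

#' Compound-symmetry block LD matrix
#'
#' Builds an [ld_matrix] in which consecutive variants form blocks with a
#' constant pairwise correlation `r` inside each block and zero across
#' blocks. The default simulated genotypes are independent; this matrix
#' exists to exercise LD pruning against a known block structure.
#'
#' @param variant_ids variant identifiers, in block order.
#' @param block_size variants per block (the last block may be shorter).
#' @param r within-block correlation.
#' @return An [ld_matrix].
#' @export
block_ld_matrix <- function(variant_ids, block_size = 5L, r = 0.9) {
  n <- length(variant_ids)
  stopifnot(block_size >= 1L, abs(r) <= 1)
  blk <- rep(seq_len(ceiling(n / block_size)), each = block_size)[seq_len(n)]
  m <- outer(blk, blk, "==") * r
  diag(m) <- 1
  ld_matrix(m, variant_ids)
}

#' Calibration grid for the corrected-to-uncorrected ratio
#'
#' For each (beta_xy, beta_yx) grid cell: simulates a cohort, scans the
#' observed food trait Yo and the mediator trait X, fits the mediator model
#' (X as the single candidate mediator, instruments at `p_instr`), corrects
#' the Yo effects, and tabulates the CUR distribution and the
#' non-mediated/uncertain classification per true variant class among
#' genome-wide-significant variants.
#'
#' @param base a [sim_config]; its seed is advanced per cell so cells are
#'   independent but the grid is reproducible.
#' @param grid data.frame with columns `beta_xy`, `beta_yx`.
#' @param window CUR classification half-width (default 0.05).
#' @param p_instr instrument p-value threshold for the mediator model.
#' @param p_sig significance threshold defining which focal variants are
#'   classified.
#' @param use_fast use [simulate_sumstats()] instead of the individual-level
#'   path.
#' @return data.frame, one row per cell x true class: counts, significant
#'   counts, CUR quartiles among significant variants, and classification
#'   tallies.
#' @export
simulate_scenario_grid <- function(base, grid, window = 0.05,
                                   p_instr = 5e-8, p_sig = 5e-8,
                                   use_fast = FALSE) {
  stopifnot(inherits(base, "sim_config"),
            all(c("beta_xy", "beta_yx") %in% names(grid)))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    cfg$beta_xy <- grid$beta_xy[i]
    cfg$beta_yx <- grid$beta_yx[i]
    cfg$seed <- base$seed + i - 1L
    cfg <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
    if (use_fast) {
      sims <- simulate_sumstats(cfg, traits = c("Yo", "X"))
      focal <- sims$Yo; med <- sims$X; truth <- sims$truth
    } else {
      cohort <- simulate_cohort(cfg)
      focal <- gwas_scan(cohort, "Yo")
      med <- gwas_scan(cohort, "X")
      truth <- cohort$truth
    }
    model <- fit_prior(focal, list(X = med), p_instr = p_instr)
    ce <- correct_effects(focal, model, list(X = med), window = window)
    m <- merge(as.data.frame(ce),
               truth[c("variant_id", "class")], by = "variant_id")
    m$sig <- m$pval <= p_sig
    for (cls in unique(m$class)) {
      sub <- m[m$class == cls, ]
      sig <- sub[sub$sig, ]
      q <- if (nrow(sig)) stats::quantile(sig$cur, c(.25, .5, .75),
                                          na.rm = TRUE) else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        beta_xy = cfg$beta_xy, beta_yx = cfg$beta_yx, class = cls,
        n = nrow(sub), n_sig = nrow(sig),
        cur_q25 = q[1], cur_q50 = q[2], cur_q75 = q[3],
        n_nonmediated_sig = sum(sig$type == "non-mediated"),
        n_uncertain_sig = sum(sig$type == "uncertain"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
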