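#' Construct (and repair) a trait genetic-correlation matrix
#'
#' Validates symmetry, unit diagonal and bounded entries. Estimated genetic
#' correlation matrices are often slightly indefinite; eigenvalues above
#' `-tol` are treated as numerically zero and mildly negative ones (down to
#' `hard_limit` times the largest eigenvalue) are clipped at zero, after
#' which the matrix is rescaled to a unit diagonal. A materially indefinite
#' matrix is an error.
#'
#' @param rg square symmetric matrix of genetic correlations.
#' @param trait_names trait labels; default the dimnames.
#' @param se_rg optional matching matrix of standard errors.
#' @param tol numerical tolerance for eigenvalues (default 1e-8).
#' @param hard_limit most negative acceptable eigenvalue, as a fraction of
#'   the largest (default 0.05).
#' @return A `trait_cor` object (matrix subclass).
#' @export
trait_cor_matrix <- function(rg, trait_names = rownames(rg), se_rg = NULL,
                             tol = 1e-8, hard_limit = 0.05) {
  rg <- as.matrix(rg)
  if (is.null(trait_names))
    trait_names <- paste0("trait", seq_len(nrow(rg)))
  if (nrow(rg) != ncol(rg) || nrow(rg) != length(trait_names))
    stop("rg must be square with one row per trait")
  if (max(abs(rg - t(rg))) > 1e-6) stop("rg must be symmetric")
  if (max(abs(diag(rg) - 1)) > 1e-6) stop("rg diagonal must be 1")
  if (max(abs(rg)) > 1 + 1e-6) stop("|rg| must not exceed 1")
  rg <- (rg + t(rg)) / 2
  diag(rg) <- 1
  ev <- eigen(rg, symmetric = TRUE)
  if (min(ev$values) < -hard_limit * max(ev$values))
    stop("rg is not repairably positive semi-definite (min eigenvalue ",
         format(min(ev$values), digits = 3), ")")
  if (min(ev$values) < -tol) {
    lam <- pmax(ev$values, 0)
    rg <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(rg))
    rg <- rg / tcrossprod(d)
    diag(rg) <- 1
  }
  dimnames(rg) <- list(trait_names, trait_names)
  structure(rg, class = c("trait_cor", "matrix"), se_rg = se_rg)
}

# standardized-alpha reliability of a cluster, from its signed correlations
.cluster_alpha <- function(rg, members, signs) {
  k <- length(members)
  if (k < 2L) return(0)
  sub <- rg[members, members, drop = FALSE] *
    tcrossprod(signs[members])
  rbar <- (sum(sub) - k) / (k * (k - 1))
  k * rbar / (1 + (k - 1) * rbar)
}

#' Hierarchical clustering of traits on a genetic-correlation matrix
#'
#' Agglomerative merging in the style of item clustering: at each step the
#' pair of clusters with the highest mean inter-correlation is joined (ties
#' broken by cluster order for determinism), with the joined cluster's sign
#' keys flipped when the cross-correlation is negative so that reversed items
#' load consistently. The flat grouping keeps a merge only when the merged
#' cluster's standardized-alpha reliability is at least the larger of its
#' children's; once a cluster fails that rule it is sealed and the flat
#' groups below it are final. This is a simplified reliability rule — the
#' contract is recovering the grouping on separable matrices, not replicating
#' any particular published implementation.
#'
#' @param corr a [trait_cor_matrix()].
#' @return A `trait_clusters` object: `merges` (step, members joined, mean
#'   inter-correlation height, merged alpha, accepted flag), `groups` (list
#'   of trait-name vectors, the flat partition), `signs` (named sign keys,
#'   -1 for reversed traits).
#' @export
cluster_traits <- function(corr) {
  stopifnot(inherits(corr, "trait_cor"))
  n <- nrow(corr)
  if (n < 2L) stop("clustering requires at least 2 traits")
  traits <- rownames(corr)
  clusters <- lapply(seq_len(n), identity)   # member indices
  signs <- rep(1, n)
  alive <- rep(TRUE, n + 0L)
  eligible <- rep(TRUE, n)
  alphas <- rep(0, n)
  merges <- list()
  cross_cor <- function(a, b) {
    mean(corr[clusters[[a]], clusters[[b]], drop = FALSE] *
           tcrossprod(signs[clusters[[a]]], signs[clusters[[b]]]))
  }
  while (sum(alive) > 1L) {
    live <- which(alive)
    best <- c(NA, NA)
    best_h <- -Inf
    for (i in seq_along(live)) for (j in seq_len(i - 1L)) {
      h <- abs(cross_cor(live[i], live[j]))
      if (h > best_h + 1e-12) {
        best_h <- h
        best <- c(live[j], live[i])
      }
    }
    a <- best[1]; b <- best[2]
    if (cross_cor(a, b) < 0)
      signs[clusters[[b]]] <- -signs[clusters[[b]]]
    members <- c(clusters[[a]], clusters[[b]])
    alpha_new <- .cluster_alpha(corr, members, signs)
    accepted <- eligible[a] && eligible[b] &&
      alpha_new >= max(alphas[a], alphas[b])
    clusters[[length(clusters) + 1L]] <- members
    alive[c(a, b)] <- FALSE
    alive <- c(alive, TRUE)
    eligible <- c(eligible, accepted)
    alphas <- c(alphas, alpha_new)
    merges[[length(merges) + 1L]] <- data.frame(
      step = length(merges) + 1L,
      cluster_a = paste(traits[clusters[[a]]], collapse = "+"),
      cluster_b = paste(traits[clusters[[b]]], collapse = "+"),
      height = best_h, alpha = alpha_new, accepted = accepted,
      stringsAsFactors = FALSE)
  }
  # flat groups: maximal clusters that stayed eligible through their merges
  group_of <- seq_len(n)
  for (ci in seq.int(n + 1L, length.out = length(clusters) - n)) {
    if (eligible[ci]) group_of[clusters[[ci]]] <- ci
  }
  groups <- lapply(split(seq_len(n), group_of),
                   function(ix) traits[ix])
  names(groups) <- NULL
  structure(list(merges = do.call(rbind, merges), groups = groups,
                 signs = stats::setNames(signs, traits)),
            class = "trait_clusters")
}

#' @export
print.trait_clusters <- function(x, ...) {
  cat("Trait clustering:", length(x$groups), "flat group(s)\n")
  for (i in seq_along(x$groups))
    cat("  group ", i, ": ", paste(x$groups[[i]], collapse = ", "),
        "\n", sep = "")
  if (any(x$signs < 0))
    cat("  reversed:", paste(names(x$signs)[x$signs < 0], collapse = ", "),
        "\n")
  invisible(x)
}

#' Leading-principal-component trait definition for a trait group
#'
#' Eigendecomposition of the genetic-correlation submatrix for one group of
#' traits. The loadings are the leading eigenvector (unit norm), the
#' explained-variance share is `lambda_1 / sum(lambda)` (negative
#' eigenvalues clipped at zero), and the sign is fixed so the reference
#' trait loads positively. Only the first component is retained.
#'
#' @param corr a [trait_cor_matrix()].
#' @param members trait names (or indices) of the group; default all traits.
#' @param name label for the PC trait.
#' @param reference trait whose loading is forced positive; default the
#'   trait with the largest absolute loading.
#' @return A `pc_trait`: `name`, `member_traits`, `loadings` (named unit
#'   vector), `explained_share`, `reference`.
#' @export
pc_rotation <- function(corr, members = rownames(corr), name = "PC1",
                        reference = NULL) {
  stopifnot(inherits(corr, "trait_cor"))
  if (is.numeric(members)) members <- rownames(corr)[members]
  if (length(members) < 1L) stop("group must contain at least 1 trait")
  if (!all(members %in% rownames(corr)))
    stop("unknown trait(s): ",
         paste(setdiff(members, rownames(corr)), collapse = ", "))
  sub <- corr[members, members, drop = FALSE]
  ev <- eigen(sub, symmetric = TRUE)
  if (anyNA(ev$values)) stop("eigendecomposition failed")
  lam <- pmax(ev$values, 0)
  loadings <- ev$vectors[, 1]
  names(loadings) <- members
  if (is.null(reference)) reference <- members[which.max(abs(loadings))]
  if (!reference %in% members) stop("reference trait not in the group")
  if (loadings[reference] == 0)
    reference <- members[which.max(abs(loadings))]
  if (loadings[reference] < 0) loadings <- -loadings
  structure(list(name = name, member_traits = members,
                 loadings = loadings,
                 explained_share = lam[1] / sum(lam),
                 reference = reference),
            class = "pc_trait")
}

#' @export
print.pc_trait <- function(x, digits = 3, ...) {
  cat("PC trait '", x$name, "' over ", length(x$member_traits),
      " trait(s), explained share ",
      format(x$explained_share, digits = digits), "\n", sep = "")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Project per-variant effects onto a principal-component trait
#'
#' For every variant present in each member trait's summary statistics (with
#' alleles aligned to the first member's coding) the projected effect is the
#' loading-weighted linear combination `beta_pc = sum_i l_i beta_i`, with
#' `se_pc = sqrt(sum_i l_i^2 se_i^2)` under the default independent-error
#' assumption (a cross-trait error covariance matrix may be supplied) and a
#' two-sided normal p-value. When corrected statistics are also supplied the
#' corrected projection is computed identically and the projected CUR is
#' their ratio.
#'
#' @param stats_list named list of [sumstats], covering the PC members.
#' @param pc a [pc_rotation()] result.
#' @param corrected optional named list of [correct_effects()] results (or
#'   sumstats of corrected effects) matching the members.
#' @param error_cov optional member x member covariance matrix of the
#'   per-variant estimation errors across traits (sample-overlap
#'   correction); the diagonal is taken from the per-variant SEs.
#' @param window CUR window for the projected classification (default 0.05).
#' @return A `sumstats` object for the PC trait with extra columns
#'   `corr_beta`, `corr_se`, `cur`, `type` when `corrected` is supplied;
#'   variants missing from any member are dropped, with reasons in the
#'   `"dropped"` attribute.
#' @export
project_effects <- function(stats_list, pc, corrected = NULL,
                            error_cov = NULL, window = 0.05) {
  stopifnot(inherits(pc, "pc_trait"), is.list(stats_list))
  members <- pc$member_traits
  if (!all(members %in% names(stats_list)))
    stop("stats_list lacks member trait(s): ",
         paste(setdiff(members, names(stats_list)), collapse = ", "))
  l <- pc$loadings[members]
  base <- stats_list[[members[1]]]
  if (length(members) == 1L && abs(l - 1) < 1e-15) {
    out <- base          # identity: a singleton group reproduces its input
    attr(out, "trait") <- pc$name
    attr(out, "dropped") <- data.frame(variant_id = character(0),
                                       reason = character(0))
    if (!is.null(corrected)) {
      ce <- as.data.frame(corrected[[members[1]]])
      i <- match(out$variant_id, ce$variant_id)
      out$corr_beta <- ce$corr_beta[i]
      out$corr_se <- ce$corr_se[i]
      out$cur <- ce$cur[i]
      out$type <- ce$type[i]
    }
    return(out)
  }
  ids <- base$variant_id
  B <- SE <- matrix(NA_real_, length(ids), length(members),
                    dimnames = list(ids, members))
  B[, 1] <- base$beta
  SE[, 1] <- base$se
  for (j in seq_along(members)[-1]) {
    al <- .align_to_focal(base, stats_list[[members[j]]])
    B[, j] <- al$beta
    SE[, j] <- al$se
  }
  complete <- rowSums(is.na(B)) == 0L
  dropped <- data.frame(variant_id = ids[!complete],
                        reason = rep("missing in a member trait",
                                     sum(!complete)),
                        stringsAsFactors = FALSE)
  B <- B[complete, , drop = FALSE]
  SE <- SE[complete, , drop = FALSE]
  beta_pc <- drop(B %*% l)
  if (is.null(error_cov)) {
    var_pc <- drop(SE^2 %*% l^2)
  } else {
    ec <- stats::cov2cor(as.matrix(error_cov))[members, members]
    var_pc <- vapply(seq_len(nrow(SE)), function(i) {
      S <- ec * tcrossprod(SE[i, ])
      drop(t(l) %*% S %*% l)
    }, 0)
  }
  se_pc <- sqrt(var_pc)
  out <- sumstats(data.frame(variant_id = ids[complete],
                             effect_allele = base$effect_allele[complete],
                             other_allele = base$other_allele[complete],
                             eaf = base$eaf[complete],
                             beta = beta_pc, se = se_pc,
                             pval = pmax(2 * stats::pnorm(-abs(beta_pc / se_pc)),
                                         .Machine$double.xmin),
                             n = base$n[complete],
                             stringsAsFactors = FALSE),
                  trait = pc$name, scale = attr(base, "scale"), quiet = TRUE)
  if (!is.null(corrected)) {
    if (!all(members %in% names(corrected)))
      stop("corrected lacks member trait(s): ",
           paste(setdiff(members, names(corrected)), collapse = ", "))
    CB <- CSE <- matrix(NA_real_, nrow(out), length(members))
    for (j in seq_along(members)) {
      ce <- as.data.frame(corrected[[members[j]]])
      i <- match(out$variant_id, ce$variant_id)
      CB[, j] <- ce$corr_beta[i]
      CSE[, j] <- ce$corr_se[i]
    }
    out$corr_beta <- drop(CB %*% l)
    out$corr_se <- sqrt(drop(CSE^2 %*% l^2))
    out$cur <- ifelse(out$beta == 0, NA_real_,
                      ifelse(out$corr_beta == out$beta, 1,
                             out$corr_beta / out$beta))
    out$type <- classify_cur(out$cur, window)
  }
  attr(out, "dropped") <- dropped
  out
}
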