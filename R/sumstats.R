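#' Construct a validated summary-statistics table
#'
#' A `sumstats` object holds per-variant association records for one trait:
#' variant identifier, effect and other allele, effect-allele frequency, the
#' additive effect `beta` per copy of the effect allele (in outcome SD units
#' for quantitative traits, log odds ratio for binary traits), its standard
#' error, the two-sided p-value and the sample size. Rows that violate the
#' record invariants (`se > 0`, `pval` in (0, 1], distinct single-base
#' alleles, `eaf` in \[0, 1\] when present, unique `variant_id`) are rejected;
#' the rejected rows and reasons are attached as the `"rejected"` attribute.
#'
#' @param x data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `eaf`, `n`.
#' @param trait trait label.
#' @param scale effect-size scale tag, `"sd"` (per-SD quantitative) or
#'   `"logor"` (binary outcome). The tag is carried through the pipeline so
#'   scales are never mixed silently.
#' @param quiet suppress the message listing rejected rows.
#' @return A `sumstats` object (a data.frame subclass) with attributes
#'   `trait`, `scale` and `rejected`.
#' @seealso [read_sumstats()], [harmonize()], [ld_prune()]
#' @export
sumstats <- function(x, trait = "trait", scale = c("sd", "logor"),
                     quiet = FALSE) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(x))
  mandatory <- c("variant_id", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(x$eaf)) x$eaf <- NA_real_
  if (is.null(x$n)) x$n <- NA_integer_

  x$variant_id <- as.character(x$variant_id)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) {
    bad_num <- !is.na(x[[col]]) & is.na(suppressWarnings(as.numeric(x[[col]])))
    if (any(bad_num))
      stop("non-numeric ", col, " in row(s): ",
           paste(which(bad_num), collapse = ", "))
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$n <- suppressWarnings(as.integer(round(as.numeric(x$n))))

  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  bases <- c("A", "C", "G", "T")
  flag(is.na(x$beta) | is.na(x$se) | is.na(x$pval), "missing beta/se/pval")
  flag(!(x$effect_allele %in% bases) | !(x$other_allele %in% bases),
       "allele not a single base")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(x$se <= 0, "non-positive se")
  flag(x$pval <= 0 | x$pval > 1, "p-value outside (0, 1]")
  flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf outside [0, 1]")
  flag(!is.na(x$n) & x$n <= 0, "non-positive n")
  flag(duplicated(x$variant_id), "duplicate variant_id")

  rejected <- data.frame(variant_id = x$variant_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L && !quiet)
    message("sumstats: rejected ", nrow(rejected), " of ", nrow(x),
            " row(s) (", paste(unique(rejected$reason), collapse = "; "), ")")
  out <- x[is.na(reason), c("variant_id", "effect_allele", "other_allele",
                            "eaf", "beta", "se", "pval", "n")]
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            trait = trait, scale = scale, rejected = rejected)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for trait '", attr(x, "trait"),
      "' (", nrow(x), " variants, scale: ", attr(x, "scale"), ")\n", sep = "")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L)
    cat("  ", nrow(rej), " row(s) rejected at validation\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more row(s)\n", sep = "")
  invisible(x)
}

.canonical_cols <- c("variant_id", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-separated table with a header and returns a validated
#' [sumstats] object. Foreign column names are supported through `dialect`, a
#' named character vector mapping canonical names to the file's names, e.g.
#' `c(variant_id = "SNP", pval = "P")`. Columns not covered by the mapping are
#' matched by canonical name.
#'
#' @param path file path.
#' @param dialect named character vector; names are canonical column names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`), values are the file's column names.
#' @inheritParams sumstats
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, dialect = NULL, trait = NULL,
                          scale = c("sd", "logor"), quiet = FALSE) {
  scale <- match.arg(scale)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), .canonical_cols)
    if (length(bad) > 0L)
      stop("unknown canonical name(s) in dialect: ", paste(bad, collapse = ", "))
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw))
        stop("dialect column '", src, "' not found in ", path)
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- c("variant_id", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0L)
    stop("format error: ", path, " lacks mandatory column(s) ",
         paste(absent, collapse = ", "))
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  sumstats(raw[intersect(.canonical_cols, names(raw))],
           trait = trait, scale = scale, quiet = quiet)
}

#' Write summary statistics to a canonical tab-separated file
#'
#' The canonical dialect has header `variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Numeric columns are
#' written at full precision so a read/write/read cycle reproduces the
#' records exactly.
#'
#' @param x a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- as.data.frame(x)
  for (col in c("eaf", "beta", "se", "pval"))
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an LD correlation matrix
#'
#' @param r square symmetric matrix of pairwise allelic correlations with unit
#'   diagonal; `r^2` against this matrix drives [ld_prune()].
#' @param variant_ids variant identifiers; defaults to the matrix dimnames.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) stop("variant_ids required (no dimnames on r)")
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids))
    stop("r must be square with one row per variant id")
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) stop("|r| must not exceed 1")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix from a square TSV with a variant-id header
#' @param path file path.
#' @return An [ld_matrix] object.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  ld_matrix(as.matrix(m))
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses exposure and outcome effects for the same effect allele at every
#' shared variant. Outcome records whose alleles are swapped relative to the
#' exposure have their beta sign flipped (and eaf reflected). Strand-ambiguous
#' palindromic variants (A/T, C/G) are retained only when both allele
#' frequencies are available and both are farther than `palindrome_eaf_limit`
#' from 0.5; frequencies on opposite sides of 0.5 trigger a sign flip. All
#' other shared variants are dropped with a reason. Variants found in only one
#' input are outside the harmonization contract and are not reported.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_limit half-width of the ambiguity zone around eaf 0.5
#'   within which palindromic variants are dropped (default 0.08).
#' @return A `harmonized_set`: list with `pairs` (data.frame `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_exposure`) and `dropped`
#'   (data.frame `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L)
    stop("empty intersection of exposure and outcome variant ids")
  e <- as.data.frame(exposure)[match(shared, exposure$variant_id), ]
  o <- as.data.frame(outcome)[match(shared, outcome$variant_id), ]

  aligned <- e$effect_allele == o$effect_allele &
    e$other_allele == o$other_allele
  swapped <- e$effect_allele == o$other_allele &
    e$other_allele == o$effect_allele
  pal <- .is_palindromic(e$effect_allele, e$other_allele)

  beta_o <- o$beta
  eaf_o <- o$eaf
  beta_o[swapped & !pal] <- -beta_o[swapped & !pal]
  eaf_o[swapped & !pal] <- 1 - eaf_o[swapped & !pal]

  reason <- rep(NA_character_, length(shared))
  reason[!aligned & !swapped & !pal] <- "allele mismatch"
  # palindromes: alleles are complementary so aligned/swapped is not
  # informative; orientation is inferred from allele frequencies alone
  if (any(pal)) {
    no_eaf <- pal & (is.na(e$eaf) | is.na(eaf_o))
    reason[no_eaf] <- "missing eaf at palindrome"
    amb <- pal & !no_eaf &
      (abs(e$eaf - 0.5) <= palindrome_eaf_limit |
         abs(eaf_o - 0.5) <= palindrome_eaf_limit)
    reason[amb] <- "ambiguous palindrome"
    keep_pal <- pal & is.na(reason)
    flip <- keep_pal & ((e$eaf - 0.5) * (eaf_o - 0.5) < 0)
    beta_o[flip] <- -beta_o[flip]
    eaf_o[flip] <- 1 - eaf_o[flip]
  }
  keep <- is.na(reason)
  pairs <- data.frame(variant_id = shared[keep],
                      effect_allele = e$effect_allele[keep],
                      other_allele = e$other_allele[keep],
                      beta_exposure = e$beta[keep],
                      se_exposure = e$se[keep],
                      beta_outcome = beta_o[keep],
                      se_outcome = o$se[keep],
                      eaf_exposure = e$eaf[keep],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  dropped <- data.frame(variant_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  structure(list(pairs = pairs, dropped = dropped,
                 exposure = attr(exposure, "trait"),
                 outcome = attr(outcome, "trait")),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", x$exposure, " -> ", x$outcome, "\n",
      "  retained: ", nrow(x$pairs), "  dropped: ", nrow(x$dropped), "\n",
      sep = "")
  invisible(x)
}

#' Greedy LD pruning of summary statistics
#'
#' Keeps variants with `pval <= p_max`, sorts them by ascending p-value
#' (ties broken by `variant_id` for determinism) and accepts a variant iff its
#' squared correlation with every already accepted variant is below `r2_max`.
#' This yields an independent set at the `r2_max` threshold containing the
#' smallest-p variant of every LD-connected component.
#'
#' @param stats a [sumstats] object.
#' @param ld an [ld_matrix] covering every variant in `stats`.
#' @param r2_max squared-correlation threshold (default 0.001).
#' @param p_max p-value threshold (default 5e-8).
#' @return The accepted subset of `stats`, still a [sumstats] object.
#' @export
ld_prune <- function(stats, ld, r2_max = 0.001, p_max = 5e-8) {
  stopifnot(inherits(stats, "sumstats"), inherits(ld, "ld_matrix"))
  absent <- setdiff(stats$variant_id, rownames(ld))
  if (length(absent) > 0L)
    stop("variant(s) absent from LD matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  cand <- as.data.frame(stats)[stats$pval <= p_max, ]
  cand <- cand[order(cand$pval, cand$variant_id), ]
  accepted <- character(0)
  for (v in cand$variant_id) {
    if (length(accepted) == 0L ||
        all(ld[v, accepted]^2 < r2_max))
      accepted <- c(accepted, v)
  }
  out <- stats[match(accepted, stats$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(stats), trait = attr(stats, "trait"),
            scale = attr(stats, "scale"),
            rejected = attr(stats, "rejected"))
}
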