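# in-code fixtures shared across test files

# minimal well-formed summary statistics
make_sumstats <- function(n = 5L, trait = "trait", seed = 1L,
                          beta = NULL, se = NULL, eaf = NULL) {
  set.seed(seed)
  if (is.null(beta)) beta <- round(stats::rnorm(n, 0, 0.05), 4)
  if (is.null(se)) se <- rep(0.01, n)
  if (is.null(eaf)) eaf <- round(stats::runif(n, 0.1, 0.9), 3)
  pairs <- rbind(c("A", "G"), c("T", "C"), c("A", "C"), c("G", "T"))
  pick <- sample.int(4L, n, replace = TRUE)
  sumstats(data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
                      effect_allele = pairs[pick, 1],
                      other_allele = pairs[pick, 2],
                      eaf = eaf, beta = beta, se = se,
                      pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                      n = 10000L, stringsAsFactors = FALSE),
           trait = trait, quiet = TRUE)
}

# instrument-level data with known ratio structure
make_mr_input <- function(bx, by, se_x = 0.01, se_y = 0.02,
                          exposure = "E", outcome = "O") {
  n <- length(bx)
  mr_input(data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
                      beta_exposure = bx,
                      se_exposure = rep_len(se_x, n),
                      beta_outcome = by,
                      se_outcome = rep_len(se_y, n),
                      stringsAsFactors = FALSE),
           exposure = exposure, outcome = outcome)
}

# turn a harmonized set back into exposure/outcome sumstats (for
# idempotence checks)
harmonized_as_sumstats <- function(h) {
  p <- h$pairs
  mk <- function(beta, se) {
    sumstats(data.frame(variant_id = p$variant_id,
                        effect_allele = p$effect_allele,
                        other_allele = p$other_allele,
                        eaf = p$eaf_exposure, beta = beta, se = se,
                        pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                        n = 10000L, stringsAsFactors = FALSE),
             quiet = TRUE)
  }
  list(exposure = mk(p$beta_exposure, p$se_exposure),
       outcome = mk(p$beta_outcome, p$se_outcome))
}
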