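test_that("reading a well-formed table round-trips through write and read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  orig <- make_sumstats(3L, seed = 11)
  write_sumstats(orig, path)
  back <- read_sumstats(path, trait = attr(orig, "trait"))
  expect_s3_class(back, "sumstats")
  expect_equal(nrow(back), 3L)
  expect_identical(as.data.frame(back), as.data.frame(orig))
  # a second cycle is bit-identical for the canonical dialect
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("rows violating record invariants are rejected with reasons", {
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "A", "A"),
                   other_allele = c("G", "G", "G"),
                   eaf = c(0.2, 0.3, 0.4),
                   beta = c(0.1, 0.2, 0.3),
                   se = c(0.01, 0, 0.02),
                   pval = c(1e-5, 1e-5, 1e-5), n = 100L)
  s <- suppressMessages(sumstats(df))
  expect_equal(nrow(s), 2L)
  expect_equal(attr(s, "rejected")$variant_id, "rs2")
  expect_match(attr(s, "rejected")$reason, "non-positive se")

  df$pval[3] <- 1.5
  s2 <- suppressMessages(sumstats(df))
  expect_true(all(c("rs2", "rs3") %in% attr(s2, "rejected")$variant_id))

  df$variant_id[2] <- "rs1"        # duplicate id
  df$se[2] <- 0.01
  df$pval[3] <- 1e-5
  s3 <- suppressMessages(sumstats(df))
  expect_false(anyDuplicated(s3$variant_id) > 0)
})

test_that("missing mandatory columns and non-numeric values are errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\teffect_allele\tother_allele\tbeta",
               "rs1\tA\tG\t0.1"), path)
  expect_error(read_sumstats(path), "mandatory column")
  df <- data.frame(variant_id = "rs1", effect_allele = "A",
                   other_allele = "G", beta = "abc", se = 0.1, pval = 0.5)
  expect_error(sumstats(df), "non-numeric beta")
})

test_that("dialect mapping renames foreign headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tBETA\tSE\tP",
               "rs1\tA\tG\t0.1\t0.02\t1e-6"), path)
  s <- read_sumstats(path, dialect = c(variant_id = "SNP",
                                       effect_allele = "A1",
                                       other_allele = "A2",
                                       beta = "BETA", se = "SE",
                                       pval = "P"))
  expect_equal(s$variant_id, "rs1")
  expect_equal(s$beta, 0.1)
  expect_error(read_sumstats(path, dialect = c(foo = "SNP")),
               "unknown canonical name")
})

test_that("harmonization flips swapped alleles and drops mismatches", {
  e <- sumstats(data.frame(variant_id = c("rs1", "rs2"),
                           effect_allele = c("A", "A"),
                           other_allele = c("G", "G"),
                           eaf = 0.3, beta = c(0.1, 0.1), se = 0.01,
                           pval = 1e-8, n = 1000L), quiet = TRUE)
  o <- sumstats(data.frame(variant_id = c("rs1", "rs2"),
                           effect_allele = c("G", "C"),
                           other_allele = c("A", "G"),
                           eaf = 0.7, beta = c(0.2, 0.2), se = 0.01,
                           pval = 1e-8, n = 1000L), quiet = TRUE)
  h <- harmonize(e, o)
  expect_equal(h$pairs$variant_id, "rs1")
  expect_equal(h$pairs$beta_outcome, -0.2)      # swapped alleles flip sign
  expect_equal(h$dropped$reason, "allele mismatch")
})

test_that("ambiguous palindromic variants are dropped, clear ones kept", {
  mk <- function(eaf_vec) {
    sumstats(data.frame(variant_id = c("rs1", "rs2", "rs3"),
                        effect_allele = "A", other_allele = "T",
                        eaf = eaf_vec, beta = 0.1, se = 0.01,
                        pval = 1e-8, n = 1000L), quiet = TRUE)
  }
  e <- mk(c(0.1, 0.5, NA))
  o <- mk(c(0.9, 0.5, 0.1))
  h <- harmonize(e, o)
  # rs1: clear frequencies on opposite sides of 0.5 -> retained, flipped
  expect_equal(h$pairs$variant_id, "rs1")
  expect_equal(h$pairs$beta_outcome, -0.1)
  expect_setequal(h$dropped$reason,
                  c("ambiguous palindrome", "missing eaf at palindrome"))
  expect_error(harmonize(mk(0.1), make_sumstats(3, seed = 99)),
               "empty intersection")
})

test_that("harmonization is idempotent and allele-flip equivariant", {
  set.seed(21)
  e <- make_sumstats(20L, seed = 21)
  o <- make_sumstats(20L, seed = 22)
  # force some allele swaps in the outcome
  swap <- c(3, 7, 11)
  tmp <- o$effect_allele[swap]
  o$effect_allele[swap] <- o$other_allele[swap]
  o$other_allele[swap] <- tmp
  o$beta[swap] <- -o$beta[swap]
  h1 <- harmonize(e, o)
  rt <- harmonized_as_sumstats(h1)
  h2 <- harmonize(rt$exposure, rt$outcome)
  expect_equal(h2$pairs$variant_id, h1$pairs$variant_id)
  expect_equal(h2$pairs$beta_exposure, h1$pairs$beta_exposure)
  expect_equal(h2$pairs$beta_outcome, h1$pairs$beta_outcome)

  # flipping the exposure coding leaves beta products unchanged
  e_flip <- e
  tmp <- e_flip$effect_allele
  e_flip$effect_allele <- e_flip$other_allele
  e_flip$other_allele <- tmp
  e_flip$beta <- -e_flip$beta
  e_flip$eaf <- 1 - e_flip$eaf
  h3 <- harmonize(e_flip, o)
  common <- intersect(h1$pairs$variant_id, h3$pairs$variant_id)
  p1 <- with(h1$pairs[match(common, h1$pairs$variant_id), ],
             beta_exposure * beta_outcome)
  p3 <- with(h3$pairs[match(common, h3$pairs$variant_id), ],
             beta_exposure * beta_outcome)
  expect_equal(p1, p3)
})

test_that("greedy LD pruning keeps independent smallest-p variants", {
  s <- make_sumstats(2L, beta = c(0.1, 0.08), se = 0.01, seed = 5)
  r0 <- diag(2)
  dimnames(r0) <- list(s$variant_id, s$variant_id)
  both <- ld_prune(s, ld_matrix(r0), r2_max = 0.001, p_max = 1)
  expect_setequal(both$variant_id, s$variant_id)

  r <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2)
  dimnames(r) <- list(s$variant_id, s$variant_id)
  s$pval <- c(1e-10, 1e-9)
  one <- ld_prune(s, ld_matrix(r), r2_max = 0.5, p_max = 1)
  expect_equal(one$variant_id, s$variant_id[1])

  expect_error(ld_prune(make_sumstats(3), ld_matrix(r0)), "absent from LD")
})

test_that("pruning matches an exhaustive admissibility oracle", {
  set.seed(31)
  n <- 50L
  s <- make_sumstats(n, beta = rnorm(n, 0, 0.05), se = 0.01, seed = 31)
  # random sparse positive-definite-ish correlation structure
  r <- diag(n)
  for (k in 1:120) {
    ij <- sample.int(n, 2)
    r[ij[1], ij[2]] <- r[ij[2], ij[1]] <- runif(1, -0.9, 0.9)
  }
  dimnames(r) <- list(s$variant_id, s$variant_id)
  ld <- ld_matrix(r)
  r2_max <- 0.1
  p_max <- 0.05
  kept <- ld_prune(s, ld, r2_max = r2_max, p_max = p_max)$variant_id

  sig <- s$variant_id[s$pval <= p_max]
  # oracle checks: (1) admissible independent set
  for (a in kept) for (b in setdiff(kept, a))
    expect_lt(ld[a, b]^2, r2_max)
  # (2) maximal in p-order: every excluded significant variant conflicts
  # with an accepted variant of smaller (p, id)
  ord <- order(s$pval, s$variant_id)
  rank_of <- setNames(seq_len(n), s$variant_id[ord])
  for (v in setdiff(sig, kept)) {
    conflicts <- kept[ld[v, kept]^2 >= r2_max]
    expect_true(length(conflicts) > 0)
    expect_true(min(rank_of[conflicts]) < rank_of[v])
  }
  # (3) the smallest-p variant of every LD-connected component is kept
  adj <- (r^2 >= r2_max) & !diag(n)
  adj <- adj[sig, sig, drop = FALSE]
  comp <- seq_along(sig)
  repeat {
    changed <- FALSE
    for (i in seq_along(sig)) for (j in which(adj[i, ])) {
      if (comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  for (cc in unique(comp)) {
    members <- sig[comp == cc]
    best <- members[order(s$pval[match(members, s$variant_id)],
                          members)][1]
    expect_true(best %in% kept)
  }
})

test_that("LD matrix validation enforces symmetry and unit diagonal", {
  m <- matrix(c(1, 0.5, 0.4, 1), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_error(ld_matrix(m), "symmetric")
  m2 <- matrix(c(0.9, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  expect_error(ld_matrix(m2), "diagonal")
  path <- withr::local_tempfile(fileext = ".tsv")
  good <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  write.table(good, path, sep = "\t", quote = FALSE)
  expect_s3_class(read_ld_matrix(path), "ld_matrix")
})
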