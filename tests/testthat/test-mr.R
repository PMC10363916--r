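test_that("harmonization removes palindromic SNPs and frequency mismatches", {
  exp <- rbind(toy_assoc("s1", "A", "T", 0.3, 0.2),
               toy_assoc("s2", "A", "G", 0.30, 0.2),
               toy_assoc("s3", "A", "G", 0.30, 0.2))
  out <- rbind(toy_assoc("s1", "A", "T", 0.3, 0.1),
               toy_assoc("s2", "A", "G", 0.36, 0.1),
               toy_assoc("s3", "A", "G", 0.34, 0.1))
  h <- harmonize(exp, out)
  expect_equal(h$snp_id, "s3")
  expect_equal(attr(h, "n_removed")[["palindromic"]], 1)
  expect_equal(attr(h, "n_removed")[["freq_mismatch"]], 1)
})

test_that("swapped alleles flip the outcome beta and complement frequency", {
  exp <- toy_assoc("s1", "A", "G", 0.3, 0.2)
  out <- toy_assoc("s1", "G", "A", 0.7, 0.1)
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 1)
  expect_equal(h$beta_out, -0.1)
  expect_equal(h$freq_out, 0.3)
  bad <- toy_assoc("s1", "A", "C", 0.3, 0.1)
  expect_warning(h2 <- harmonize(exp, bad), "irreconcilable")
  expect_equal(nrow(h2), 0)
})

test_that("harmonization is idempotent", {
  exp <- rbind(toy_assoc("s1", "A", "G", 0.3, 0.2),
               toy_assoc("s2", "T", "C", 0.6, -0.1))
  out <- rbind(toy_assoc("s1", "G", "A", 0.72, 0.1),
               toy_assoc("s2", "T", "C", 0.58, 0.05))
  h1 <- harmonize(exp, out)
  back_exp <- data.frame(snp_id = h1$snp_id, allele_effect = h1$allele_effect_exp,
                         allele_other = h1$allele_other_exp, freq = h1$freq_exp,
                         beta = h1$beta_exp, se = h1$se_exp, p = h1$p_exp,
                         n = h1$n_exp)
  back_out <- data.frame(snp_id = h1$snp_id, allele_effect = h1$allele_effect_out,
                         allele_other = h1$allele_other_out, freq = h1$freq_out,
                         beta = h1$beta_out, se = h1$se_out, p = h1$p_out,
                         n = h1$n_out)
  h2 <- harmonize(back_exp, back_out)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$freq_out, h1$freq_out)
  expect_equal(nrow(h2), nrow(h1))
})

test_that("instrument selection applies the exposure threshold and LD pruning", {
  pairs <- data.frame(snp_id = c("a", "b", "c"),
                      p_exp = c(1e-8, 1e-7, 1e-5))
  sel <- select_instruments(pairs, ld = NULL)
  expect_equal(sel$snp_id, c("a", "b"))
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  pairs2 <- data.frame(snp_id = c("a", "b"), p_exp = c(1e-9, 1e-8))
  expect_equal(select_instruments(pairs2, ld)$snp_id, "a")
})

test_that("greedy instrument selection returns a valid independent set", {
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    L <- matrix(rnorm(k * 2 * k), 2 * k)
    S <- cov2cor(crossprod(L))
    ids <- sprintf("s%d", seq_len(2 * k))[1:k]
    dimnames(S) <- NULL
    S <- S[1:k, 1:k]
    dimnames(S) <- list(ids, ids)
    pairs <- data.frame(snp_id = ids, p_exp = 10^-runif(k, 6.1, 12))
    sel <- select_instruments(pairs, S, r2_max = 0.1)
    expect_gte(nrow(sel), 1)
    if (nrow(sel) > 1) {
      sub <- S[sel$snp_id, sel$snp_id]^2
      diag(sub) <- 0
      expect_lt(max(sub), 0.1)  # pairwise independence holds
    }
    # greedy by ascending p: the best-p candidate is always retained
    expect_true(pairs$snp_id[which.min(pairs$p_exp)] %in% sel$snp_id)
  }
})

test_that("Steiger filter removes reverse-causal instruments only", {
  mk <- function(z_exp, z_out) {
    data.frame(snp_id = "s", beta_exp = z_exp * 0.01, se_exp = 0.01,
               beta_out = z_out * 0.01, se_out = 0.01)
  }
  expect_equal(nrow(steiger_filter(mk(10, 2), 30000, 30000)), 1)
  expect_equal(nrow(steiger_filter(mk(2, 10), 30000, 30000)), 0)
  # near-tied explained variances are not significantly different
  kept <- steiger_filter(mk(5, 5.1), 30000, 30000)
  expect_equal(nrow(kept), 1)
  # oracle: direct correlation comparison via Fisher z
  r <- function(z, n) sqrt(z^2 / (z^2 + n))
  zstat <- (atanh(r(5.1, 30000)) - atanh(r(5, 30000))) / sqrt(2 / (30000 - 3))
  expect_lt(zstat, qnorm(0.95))
  expect_warning(steiger_filter(mk(2, 10)), "without sample size")
})

test_that("IVW combines Wald ratios with inverse-variance weights", {
  one <- data.frame(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.25, se_out = 0.02)
  expect_equal(mr_ivw(one)$statistic, 0.5)
  two <- rbind(one, one)
  expect_equal(mr_ivw(two)$statistic, 0.5)
  expect_equal(mr_ivw(two)$se, mr_ivw(one)$se / sqrt(2), tolerance = 1e-12)
  set.seed(5)
  het <- data.frame(beta_exp = runif(5, 0.2, 0.6), se_exp = 0.01,
                    beta_out = rnorm(5, 0.1, 0.05), se_out = runif(5, 0.01, 0.05))
  fit <- mr_ivw(het)
  w <- het$beta_exp^2 / het$se_out^2      # 1 / se_ratio^2
  wald <- het$beta_out / het$beta_exp
  expect_equal(fit$statistic, sum(w * wald) / sum(w), tolerance = 1e-12)
  expect_equal(fit$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  het$beta_exp[1] <- 0
  expect_warning(fit2 <- mr_ivw(het), "zero exposure beta")
  expect_equal(fit2$n_snps_or_ivs, 4)
})

test_that("tissue aggregation keeps the lowest p-value result", {
  res <- data.frame(p = c(0.01, 0.001), tissue = c("blood", "brain"),
                    statistic = c(0.1, 0.3))
  expect_equal(aggregate_tissues(res)$tissue, "brain")
  expect_equal(aggregate_tissues(res[1, , drop = FALSE])$tissue, "blood")
  set.seed(8)
  many <- data.frame(p = runif(10), tissue = sprintf("t%02d", 1:10))
  expect_equal(aggregate_tissues(many)$p, min(many$p))
  expect_error(aggregate_tissues(many[0, ]), "no tissue")
})

test_that("noise-free Wald ratios recover the causal effect exactly", {
  pairs <- data.frame(beta_exp = c(0.2, -0.15, 0.3),
                      se_exp = 1e-6,
                      beta_out = 0.4 * c(0.2, -0.15, 0.3),
                      se_out = c(0.01, 0.02, 0.005))
  expect_equal(mr_ivw(pairs)$statistic, 0.4, tolerance = 1e-12)
})
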