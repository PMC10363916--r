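# shared fixtures, all built in code

path_network <- function(weights = c(1, 1)) {
  gene_network(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                          weight = weights))
}

star_network <- function(n_leaves = 4) {
  gene_network(data.frame(node_a = "HUB",
                          node_b = paste0("L", seq_len(n_leaves)),
                          weight = 1))
}

# random connected weighted graph: random tree plus extra random edges
random_connected_network <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  el <- data.frame(node_a = nodes[parent[-1]], node_b = nodes[-1])
  if (extra > 0) {
    a <- sample.int(n, extra, replace = TRUE)
    b <- sample.int(n, extra, replace = TRUE)
    keep <- a != b
    el <- rbind(el, data.frame(node_a = nodes[a[keep]], node_b = nodes[b[keep]]))
  }
  el$weight <- runif(nrow(el), 0.2, 1)
  gene_network(el)
}

toy_assoc <- function(snp_id, ae, ao, freq, beta, se = 0.05, n = 10000) {
  data.frame(snp_id = snp_id, allele_effect = ae, allele_other = ao,
             freq = freq, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n = n, stringsAsFactors = FALSE)
}

# AR(1) correlation matrix
ar1 <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

# minimum-likelihood two-sided exact p oracles
hypergeom_twosided_oracle <- function(a, b, cc, d) {
  K <- a + cc            # targets
  n <- a + b             # prioritized
  N <- a + b + cc + d
  supp <- max(0, n + K - N):min(n, K)
  pmf <- dhyper(supp, K, N - K, n)
  sum(pmf[pmf <= dhyper(a, K, N - K, n) * (1 + 1e-7)])
}

binom_twosided_oracle <- function(x, n, p) {
  pmf <- dbinom(0:n, n, p)
  sum(pmf[pmf <= dbinom(x, n, p) * (1 + 1e-7)])
}

# brute-force AUC: concordant pairs + half ties
auc_pairs_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

small_cohort_config <- function(...) {
  defaults <- list(n_genes = 400, n_traits = 3, n_databases = 2,
                   testable_fractions = c("GWAS" = 1, "Exome" = 0.9),
                   frac_disease_genes = 0.1, target_enrichment_or = 2,
                   hub_bias = 1, edges_per_node = 3,
                   top_fraction = c("GWAS" = 0.05, "Exome" = 0.05),
                   seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}
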