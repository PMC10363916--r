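test_that("universe and backgrounds respect fractions, seeds and subsets", {
  cfg <- small_cohort_config(n_genes = 1000,
                             testable_fractions = c("GWAS" = 1, "Exome" = 0.1))
  u <- generate_universe(cfg)
  expect_length(u$universe, 1000)
  expect_identical(u$backgrounds$GWAS, u$universe)   # fraction 1 = identity
  expect_length(u$backgrounds$Exome, 100)
  expect_identical(generate_universe(cfg)$backgrounds$Exome,
                   u$backgrounds$Exome)              # determinism
  expect_true(all(u$backgrounds$Exome %in% u$universe))
  # different seeds give different subsets (checked on a small universe)
  draws <- vapply(1:20, function(s) {
    cfg_s <- small_cohort_config(n_genes = 10,
                                 testable_fractions = c("GWAS" = 1, "Exome" = 0.5),
                                 seed = s)
    paste(generate_universe(cfg_s)$backgrounds$Exome, collapse = ",")
  }, "")
  expect_gt(length(unique(draws)), 10)
  expect_error(synthetic_config(testable_fractions = c(GWAS = 1.4)),
               "testable_fractions")
})

test_that("cohort regeneration is deterministic and schema-consistent", {
  cfg <- small_cohort_config()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(serialize(c1$score_tables, NULL),
                   serialize(c2$score_tables, NULL))
  expect_identical(igraph::as_data_frame(c1$networks[[1]]$graph),
                   igraph::as_data_frame(c2$networks[[1]]$graph))
  for (me in names(c1$score_tables)) {
    for (tr in names(c1$score_tables[[me]])) {
      tab <- c1$score_tables[[me]][[tr]]
      expect_true(all(tab$gene_id %in% c1$backgrounds[[me]]))
      expect_true(all(tab$p > 0 & tab$p <= 1))
    }
    expect_true(all(c1$backgrounds[[me]] %in% c1$universe))
  }
})

test_that("null score tables are uniform and planted enrichment calibrates", {
  cfg_null <- small_cohort_config(n_genes = 2000, n_traits = 1,
                                  target_enrichment_or = 1)
  co <- generate_cohort(cfg_null, network = FALSE)
  tab <- co$score_tables$GWAS$T01
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # planted OR = 3: mean Fisher OR across seeded replicates near 3
  ors <- vapply(1:40, function(s) {
    cfg <- small_cohort_config(n_genes = 4000, n_traits = 1, n_databases = 1,
                               target_enrichment_or = 3,
                               top_fraction = c(GWAS = 0.02, Exome = 0.02),
                               seed = 1000 + s)
    co <- generate_cohort(cfg, network = FALSE)
    tab <- co$score_tables$GWAS$T01
    tg <- intersect(co$truth$targets$DB1$T01, co$backgrounds$GWAS)
    fe <- fisher_enrichment(top_genes(tab, 0.02), tg, co$backgrounds$GWAS)
    fe$log_or
  }, 1)
  mc_se <- sd(ors) / sqrt(length(ors))
  expect_lt(abs(mean(ors) - log(3)), 3 * mc_se + 0.05)
})

test_that("hub bias raises target degrees only when planted", {
  deltas <- function(hub_bias, seeds) {
    vapply(seeds, function(s) {
      cfg <- small_cohort_config(n_genes = 600, n_traits = 2,
                                 hub_bias = hub_bias, seed = s)
      co <- generate_cohort(cfg, score_tables = FALSE)
      d <- degree_scores(co$networks[[1]])
      tg <- unique(unlist(co$truth$targets, use.names = FALSE))
      is_t <- names(d) %in% tg
      t.test(log(d[is_t]), log(d[!is_t]))$p.value *
        sign(mean(log(d[is_t])) - mean(log(d[!is_t])))
    }, 1)
  }
  unbiased <- deltas(0, 1:20)
  expect_gte(mean(abs(unbiased) > 0.05), 0.75)  # mostly non-significant
  biased <- deltas(2, 21:35)
  expect_gte(mean(biased > 0 & biased < 0.05), 0.8)  # positive and significant
})

test_that("erdos-renyi networks are symmetric and repaired to one component", {
  cfg <- small_cohort_config(n_genes = 5, network_model = "erdos_renyi",
                             er_edge_prob = 1)
  co <- generate_cohort(cfg, score_tables = FALSE)
  d <- degree_scores(co$networks[[1]])
  expect_equal(igraph::ecount(co$networks[[1]]$graph), 10)  # complete graph
  cfg2 <- small_cohort_config(n_genes = 300, network_model = "erdos_renyi",
                              er_edge_prob = 0.005)
  co2 <- generate_cohort(cfg2, score_tables = FALSE)
  expect_equal(igraph::count_components(co2$networks[[1]]$graph), 1)
  expect_error(generate_network(list(universe = c("a", "b"),
                                     truth = list(targets = list())),
                                cfg2),
               "at least 3")
})

test_that("drug tables exercise the filters and recover planted targets", {
  cfg <- small_cohort_config()
  co <- generate_cohort(cfg, score_tables = FALSE, network = FALSE)
  for (db in names(co$drug_tables)) {
    tabs <- co$drug_tables[[db]]
    sets <- build_target_sets(tabs$indications, tabs$drug_targets,
                              min_confidence = 700,
                              allowed_types = c("inhibition", "activation"),
                              universe = co$universe)
    for (tr in names(tabs$targets)) {
      expect_equal(sets[[tr]], tabs$targets[[tr]])
    }
    # decoys exist and are removed by the filters
    expect_gt(nrow(tabs$drug_targets),
              sum(lengths(tabs$targets)))
  }
  # all-high-confidence inhibition rows survive default-free filtering
  ind <- data.frame(trait_id = "t", drug_id = "d")
  tgt <- data.frame(drug_id = "d", gene_id = c("g1", "g2"),
                    confidence = 900, interaction_type = "inhibition")
  expect_length(build_target_sets(ind, tgt, 700,
                                  c("inhibition", "activation"))$t, 2)
  tgt$confidence <- 600
  s600 <- build_target_sets(ind, tgt, 700, c("inhibition", "activation"))
  expect_length(s600$t, 0)
  expect_true(attr(s600, "empty")[["t"]])
})

test_that("MR dataset generation plants effects and contaminants exactly", {
  d <- generate_mr_dataset(10, 0.4, 30000, 50000,
                           contamination = c(palindromic = 3,
                                             freq_mismatch = 2,
                                             reverse_causal = 2),
                           seed = 4)
  expect_equal(nrow(d$exposure), 17)
  h <- harmonize(d$exposure, d$outcome)
  expect_false(any(d$truth$palindromic %in% h$snp_id))
  expect_false(any(d$truth$freq_mismatch %in% h$snp_id))
  expect_true(all(d$truth$clean %in% h$snp_id))
  sel <- select_instruments(h)
  st <- steiger_filter(sel, n_exp = 30000, n_out = 50000)
  expect_false(any(d$truth$reverse_causal %in% st$snp_id))
  expect_true(all(d$truth$clean %in% st$snp_id))
  expect_error(generate_mr_dataset(-1, 0.4, 100, 100), "nonnegative")
  expect_error(generate_mr_dataset(5, 0.4, -100, 100), "positive")
})

test_that("IVW recovers the planted causal effect across replicates", {
  est <- vapply(1:60, function(s) {
    d <- generate_mr_dataset(30, 0.4, 30000, 50000, seed = s)
    h <- harmonize(d$exposure, d$outcome)
    mr_ivw(steiger_filter(select_instruments(h), 30000, 50000))$statistic
  }, 1)
  expect_lt(abs(mean(est) - 0.4), 3 * sd(est) / sqrt(length(est)) + 0.005)
})

test_that("a cohort round-trips through the on-disk formats", {
  cfg <- small_cohort_config(n_genes = 120, n_traits = 2, n_databases = 1)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  net <- load_network(file.path(dir, "network_preferential_attachment.tsv"))
  expect_equal(igraph::ecount(net$graph),
               igraph::ecount(co$networks[[1]]$graph))
  sc <- read.delim(file.path(dir, "scores_GWAS_T01.tsv"))
  expect_equal(nrow(sc), nrow(co$score_tables$GWAS$T01))
  ing <- ingest_gene_pvalues(sc[, c("gene_id", "p")], "GWAS")
  expect_equal(nrow(ing), nrow(sc))
  gmt <- read_gmt(file.path(dir, "targets_DB1.gmt"))
  expect_equal(gmt[["T01"]], co$truth$targets$DB1$T01, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$target_enrichment_or, cfg$target_enrichment_or)
})
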