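METHODS <- c("GWAS", "eQTL-GWAS", "pQTL-GWAS", "Exome")

#' Configuration of the synthetic benchmarking cohort
#'
#' Defines the statistical structure of generated inputs: universe size,
#' per-method testable fractions (very different between methods, as in
#' real data, where plasma pQTL instruments exist for only ~10% of
#' protein-coding genes), planted disease genes and target enrichment,
#' hub bias of target genes in the interaction network, and the
#' trait/database correlation model.
#'
#' @param n_genes number of genes in the universe (default 19430, the
#'   conventional count of autosomal protein-coding genes).
#' @param n_traits number of traits (default 30).
#' @param n_databases number of drug databases (default 5).
#' @param testable_fractions named per-method fractions in (0, 1].
#' @param frac_disease_genes fraction of the universe planted as disease
#'   genes per trait, in (0, 1).
#' @param target_enrichment_or planted odds ratio between top-scored genes
#'   and drug targets (positive; 1 = no enrichment).
#' @param hub_bias nonnegative attachment multiplier surplus for target
#'   genes in the preferential-attachment network (0 = no bias; the
#'   attachment probability of a target is scaled by `1 + hub_bias`).
#' @param network_model `"preferential_attachment"` or `"erdos_renyi"`.
#' @param db_target_fraction probability that a trait's disease gene is a
#'   target in any given database (controls between-database overlap).
#' @param top_fraction named per-method top fractions used to calibrate
#'   the planted enrichment (defaults 0.01, and 0.05 for pQTL-GWAS).
#' @param trait_corr trait correlation matrix (default identity: traits
#'   are generated independently).
#' @param db_corr database correlation matrix, or NULL to estimate it
#'   from generated target membership (the gene-level indicator
#'   correlation).
#' @param edges_per_node attachment edges per node in the
#'   preferential-attachment model (default 3).
#' @param er_edge_prob edge probability of the Erdos-Renyi model.
#' @param seed integer global seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 19430, n_traits = 30, n_databases = 5,
                             testable_fractions = c("GWAS" = 0.985,
                                                    "eQTL-GWAS" = 0.84,
                                                    "pQTL-GWAS" = 0.096,
                                                    "Exome" = 0.97),
                             frac_disease_genes = 0.05,
                             target_enrichment_or = 2,
                             hub_bias = 1,
                             network_model = c("preferential_attachment",
                                               "erdos_renyi"),
                             db_target_fraction = 0.6,
                             top_fraction = c("GWAS" = 0.01,
                                              "eQTL-GWAS" = 0.01,
                                              "pQTL-GWAS" = 0.05,
                                              "Exome" = 0.01),
                             trait_corr = NULL, db_corr = NULL,
                             edges_per_node = 3, er_edge_prob = NULL,
                             seed = 1L) {
  network_model <- match.arg(network_model)
  if (any(testable_fractions <= 0) || any(testable_fractions > 1)) {
    stop_config("testable_fractions must lie in (0, 1]")
  }
  if (is.null(names(testable_fractions))) {
    stop_config("testable_fractions must be named by method")
  }
  if (frac_disease_genes <= 0 || frac_disease_genes >= 1) {
    stop_config("frac_disease_genes must lie in (0, 1)")
  }
  if (target_enrichment_or <= 0) stop_config("target_enrichment_or must be positive")
  if (hub_bias < 0) stop_config("hub_bias must be nonnegative")
  if (db_target_fraction <= 0 || db_target_fraction > 1) {
    stop_config("db_target_fraction must lie in (0, 1]")
  }
  if (!is.null(trait_corr)) check_correlation_matrix(trait_corr, "trait_corr")
  if (!is.null(db_corr)) check_correlation_matrix(db_corr, "db_corr")
  cfg <- list(n_genes = as.integer(n_genes), n_traits = as.integer(n_traits),
              n_databases = as.integer(n_databases),
              testable_fractions = testable_fractions,
              frac_disease_genes = frac_disease_genes,
              target_enrichment_or = target_enrichment_or,
              hub_bias = hub_bias, network_model = network_model,
              db_target_fraction = db_target_fraction,
              top_fraction = top_fraction,
              trait_corr = trait_corr, db_corr = db_corr,
              edges_per_node = as.integer(edges_per_node),
              er_edge_prob = er_edge_prob, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic_config: %d genes, %d traits, %d databases, ",
                     "planted OR %.2f, hub bias %.2f, %s network, seed %d\n"),
              x$n_genes, x$n_traits, x$n_databases, x$target_enrichment_or,
              x$hub_bias, x$network_model, x$seed))
  invisible(x)
}

#' Generate the gene universe and per-method backgrounds
#'
#' @param config a [synthetic_config()].
#' @return Cohort skeleton: list with `universe` (gene ids) and
#'   `backgrounds` (named list of seeded gene subsets, one per method,
#'   of the configured fractions).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  universe <- sprintf("G%06d", seq_len(config$n_genes))
  backgrounds <- lapply(seq_along(config$testable_fractions), function(i) {
    f <- config$testable_fractions[i]
    if (f == 1) return(universe)
    k <- max(1L, round(f * config$n_genes))
    sort(with_seed(child_seed(config$seed, 100 + i),
                   sample(universe, k)))
  })
  names(backgrounds) <- names(config$testable_fractions)
  list(universe = universe, backgrounds = backgrounds)
}

# mean of the folded-normal signal z-scores needed to plant a given
# top-fraction x target odds ratio. Calibrated against the finite-sample
# estimator: mu is chosen so that the expected *estimated* log-OR of the
# exact-top-k Fisher table (binomial model over the target cell, with the
# pipeline's a = 0 -> OR := 1 and zero-diagonal fallbacks) equals
# log(or_target) at the given background size. See the methods vignette.
calibrate_signal_mu <- function(or_target, q, frac_disease, db_fraction,
                                n_bg) {
  if (or_target < 1) stop_config("planted odds ratios below 1 are not supported")
  if (abs(or_target - 1) < 1e-12) return(0)
  f <- frac_disease
  s <- db_fraction
  k <- max(1L, floor(q * n_bg))
  n_t <- max(1L, round(f * s * n_bg))     # expected targets in the background
  pi_sig <- function(mu, c) {
    x <- qnorm(c / 2, lower.tail = FALSE)
    pnorm(mu - x) + pnorm(-mu - x)
  }
  elog_or <- function(mu) {
    # threshold c* keeps the expected top fraction at q (solved on the log
    # scale: c* can be astronomically small for strong signal means)
    cstar <- exp(uniroot(function(lc) f * pi_sig(mu, exp(lc)) +
                           (1 - f) * exp(lc) - q,
                         lower = log(1e-280), upper = log(q),
                         tol = 1e-12)$root)
    pt <- pi_sig(mu, cstar)
    a <- 0:min(k, n_t)
    pa <- dbinom(a, n_t, pt)
    lor <- log(pmax(a, 1)) + log(pmax(n_bg - k - n_t + a, 1)) -
      log(pmax(k - a, 1)) - log(pmax(n_t - a, 1))
    lor[a == 0] <- 0                       # fallback rule: OR set to 1
    sum(pa * lor)
  }
  uniroot(function(mu) elog_or(mu) - log(or_target), lower = 0, upper = 15,
          tol = 1e-10, extendInt = "upX")$root
}

#' Generate one trait x method gene score table
#'
#' Null genes receive uniform p-values; the trait's disease genes receive
#' p-values mapped from folded-normal z-scores with mean `mu` calibrated
#' numerically so that the expected 2x2 table of top-fraction membership
#' against database target membership has the configured odds ratio.
#'
#' @param cohort a generated cohort (needs `backgrounds` and
#'   `disease_genes`).
#' @param trait trait id (e.g. `"T01"`).
#' @param method one of the configured method names.
#' @param config the [synthetic_config()].
#' @return data.frame with `gene_id`, `p`, `statistic` (z), `method`,
#'   `trait`, sorted by ascending p.
#' @export
generate_score_table <- function(cohort, trait, method, config) {
  if (!method %in% names(cohort$backgrounds)) {
    stop_config("unknown method '%s'", method)
  }
  bg <- cohort$backgrounds[[method]]
  disease <- intersect(cohort$disease_genes[[trait]], bg)
  q <- config$top_fraction[[method]] %||% 0.01
  mu <- calibrate_signal_mu(config$target_enrichment_or, q,
                            config$frac_disease_genes,
                            config$db_target_fraction, length(bg))
  trait_i <- match(trait, names(cohort$disease_genes))
  method_i <- match(method, names(cohort$backgrounds))
  tab <- with_seed(child_seed(config$seed, 1000 + 50 * trait_i + method_i), {
    z <- rnorm(length(bg))
    sig <- bg %in% disease
    z[sig] <- z[sig] + mu * sample(c(-1, 1), sum(sig), replace = TRUE)
    data.frame(gene_id = bg, p = 2 * pnorm(-abs(z)), statistic = z,
               method = method, trait = trait, stringsAsFactors = FALSE)
  })
  tab[order(tab$p, tab$gene_id), , drop = FALSE]
}

# preferential attachment with a fitness multiplier for target genes,
# sampled by endpoint-list rejection (attachment prob proportional to
# degree x fitness)
sample_pa_fitness <- function(nodes, m, fitness, seed) {
  n <- length(nodes)
  if (n < 3) stop_config("need at least 3 genes to build a network")
  m <- min(m, n - 1L)
  with_seed(seed, {
    order_idx <- sample.int(n)       # arrival order decoupled from identity
    fmax <- max(fitness)
    ends <- integer(2L * m * n)      # flat endpoint list, nodes repeated by degree
    n_ends <- 0L
    efrom <- integer(m * n); eto <- integer(m * n); n_e <- 0L
    init <- order_idx[seq_len(m + 1L)]
    for (i in seq_len(m)) {
      for (j in seq(i + 1L, m + 1L)) {
        n_e <- n_e + 1L
        efrom[n_e] <- init[i]; eto[n_e] <- init[j]
        ends[n_ends + 1L] <- init[i]; ends[n_ends + 2L] <- init[j]
        n_ends <- n_ends + 2L
      }
    }
    chosen <- integer(m)
    blk <- 8L * m
    for (t in seq(m + 2L, n)) {
      v <- order_idx[t]
      n_chosen <- 0L
      while (n_chosen < m) {
        # endpoint-list rejection sampling, drawn in blocks for speed
        cand_blk <- ends[sample.int(n_ends, blk, replace = TRUE)]
        acc_blk <- runif(blk) <= fitness[cand_blk] / fmax
        for (bi in seq_len(blk)) {
          if (!acc_blk[bi]) next
          cand <- cand_blk[bi]
          if (n_chosen > 0L && cand %in% chosen[seq_len(n_chosen)]) next
          n_chosen <- n_chosen + 1L
          chosen[n_chosen] <- cand
          if (n_chosen == m) break
        }
      }
      for (ci in seq_len(m)) {
        u <- chosen[ci]
        n_e <- n_e + 1L
        efrom[n_e] <- v; eto[n_e] <- u
        ends[n_ends + 1L] <- v; ends[n_ends + 2L] <- u
        n_ends <- n_ends + 2L
      }
    }
    data.frame(node_a = nodes[efrom[seq_len(n_e)]],
               node_b = nodes[eto[seq_len(n_e)]],
               stringsAsFactors = FALSE)
  })
}

#' Generate a weighted gene network with optional target hub bias
#'
#' Under the preferential-attachment model, target genes attach with
#' probability scaled by `1 + hub_bias`, reproducing the empirical
#' pattern that drug targets tend to be network hubs. Edge weights are
#' drawn uniformly from (0.15, 1] (score-like weights). Disconnected
#' components (possible under the Erdos-Renyi model) are bridged by
#' minimum-weight edges so the restart-free random walk is irreducible.
#'
#' @param cohort generated cohort (needs `universe` and `truth$targets`).
#' @param config the [synthetic_config()].
#' @return A `gene_network` over the universe.
#' @export
generate_network <- function(cohort, config) {
  nodes <- cohort$universe
  n <- length(nodes)
  if (n < 3) stop_config("need at least 3 genes to build a network")
  all_targets <- unique(unlist(cohort$truth$targets, use.names = FALSE))
  seed <- child_seed(config$seed, 300)
  if (config$network_model == "preferential_attachment") {
    fitness <- ifelse(nodes %in% all_targets, 1 + config$hub_bias, 1)
    el <- sample_pa_fitness(nodes, config$edges_per_node, fitness, seed)
  } else {
    p <- config$er_edge_prob %||% min(1, 2 * config$edges_per_node / (n - 1))
    g <- with_seed(seed, igraph::sample_gnp(n, p))
    igraph::V(g)$name <- nodes
    el <- igraph::as_data_frame(g, what = "edges")
    names(el) <- c("node_a", "node_b")
  }
  el$weight <- with_seed(child_seed(config$seed, 301),
                         runif(nrow(el), min = 0.15, max = 1))
  net <- gene_network(el)
  # connectivity repair: bridge every secondary component to the giant one
  comp <- igraph::components(net$graph)
  if (comp$no > 1L) {
    giant <- which.max(comp$csize)
    wmin <- min(igraph::E(net$graph)$weight)
    anchor <- network_nodes(net)[comp$membership == giant][1L]
    extra <- lapply(setdiff(seq_len(comp$no), giant), function(k) {
      data.frame(node_a = network_nodes(net)[comp$membership == k][1L],
                 node_b = anchor, weight = wmin, stringsAsFactors = FALSE)
    })
    el <- rbind(el, do.call(rbind, extra))
    net <- gene_network(el)
  }
  net
}

#' Generate indication-drug and drug-target tables for one database
#'
#' Each trait is indicated for at least one drug and each drug targets at
#' least one gene. True target rows carry high confidence scores (700 to
#' 1000) and allowed interaction types ("inhibition"/"activation"); decoy
#' rows with sub-threshold confidence or disallowed types are added so
#' that the standard filters are exercised and recover exactly the
#' planted target sets.
#'
#' @param cohort generated cohort (needs `disease_genes`, `universe`).
#' @param config the [synthetic_config()].
#' @param db_index database index (1 .. n_databases).
#' @return List with `indications` (trait_id, drug_id), `drug_targets`
#'   (drug_id, gene_id, confidence, interaction_type) and `targets`
#'   (planted per-trait target sets after filtering).
#' @export
generate_drug_tables <- function(cohort, config, db_index = 1L) {
  traits <- names(cohort$disease_genes)
  seed <- child_seed(config$seed, 400 + db_index)
  with_seed(seed, {
    ind <- list(); tgt <- list(); planted <- list()
    for (tr in traits) {
      genes <- cohort$disease_genes[[tr]]
      sel <- genes[runif(length(genes)) < config$db_target_fraction]
      planted[[tr]] <- sort(sel)
      n_drugs <- sample(1:3, 1L)
      drugs <- sprintf("DB%d_%s_drug%d", db_index, tr, seq_len(n_drugs))
      ind[[tr]] <- data.frame(trait_id = tr, drug_id = drugs,
                              stringsAsFactors = FALSE)
      if (length(sel) > 0) {
        # every drug gets >= 1 target when possible
        assign_to <- if (length(sel) >= n_drugs) {
          c(seq_len(n_drugs), sample.int(n_drugs, length(sel) - n_drugs,
                                         replace = TRUE))
        } else sample.int(n_drugs, length(sel), replace = TRUE)
        rows <- data.frame(drug_id = drugs[assign_to], gene_id = sample(sel),
                           confidence = round(runif(length(sel), 700, 1000)),
                           interaction_type = sample(c("inhibition", "activation"),
                                                     length(sel), replace = TRUE),
                           stringsAsFactors = FALSE)
      } else rows <- NULL
      # decoys removed by the default filters
      n_decoy <- max(2L, ceiling(length(sel) / 2))
      decoy_genes <- sample(cohort$universe, n_decoy)
      half <- n_decoy %/% 2
      decoys <- data.frame(
        drug_id = sample(drugs, n_decoy, replace = TRUE),
        gene_id = decoy_genes,
        confidence = c(round(runif(half, 150, 699)),
                       round(runif(n_decoy - half, 700, 1000))),
        interaction_type = c(sample(c("inhibition", "activation", "binding"),
                                    half, replace = TRUE),
                             rep("binding", n_decoy - half)),
        stringsAsFactors = FALSE)
      # a decoy hitting a planted target would survive the filters
      decoys <- decoys[!(decoys$gene_id %in% sel &
                           decoys$confidence >= 700 &
                           decoys$interaction_type %in% c("inhibition", "activation")), ,
                       drop = FALSE]
      tgt[[tr]] <- rbind(rows, decoys)
    }
    list(indications = unique(do.call(rbind, ind)),
         drug_targets = unique(do.call(rbind, tgt)),
         targets = planted)
  })
}

#' Generate paired exposure/outcome summary statistics for MR testing
#'
#' Simulates `n_iv` strong, independent instruments with exposure effects
#' of magnitude 0.1 to 0.3 and outcome effects `true_beta` times the
#' exposure effect, plus sampling noise at the stated sample sizes
#' (standardized-trait standard errors `1/sqrt(n)`). Optional
#' contamination injects palindromic SNPs, allele-frequency mismatches
#' and reverse-causal instruments, whose identities are recorded in the
#' truth so that filter behaviour can be checked exactly.
#'
#' @param n_iv number of clean instruments (>= 0).
#' @param true_beta causal effect of the exposure on the outcome.
#' @param n_exp,n_out positive sample sizes of the exposure and outcome
#'   studies.
#' @param contamination named counts
#'   `c(palindromic =, freq_mismatch =, reverse_causal =)`.
#' @param seed integer seed.
#' @return List with `exposure` and `outcome` association data.frames and
#'   `truth` (true beta and per-type contaminant snp ids).
#' @export
generate_mr_dataset <- function(n_iv, true_beta, n_exp, n_out,
                                contamination = c(palindromic = 0L,
                                                  freq_mismatch = 0L,
                                                  reverse_causal = 0L),
                                seed = 1L) {
  if (n_iv < 0) stop_config("n_iv must be nonnegative")
  if (n_exp <= 0 || n_out <= 0) stop_config("sample sizes must be positive")
  cont <- c(palindromic = 0L, freq_mismatch = 0L, reverse_causal = 0L)
  cont[names(contamination)] <- as.integer(contamination)
  n_total <- n_iv + sum(cont)
  allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                        c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  with_seed(child_seed(seed, 500), {
    snp <- sprintf("rs%05d", seq_len(n_total))
    kind <- rep(c("clean", "palindromic", "freq_mismatch", "reverse_causal"),
                c(n_iv, cont["palindromic"], cont["freq_mismatch"],
                  cont["reverse_causal"]))
    ap <- allele_pairs[sample.int(nrow(allele_pairs), n_total, replace = TRUE), ,
                       drop = FALSE]
    pal_idx <- which(kind == "palindromic")
    if (length(pal_idx)) {
      pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
      ap[pal_idx, ] <- pal_pairs[sample.int(4, length(pal_idx), replace = TRUE), ,
                                 drop = FALSE]
    }
    freq <- runif(n_total, 0.10, 0.90)
    se_e <- 1 / sqrt(n_exp)
    se_o <- 1 / sqrt(n_out)
    b0 <- sample(c(-1, 1), n_total, replace = TRUE) * runif(n_total, 0.1, 0.3)
    beta_e <- b0 + rnorm(n_total, sd = se_e)
    beta_o <- true_beta * b0 + rnorm(n_total, sd = se_o)
    rev_idx <- which(kind == "reverse_causal")
    if (length(rev_idx)) {
      # outcome effect far stronger than the exposure effect
      beta_e[rev_idx] <- sample(c(-1, 1), length(rev_idx), TRUE) *
        (6 * se_e + abs(rnorm(length(rev_idx), sd = se_e)))
      beta_o[rev_idx] <- sample(c(-1, 1), length(rev_idx), TRUE) *
        (30 * se_o + abs(rnorm(length(rev_idx), sd = se_o)))
    }
    freq_out <- freq
    fm_idx <- which(kind == "freq_mismatch")
    if (length(fm_idx)) {
      shift <- runif(length(fm_idx), 0.06, 0.2)
      freq_out[fm_idx] <- pmin(0.99, pmax(0.01, freq[fm_idx] +
                                            ifelse(freq[fm_idx] < 0.5, shift, -shift)))
    }
    exposure <- data.frame(snp_id = snp, allele_effect = ap[, 1],
                           allele_other = ap[, 2], freq = freq,
                           beta = beta_e, se = se_e,
                           p = 2 * pnorm(-abs(beta_e / se_e)), n = n_exp,
                           stringsAsFactors = FALSE)
    outcome <- data.frame(snp_id = snp, allele_effect = ap[, 1],
                          allele_other = ap[, 2], freq = freq_out,
                          beta = beta_o, se = se_o,
                          p = 2 * pnorm(-abs(beta_o / se_o)), n = n_out,
                          stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         truth = list(true_beta = true_beta,
                      clean = snp[kind == "clean"],
                      palindromic = snp[kind == "palindromic"],
                      freq_mismatch = snp[kind == "freq_mismatch"],
                      reverse_causal = snp[kind == "reverse_causal"]))
  })
}

#' Generate a complete synthetic benchmarking cohort
#'
#' Orchestrates [generate_universe()], per-trait disease gene planting,
#' [generate_drug_tables()] for each database, [generate_network()] and
#' [generate_score_table()] for every trait x method, and records the
#' ground truth (planted disease genes, target sets, odds ratio, hub
#' bias). Regenerating with the same configuration reproduces identical
#' output.
#'
#' @param config a [synthetic_config()].
#' @param score_tables generate the full set of score tables (default
#'   TRUE; FALSE defers to on-demand [generate_score_table()] calls).
#' @param network build the gene network (default TRUE).
#' @return Object of class `synthetic_cohort`.
#' @export
generate_cohort <- function(config, score_tables = TRUE, network = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  skel <- generate_universe(config)
  cohort <- list(universe = skel$universe, backgrounds = skel$backgrounds,
                 config = config)
  n_dis <- max(1L, round(config$frac_disease_genes * config$n_genes))
  traits <- sprintf("T%02d", seq_len(config$n_traits))
  cohort$disease_genes <- setNames(lapply(seq_along(traits), function(i) {
    sort(with_seed(child_seed(config$seed, 200 + i),
                   sample(cohort$universe, n_dis)))
  }), traits)
  dbs <- sprintf("DB%d", seq_len(config$n_databases))
  cohort$drug_tables <- setNames(lapply(seq_len(config$n_databases), function(d) {
    generate_drug_tables(cohort, config, d)
  }), dbs)
  targets <- setNames(lapply(dbs, function(d) cohort$drug_tables[[d]]$targets), dbs)
  cohort$truth <- list(disease_genes = cohort$disease_genes,
                       targets = targets,
                       target_enrichment_or = config$target_enrichment_or,
                       hub_bias = config$hub_bias,
                       seed = config$seed)
  if (network) cohort$networks <- setNames(list(generate_network(cohort, config)),
                                           config$network_model)
  if (score_tables) {
    cohort$score_tables <- setNames(lapply(names(cohort$backgrounds), function(me) {
      setNames(lapply(traits, function(tr) {
        generate_score_table(cohort, tr, me, config)
      }), traits)
    }), names(cohort$backgrounds))
  }
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d genes, %d traits, %d database(s); ",
                     "backgrounds: %s\n"),
              length(x$universe), length(x$disease_genes),
              length(x$drug_tables),
              paste(sprintf("%s=%d", names(x$backgrounds),
                            vapply(x$backgrounds, length, 1L)), collapse = ", ")))
  invisible(x)
}

#' Database correlation from target membership indicators
#'
#' The database correlation matrix is derived at the gene level: for each
#' database, a gene scores 1 if it is a drug target for any trait and 0
#' otherwise, and the correlation of these indicator vectors over the
#' universe is returned (diagonal exactly 1).
#'
#' @param targets_by_db named list (per database) of per-trait target
#'   gene set lists.
#' @param universe gene universe.
#' @return Database correlation matrix.
#' @export
db_membership_correlation <- function(targets_by_db, universe) {
  M <- vapply(targets_by_db, function(per_trait) {
    as.numeric(universe %in% unique(unlist(per_trait, use.names = FALSE)))
  }, numeric(length(universe)))
  R <- suppressWarnings(cor(M))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes per-method score tables and backgrounds as TSV, the network as
#' a three-column edge list TSV, indication and drug-target tables as
#' TSV, target sets as GMT, and the ground truth as JSON, under `dir`.
#'
#' @param cohort a `synthetic_cohort` with score tables and network.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  for (me in names(cohort$score_tables)) {
    for (tr in names(cohort$score_tables[[me]])) {
      wt(cohort$score_tables[[me]][[tr]],
         sprintf("scores_%s_%s.tsv", gsub("[^A-Za-z0-9]", "", me), tr))
    }
    writeLines(cohort$backgrounds[[me]],
               file.path(dir, sprintf("background_%s.txt",
                                      gsub("[^A-Za-z0-9]", "", me))))
  }
  for (db in names(cohort$drug_tables)) {
    wt(cohort$drug_tables[[db]]$indications, sprintf("indications_%s.tsv", db))
    wt(cohort$drug_tables[[db]]$drug_targets, sprintf("drug_targets_%s.tsv", db))
    write_gmt(cohort$drug_tables[[db]]$targets,
              file.path(dir, sprintf("targets_%s.gmt", db)))
  }
  if (!is.null(cohort$networks)) {
    for (nm in names(cohort$networks)) {
      el <- igraph::as_data_frame(cohort$networks[[nm]]$graph, what = "edges")
      names(el) <- c("node_a", "node_b", "weight")
      wt(el, sprintf("network_%s.tsv", nm))
    }
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
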