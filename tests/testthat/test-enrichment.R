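make_diff <- function(log2FC, p, ids = paste0("m", seq_along(p))) {
  data.frame(feature_id = ids, log2FC = log2FC, p = p, fdr = bh_adjust(p),
             stringsAsFactors = FALSE)
}

test_that("DA score hits the +/-100 boundaries and the direct formula", {
  ann5 <- pathway_annotation(paste0("m", 1:5), rep("Lipid", 5), rep("DG", 5))
  up <- make_diff(rep(1, 5), rep(0.01, 5))
  expect_equal(differential_abundance_score(up, ann5)$da_score, 100)
  down <- make_diff(rep(-1, 5), rep(0.01, 5))
  expect_equal(differential_abundance_score(down, ann5)$da_score, -100)

  # 10 measured, 7 significantly up, 2 significantly down -> 50
  d <- make_diff(c(rep(1, 7), rep(-1, 2), 1),
                 c(rep(0.01, 9), 0.5), ids = paste0("m", 1:10))
  ann10 <- pathway_annotation(paste0("m", 1:10), rep("Lipid", 10), rep("TG", 10))
  tab <- differential_abundance_score(d, ann10)
  expect_equal(tab[, c("n_measured", "n_up", "n_down", "da_score")],
               data.frame(n_measured = 10L, n_up = 7L, n_down = 2L, da_score = 50))
})

test_that("inclusion rules gate subpathways as documented", {
  # 3 measured, none significant: excluded under the altered rule,
  # kept (score 0) under the measured rule
  d <- make_diff(rep(1, 3), rep(0.5, 3), ids = paste0("m", 1:3))
  ann <- pathway_annotation(paste0("m", 1:3), rep("Lipid", 3), rep("SP", 3))
  tab_alt <- differential_abundance_score(d, ann, rule = "altered")
  expect_equal(nrow(tab_alt), 0)
  expect_equal(attr(tab_alt, "excluded"), "SP")
  tab_meas <- differential_abundance_score(d, ann, rule = "measured")
  expect_equal(tab_meas$da_score, 0)
  expect_error(differential_abundance_score(d, ann[0, ]), "empty")
})

test_that("hypergeometric ORA equals exhaustive enumeration", {
  # worked example: N=10, K=4, n=3, k=3 -> 4/120
  d <- make_diff(rep(1, 10), c(rep(0.01, 4), rep(0.5, 6)),
                 ids = paste0("m", 1:10))
  res <- ora_hypergeometric(d, list(S = paste0("m", 1:3)))
  expect_equal(res$p, 4 / 120, tolerance = 1e-12)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 3L, K = 4L, n = 3L, N = 10L))

  # k = 0 with K = 0 -> p = 1
  d0 <- make_diff(rep(1, 6), rep(0.5, 6), ids = paste0("m", 1:6))
  expect_equal(ora_hypergeometric(d0, list(S = paste0("m", 1:3)))$p, 1)

  # members outside the universe are dropped with a warning
  expect_warning(
    res2 <- ora_hypergeometric(d, list(S = c("m1", "m2", "nope"))),
    "not in the measured universe")
  expect_equal(res2$n, 2L)

  # enumeration across universes up to N = 12
  withr::with_seed(21, {
    for (N in 5:12) {
      K <- sample(0:N, 1)
      n <- sample(1:(N - 1), 1)
      d <- make_diff(rep(1, N), c(rep(0.01, K), rep(0.5, N - K)),
                     ids = paste0("m", 1:N))
      for (rep_i in 1:3) {
        set_members <- paste0("m", sample(N, n))
        got <- ora_hypergeometric(d, list(S = set_members))
        want <- hyper_enum_oracle(got$k, K, n, N)
        expect_equal(got$p, want, tolerance = 1e-10)
      }
    }
  })
})

test_that("subpathway ranking orders by stars, then mean |DA|, then name", {
  mk <- function(sp, da, star) {
    data.frame(sub_pathway = sp, n_measured = 5L, n_up = 0L, n_down = 0L,
               da_score = da, ora_p = NA_real_, ora_fdr = NA_real_,
               star = star, stringsAsFactors = FALSE)
  }
  t1 <- mk(c("A", "B", "C", "D"), c(60, 40, 60, 60), c(TRUE, TRUE, FALSE, FALSE))
  t2 <- mk(c("A", "B", "C", "D"), c(60, -40, 40, 60), c(TRUE, FALSE, FALSE, FALSE))
  rk <- rank_subpathways(list(x = t1, y = t2))
  expect_equal(rk$sub_pathway, c("A", "B", "D", "C"))
  expect_equal(rk$n_star, c(2, 1, 0, 0))
  # fully tied subpathways fall back to alphabetical order
  t3 <- mk(c("Z", "M", "A"), c(10, 10, 10), rep(FALSE, 3))
  expect_equal(rank_subpathways(list(only = t3))$sub_pathway, c("A", "M", "Z"))
  # outer union: subpathway missing from one comparison
  t4 <- mk("A", 20, FALSE)
  rk2 <- rank_subpathways(list(x = t1, y = t4))
  expect_equal(rk2$mean_abs_da[rk2$sub_pathway == "B"], 40)
})

test_that("signal-to-noise metric follows the floored formula and antisymmetry", {
  withr::with_seed(22, {
    m <- rbind(matrix(rnorm(20, 2), nrow = 4), matrix(rnorm(20, 1), nrow = 4))
    dimnames(m) <- list(paste0("s", 1:8), paste0("f", 1:5))
    fm <- feature_matrix(m, data.frame(group = rep(c("P1", "P2"), each = 4),
                                       row.names = rownames(m)), unit = "log2")
    r <- signal_to_noise_ranking(fm, c("P1", "P2"))
    for (j in 1:5) {
      mu1 <- mean(m[1:4, j]); mu2 <- mean(m[5:8, j])
      s1 <- max(sd(m[1:4, j]), 0.2 * abs(mu1), 1e-8)
      s2 <- max(sd(m[5:8, j]), 0.2 * abs(mu2), 1e-8)
      expect_equal(r$metric[r$feature_id == paste0("f", j)],
                   (mu1 - mu2) / (s1 + s2), tolerance = 1e-12)
    }
    # swapping the phenotype labels negates the metric and reverses the order
    r_swap <- signal_to_noise_ranking(fm, c("P2", "P1"))
    expect_equal(r_swap$metric[match(r$feature_id, r_swap$feature_id)],
                 -r$metric, tolerance = 1e-12)
    # identical groups give metric 0
    m0 <- rbind(m[1:4, ], m[1:4, ])
    rownames(m0) <- paste0("s", 1:8)
    fm0 <- feature_matrix(m0, fm$sample_metadata, unit = "log2")
    expect_equal(signal_to_noise_ranking(fm0, c("P1", "P2"))$metric, rep(0, 5))
  })
  expect_error(signal_to_noise_ranking(
    feature_matrix(matrix(1:4, 2, dimnames = list(c("a", "b"), c("x", "y"))) + 0,
                   data.frame(group = c("P1", "P2"), row.names = c("a", "b")),
                   unit = "log2"), c("P1", "P2")), "2 samples")
})

test_that("enrichment score matches the brute-force running sum", {
  # hand example: metrics (3,2,1), set = {top feature} -> ES = 1
  ranked <- data.frame(feature_id = c("a", "b", "c"), metric = c(3, 2, 1),
                       stringsAsFactors = FALSE)
  res <- gsea_enrichment(ranked, list(S = "a"), n_perm = 10, min_set = 1, seed = 1)
  expect_equal(res$es, 1)

  withr::with_seed(23, {
    for (i in 1:60) {
      N <- sample(4:10, 1)
      metric <- sort(rnorm(N), decreasing = TRUE)
      ranked <- data.frame(feature_id = paste0("f", 1:N), metric = metric,
                           stringsAsFactors = FALSE)
      n <- sample(1:(N - 1), 1)
      hits <- sample(N, n)
      w <- sample(c(0, 1), 1)
      res <- gsea_enrichment(ranked, list(S = paste0("f", hits)),
                             n_perm = 5, weight = w, min_set = 1, seed = i)
      want <- es_oracle(metric, seq_len(N) %in% hits, weight = w)
      expect_equal(res$es, want, tolerance = 1e-12)
    }
  })
})

test_that("enrichment ES flips sign under list reversal and p respects its bound", {
  ranked <- data.frame(feature_id = paste0("f", 1:20), metric = 10:-9,
                       stringsAsFactors = FALSE)
  fwd <- gsea_enrichment(ranked, list(S = paste0("f", 1:5)), n_perm = 99, seed = 5)
  # phenotype label swap: every metric negates, the order reverses
  rev_ranked <- ranked[20:1, ]
  rev_ranked$metric <- -rev_ranked$metric
  bwd <- gsea_enrichment(rev_ranked, list(S = paste0("f", 1:5)), n_perm = 99, seed = 5)
  expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
  expect_gte(fwd$p_perm, 1 / 100)
  # undersized sets are skipped with a reason
  res <- gsea_enrichment(ranked, list(Tiny = "f1"), n_perm = 9, seed = 1)
  expect_equal(attr(res, "skipped"), "Tiny")
  expect_error(gsea_enrichment(ranked, list(S = paste0("f", 1:5)), n_perm = 0),
               "n_perm")
})

test_that("classification network carries sizes, direction classes and edges", {
  diff <- make_diff(c(-1, 0.5, 2, 1, -2, 0.3),
                    c(0.01, 0.2, 0.03, 0.04, 0.001, 0.9))
  ann <- pathway_annotation(paste0("m", 1:6), rep("Lipid", 6),
                            rep(c("DG", "TG"), each = 3))
  net <- build_classification_network(diff, ann)
  expect_equal(nrow(net$edges), 6)
  expect_equal(nrow(net$nodes), 8)
  m1 <- net$nodes[net$nodes$id == "m1", ]
  expect_equal(m1$direction_class, "down")
  expect_equal(m1$size, 1)
  expect_equal(net$nodes$direction_class[net$nodes$id == "m2"], "ns")
  # every metabolite has exactly one source edge
  expect_equal(sort(table(net$edges$feature_id)), sort(rep(1L, 6)),
               ignore_attr = TRUE)
})

test_that("planted subpathway recovery: DG scores positive across seeds", {
  signs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_samples_per_group = 10, n_subpathways = 8,
                      metabolites_per_subpathway = 5,
                      planted_effects = list(DG = list(direction = "up", effect = 2)),
                      seed = s)
    sim <- simulate_metabolomics(cfg)
    dt <- differential_table(sim$matrix, c("group2", "group1"), method = "welch")
    da <- differential_abundance_score(dt, sim$annotation)
    da$da_score[da$sub_pathway == "DG"]
  }, 1)
  expect_true(all(signs > 0))
})
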