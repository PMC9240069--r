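toy_cohort <- function(n = 60, effect = 2, seed = 41) {
  simulate_expression_cohort(
    n, list(up = paste0("U", 1:10), down = paste0("D", 1:10)),
    effect = effect, seed = seed
  )
}

test_that("gene Z-scoring standardizes and flags constant genes", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("g1", "g2")))
  z <- zscore_genes(feature_matrix(m, unit = "log2"))
  expect_equal(unname(z$values[, "g1"]), c(-1, 0, 1))
  expect_equal(unname(z$values[, "g2"]), c(0, 0, 0))
  expect_equal(attr(z, "zero_sd"), "g2")
  withr::with_seed(42, {
    big <- matrix(rnorm(200), nrow = 20,
                  dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
    zz <- zscore_genes(feature_matrix(big, unit = "log2"))
    expect_equal(unname(colMeans(zz$values)), rep(0, 10), tolerance = 1e-12)
    expect_equal(unname(apply(zz$values, 2, sd)), rep(1, 10), tolerance = 1e-12)
  })
  expect_error(zscore_genes(feature_matrix(m[1, , drop = FALSE], unit = "log2")),
               "2 samples")
})

test_that("activity score sums up-gene Z-scores minus down-gene Z-scores", {
  z <- feature_matrix(
    matrix(c(1, -1, 0.5, -0.5, -0.5, 0.5), nrow = 2,
           dimnames = list(c("s1", "s2"), c("u1", "u2", "d1"))),
    unit = "log2")
  sc <- activity_score(z, c("u1", "u2"), "d1")
  expect_equal(unname(sc["s1"]), 1 + 0.5 - (-0.5))
  # empty down list reduces to the up sum
  expect_equal(unname(activity_score(z, c("u1", "u2"))["s1"]), 1.5)
  # absent genes are skipped and recorded
  sc2 <- activity_score(z, c("u1", "u2", "ghost"), "d1")
  expect_equal(attr(sc2, "missing_genes"), "ghost")
  expect_error(activity_score(z, "u1", "u1"), "overlap")
  expect_error(activity_score(z, "ghost1", "ghost2"), "no signature genes")
  # cohort mean of scores is zero when built from true Z-scores
  co <- toy_cohort()
  z_big <- zscore_genes(co$matrix)
  sc3 <- activity_score(z_big, paste0("U", 1:10), paste0("D", 1:10))
  expect_equal(mean(sc3), 0, tolerance = 1e-10)
})

test_that("activity score recovers the latent driver and stays null without effect", {
  co <- simulate_expression_cohort(
    500, list(up = paste0("U", 1:20), down = paste0("D", 1:20)),
    effect = 2, seed = 7)
  sc <- activity_score(zscore_genes(co$matrix), paste0("U", 1:20), paste0("D", 1:20))
  expect_gt(cor(sc, co$latent), 0.8)

  co0 <- simulate_expression_cohort(
    500, list(up = paste0("U", 1:20), down = paste0("D", 1:20)),
    effect = 0, seed = 8)
  sc0 <- activity_score(zscore_genes(co0$matrix), paste0("U", 1:20), paste0("D", 1:20))
  expect_lt(abs(cor(sc0, co0$latent)), 0.2)
})

test_that("masked correlations report r, p and mask non-significant entries", {
  withr::with_seed(43, {
    n <- 100
    x <- rnorm(n)
    m <- cbind(g1 = x, g2 = -x + rnorm(n, sd = 0.01), g3 = rnorm(n), g4 = rep(1, n))
    rownames(m) <- paste0("s", 1:n)
    fm <- feature_matrix(m, unit = "log2")
    res <- masked_correlations(fm, c("g1", "g2", "g3", "g4"),
                               extra = list(score = x + rnorm(n, sd = 0.01)))
    expect_equal(res$r["g1", "g1"], 1)
    expect_lt(res$r["g1", "g2"], -0.99)
    expect_gt(res$r["g1", "score"], 0.99)
    expect_true(is.na(res$masked["g1", "g3"]))  # independent noise masked
    expect_equal(res$degenerate, "g4")
    expect_true(all(is.na(res$r["g4", ])))
  })
  expect_error(masked_correlations(
    feature_matrix(matrix(rnorm(4), 2, dimnames = list(c("a", "b"), c("x", "y"))),
                   unit = "log2"), "x"), "3 samples")
})

test_that("tertile stratification cuts at empirical thirds with lower-stratum ties", {
  lab <- tertile_stratify(setNames(1:9, paste0("s", 1:9)))
  expect_equal(unname(as.character(lab[1:3])), rep("bottom", 3))
  expect_equal(unname(as.character(lab[7:9])), rep("top", 3))
  expect_equal(as.character(tertile_stratify(c(1, 2, 3))),
               c("bottom", "middle", "top"))
  allsame <- tertile_stratify(rep(5, 6))
  expect_true(all(allsame == "bottom"))
  expect_true(attr(allsame, "degenerate"))
  expect_error(tertile_stratify(c(1, 2)), "at least 3")
})

test_that("log-rank agrees with the observed-minus-expected oracle", {
  # identical groups: no signal
  d <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = c(1, 1, 0, 1, 1, 0),
                  group = rep(c("a", "b"), each = 3))
  res <- km_logrank(d, c("a", "b"))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  # separated groups: matches the hand-tabulated statistic
  d2 <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                   group = c("a", "a", "b", "b"))
  res2 <- km_logrank(d2, c("a", "b"))
  want <- logrank_oracle(d2$time, d2$event, d2$group)
  expect_equal(res2$chisq, want$chisq, tolerance = 1e-8)
  expect_equal(res2$p, want$p, tolerance = 1e-8)

  expect_error(km_logrank(data.frame(time = c(1, 2), event = c(0, 0),
                                     group = c("a", "b")), c("a", "b")),
               "at least one event")
  expect_error(km_logrank(d2, c("a", "c")), "absent")
})

test_that("log-rank matches the oracle across enumerated small tables", {
  checked <- 0L
  for (n in 4:5) {
    groups_all <- expand.grid(rep(list(c("a", "b")), n), stringsAsFactors = FALSE)
    events_all <- expand.grid(rep(list(c(0L, 1L)), n))
    for (gi in seq_len(nrow(groups_all))) {
      g <- unlist(groups_all[gi, ], use.names = FALSE)
      if (length(unique(g)) < 2) next
      for (ei in seq_len(nrow(events_all))) {
        ev <- unlist(events_all[ei, ], use.names = FALSE)
        if (sum(ev) == 0) next
        d <- data.frame(time = seq_len(n), event = ev, group = g)
        got <- km_logrank(d, c("a", "b"))
        want <- logrank_oracle(d$time, d$event, d$group)
        expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 1000)
  # tied event times, 6 subjects
  withr::with_seed(44, {
    for (i in 1:25) {
      d <- data.frame(time = sample(1:3, 6, replace = TRUE),
                      event = sample(0:1, 6, replace = TRUE),
                      group = sample(c("a", "a", "a", "b", "b", "b")))
      if (sum(d$event) == 0) next
      got <- km_logrank(d, c("a", "b"))
      want <- logrank_oracle(d$time, d$event, d$group)
      expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
    }
  })
})

test_that("gene-set survival ranking colors harmful high expression red", {
  co <- simulate_expression_cohort(
    300, list(up = paste0("U", 1:10), down = paste0("D", 1:10)),
    effect = 3, seed = 45)
  surv <- list(
    OS = data.frame(subject_id = co$clinical$subject_id,
                    time = co$clinical$os_time, event = co$clinical$os_event),
    EFS = data.frame(subject_id = co$clinical$subject_id,
                     time = co$clinical$efs_time, event = co$clinical$efs_event)
  )
  # up-genes track the latent hazard driver: high expression is harmful
  rk <- geneset_survival_ranking(co$matrix, surv, c("U1", "U2", "BG001", "nope"))
  expect_equal(attr(rk, "missing_genes"), "nope")
  u_rows <- rk[rk$gene %in% c("U1", "U2"), ]
  expect_true(all(u_rows$direction == "red"))
  expect_true(all(rk$neg_log10_p >= 0, na.rm = TRUE))
  # background genes are mostly uninformative (gray), up to the nominal
  # false-positive rate of the color call
  bg <- geneset_survival_ranking(co$matrix, surv, paste0("BG00", 1:5))
  expect_gte(mean(bg$direction == "gray"), 0.8)
})

test_that("dependency ranking aggregates per disease, most dependent first", {
  tab <- data.frame(
    cell_line = paste0("cl", 1:5),
    disease = c("NB", "NB", "Lung", "Lung", "Skin"),
    SLC27A2 = c(-0.5, -0.1, 0.1, -0.05, 0.4),
    stringsAsFactors = FALSE
  )
  rk <- dependency_rank(tab, "SLC27A2", disease = "NB")
  expect_equal(rk$disease[1], "NB")
  expect_equal(rk$score[1], -0.3)
  expect_equal(attr(rk, "disease_rank"), 1L)
  expect_equal(rk$score[rk$disease == "Skin"], 0.4)  # single line
  # skewed toy table where mean and median disagree on the order
  tab2 <- data.frame(cell_line = paste0("c", 1:6),
                     disease = rep(c("A", "B"), each = 3),
                     G = c(-2, 0.1, 0.2, -0.5, -0.45, -0.4))
  expect_equal(dependency_rank(tab2, "G", "mean")$disease[1], "A")
  expect_equal(dependency_rank(tab2, "G", "median")$disease[1], "B")
  expect_error(dependency_rank(tab, "GENE2"), "absent")
})

test_that("tertile log-rank p-values are uniform on null cohorts", {
  withr::with_seed(46, {
    ps <- replicate(400, {
      n <- 60
      expr <- rnorm(n)
      t_event <- rexp(n, 0.15)
      t_cens <- runif(n, 0, 10)
      d <- data.frame(time = pmin(t_event, t_cens),
                      event = as.integer(t_event <= t_cens),
                      group = as.character(tertile_stratify(expr)))
      d <- d[d$group %in% c("bottom", "top"), ]
      km_logrank(d, c("top", "bottom"))$p
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  })
})
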