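test_that("normalization follows the 100 MY = 1 convention", {
  expect_equal(normalize_distance(0.32, 160), 0.2)
  expect_equal(normalize_distance(0.41, 100), 0.41)   # fixed point
  expect_equal(normalize_distance(0, 55), 0)
  expect_error(normalize_distance(0.3, 0), "normalization error")
  expect_error(normalize_distance(0.3, -4), "normalization error")

  # scale consistency: doubling all ages halves every normalized distance
  d <- runif(20)
  t <- runif(20, 10, 200)
  expect_equal(normalize_distance(d, 2 * t), normalize_distance(d, t) / 2,
               tolerance = 1e-12)
})

test_that("build_pair_table emits one consistent record per unordered pair", {
  tree <- read_timetree("((A:40,B:40):60,C:100);")
  clades <- c(A = "g1", B = "g1", C = "g2")
  aln <- locus_alignment("z", c(A = "MKVLQACD", B = "MKVAQACD", C = "WKVAQGCD"))
  dm <- distance_matrix(aln)
  tab <- build_pair_table(dm, tree, clades)

  expect_equal(nrow(tab), 3L)   # n(n-1)/2
  expect_equal(tab$D_norm, tab$D_raw / (tab$T_mya / 100), tolerance = 1e-12)
  ab <- tab[tab$taxonA == "A" & tab$taxonB == "B", ]
  expect_equal(ab$T_mya, 40)
  expect_equal(ab$clade_pair, "g1|g1")
  expect_equal(sort(unique(tab$clade_pair)), c("g1|g1", "g1|g2"))

  expect_error(build_pair_table(dm, tree, c(A = "g1", B = "g1")),
               "coverage error.*C")
})

test_that("missing-distance pairs are excluded with a message, not zeroed", {
  tree <- read_timetree("((A:40,B:40):60,C:100);")
  clades <- c(A = "g1", B = "g1", C = "g2")
  aln <- locus_alignment("z", c(A = "MK---", B = "---VL", C = "MKAVL"))
  dm <- suppressWarnings(distance_matrix(aln))
  expect_message(tab <- build_pair_table(dm, tree, clades), "excluded 1 pair")
  expect_equal(nrow(tab), 2L)
  expect_false(any(tab$taxonA == "A" & tab$taxonB == "B"))
})

test_that("interclade distributions match brute-force summaries", {
  expect_equal(interclade_distribution(
    data.frame(taxonA = "x", taxonB = "y", cladeA = "a", cladeB = "b",
               clade_pair = "a|b", D_raw = 2, T_mya = 100, D_norm = 2),
    "a", "b", "raw")$median, 2)

  set.seed(401)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    tab <- data.frame(
      taxonA = paste0("x", 1:n), taxonB = paste0("y", 1:n),
      cladeA = "a", cladeB = "b", clade_pair = "a|b",
      D_raw = runif(n), T_mya = runif(n, 50, 150)
    )
    tab$D_norm <- tab$D_raw / (tab$T_mya / 100)
    d <- interclade_distribution(tab, "b", "a", "normalized")  # order-free
    expect_equal(d$mean, mean(tab$D_norm), tolerance = 1e-12)
    expect_equal(d$sd, sd(tab$D_norm), tolerance = 1e-12)
    expect_equal(d$median, median(tab$D_norm), tolerance = 1e-12)
    expect_equal(d$q1, unname(quantile(tab$D_norm, 0.25)), tolerance = 1e-12)
    expect_equal(d$n, n)
  }

  expect_error(interclade_distribution(tab, "a", "zzz"), "empty-group")
})

test_that("within-clade selection picks pairs with both members in the clade", {
  tab <- data.frame(
    taxonA = c("a1", "a1", "a2"), taxonB = c("a2", "b1", "b1"),
    cladeA = c("g1", "g1", "g1"), cladeB = c("g1", "g2", "g2"),
    clade_pair = c("g1|g1", "g1|g2", "g1|g2"),
    D_raw = c(0.1, 0.5, 0.6), T_mya = 100
  )
  tab$D_norm <- tab$D_raw
  within <- interclade_distribution(tab, "g1", "g1", "raw")
  expect_equal(within$values, 0.1)
})

test_that("anova_tukey agrees with the hand-written oracle to 1e-6", {
  groups <- list(g1 = c(1, 2, 3, 4), g2 = c(2, 3, 4, 5), g3 = c(8, 9, 10, 11))
  res <- anova_tukey(groups)
  ora <- oracle_anova_tukey(groups)
  expect_equal(res$F, ora$F, tolerance = 1e-6)
  expect_equal(res$p_value, ora$p_value, tolerance = 1e-6)
  expect_equal(res$df_between, ora$df_between)
  expect_equal(res$df_within, ora$df_within)
  expect_equal(res$tukey$p_adj, unname(ora$tukey[, "p_adj"]), tolerance = 1e-6)
  expect_equal(res$tukey$diff, unname(ora$tukey[, "diff"]), tolerance = 1e-6)

  # unequal group sizes exercise the Tukey-Kramer variant
  set.seed(402)
  for (rep in 1:10) {
    g <- list(a = rnorm(sample(3:9, 1)), b = rnorm(sample(3:9, 1), 1),
              c = rnorm(sample(3:9, 1), -0.5), d = rnorm(sample(3:9, 1)))
    res <- anova_tukey(g)
    ora <- oracle_anova_tukey(g)
    expect_equal(res$F, ora$F, tolerance = 1e-6)
    expect_equal(sort(res$tukey$p_adj), sort(unname(ora$tukey[, "p_adj"])),
                 tolerance = 1e-6)
  }
})

test_that("anova_tukey reproduces the published PlantGrowth example", {
  groups <- split(PlantGrowth$weight, PlantGrowth$group)
  res <- anova_tukey(groups)
  expect_equal(res$F, 4.846088, tolerance = 1e-6)
  expect_equal(res$p_value, 0.015910, tolerance = 1e-5)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 27)
  tt <- res$tukey$p_adj[res$tukey$comparison == "trt2-trt1"]
  expect_equal(tt, 0.01200642, tolerance = 1e-6)
  expect_equal(res$tukey$stars[res$tukey$comparison == "trt2-trt1"], "*")
})

test_that("anova_tukey degenerate and invariance properties hold", {
  expect_error(anova_tukey(list(a = c(1, 2, 3))), ">= 2 groups")
  expect_error(anova_tukey(list(a = c(1, 2, 3), b = 5)),
               "degrees-of-freedom")

  ident <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p_value, 1)

  g <- list(a = c(1.2, 3.1, 2.2, 0.5), b = c(2.0, 2.5, 4.1), c = c(5, 6, 5.5))
  shifted <- lapply(g, function(x) x + 17.3)
  expect_equal(anova_tukey(shifted)$F, anova_tukey(g)$F, tolerance = 1e-10)
})

test_that("significance stars follow the *, **, *** thresholds", {
  expect_equal(protrate:::significance_stars(c(0.04, 0.009, 0.0009, 0.2)),
               c("*", "**", "***", "ns"))
})

test_that("normalized distances separate slow from fast clades on simulated truth", {
  # three clades: slow outgroup diverged earliest; fast clade is recent
  newick <- paste0(
    "(((F1:30,F2:30)FAST:30,(N1:45,N2:45)NORM:15)IN:100,",
    "(S1:70,S2:70)SLOW:90)ROOT;"
  )
  tree <- read_timetree(newick)
  rates <- c(FAST = 2, F1 = 2, F2 = 2, SLOW = 0.5, S1 = 0.5, S2 = 0.5)
  cfg <- sim_config(tree, mu = 0.25,
                    loci = data.frame(name = "L", length = 2000L),
                    branch_rate = rates, seed = 403)
  sim <- simulate_alignments(cfg)
  aln <- concatenate(sim$loci)
  dm <- distance_matrix(aln)
  clades <- c(F1 = "fast", F2 = "fast", N1 = "norm", N2 = "norm",
              S1 = "slow", S2 = "slow")
  tab <- build_pair_table(dm, tree, clades)
  slow_fast <- interclade_distribution(tab, "slow", "fast", "normalized")$mean
  within_slow <- interclade_distribution(tab, "slow", "slow", "normalized")$mean
  within_fast <- interclade_distribution(tab, "fast", "fast", "normalized")$mean
  expect_lt(within_slow, within_fast)
  expect_lt(within_slow, slow_fast)
})

test_that("taxon-level jackknife reports one ANOVA per dropped taxon", {
  ds <- make_paper_like_dataset(seed = 404)
  aln <- concatenate(ds$sim$loci, missing_policy = "gap_fill")
  dm <- distance_matrix(aln)
  tab <- build_pair_table(dm, ds$tree, ds$clades)
  labels <- c("marsupials|rodents", "marsupials|primates", "primates|rodents")
  jk <- jackknife_anova(tab, labels, "normalized")
  expect_true(all(jk$F >= 0))
  expect_true(all(jk$p_value >= 0 & jk$p_value <= 1))
  expect_gt(nrow(jk), 10)
})
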