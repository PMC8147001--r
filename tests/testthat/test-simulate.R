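test_that("sim_config validates its inputs", {
  tree <- read_timetree("((A:50,B:50):50,C:100);")
  loci <- data.frame(name = "L", length = 100L)
  expect_s3_class(sim_config(tree, 0.2, loci), "sim_config")
  expect_error(sim_config(tree, 0, loci), "mu")
  expect_error(sim_config(tree, 0.2, data.frame(name = "L", length = 0L)),
               "lengths")
  expect_error(sim_config(tree, 0.2, loci, branch_rate = c(A = -1)),
               "multipliers")
  expect_error(sim_config(tree, 0.2, loci, freqs = rep(1, 20)), "freqs")
  expect_error(sim_config(tree, 0.2, loci, gamma_shape = -2), "gamma")
})

test_that("same config and seed regenerate alignments bit-identically", {
  tree <- read_timetree("((A:50,B:50):50,C:100);")
  cfg <- sim_config(tree, 0.3, data.frame(name = c("L1", "L2"),
                                          length = c(80L, 120L)),
                    gamma_shape = 0.8, seed = 601)
  s1 <- simulate_alignments(cfg)
  s2 <- simulate_alignments(cfg)
  expect_identical(lapply(s1$loci, `[[`, "members"),
                   lapply(s2$loci, `[[`, "members"))

  # byte-identical FASTA output
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s1$loci$L1, p1)
  write_fasta(s2$loci$L1, p2)
  expect_identical(readLines(p1), readLines(p2))

  s3 <- simulate_alignments(sim_config(tree, 0.3,
                                       data.frame(name = c("L1", "L2"),
                                                  length = c(80L, 120L)),
                                       gamma_shape = 0.8, seed = 602))
  expect_false(identical(s1$loci$L1$members, s3$loci$L1$members))
})

test_that("near-zero rate keeps sequences essentially identical", {
  tree <- read_timetree("((A:50,B:50):50,C:100);")
  cfg <- sim_config(tree, 1e-9, data.frame(name = "L", length = 5000L),
                    seed = 603)
  sim <- simulate_alignments(cfg)
  pd <- p_distance(sim$loci$L$members[["A"]], sim$loci$L$members[["C"]])
  expect_gte(1 - pd$p, 0.999)
})

test_that("empirical p-distance matches the closed-form expectation", {
  # two leaves at total path distance 0.2314 under the equal-rates chain
  tree <- read_timetree("(A:50,B:50);")
  for (seed in 604:608) {
    cfg <- sim_config(tree, mu = 0.2314,
                      loci = data.frame(name = "L", length = 20000L),
                      seed = seed)
    sim <- simulate_alignments(cfg)
    p_emp <- p_distance(sim$loci$L$members[["A"]], sim$loci$L$members[["B"]])$p
    p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 0.2314))
    se <- sqrt(p_exp * (1 - p_exp) / 20000)
    expect_lt(abs(p_emp - p_exp), 3 * se)
  }
})

test_that("expected_p implements the closed form and its limits", {
  tree <- read_timetree("(A:50,B:50);")
  loci <- data.frame(name = "L", length = 10L)

  cfg0 <- sim_config(tree, mu = 1e-12, loci = loci, seed = 1)
  expect_equal(expected_p(cfg0, "A", "A", "L"), 0)
  expect_lt(expected_p(cfg0, "A", "B", "L"), 1e-10)

  # saturation: d -> Inf gives 19/20
  cfg_sat <- sim_config(tree, mu = 1e6, loci = loci, seed = 1)
  expect_equal(expected_p(cfg_sat, "A", "B", "L"), 0.95, tolerance = 1e-12)

  # d_path = 0.1: mu chosen so 2 x (50/100) x mu = 0.1
  cfg1 <- sim_config(tree, mu = 0.1, loci = loci, seed = 1)
  expect_equal(expected_p(cfg1, "A", "B", "L"),
               0.95 * (1 - exp(-(20 / 19) * 0.1)), tolerance = 1e-12)
  expect_equal(round(expected_p(cfg1, "A", "B", "L"), 4), 0.0949)

  # locus scalar multiplies the path distance
  cfg2 <- sim_config(tree, mu = 0.1,
                     loci = data.frame(name = "L", length = 10L, scalar = 2),
                     seed = 1)
  expect_equal(expected_p(cfg2, "A", "B", "L"),
               0.95 * (1 - exp(-(20 / 19) * 0.2)), tolerance = 1e-12)

  # gamma averaging never exceeds the homogeneous expectation (Jensen)
  cfgg <- sim_config(tree, mu = 0.4, loci = loci, gamma_shape = 0.5, seed = 1)
  expect_lt(expected_p(cfgg, "A", "B", "L"),
            expected_p(sim_config(tree, mu = 0.4, loci = loci, seed = 1),
                       "A", "B", "L"))

  exch <- matrix(1, 20, 20); diag(exch) <- 0
  cfgx <- sim_config(tree, mu = 0.1, loci = loci, exchangeability = exch, seed = 1)
  expect_error(expected_p(cfgx, "A", "B", "L"), "unsupported-oracle")
})

test_that("branch rate multipliers scale expected path distances", {
  tree <- read_timetree("((A:50,B:50):50,C:100);")
  loci <- data.frame(name = "L", length = 10L)
  base <- sim_config(tree, mu = 0.2, loci = loci, seed = 1)
  fast_a <- sim_config(tree, mu = 0.2, loci = loci,
                       branch_rate = c(A = 3), seed = 1)
  d_base <- protrate:::path_expected_distance(base, "A", "B")
  d_fast <- protrate:::path_expected_distance(fast_a, "A", "B")
  # only A's terminal branch (50 MY of the 100 MY path) is scaled by 3
  expect_equal(d_base, 0.2, tolerance = 1e-12)
  expect_equal(d_fast, 0.2 / 2 * 3 + 0.2 / 2, tolerance = 1e-12)

  # doubling mu doubles every expected path distance
  dbl <- sim_config(tree, mu = 0.4, loci = loci, seed = 1)
  expect_equal(protrate:::path_expected_distance(dbl, "A", "C"),
               2 * protrate:::path_expected_distance(base, "A", "C"),
               tolerance = 1e-12)
})

test_that("rate doubling is visible in Poisson-corrected empirical distances", {
  tree <- read_timetree("(A:50,B:50);")
  loci <- data.frame(name = "L", length = 10000L)
  d1 <- local({
    sim <- simulate_alignments(sim_config(tree, 0.1, loci, seed = 610))
    poisson_distance(p_distance(sim$loci$L$members[["A"]],
                                sim$loci$L$members[["B"]])$p)
  })
  d2 <- local({
    sim <- simulate_alignments(sim_config(tree, 0.2, loci, seed = 611))
    poisson_distance(p_distance(sim$loci$L$members[["A"]],
                                sim$loci$L$members[["B"]])$p)
  })
  # Poisson correction is exact for this chain up to the 19/20 state-space
  # factor, so the ratio should be near 2 within Monte-Carlo error
  expect_gt(d2 / d1, 1.75)
  expect_lt(d2 / d1, 2.25)
})

test_that("leaf residue frequencies stay near equilibrium", {
  tree <- read_timetree("((A:50,B:50):50,C:100);")
  cfg <- sim_config(tree, 0.5, data.frame(name = "L", length = 20000L),
                    seed = 612)
  sim <- simulate_alignments(cfg)
  freqs <- table(strsplit(sim$loci$L$members[["A"]], "")[[1]]) / 20000
  # uniform equilibrium: each residue ~ 1/20; multinomial SE ~ 0.0015
  expect_true(all(abs(freqs - 0.05) < 0.01))
  expect_equal(length(freqs), 20L)
})

test_that("discrete gamma categories have unit mean and order by shape", {
  r4 <- protrate:::discrete_gamma_rates(0.5, 4)
  expect_equal(mean(r4), 1, tolerance = 1e-12)
  expect_true(all(diff(r4) > 0))
  # larger shape concentrates rates near 1
  r_tight <- protrate:::discrete_gamma_rates(50, 4)
  expect_lt(max(abs(r_tight - 1)), 0.2)
})

test_that("general exchangeability model preserves its equilibrium", {
  tree <- read_timetree("(A:100,B:100);")
  exch <- matrix(1, 20, 20); diag(exch) <- 0
  freqs <- c(rep(0.09, 5), rep(0.055, 10), rep(0.002, 5))
  freqs <- freqs / sum(freqs)
  cfg <- sim_config(tree, 0.5, data.frame(name = "L", length = 8000L),
                    freqs = freqs, exchangeability = exch, seed = 613)
  sim <- simulate_alignments(cfg)
  counts <- table(factor(strsplit(sim$loci$L$members[["A"]], "")[[1]],
                         levels = protrate:::AA_LETTERS))
  obs <- as.numeric(counts) / 8000
  expect_lt(max(abs(obs - freqs)), 0.015)
})

test_that("the therian study dataset has the designed structure", {
  ds <- make_paper_like_dataset(seed = 614)
  expect_equal(length(ds$sim$loci), 10L)
  expect_gte(sum(vapply(ds$sim$loci, function(a) a$length, integer(1))), 2000L)

  # exactly one (locus, taxon) dropout: the opossum-like taxon lacks CatSperZ
  n_members <- vapply(ds$sim$loci, function(a) length(a$members), integer(1))
  expect_equal(sum(15 - n_members), 1L)
  expect_false("Mdomestica" %in% names(ds$sim$loci$CatSperZ$members))

  expect_setequal(unique(ds$clades),
                  c("primates", "rodents", "Laurasiatherians",
                    "Afrotherians", "marsupials"))
  expect_equal(divergence_time(ds$tree, "Mmusculus", "Sharrisii"), 160)
})

test_that("the simulated dataset reproduces the raw/normalized rank reversal", {
  ds <- make_paper_like_dataset(seed = 615)
  aln <- concatenate(ds$sim$loci, missing_policy = "gap_fill")
  dm <- distance_matrix(aln)
  tab <- build_pair_table(dm, ds$tree, ds$clades)
  ic <- tab[tab$cladeA != tab$cladeB, ]
  clade_mean <- function(col) {
    vapply(unique(ds$clades), function(cl)
      mean(ic[[col]][xor(ic$cladeA == cl, ic$cladeB == cl)]), numeric(1))
  }
  raw <- clade_mean("D_raw")
  norm <- clade_mean("D_norm")
  # raw: marsupials in the top divergence tier (rank <= 2, above every
  # non-rodent clade); normalized: least divergent, below rodents
  expect_lte(rank(-raw)[["marsupials"]], 2)
  expect_true(all(raw[["marsupials"]] >
                  raw[setdiff(names(raw), c("marsupials", "rodents"))]))
  expect_lt(norm[["marsupials"]], norm[["rodents"]])
  expect_equal(rank(norm)[["marsupials"]], 1)
})
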