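test_that("tree simulation is ultrametric, unit height, reproducible", {
  cfg <- sim_config(n_tips = 8, seed = 4)
  tr <- simulate_tree(cfg)
  expect_identical(ape::Ntip(tr), 8L)
  expect_identical(tr$Nnode, 7L)  # bifurcating
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(phylosyndrome:::tree_height(tr), 1)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(cfg)))
  # two tips: a single cherry of height 1
  cherry <- simulate_tree(sim_config(n_tips = 2, seed = 1))
  expect_identical(ape::Ntip(cherry), 2L)
  expect_equal(phylosyndrome:::tree_height(cherry), 1)
  # invalid birth-death rates
  expect_error(sim_config(tree_model = "birth_death", birth = 1, death = 1),
               "death < birth")
})

test_that("clade-block predictor covers 30-70% of tips", {
  for (seed in 1:5) {
    cfg <- sim_config(n_tips = 100, seed = seed)
    x <- simulate_predictor(simulate_tree(cfg), cfg)
    expect_gte(mean(x), 0.3)
    expect_lte(mean(x), 0.7)
  }
})

test_that("clade-block falls back to switching when no clade fits", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  cfg <- sim_config(n_tips = 6, seed = 3)
  expect_warning(x <- simulate_predictor(star, cfg), "falling back")
  expect_length(x, 6L)
})

test_that("switching-process predictor has the stated limits", {
  cfg0 <- sim_config(n_tips = 50, predictor_model = "mk_switch",
                     mk_rate = 0, seed = 2)
  tr <- simulate_tree(cfg0)
  x0 <- simulate_predictor(tr, cfg0)
  expect_identical(length(unique(x0)), 1L)  # no transitions
  # high rate: tip states near-independent fair coins
  freqs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_tips = 150, predictor_model = "mk_switch",
                      mk_rate = 400, seed = 100 + s)
    mean(simulate_predictor(simulate_tree(cfg), cfg))
  }, numeric(1))
  expect_equal(mean(freqs), 0.5, tolerance = 0.05)
})

test_that("response margins match the logistic model", {
  # independence limit: i.i.d. Bernoulli at the intercept frequency
  cfg <- sim_config(n_tips = 1000, alpha_true = 500,
                    beta_true = c(-0.5, 0), seed = 6)
  tr <- simulate_tree(cfg)
  x <- simulate_predictor(tr, cfg)
  y <- simulate_response(tr, x, cfg)
  p <- plogis(-0.5)
  expect_lt(abs(mean(y) - p), 3 * sqrt(p * (1 - p) / 1000))
  # saturation
  cfg0 <- sim_config(n_tips = 200, beta_true = c(-20, 0), seed = 7)
  tr0 <- simulate_tree(cfg0)
  expect_identical(sum(simulate_response(tr0,
                                         simulate_predictor(tr0, cfg0),
                                         cfg0)), 0L)
  # positive effect raises prevalence among predictor-1 tips; margins
  # match logistic(b0 + b1 x) within binomial error at n = 2000
  n1 <- n0 <- k1 <- k0 <- 0
  for (s in 1:10) {
    cfg2 <- sim_config(n_tips = 200, beta_true = c(-1, 2), seed = 400 + s)
    tr2 <- simulate_tree(cfg2)
    x2 <- simulate_predictor(tr2, cfg2)
    y2 <- simulate_response(tr2, x2, cfg2)
    k1 <- k1 + sum(y2[x2 == 1]); n1 <- n1 + sum(x2 == 1)
    k0 <- k0 + sum(y2[x2 == 0]); n0 <- n0 + sum(x2 == 0)
  }
  expect_gt(k1 / n1, k0 / n0)
  expect_lt(abs(k1 / n1 - plogis(1)), 4 * sqrt(0.25 / n1) + 0.03)
  expect_lt(abs(k0 / n0 - plogis(-1)), 4 * sqrt(0.25 / n0) + 0.03)
})

test_that("observer noise flips traits at the configured rate", {
  species <- sprintf("s%04d", 1:1000)
  truth <- data.frame(species = species)
  truth$colours <- rep(list("green"), 1000)
  truth$patterns <- rep(list("stripe"), 1000)
  # zero disagreement: both observers identical to the truth
  cfg0 <- sim_config(n_tips = 4, disagreement_rate = 0, seed = 1)
  sc0 <- simulate_observers(truth[1:50, ], cfg0)
  expect_true(all(sc0$colour1 == "green"))
  expect_true(all(sc0$stripe == 1L))
  expect_true(all(sc0$band == 0L))
  # certain disagreement on a binary pattern: always flipped
  cfg1 <- sim_config(n_tips = 4, disagreement_rate = 1, seed = 1)
  sc1 <- simulate_observers(truth[1:50, ], cfg1)
  expect_true(all(sc1$stripe == 0L))
  expect_true(all(sc1$band == 1L))
  # rate 0.1: between-observer disagreement per trait ~ 2 * 0.1 * 0.9
  cfg <- sim_config(n_tips = 4, disagreement_rate = 0.1, seed = 9)
  sc <- simulate_observers(truth, cfg)
  o1 <- sc[sc$observer == "obs1", ]
  o2 <- sc[sc$observer == "obs2", ]
  dis <- mean(o1$stripe != o2$stripe)
  expect_lt(abs(dis - 2 * 0.1 * 0.9), 4 * sqrt(0.18 * 0.82 / 1000))
  # colour cap respected
  truth3 <- data.frame(species = species[1:200])
  truth3$colours <- rep(list(c("green", "brown", "black")), 200)
  truth3$patterns <- rep(list(character(0)), 200)
  sc3 <- simulate_observers(truth3, cfg)
  n_cols <- rowSums(sc3[, paste0("colour", 1:3)] != "")
  expect_lte(max(n_cols), 3L)
})

test_that("a simulated study is reproducible and internally consistent", {
  cfg <- sim_config(n_tips = 60, seed = 13)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$ecology, s2$ecology)
  # ecology mirrors the predictor
  expect_identical(unname(s1$truth$predictor == 1L),
                   s1$ecology$growth_forms == "forb")
  expect_identical(s1$truth$planted[["response"]], "black")
  # every species scored by both observers
  expect_identical(sort(unique(s1$scores$observer)), c("obs1", "obs2"))
  expect_identical(nrow(s1$scores), 120L)
  # round trip through the on-disk formats
  dir <- withr::local_tempdir()
  write_study(s1, dir)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_identical(sort(tr$tip.label), sort(s1$tree$tip.label))
  expect_identical(nrow(read_scores(file.path(dir, "scores.csv"))), 120L)
  expect_identical(nrow(read_ecology(file.path(dir, "ecology.csv"))), 60L)
})
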