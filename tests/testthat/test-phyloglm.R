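test_that("tip correlation has the stated closed form", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  pd <- patristic_matrix(tr)  # height normalized to 1
  R0 <- tip_correlation(pd, 0)
  expect_true(all(R0 == 1))
  R1 <- tip_correlation(pd, 1)
  expect_equal(R1["A", "B"], exp(-1))
  expect_equal(R1["A", "C"], exp(-2))
  expect_identical(diag(R1), stats::setNames(rep(1, 3), c("A", "B", "C")))
  # large alpha approaches independence on a star tree
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  Rbig <- tip_correlation(patristic_matrix(star), 500)
  expect_equal(Rbig, diag(4), ignore_attr = TRUE, tolerance = 1e-10)
  # arcsine form: bounded above by the exponential, with a steeper
  # square-root-type initial drop
  Ra <- tip_correlation(pd, 1, form = "arcsine")
  expect_equal(Ra["A", "B"], (2 / pi) * asin(exp(-1)))
  expect_true(all(Ra <= R1 + 1e-12))
  expect_gt(1 - Ra["A", "B"], 1 - R1["A", "B"])
  expect_error(tip_correlation(pd, -1), "non-negative")
})

test_that("correlation matrices stay positive semi-definite", {
  for (seed in 1:4) {
    tr <- random_tree(sample(10:60, 1), seed + 20)
    pd <- patristic_matrix(tr)
    for (a in c(1e-3, 0.5, 5, 1e3)) {
      for (fm in c("exponential", "arcsine")) {
        ev <- eigen(tip_correlation(pd, a, form = fm),
                    symmetric = TRUE, only.values = TRUE)$values
        expect_gt(min(ev), -1e-8)
      }
    }
  }
})

test_that("independence limit reproduces Firth logistic regression", {
  n <- 100
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  pd <- patristic_matrix(star)
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + x))
    X <- cbind(1, x)
    fit <- fit_phyloglm(y, X, pd,
                        control = phyloglm_control(alpha_fixed = 1e3))
    oracle <- firth_logistic_oracle(y, X)
    expect_lt(max(abs(coef(fit) - oracle)), 1e-4)
    expect_false(fit$alpha_at_bound)
  }
})

test_that("separated data keep finite estimates under the penalty", {
  n <- 60
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  pd <- patristic_matrix(star)
  x <- rep(0:1, each = n / 2)
  y <- x  # perfect separation
  fit <- fit_phyloglm(y, x, pd,
                      control = phyloglm_control(alpha_fixed = 1e3))
  expect_true(all(is.finite(coef(fit))))
  expect_true(all(is.finite(fit$se)))
  expect_lt(abs(coef(fit)[2]), 15)
})

test_that("tip permutation leaves the fit unchanged", {
  cfg <- sim_config(n_tips = 80, seed = 5)
  tr <- simulate_tree(cfg)
  x <- simulate_predictor(tr, cfg)
  y <- simulate_response(tr, x, cfg)
  pd <- patristic_matrix(tr)
  f1 <- fit_phyloglm(y, x, pd)
  set.seed(9)
  perm <- sample(length(y))
  f2 <- fit_phyloglm(y[perm], x[perm], pd$D[perm, perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  tr <- random_tree(10, 2)
  pd <- patristic_matrix(tr)
  expect_error(fit_phyloglm(rep(1, 10), NULL, pd), "degenerate response")
  y <- rep(c(0, 1), 5)
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(fit_phyloglm(y, X, pd), "singular")
  expect_error(fit_phyloglm(y, NULL, pd$D[1:9, 1:9]), "dimensions")
})

test_that("Wald p-values follow the normal approximation", {
  fit <- structure(list(coefficients = c(a = 0, b = 1.96, c = -3),
                        se = c(a = 1, b = 1, c = 1),
                        p_values = NULL), class = "phyloglm_fit")
  fit$p_values <- 2 * pnorm(-abs(fit$coefficients / fit$se))
  expect_equal(wald_p(fit, 1)$p, 1)
  expect_identical(wald_p(fit, 1)$sign, 0)
  expect_equal(wald_p(fit, 2)$p, 0.05, tolerance = 1e-2)
  expect_equal(wald_p(fit, 3)$p, 2 * pnorm(-3), tolerance = 1e-12)
  expect_identical(wald_p(fit, 3)$sign, -1)
  expect_error(wald_p(fit, 4), "out of range")
})

test_that("fits are deterministic and serialize to JSON", {
  cfg <- sim_config(n_tips = 60, seed = 11)
  tr <- simulate_tree(cfg)
  x <- simulate_predictor(tr, cfg)
  y <- simulate_response(tr, x, cfg)
  pd <- patristic_matrix(tr)
  f1 <- fit_phyloglm(y, x, pd)
  f2 <- fit_phyloglm(y, x, pd)
  expect_identical(coef(f1), coef(f2))
  path <- file.path(withr::local_tempdir(), "fit.json")
  write_phyloglm(f1, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$coefficients$x, unname(coef(f1)[2]), tolerance = 1e-12)
  expect_equal(back$alpha, f1$alpha, tolerance = 1e-12)
})

test_that("signal parameter is recovered from switching-process traits", {
  # pure-alpha check: data generated by the exact two-state switching
  # process, fitted with the matching exponential correlation form
  hits <- 0L
  for (seed in 1:4) {
    cfg <- sim_config(n_tips = 250, predictor_model = "mk_switch",
                      mk_rate = 1.5, seed = 300 + seed)
    tr <- simulate_tree(cfg)
    y <- simulate_predictor(tr, cfg)  # switching-process trait
    if (var(y) == 0) next
    fit <- suppressWarnings(fit_phyloglm(
      y, NULL, patristic_matrix(tr),
      control = phyloglm_control(corr_form = "exponential")))
    # the decay rate should be on the order of the switching rate,
    # far from both search bounds
    if (fit$alpha > 1.5 / 5 && fit$alpha < 1.5 * 10) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
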