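test_that("composite expansion yields singles plus canonical pairs", {
  # the worked three-colour example: six traits, pairs named in
  # lexicographic order
  out <- expand_composites(c("yellow", "black", "white"))
  expect_length(out, 6L)
  expect_setequal(out, c("yellow", "black", "white",
                         "black/yellow", "black/white", "white/yellow"))
  expect_identical(expand_composites("green"), "green")
  expect_identical(expand_composites(character(0)), character(0))
  # k + k(k-1)/2 for every colour set size up to the cap
  voc <- colour_vocabulary()
  for (k in 0:3) {
    for (rep in 1:5) {
      cols <- sample(voc, k)
      out <- expand_composites(cols)
      expect_length(out, k + k * (k - 1) / 2)
      expect_false(any(vapply(strsplit(out, "/"), length, 1L) > 2L))
    }
  }
})

test_that("composite expansion rejects bad input", {
  expect_error(expand_composites(c("green", "chartreuse")), "chartreuse")
  expect_error(expand_composites(c("green", "brown", "black", "white")),
               "at most 3")
})

test_that("pair traits equal the AND of their component colours", {
  set.seed(71)
  voc <- colour_vocabulary()
  colours <- lapply(1:40, function(i) sample(voc, sample(0:3, 1)))
  patterns <- lapply(1:40, function(i) sample(pattern_vocabulary(),
                                              sample(0:2, 1)))
  sc <- make_scores(sprintf("s%02d", 1:40), colours, patterns)
  tm <- build_trait_matrix(sc, ecology = NULL, min_occurrences = 1L)
  cls <- tm$trait_class
  for (pr in names(cls)[cls == "colour_pair"]) {
    parts <- strsplit(pr, "/", fixed = TRUE)[[1]]
    expect_identical(unname(tm$values[, pr]),
                     as.integer(tm$values[, parts[1]] &
                                  tm$values[, parts[2]]),
                     info = pr)
  }
})

test_that("rarity filter uses a strict threshold and is idempotent", {
  colours <- c(rep(list("green"), 5), rep(list("red"), 4),
               rep(list(c("green", "red")), 0))
  sc <- make_scores(sprintf("s%02d", 1:9), colours,
                    rep(list("stripe"), 9))
  tm <- build_trait_matrix(sc, ecology = NULL, min_occurrences = 0L)
  f1 <- filter_rare_traits(tm, 5L)
  # 4 occurrences excluded, exactly 5 retained
  expect_true("green" %in% colnames(f1$values))
  expect_false("red" %in% colnames(f1$values))
  expect_identical(excluded_traits(f1), "red")
  # patterns out of scope by default
  expect_true("stripe" %in% colnames(f1$values))
  # idempotent
  f2 <- filter_rare_traits(f1, 5L)
  expect_identical(f2$values, f1$values)
  expect_identical(excluded_traits(f2), character(0))
  # nothing rare: untouched with empty exclusion log
  f3 <- filter_rare_traits(f1, 1L)
  expect_identical(f3$values, f1$values)
  expect_identical(excluded_traits(f3), character(0))
  # widened scope removes the rare-in-scope pattern column too
  f4 <- filter_rare_traits(tm, 5L, scope = "all")
  expect_true("stripe" %in% colnames(f4$values))
  tm_sparse <- build_trait_matrix(
    make_scores("x1", list("green"), list("spot")),
    ecology = NULL, min_occurrences = 0L)
  f5 <- filter_rare_traits(tm_sparse, 2L, scope = "all")
  expect_identical(ncol(f5$values), 0L)
})

test_that("trait matrix assembles colour, pattern and ecology columns", {
  sc <- make_scores(c("a", "b", "c"),
                    rep(list("green"), 3), rep(list("stripe"), 3))
  eco <- make_ecology(c("a", "b", "c"))
  tm <- build_trait_matrix(sc, eco, min_occurrences = 1L)
  expect_identical(sum(tm$values[, "green"]), 3L)
  expect_identical(sum(tm$values[, "stripe"]), 3L)
  expect_identical(unname(tm$values[, "diet_oligophagous"]), rep(1L, 3))
  expect_identical(unname(tm$values[, "forb"]), rep(1L, 3))
  expect_identical(unname(tm$values[, "woody"]), rep(0L, 3))
  # with the rarity threshold at the study default the colour column goes
  tm5 <- build_trait_matrix(sc, eco, min_occurrences = 5L)
  expect_false("green" %in% colnames(tm5$values))
  expect_identical(excluded_traits(tm5), "green")
  # three-colour species contributes to six colour columns
  sc2 <- make_scores(sprintf("s%d", 1:5),
                     rep(list(c("yellow", "black", "white")), 5),
                     rep(list(character(0)), 5))
  tm2 <- build_trait_matrix(sc2, ecology = NULL, min_occurrences = 5L)
  expect_setequal(
    names(tm2$trait_class)[tm2$trait_class %in%
                             c("colour_single", "colour_pair")],
    c("yellow", "black", "white",
      "black/yellow", "black/white", "white/yellow"))
  colour_cols <- names(tm2$trait_class)[tm2$trait_class != "pattern"]
  expect_true(all(tm2$values[, colour_cols] == 1L))
})

test_that("trait matrix flags duplicates, missing ecology, empty input", {
  sc <- make_scores(c("a", "a"), rep(list("green"), 2),
                    rep(list("stripe"), 2))
  expect_error(build_trait_matrix(sc, NULL), "duplicate species")
  sc2 <- make_scores(c("a", "b"), rep(list("green"), 2),
                     rep(list("stripe"), 2))
  eco <- make_ecology("a")
  tm <- build_trait_matrix(sc2, eco, min_occurrences = 1L)
  expect_identical(attr(tm, "missing_ecology"), "b")
  expect_true(is.na(tm$values["b", "forb"]))
  empty <- build_trait_matrix(sc2[0, ], NULL)
  expect_identical(nrow(empty$values), 0L)
})

test_that("species feeding on several growth forms get multiple 1s", {
  sc <- make_scores("a", list("green"), list("stripe"))
  eco <- make_ecology("a", growth = "forb;woody")
  tm <- build_trait_matrix(sc, eco, min_occurrences = 0L)
  expect_identical(unname(tm$values[1, c("forb", "graminoid", "woody")]),
                   c(1L, 0L, 1L))
})

test_that("trait matrix round-trips through CSV with JSON sidecar", {
  sc <- make_scores(c("a", "b"), list("green", c("green", "black")),
                    list("stripe", character(0)))
  tm <- build_trait_matrix(sc, make_ecology(c("a", "b")),
                           min_occurrences = 1L)
  path <- file.path(withr::local_tempdir(), "traits.csv")
  write_trait_matrix(tm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(back$species, c("a", "b"))
  expect_identical(back$green, c(1L, 1L))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$trait_class$green, "colour_single")
})
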