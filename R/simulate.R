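#' Configuration for the synthetic-data generator
#'
#' Collects every parameter of the simulation: tree size and branching
#' model, the true phylogenetic signal and effect sizes on the log-odds
#' scale, how the binary predictor arises on the tree, the per-trait
#' observer disagreement rate, and the seed. Defaults describe a
#' desk-scale comparative study: a 300-tip Yule tree of unit height,
#' moderate signal (alpha_true = 1), a clade-structured predictor, a
#' log-odds effect of 1 on a baseline of -1, two observers disagreeing on
#' 10% of trait assignments.
#'
#' @param n_tips Number of tips (>= 2).
#' @param tree_model `"yule"` (pure birth) or `"birth_death"`.
#' @param birth,death Branching rates; `death < birth` required for
#'   `"birth_death"`.
#' @param alpha_true Signal parameter of the latent trait process
#'   (inverse unit-height distance; larger = less phylogenetic structure).
#' @param beta_true Length-2 vector (intercept, predictor effect) in
#'   log-odds.
#' @param predictor_model `"clade_block"` (a clade covering 30-70% of tips
#'   carries the trait) or `"mk_switch"` (two-state symmetric Markov
#'   process along branches).
#' @param mk_rate Transition rate for `"mk_switch"`.
#' @param disagreement_rate Per-trait probability that an observer's score
#'   toggles relative to the truth, in [0, 1].
#' @param seed Integer seed; every generator is reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_tips = 300L, tree_model = c("yule", "birth_death"),
                       birth = 1, death = 0, alpha_true = 1,
                       beta_true = c(-1, 1),
                       predictor_model = c("clade_block", "mk_switch"),
                       mk_rate = 1, disagreement_rate = 0.1, seed = 1L) {
  tree_model <- match.arg(tree_model)
  predictor_model <- match.arg(predictor_model)
  stopifnot(n_tips >= 2L, birth > 0, death >= 0,
            alpha_true >= 0, length(beta_true) == 2L, mk_rate >= 0,
            disagreement_rate >= 0, disagreement_rate <= 1)
  if (tree_model == "birth_death" && death >= birth) {
    stop("birth_death requires death < birth", call. = FALSE)
  }
  structure(list(n_tips = as.integer(n_tips), tree_model = tree_model,
                 birth = birth, death = death, alpha_true = alpha_true,
                 beta_true = beta_true, predictor_model = predictor_model,
                 mk_rate = mk_rate, disagreement_rate = disagreement_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an ultrametric tree
#'
#' Draws a tree with `n_tips` tips under a Yule or birth-death process
#' (conditioned on the tip count) and rescales branch lengths to unit
#' height, so the simulated signal parameter and the fitted one share
#' units.
#'
#' @param config A [sim_config()].
#' @return An [ape::phylo] ultrametric tree of height 1.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- with_seed(config$seed, {
    ape::rphylo(config$n_tips, birth = config$birth, death = config$death)
  })
  tree$edge.length <- tree$edge.length / tree_height(tree)
  tree$tip.label <- sprintf("sp%04d", seq_len(config$n_tips))
  tree
}

#' Simulate a phylogenetically structured binary predictor
#'
#' `"clade_block"` emulates a conserved ecological trait (e.g. feeding on
#' forbs): one internal node whose clade spans 30-70% of the tips is chosen
#' at random and its descendants are assigned 1. `"mk_switch"` runs a
#' two-state symmetric Markov process with rate `mk_rate` along branches
#' from a uniformly drawn root state. If no internal node falls in the
#' clade-size window, the generator falls back to `"mk_switch"` with a
#' warning.
#'
#' @param tree An [ape::phylo] tree.
#' @param config A [sim_config()]; the seed is offset internally so the
#'   predictor draw is independent of the tree draw.
#' @return Named integer vector of 0/1, one per tip.
#' @export
simulate_predictor <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- ape::Ntip(tree)
  with_seed(config$seed + 1L, {
    if (config$predictor_model == "clade_block") {
      parts <- ape::prop.part(tree)
      sizes <- lengths(parts)
      ok <- which(sizes >= 0.3 * n & sizes <= 0.7 * n)
      if (length(ok) == 0L) {
        warning("no clade covers 30-70% of tips; falling back to mk_switch")
        return(mk_switch_states(tree, config$mk_rate))
      }
      pick <- parts[[ok[sample.int(length(ok), 1L)]]]
      x <- integer(n)
      x[pick] <- 1L
      names(x) <- tree$tip.label
      x
    } else {
      mk_switch_states(tree, config$mk_rate)
    }
  })
}

# two-state symmetric Markov ("exact switching") process along branches
mk_switch_states <- function(tree, rate) {
  if (rate == 0) {
    x <- rep(sample(0:1, 1L), ape::Ntip(tree))
    names(x) <- tree$tip.label
    return(x)
  }
  st <- ape::rTraitDisc(tree, model = "ER", k = 2L, rate = rate,
                        states = c("0", "1"), root.value = sample(1:2, 1L))
  x <- as.integer(as.character(st))
  names(x) <- tree$tip.label
  x
}

#' Simulate a binary response with known effect and phylogenetic signal
#'
#' Latent-threshold generator: z ~ MVN(0, R(alpha_true)) on the patristic
#' distances, and y_i = 1 iff Phi(z_i) < logistic(beta0 + beta1 x_i). The
#' marginal success probability is exactly logistic(beta0 + beta1 x_i),
#' while the between-tip dependence decays with distance like the latent
#' correlation — an approximation (exact margins, qualitatively matched
#' correlation shape) to a two-state switching process with
#' covariate-dependent stationary frequencies.
#'
#' @param tree An [ape::phylo] tree (height is normalized internally).
#' @param predictor 0/1 vector aligned with the tips.
#' @param config A [sim_config()]; `beta_true` and `alpha_true` are used.
#' @param seed_offset Internal offset so independent traits can be drawn
#'   from one config.
#' @return Named integer 0/1 vector.
#' @export
simulate_response <- function(tree, predictor, config, seed_offset = 2L) {
  stopifnot(inherits(config, "sim_config"),
            length(predictor) == ape::Ntip(tree))
  pd <- patristic_matrix(tree, normalize = TRUE)
  R <- tip_correlation(pd, config$alpha_true)
  L <- tryCatch(chol(R + 1e-10 * diag(nrow(R))),
                error = function(e) {
                  stop("latent correlation matrix is not positive definite",
                       call. = FALSE)
                })
  with_seed(config$seed + seed_offset, {
    z <- drop(crossprod(L, stats::rnorm(nrow(R))))
    p <- stats::plogis(config$beta_true[1] + config$beta_true[2] * predictor)
    y <- as.integer(stats::pnorm(z) < p)
    names(y) <- tree$tip.label
    y
  })
}

#' Add two-observer scoring noise to true colour/pattern assignments
#'
#' Each observer's score of each species is the truth with every trait
#' toggled independently with probability `disagreement_rate`; colour
#' toggles respect the three-colour cap by random eviction of one held
#' colour when an addition would exceed it.
#'
#' @param truth Data frame with columns `species`, `colours`
#'   (list-column of character vectors, each of length <= 3) and `patterns`
#'   (list-column).
#' @param config A [sim_config()].
#' @return A scores data frame (see [read_scores()]) with observers
#'   `"obs1"` and `"obs2"`.
#' @export
simulate_observers <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$disagreement_rate
  voc <- colour_vocabulary()
  pats <- pattern_vocabulary()
  with_seed(config$seed + 7L, {
    one_observer <- function(obs_id) {
      rows <- lapply(seq_len(nrow(truth)), function(i) {
        cols <- truth$colours[[i]]
        flip <- voc[stats::runif(length(voc)) < rate]
        newc <- union(setdiff(cols, flip), setdiff(flip, cols))
        while (length(newc) > 3L) {
          newc <- newc[-sample.int(length(newc), 1L)]
        }
        pp <- truth$patterns[[i]]
        flip_p <- pats[stats::runif(length(pats)) < rate]
        newp <- union(setdiff(pp, flip_p), setdiff(flip_p, pp))
        newc <- c(sort(newc), "", "", "")[1:3]
        c(list(species = truth$species[i], observer = obs_id,
               colour1 = newc[1], colour2 = newc[2], colour3 = newc[3]),
          as.list(stats::setNames(as.integer(pats %in% newp), pats)))
      })
      do.call(rbind.data.frame, rows)
    }
    rbind(one_observer("obs1"), one_observer("obs2"))
  })
}

#' Simulate a complete two-observer comparative study
#'
#' Builds everything the analysis pipeline consumes: a tree; one
#' clade-structured (or Markov) binary ecology predictor mapped to host
#' growth form (forb when 1, woody otherwise); one "planted" colour trait
#' associated with the predictor at effect `beta_true[2]` (skipped when
#' `planted = FALSE`); further null colour and pattern traits with the
#' same phylogenetic signal but no association; and two observers with
#' scoring noise. Diet breadth is drawn independently of everything.
#'
#' @param config A [sim_config()].
#' @param planted Plant a colour~growth-form association? Default TRUE.
#' @param planted_colour Colour carrying the planted effect.
#' @param null_colours,null_patterns Names of additional null traits.
#' @param null_beta0 Baseline log-odds of each null trait.
#' @return List with `tree`, `scores` (two observers), `ecology`, `truth`
#'   (list: predictor vector, per-trait response vectors, config).
#' @export
simulate_study <- function(config, planted = TRUE,
                           planted_colour = "black",
                           null_colours = c("green", "brown"),
                           null_patterns = c("stripe", "band"),
                           null_beta0 = -1) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config)
  x <- simulate_predictor(tree, config)
  traits <- list()
  off <- 2L
  if (planted) {
    traits[[planted_colour]] <- simulate_response(tree, x, config, off)
    off <- off + 11L
  }
  null_cfg <- config
  null_cfg$beta_true <- c(null_beta0, 0)
  for (tn in c(null_colours, null_patterns)) {
    traits[[tn]] <- simulate_response(tree, x, null_cfg, off)
    off <- off + 11L
  }
  colour_names <- intersect(names(traits), colour_vocabulary())
  pattern_names <- intersect(names(traits), pattern_vocabulary())
  truth_df <- data.frame(species = tree$tip.label)
  truth_df$colours <- lapply(seq_along(tree$tip.label), function(i) {
    colour_names[vapply(colour_names, function(tn) traits[[tn]][i] == 1L,
                        logical(1))]
  })
  truth_df$patterns <- lapply(seq_along(tree$tip.label), function(i) {
    pattern_names[vapply(pattern_names, function(tn) traits[[tn]][i] == 1L,
                         logical(1))]
  })
  scores <- simulate_observers(truth_df, config)
  diet <- with_seed(config$seed + 5L, {
    sample(diet_levels(), ape::Ntip(tree), replace = TRUE)
  })
  ecology <- data.frame(species = tree$tip.label,
                        diet_breadth = diet,
                        tissue = "leaves",
                        growth_forms = ifelse(x == 1L, "forb", "woody"))
  list(tree = tree, scores = scores, ecology = ecology,
       truth = list(predictor = x, traits = traits, config = config,
                    planted = if (planted) {
                      c(response = planted_colour, predictor = "forb")
                    }))
}

#' Write a simulated study to disk in the analysis input formats
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed): `tree.nwk`,
#'   `scores.csv`, `ecology.csv`, `truth.json`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(study$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(study$ecology, file.path(dir, "ecology.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(study$truth$config),
         predictor = as.list(study$truth$predictor),
         planted = as.list(study$truth$planted)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
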