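#' Configuration for the association analysis
#'
#' @param a_priori Data frame with columns `response` and `predictor`
#'   naming literature-predicted trait pairs; these form the a-priori FDR
#'   family, everything else is exploratory. NULL for none.
#' @param pairs Optional data frame (`response`, `predictor`) restricting
#'   the model list to the given pairs instead of the full cross of trait
#'   classes.
#' @param B Number of observer-bootstrap replicates (study default 1000).
#' @param consensus_threshold Minimum fraction of significant,
#'   sign-consistent bootstrap replicates for a supported association
#'   (study default 0.90; the comparison is `support >= threshold`).
#' @param level Significance level applied to FDR-adjusted p-values
#'   (default 0.05).
#' @param seed Master seed; per-replicate sub-seeds are derived from it so
#'   replicates are independently reproducible.
#' @param min_occurrences Rarity threshold for colour traits when freezing
#'   the trait universe.
#' @param direction `"colour_response"` (default): coloration is the
#'   response in colour~pattern and colour~ecology models, pattern the
#'   response in pattern~ecology models. `"reversed"` swaps response and
#'   predictor for sensitivity checks.
#' @param fdr_scope `"subset"` (default) adjusts within the a-priori and
#'   exploratory families separately; `"global"` adjusts across all models.
#' @param refilter_per_replicate Re-apply the rarity filter inside each
#'   bootstrap replicate instead of freezing the pooled trait universe.
#' @param control A [phyloglm_control()]; the pipeline restricts the
#'   signal-parameter search to the `n_grid` profile grid so correlation
#'   factor work is shared across all fits on one tree.
#' @return List of class `assoc_config`.
#' @export
assoc_config <- function(a_priori = NULL, pairs = NULL, B = 1000L,
                         consensus_threshold = 0.90, level = 0.05,
                         seed = 1L, min_occurrences = 5L,
                         direction = c("colour_response", "reversed"),
                         fdr_scope = c("subset", "global"),
                         refilter_per_replicate = FALSE,
                         control = phyloglm_control()) {
  direction <- match.arg(direction)
  fdr_scope <- match.arg(fdr_scope)
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  stopifnot(consensus_threshold > 0, consensus_threshold <= 1,
            level > 0, level < 1)
  structure(list(a_priori = a_priori, pairs = pairs, B = as.integer(B),
                 consensus_threshold = consensus_threshold, level = level,
                 seed = as.integer(seed),
                 min_occurrences = as.integer(min_occurrences),
                 direction = direction, fdr_scope = fdr_scope,
                 refilter_per_replicate = isTRUE(refilter_per_replicate),
                 control = control),
            class = "assoc_config")
}

hypothesis_tag <- function(response_class, predictor_name) {
  eco_kind <- function(nm) {
    ifelse(startsWith(nm, "diet_"), "diet",
    ifelse(startsWith(nm, "tissue_"), "tissue", "growth_form"))
  }
  ifelse(predictor_name %in% pattern_vocabulary() |
           response_class == "pattern_vs_colour",
         "HI: colour~pattern",
  ifelse(response_class == "pattern",
         paste0("H-expl: pattern~", eco_kind(predictor_name)),
  ifelse(eco_kind(predictor_name) == "diet",
         "HIV: colour~diet", "HII/III: colour~host")))
}

#' Enumerate the bivariate trait-pair models
#'
#' Builds one model per trait pair across the hypothesis families: every
#' colour trait against every pattern trait (colour as response), every
#' colour and pattern trait against every ecology column (ecology as
#' predictor). A pair listed in `config$a_priori` is tagged `a_priori`,
#' all others `exploratory`; FDR correction is later applied within these
#' subsets. `config$pairs`, when given, restricts the list.
#'
#' @param x A `trait_matrix` (the frozen trait universe).
#' @param config An [assoc_config()].
#' @return Data frame: `response`, `predictor`, `subset`, `hypothesis`.
#' @export
enumerate_models <- function(x, config = assoc_config()) {
  stopifnot(inherits(x, "trait_matrix"))
  cls <- x$trait_class
  colour_tr <- names(cls)[cls %in% c("colour_single", "colour_pair")]
  pattern_tr <- names(cls)[cls == "pattern"]
  ecology_tr <- names(cls)[cls == "ecology"]
  if (!is.null(config$pairs)) {
    specs <- data.frame(response = as.character(config$pairs$response),
                        predictor = as.character(config$pairs$predictor),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(c(specs$response, specs$predictor), names(cls))
    if (length(unknown)) stop("config references unknown trait(s): ",
                              paste(unique(unknown), collapse = ", "),
                              call. = FALSE)
  } else {
    specs <- rbind(
      expand.grid(response = colour_tr, predictor = pattern_tr,
                  stringsAsFactors = FALSE),
      expand.grid(response = colour_tr, predictor = ecology_tr,
                  stringsAsFactors = FALSE),
      expand.grid(response = pattern_tr, predictor = ecology_tr,
                  stringsAsFactors = FALSE))
  }
  if (nrow(specs) == 0L) return(cbind(specs, subset = character(0),
                                      hypothesis = character(0)))
  if (identical(config$direction, "reversed")) {
    specs[, c("response", "predictor")] <-
      specs[, c("predictor", "response")]
  }
  specs <- specs[specs$response != specs$predictor, , drop = FALSE]
  ap <- config$a_priori
  if (!is.null(ap) && nrow(ap)) {
    unknown <- setdiff(c(ap$response, ap$predictor), names(cls))
    if (length(unknown)) stop("a_priori list references unknown trait(s): ",
                              paste(unique(unknown), collapse = ", "),
                              call. = FALSE)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    specs$subset <- ifelse(key(specs$response, specs$predictor) %in%
                             key(as.character(ap$response),
                                 as.character(ap$predictor)),
                           "a_priori", "exploratory")
  } else {
    specs$subset <- "exploratory"
  }
  rcls <- ifelse(cls[specs$response] == "pattern" &
                   cls[specs$predictor] %in%
                     c("colour_single", "colour_pair"),
                 "pattern_vs_colour", cls[specs$response])
  specs$hypothesis <- hypothesis_tag(rcls, specs$predictor)
  rownames(specs) <- NULL
  specs
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment as used within each hypothesis family. Thin
#' validating wrapper around [stats::p.adjust()] with `method = "BH"`:
#' adjusted values are monotone in rank, at least the raw p, and capped
#' at 1. Raw p-values must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# one full set of model fits on a single-observer trait matrix;
# returns p, sign, converged per model row
fit_all_specs <- function(values, specs, grid, control) {
  m <- nrow(specs)
  p <- sgn <- beta <- se <- alpha <- rep(NA_real_, m)
  conv <- rep(FALSE, m)
  for (k in seq_len(m)) {
    y <- values[, specs$response[k]]
    x <- values[, specs$predictor[k]]
    keep <- !is.na(y) & !is.na(x)
    fit <- tryCatch({
      if (sum(keep) < 4L || length(unique(y[keep])) < 2L ||
          length(unique(x[keep])) < 2L) NULL
      else if (all(keep)) {
        fit_phyloglm_grid(y, cbind(`(Intercept)` = 1, x = x), grid, control)
      } else {
        NULL  # handled below with a subset refit
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) && any(!keep) && sum(keep) >= 4L &&
        length(unique(y[keep])) == 2L && length(unique(x[keep])) == 2L) {
      fit <- tryCatch(
        suppressWarnings(fit_phyloglm(
          y[keep], cbind(`(Intercept)` = 1, x = x[keep]),
          attr(grid, "D")[keep, keep, drop = FALSE],
          modifyList(control, list(refine = 0L)))),
        error = function(e) NULL)
    }
    if (!is.null(fit) && fit$converged) {
      conv[k] <- TRUE
      p[k] <- fit$p_values[[2L]]
      sgn[k] <- sign(fit$coefficients[[2L]])
      beta[k] <- fit$coefficients[[2L]]
      se[k] <- fit$se[[2L]]
      alpha[k] <- fit$alpha
    }
  }
  list(p = p, sign = sgn, converged = conv, beta = beta, se = se,
       alpha = alpha)
}

# BH within FDR families, returning the significant & sign-consistent flag
adjusted_significant <- function(p, subset, scope, level) {
  adj <- rep(NA_real_, length(p))
  fam <- if (scope == "global") rep("all", length(p)) else subset
  for (f in unique(fam)) {
    idx <- which(fam == f & !is.na(p))
    if (length(idx)) adj[idx] <- fdr_adjust(p[idx])
  }
  adj
}

#' Run the full observer-bootstrap association analysis
#'
#' The complete pipeline: freeze the trait universe from the pooled
#' (union) two-observer scores with the rarity filter applied; align tree
#' and matrix; fit every trait-pair model on the pooled data; then for
#' each of B bootstrap replicates draw one observer per species uniformly
#' at random, rebuild the trait matrix on the frozen columns, refit all
#' models, BH-adjust within the a-priori and exploratory families, and
#' count a replicate as significant for a pair only when the adjusted p
#' is below `level` AND the coefficient sign matches the pooled-data sign.
#' An association is supported when its significant fraction (over
#' converged replicates) reaches the consensus threshold.
#'
#' @param scores Two-observer scores data frame (see [read_scores()]).
#' @param ecology Ecology data frame (see [read_ecology()]) or NULL for a
#'   colour/pattern-only analysis.
#' @param tree An [ape::phylo] tree.
#' @param config An [assoc_config()].
#' @return Object of class `association_results`: a data frame with one
#'   row per model (`response`, `predictor`, `subset`, `hypothesis`,
#'   `beta`, `se`, `alpha`, `p_full`, `adj_p_full`, `sign`, `support`,
#'   `replicates_used`, `supported`, `unreliable`), with the frozen trait
#'   universe, convergence log and configuration as attributes.
#' @export
run_full_analysis <- function(scores, ecology, tree, config = assoc_config()) {
  stopifnot(inherits(config, "assoc_config"))
  scores <- validate_scores(scores)
  species <- unique(scores$species)
  if (length(species) == 0L) stop("empty scores table", call. = FALSE)

  # pooled union scores freeze the trait universe
  pooled <- pool_observers(scores)
  pooled_tm <- build_trait_matrix(pooled, ecology,
                                  min_occurrences = config$min_occurrences)
  mt <- match_tips(tree, pooled_tm)
  tree <- mt$tree
  pooled_tm <- mt$matrix
  universe <- colnames(pooled_tm$values)
  colour_universe <- universe[pooled_tm$trait_class %in%
                                c("colour_single", "colour_pair")]

  specs <- enumerate_models(pooled_tm, config)
  if (nrow(specs) == 0L) stop("no models to fit", call. = FALSE)

  pd <- patristic_matrix(tree)
  grid <- make_corr_grid(pd$D, config$control)
  attr(grid, "D") <- pd$D

  full <- fit_all_specs(pooled_tm$values, specs, grid, config$control)
  full_adj <- adjusted_significant(full$p, specs$subset, config$fdr_scope,
                                   config$level)

  # observer bootstrap: one observer per species per replicate
  obs_by_species <- split(scores$observer, scores$species)
  obs_by_species <- obs_by_species[tree$tip.label]
  if (any(vapply(obs_by_species, length, 1L) == 0L)) {
    stop("species without any observer record", call. = FALSE)
  }
  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max, config$B))
  n_sig <- n_conv <- integer(nrow(specs))
  conv_log <- integer(config$B)
  row_of <- split(seq_len(nrow(scores)), scores$species)
  for (b in seq_len(config$B)) {
    rep_scores <- with_seed(sub_seeds[b], {
      pick <- vapply(tree$tip.label, function(sp) {
        rows <- row_of[[sp]]
        rows[sample.int(length(rows), 1L)]
      }, integer(1))
      scores[pick, , drop = FALSE]
    })
    rep_tm <- build_trait_matrix(
      rep_scores, ecology,
      min_occurrences = if (config$refilter_per_replicate) {
        config$min_occurrences
      } else 0L,
      trait_universe = colour_universe)
    vals <- rep_tm$values[tree$tip.label, universe[universe %in%
                                    colnames(rep_tm$values)], drop = FALSE]
    res <- fit_all_specs(vals, specs, grid, config$control)
    adj <- adjusted_significant(res$p, specs$subset, config$fdr_scope,
                                config$level)
    sig <- !is.na(adj) & adj < config$level &
      !is.na(res$sign) & !is.na(full$sign) &
      res$sign == full$sign & res$sign != 0
    n_sig <- n_sig + as.integer(res$converged & sig)
    n_conv <- n_conv + as.integer(res$converged)
    conv_log[b] <- sum(res$converged)
  }
  support <- ifelse(n_conv > 0, n_sig / n_conv, NA_real_)
  out <- data.frame(
    specs,
    beta = full$beta, se = full$se, alpha = full$alpha,
    p_full = full$p, adj_p_full = full_adj,
    sign = ifelse(is.na(full$sign), 0, full$sign),
    support = support,
    replicates_used = n_conv,
    supported = !is.na(support) & support >= config$consensus_threshold,
    unreliable = n_conv < 0.5 * config$B,
    stringsAsFactors = FALSE)
  structure(out,
            class = c("association_results", "data.frame"),
            trait_universe = universe,
            trait_class = pooled_tm$trait_class,
            excluded_traits = excluded_traits(pooled_tm),
            missing_ecology = attr(pooled_tm, "missing_ecology"),
            convergence_log = conv_log,
            config = config)
}

# union of the observers' colour and pattern scores per species
pool_observers <- function(scores) {
  sp <- unique(scores$species)
  rows <- lapply(sp, function(s) {
    sub <- scores[scores$species == s, , drop = FALSE]
    cols <- setdiff(unique(unlist(sub[, paste0("colour", 1:3)])), "")
    # the union can exceed three colours; keep the three most frequently
    # scored (ties broken alphabetically) to respect the scoring cap
    if (length(cols) > 3L) {
      freq <- colSums(colour_membership(sub)[, sort(cols), drop = FALSE])
      cols <- names(sort(freq, decreasing = TRUE))[1:3]
    }
    cols <- c(sort(cols), "", "", "")[1:3]
    pat <- as.integer(colSums(sub[, pattern_vocabulary(), drop = FALSE]) > 0)
    c(list(species = s, observer = "pooled",
           colour1 = cols[1], colour2 = cols[2], colour3 = cols[3]),
      as.list(stats::setNames(pat, pattern_vocabulary())))
  })
  do.call(rbind.data.frame, rows)
}

#' @export
print.association_results <- function(x, ...) {
  cat(sprintf(
    "association_results: %d models (%d a priori), B = %d, threshold %.2f\n",
    nrow(x), sum(x$subset == "a_priori"),
    attr(x, "config")$B, attr(x, "config")$consensus_threshold))
  cat(sprintf("  supported: %d\n", sum(x$supported)))
  if (any(x$supported)) {
    s <- as.data.frame(x)[x$supported,
                          c("response", "predictor", "sign", "support",
                            "subset")]
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Export the supported-association network
#'
#' Writes the Fig.-3-style outputs: `edges.csv` with one row per supported
#' association (`response`, `predictor`, `sign`, `support`, `subset`), a
#' `results.json` with the complete per-model table (support is reported
#' for every model, supported or not), and `graph.json` whose nodes carry
#' the display class used for trait-syndrome figures (circle for colour
#' traits, square for patterns, diamond for ecology).
#'
#' @param results An `association_results` object.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the edge data frame.
#' @export
export_association_network <- function(results, dir) {
  stopifnot(inherits(results, "association_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- results[results$supported,
                   c("response", "predictor", "sign", "support", "subset"),
                   drop = FALSE]
  edges$sign <- ifelse(edges$sign > 0, "+", "-")
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  jsonlite::write_json(as.data.frame(results),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  cls <- attr(results, "trait_class")
  used <- unique(c(results$response, results$predictor))
  shape_of <- c(colour_single = "circle", colour_pair = "circle",
                pattern = "square", ecology = "diamond")
  nodes <- lapply(used, function(nm) {
    list(id = nm, class = unname(cls[[nm]]),
         shape = unname(shape_of[[cls[[nm]]]]))
  })
  elist <- lapply(seq_len(nrow(edges)), function(i) {
    list(from = edges$predictor[i], to = edges$response[i],
         sign = edges$sign[i], support = edges$support[i],
         subset = edges$subset[i])
  })
  jsonlite::write_json(list(nodes = nodes, edges = elist),
                       file.path(dir, "graph.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(edges)
}
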