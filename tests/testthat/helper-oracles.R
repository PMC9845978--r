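# Independent oracles and small fixture builders shared across tests.

# Firth-penalized ordinary logistic regression by direct maximization of
# the Jeffreys-penalized log-likelihood (BFGS), independent of the
# package's estimating-equation solver.
firth_logistic_oracle <- function(y, X) {
  penalized <- function(b) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  }
  stats::optim(rep(0, ncol(X)), function(b) -penalized(b),
               method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))$par
}

# Brute-force Benjamini-Hochberg: sort, scale by m/rank, cumulative
# minimum from the largest, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# All-pairs shortest paths on the tree graph (igraph), an independent
# check of the patristic distance computation.
graph_distance_oracle <- function(tree) {
  skip_if_not_installed("igraph")
  n_tip <- ape::Ntip(tree)
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  D <- igraph::distances(g, weights = tree$edge.length)
  D <- D[seq_len(n_tip), seq_len(n_tip)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# A scores data frame for hand-built examples: colours is a list of
# character vectors, patterns a list of character vectors.
make_scores <- function(species, colours, patterns,
                        observer = "obs1") {
  stopifnot(length(species) == length(colours),
            length(species) == length(patterns))
  pats <- pattern_vocabulary()
  rows <- lapply(seq_along(species), function(i) {
    cc <- c(sort(colours[[i]]), "", "", "")[1:3]
    c(list(species = species[i], observer = observer,
           colour1 = cc[1], colour2 = cc[2], colour3 = cc[3]),
      as.list(stats::setNames(as.integer(pats %in% patterns[[i]]), pats)))
  })
  do.call(rbind.data.frame, rows)
}

make_ecology <- function(species, diet = "oligophagous",
                         tissue = "leaves", growth = "forb") {
  data.frame(species = species,
             diet_breadth = rep_len(diet, length(species)),
             tissue = rep_len(tissue, length(species)),
             growth_forms = rep_len(growth, length(species)),
             stringsAsFactors = FALSE)
}

# small random coalescent-shaped tree for property loops
random_tree <- function(n, seed) {
  cfg <- sim_config(n_tips = n, seed = seed)
  simulate_tree(cfg)
}
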