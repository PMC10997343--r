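# Independent oracles and fixture generators used across the suite.

# brute-force Gaussian log-likelihood maximization for p = 1 (numerical
# optimizer, no use of the package's closed forms)
max_loglik_1d <- function(x) {
  nll <- function(par) -sum(stats::dnorm(x, par[1], exp(par[2]), log = TRUE))
  stats::optim(c(mean(x), log(stats::sd(x))), nll,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))$value * -1
}

brute_force_wn_1d <- function(x1, x2) {
  2 * (max_loglik_1d(x1) + max_loglik_1d(x2) - max_loglik_1d(c(x1, x2)))
}

# brute-force chordality: every cycle of length >= 4 has a chord.
# Implemented as recursive vertex elimination over simplicial vertices.
brute_force_chordal <- function(adj) {
  n <- nrow(adj)
  if (n <= 3) return(TRUE)
  alive <- rep(TRUE, n)
  repeat {
    idx <- which(alive)
    if (length(idx) <= 1) return(TRUE)
    found <- FALSE
    for (v in idx) {
      nb <- intersect(which(adj[v, ]), idx)
      if (length(nb) <= 1 ||
          all(adj[nb, nb] | diag(length(nb)))) {
        alive[v] <- FALSE
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
}

random_graph <- function(n, prob, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < prob
  adj <- adj | t(adj)
  labels <- as.character(seq_len(n))
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  undirected_graph(cbind(labels[edges[, 1]], labels[edges[, 2]]),
                   nodes = labels)
}

# random decomposable graph via sequential clique attachment (clique tree)
random_chordal_graph <- function(k_cliques = 4, max_clique = 5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cliques <- list(as.character(seq_len(sample(2:max_clique, 1))))
  nxt <- length(cliques[[1]]) + 1
  for (i in seq_len(k_cliques - 1)) {
    host <- cliques[[sample(length(cliques), 1)]]
    sep <- sample(host, sample(seq_len(min(length(host), max_clique - 1)), 1))
    new_size <- sample(seq_len(max_clique - length(sep)), 1)
    new_nodes <- as.character(seq(nxt, nxt + new_size - 1))
    nxt <- nxt + new_size
    cliques[[length(cliques) + 1]] <- c(sep, new_nodes)
  }
  edges <- do.call(rbind, lapply(cliques, function(cl) {
    if (length(cl) > 1) t(utils::combn(sort(cl), 2)) else NULL
  }))
  undirected_graph(edges, nodes = as.character(seq_len(nxt - 1)))
}

# brute-force maximal clique enumeration by exhaustive subset scan
# (test-sized graphs only, |V| <= 14)
brute_force_max_cliques <- function(g) {
  n <- length(g$nodes)
  adj <- g$adj | diag(n)
  complete <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (all(adj[members, members])) complete[[length(complete) + 1]] <- members
  }
  maximal <- Filter(function(a) {
    !any(vapply(complete, function(b)
      length(b) > length(a) && all(a %in% b), logical(1)))
  }, complete)
  lapply(maximal, function(ix) sort(g$nodes[ix]))
}

# hand-built alternative RIP ordering (fields only; used to check ordering
# invariance of the decomposed statistic)
manual_rip <- function(cliques, separators, residuals, nodes) {
  structure(list(cliques = cliques, separators = separators,
                 residuals = residuals, nodes = nodes),
            class = "rip_structure")
}

null_pair <- function(p, n1, n2 = n1) {
  two_sample_data(matrix(stats::rnorm(n1 * p), n1),
                  matrix(stats::rnorm(n2 * p), n2),
                  labels = as.character(seq_len(p)))
}
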