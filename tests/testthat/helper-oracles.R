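# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: betweenness by exhaustive path enumeration in plain
# R, likelihoods by direct numeric maximization, Jaccard by element counting.

# Adjacency list (named list of character vectors) from an edge data frame.
adj_from_edges <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    if (!(b %in% adj[[a]])) adj[[a]] <- c(adj[[a]], b)
    if (!(a %in% adj[[b]])) adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# All simple paths s -> t by depth-first search.
all_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(v, seen) {
    if (v == t) { paths[[length(paths) + 1L]] <<- seen; return(invisible()) }
    for (w in adj[[v]]) if (!(w %in% seen)) walk(w, c(seen, w))
  }
  walk(s, s)
  paths
}

# Betweenness by brute-force enumeration of all geodesics.
oracle_betweenness <- function(edges) {
  adj <- adj_from_edges(edges)
  nodes <- names(adj)
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  if (length(nodes) < 3L) return(btw)
  prs <- utils::combn(nodes, 2L)
  for (i in seq_len(ncol(prs))) {
    s <- prs[1L, i]; t <- prs[2L, i]
    paths <- all_paths(adj, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    geo <- paths[lens == min(lens)]
    sigma <- length(geo)
    for (p in geo) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / sigma
    }
  }
  btw
}

# Random connected-ish simple graph as an interaction record frame.
random_graph_records <- function(n_nodes, p_edge = 0.4) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  prs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(prs)) < p_edge
  if (!any(keep)) keep[sample(ncol(prs), 1L)] <- TRUE
  data.frame(protein_a = prs[1L, keep], protein_b = prs[2L, keep],
             ht_quality = TRUE, publication_count = 2L, is_binary = TRUE,
             stringsAsFactors = FALSE)
}

# Direct numeric maximizer of the NB log-likelihood over
# (intercept, beta, log theta); independent of the IRLS fitting path.
oracle_nb_ml <- function(x, y) {
  ll <- function(par) {
    mu <- exp(pmin(pmax(par[1L] + par[2L] * x, -30), 30))
    theta <- exp(par[3L])
    -sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
           theta * log(theta / (theta + mu)) +
           ifelse(y > 0, y * log(mu / (theta + mu)), 0))
  }
  start <- c(log(mean(y) + 0.5), 0, 0)
  o1 <- stats::nlminb(start, ll, control = list(rel.tol = 1e-14,
                                                iter.max = 500L))
  o2 <- stats::optim(o1$par, ll, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 500L))
  best <- if (o2$value < o1$objective) o2$par else o1$par
  list(par = best, loglik = -min(o1$objective, o2$value))
}

# Direct numeric maximizer of the Poisson log-likelihood.
oracle_poisson_ml <- function(x, y) {
  ll <- function(par) {
    mu <- exp(pmin(pmax(par[1L] + par[2L] * x, -30), 30))
    -sum(stats::dpois(y, mu, log = TRUE))
  }
  o <- stats::optim(c(log(mean(y) + 0.5), 0), ll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 500L))
  list(par = o$par, loglik = -o$value)
}

# Jaccard by explicit element counting over the union.
oracle_jaccard <- function(da, db) {
  uni <- unique(c(da, db))
  n_both <- 0L
  for (e in uni) if ((e %in% da) && (e %in% db)) n_both <- n_both + 1L
  n_both / length(uni)
}

# Small interaction fixture writer for ingest tests.
write_lines_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
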