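# Degree-preserving edge swaps, association shuffles, and the null-trial
# runner.

test_that("edge swaps preserve the degree sequence and simplicity", {
  set.seed(51)
  for (i in 1:10) {
    g <- build_network(random_graph_records(20L, 0.2))
    r <- edge_swap_randomize(g, seed = i)
    expect_identical(sort(igraph::degree(r)), sort(igraph::degree(g)))
    expect_identical(igraph::degree(r)[igraph::V(g)$name],
                     igraph::degree(g)[igraph::V(g)$name])
    expect_equal(igraph::ecount(r), igraph::ecount(g))
    expect_true(igraph::is_simple(r))
  }
})

test_that("the triangle admits no valid swap", {
  tri <- build_network(data.frame(protein_a = c("A", "B", "C"),
                                  protein_b = c("B", "C", "A"),
                                  stringsAsFactors = FALSE))
  r <- edge_swap_randomize(tri, n_attempts = 500L, seed = 3L)
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])))
  }
  expect_identical(canon(r), canon(tri))
})

test_that("zero attempts and tiny graphs leave the network unchanged", {
  g <- build_network(random_graph_records(10L, 0.3))
  expect_identical(igraph::as_edgelist(
    edge_swap_randomize(g, n_attempts = 0L, seed = 1L)),
    igraph::as_edgelist(g))
  one <- build_network(data.frame(protein_a = "A", protein_b = "B",
                                  stringsAsFactors = FALSE))
  expect_warning(r <- edge_swap_randomize(one, seed = 1L), "fewer than 2")
  expect_equal(igraph::ecount(r), 1L)
})

test_that("edge swaps are seed-deterministic", {
  g <- build_network(random_graph_records(30L, 0.15))
  r1 <- edge_swap_randomize(g, seed = 9L)
  r2 <- edge_swap_randomize(g, seed = 9L)
  expect_identical(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
})

make_drugs <- function(target_sets) {
  d <- data.frame(drug_id = sprintf("D%d", seq_along(target_sets)),
                  stringsAsFactors = FALSE)
  d$targets <- target_sets
  class(d) <- c("drug_table", "data.frame")
  d
}

test_that("target shuffles conserve set sizes and incidences", {
  drugs <- make_drugs(list(c("P1", "P2"), "P3", c("P4", "P5", "P6"),
                           character(0)))
  sh <- shuffle_drug_targets(drugs, seed = 7L)
  expect_equal(lengths(sh$targets), lengths(drugs$targets))
  expect_setequal(unlist(sh$targets), unlist(drugs$targets))
  expect_true(all(vapply(sh$targets, anyDuplicated, integer(1)) == 0L))
  # single drug: unchanged size
  one <- shuffle_drug_targets(make_drugs(list(c("P1", "P2"))), seed = 1L)
  expect_length(one$targets[[1L]], 2L)
})

test_that("two single-target drugs swap with near-even frequency", {
  drugs <- make_drugs(list("T1", "T2"))
  swapped <- vapply(1:1000, function(s)
    shuffle_drug_targets(drugs, seed = s)$targets[[1L]] == "T2",
    logical(1))
  expect_gte(mean(swapped), 0.45)
  expect_lte(mean(swapped), 0.55)
})

test_that("disease shuffles obey the same incidence contract", {
  dmap <- list(DIS1 = c("G1", "G2", "G3"), DIS2 = "G4",
               DIS3 = c("G5", "G6"))
  sh <- shuffle_disease_genes(dmap, seed = 13L)
  expect_equal(lengths(sh), lengths(dmap))
  expect_setequal(unname(unlist(sh)), unname(unlist(dmap)))
  expect_true(all(vapply(sh, anyDuplicated, integer(1)) == 0L))
})

null_inputs <- local({
  set.seed(61)
  recs <- random_graph_records(15L, 0.25)
  g <- build_network(recs)
  nodes <- igraph::V(g)$name
  drugs <- make_drugs(list(sample(nodes, 2L), sample(nodes, 1L)))
  drugs$indicated_diseases <- list("DIS1", "DIS2")
  list(net = g, drugs = drugs,
       disease_map = list(DIS1 = sample(nodes, 3L),
                          DIS2 = sample(nodes, 2L)))
})

test_that("null trial runner summarizes per-trial statistics", {
  r <- run_null_trials(function(inputs) 42, "edge_swap", null_inputs,
                       n_trials = 5L, seed = 2L)
  expect_equal(r$mean, 42)
  expect_equal(r$standard_error, 0)
  expect_equal(r$n_skipped, 0L)

  r1 <- run_null_trials(function(inputs) 1, "target_shuffle", null_inputs,
                        n_trials = 1L, seed = 2L)
  expect_true(is.na(r1$standard_error))
})

test_that("null trial runner aborts when most trials fail", {
  flaky <- local({
    k <- 0
    function(inputs) {
      k <<- k + 1
      if (k %% 3 == 0) 1 else stop("boom")
    }
  })
  expect_error(run_null_trials(flaky, "edge_swap", null_inputs,
                               n_trials = 9L, seed = 3L),
               "half")
})

test_that("null trials are randomized: the statistic varies across trials", {
  stat <- function(inputs) sum(match(inputs$drugs$targets[[1L]],
                                     igraph::V(inputs$net)$name))
  r <- run_null_trials(stat, "target_shuffle", null_inputs,
                       n_trials = 20L, seed = 5L)
  expect_gt(stats::sd(r$per_trial_statistics), 0)
})
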