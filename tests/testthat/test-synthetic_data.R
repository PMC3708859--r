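# The synthetic study generator: determinism, marginal distributions,
# ground-truth structure.

small_cfg <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_proteins = 300L, n_drugs = 150L,
                   n_diseases = 30L, ...)
}

test_that("the generator is fully deterministic under a seed", {
  s1 <- simulate_study(small_cfg(seed = 5L))
  s2 <- simulate_study(small_cfg(seed = 5L))
  expect_identical(s1$drugs, s2$drugs)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$disease_map, s2$disease_map)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(small_cfg(seed = 6L))
  expect_false(identical(s1$drugs$side_effect_count,
                         s3$drugs$side_effect_count))
})

test_that("written study tables round-trip through the readers", {
  dir <- tempfile("study")
  st <- simulate_study(small_cfg(seed = 2L), dir = dir)
  expect_setequal(list.files(dir),
                  c("drugs.tsv", "drug_targets.tsv",
                    "target_annotations.tsv", "interactions.tsv",
                    "interfaces.tsv", "disease_genes.tsv",
                    "ground_truth.json"))
  back <- load_study(dir)
  expect_equal(back$drugs$side_effect_count,
               st$drugs$side_effect_count)
  expect_identical(back$drugs$targets, st$drugs$targets)
  expect_identical(back$annotations, st$annotations)
  expect_identical(back$disease_map[names(st$disease_map)],
                   st$disease_map)
  expect_identical(back$interactions, st$interactions)
})

test_that("attachment model edge count and heavy tail are as expected", {
  cfg <- small_cfg(seed = 3L)
  recs <- generate_interactome(cfg)
  # ~ (n - m) * m edges before filtering
  expect_gt(nrow(recs), (cfg$n_proteins - 3L) * 3L - 10L)
  expect_lte(nrow(recs), cfg$n_proteins * 3L)
  deg <- igraph::degree(build_network(recs))
  expect_gt(max(deg), 5 * stats::median(deg))
})

test_that("quality-filter pass rate matches the evidence distributions", {
  # P(fail) = P(!ht) * P(1 + Pois(0.8) < 2) = 0.4 * exp(-0.8)
  expected_pass <- 1 - 0.4 * exp(-0.8)
  rates <- vapply(1:20, function(s) {
    recs <- generate_interactome(small_cfg(seed = s))
    nrow(filter_interactions(recs)) / nrow(recs)
  }, numeric(1))
  expect_lt(abs(mean(rates) - expected_pass), 0.03)
})

test_that("full interface reuse forces single-interface targets", {
  cfg <- small_cfg(seed = 4L, iface_reuse_prob = 1)
  recs <- generate_interactome(cfg)
  ann <- generate_annotations(cfg, recs)
  snet <- build_structural_network(filter_interactions(recs), ann$iface)
  targets <- igraph::V(snet)$name
  sh <- vapply(targets, target_interface_sharing, numeric(1),
               net = snet, iface = ann$iface)
  expect_true(all(sh[!is.na(sh)] == 1))
})

test_that("mean sharing increases with the interface reuse probability", {
  mean_share <- function(rp) {
    mean(vapply(1:3, function(s) {
      cfg <- small_cfg(seed = s, iface_reuse_prob = rp)
      recs <- generate_interactome(cfg)
      ann <- generate_annotations(cfg, recs)
      snet <- build_structural_network(filter_interactions(recs),
                                       ann$iface)
      sh <- vapply(igraph::V(snet)$name, target_interface_sharing,
                   numeric(1), net = snet, iface = ann$iface)
      mean(sh, na.rm = TRUE)
    }, numeric(1)))
  }
  ms <- vapply(c(0.1, 0.5, 0.9), mean_share, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("generated counts obey the NB mean-variance identity", {
  # all effects off: counts are i.i.d. NB(mu = exp(intercept), theta)
  cfg <- generator_config(
    seed = 8L, n_proteins = 300L, n_drugs = 996L, n_diseases = 20L,
    true_beta = list(essential = 0, degree = 0, bottleneck = 0,
                     iface_share = 0, far = 0))
  st <- simulate_study(cfg)
  y <- st$drugs$side_effect_count
  mu <- exp(cfg$true_beta$intercept)
  expected_ratio <- 1 + mu / cfg$theta
  expect_lt(abs(stats::var(y) / mean(y) - expected_ratio),
            0.25 * expected_ratio)
})

test_that("near-module forcing controls the realized class structure", {
  st1 <- simulate_study(small_cfg(seed = 9L, p_near_module = 1))
  net <- build_network(filter_interactions(st1$interactions))
  dt <- distance_table(st1$drugs, st1$disease_map, net)
  fin <- !is.na(dt$dist_indicated)
  single <- lengths(st1$drugs$targets) == 1L
  # single-target drugs are guaranteed near by construction
  expect_true(all(dt$dist_indicated[fin & single] < 3))

  st0 <- simulate_study(small_cfg(seed = 9L, p_near_module = 0))
  dt0 <- distance_table(st0$drugs, st0$disease_map, net)
  near0 <- sum(dt0$dist_indicated < 3, na.rm = TRUE)
  near1 <- sum(dt$dist_indicated < 3, na.rm = TRUE)
  expect_lt(near0, near1)
  expect_lt(near0 / sum(!is.na(dt0$dist_indicated)), 0.2)
})

test_that("indicated and other distance distributions overlap broadly", {
  st <- simulate_study(small_cfg(seed = 10L))
  net <- build_network(filter_interactions(st$interactions))
  dt <- distance_table(st$drugs, st$disease_map, net)
  expect_gt(overlap_coefficient(dt$dist_indicated, dt$dist_other), 0.5)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(p_essential = 1.2), "probabilities")
  expect_error(generator_config(theta = -1), "theta")
  expect_error(generator_config(
    group_proportions = c(nutraceutical = 0.5, approved = 0.1,
                          withdrawn = 0.1, unknown = 0.1)), "sum to 1")
})
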