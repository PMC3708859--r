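# Pipeline orchestration: runs the full analysis battery on one study
# (ingested or synthetic) under a single configuration and seed, and
# returns a structured, JSON-serializable report.

#' Pipeline configuration
#'
#' Defaults match the study settings the analyses are designed around:
#' bottlenecks at the top 20% of betweenness with a sensitivity sweep over
#' 5/10/20/40%, median binning with a minimum level size of 5, a
#' target-to-disease-gene distance cutoff of 3, bootstrap resamples of size
#' 10 repeated 1000 times, and 100 randomization trials per null model.
#'
#' @param bottleneck_fraction top-betweenness fraction defining bottlenecks.
#' @param bottleneck_sweep fractions for the bottleneck-cutoff sensitivity
#'   sweep.
#' @param min_bin_size margin-merge threshold for median binning.
#' @param weight_levels weight binned levels by drug count in the
#'   regressions (see [fit_count_glm()]).
#' @param family `"auto"` (negative binomial when the raw data are
#'   overdispersed, Poisson otherwise), `"negative_binomial"`, or
#'   `"poisson"`.
#' @param distance_cutoff near/far class cutoff on average distance.
#' @param bootstrap_m,bootstrap_reps bootstrap resample size and count.
#' @param null_trials randomization trials per null model (0 disables the
#'   null analyses).
#' @param strata `"all"`, `"cancer"`, or `"non_cancer"`.
#' @param seed master integer seed (fans out to per-stage substreams).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bottleneck_fraction = 0.20,
                            bottleneck_sweep = c(0.05, 0.10, 0.20, 0.40),
                            min_bin_size = 5L,
                            weight_levels = TRUE,
                            family = c("auto", "negative_binomial",
                                       "poisson"),
                            distance_cutoff = 3,
                            bootstrap_m = 10L,
                            bootstrap_reps = 1000L,
                            null_trials = 100L,
                            strata = c("all", "cancer", "non_cancer"),
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$family <- match.arg(family)
  cfg$strata <- match.arg(strata)
  class(cfg) <- "pipeline_config"
  cfg
}

# Count essential targets per drug; errors on unannotated targets.
count_essential <- function(drugs, annotations) {
  unk <- setdiff(unique(unlist(drugs$targets, use.names = FALSE)),
                 names(annotations))
  if (length(unk))
    stop(sprintf("unannotated target protein(s): %s",
                 paste(utils::head(unk, 5L), collapse = ", ")),
         call. = FALSE)
  vapply(drugs$targets, function(ts) sum(annotations[ts]), numeric(1))
}

# Fit one regression analysis with automatic family selection; returns a
# JSON-friendly summary (or NULL, with a message, when unfittable).
fit_analysis <- function(x, y, cfg, covariate) {
  res <- tryCatch({
    family <- cfg$family
    dispersion <- NA_real_
    if (family == "auto") {
      od <- overdispersion_check(x, y)
      dispersion <- od$dispersion_stat
      family <- if (od$poisson_ok) "poisson" else "negative_binomial"
    }
    fit <- fit_count_glm(x, y, family = family, binning = TRUE,
                         min_bin_size = cfg$min_bin_size,
                         weight_levels = cfg$weight_levels)
    list(covariate = covariate, family = fit$family,
         n_drugs = length(y), n_obs_fitted = fit$n_obs_fitted,
         beta = fit$beta, se = fit$se_beta, p = fit$wald_p,
         theta = if (is.null(fit$theta)) NA_real_ else fit$theta,
         dispersion_stat = dispersion,
         converged = fit$converged,
         binned_points = fit$points)
  }, error = function(e) {
    message(sprintf("regression '%s' skipped: %s", covariate,
                    conditionMessage(e)))
    NULL
  })
  res
}

group_comparison <- function(drugs, value, g1, g2) {
  a <- value[drugs$group == g1]
  b <- value[drugs$group == g2]
  if (!length(a) || !length(b)) return(NULL)
  list(groups = paste(g1, "vs", g2), n = c(length(a), length(b)),
       median = c(stats::median(a), stats::median(b)),
       p = wilcoxon_rank_sum(a, b))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: interaction-quality filtering, network construction
#' and centrality, the drug-group and fatal/non-fatal Wilcoxon comparisons,
#' the count regressions (total targets, essential targets, targets among
#' drugs with no essential target, target degree on the
#' single-non-essential-target subset, bottleneck-target count with the
#' cutoff sweep, interface sharing), the approval-year trend, the
#' target-to-disease distance classification with the bootstrap median
#' comparison, and the three randomization nulls — all under the chosen
#' stratum and a single master seed.
#'
#' @param study list with `drugs` (`drug_table`), `interactions`
#'   (`interaction_table`), `annotations` (named logical), `iface`
#'   (`interface_map`), `disease_map` (named list); as returned by
#'   [simulate_study()] or [load_study()].
#' @param cfg a [pipeline_config()].
#' @return nested report list of class `sidefx_report`; every statistic
#'   carries the number of observations it was computed on.
#' @export
run_pipeline <- function(study, cfg = pipeline_config()) {
  drugs <- study$drugs
  if (cfg$strata == "cancer") drugs <- drugs[drugs$is_cancer_drug, ]
  if (cfg$strata == "non_cancer") drugs <- drugs[!drugs$is_cancer_drug, ]
  if (nrow(drugs) == 0L)
    stop(sprintf("empty stratum '%s': no drugs to analyze", cfg$strata),
         call. = FALSE)
  rownames(drugs) <- NULL

  filtered <- filter_interactions(study$interactions)
  net <- build_network(filtered)
  cent <- centrality_table(net, cfg$bottleneck_fraction)
  snet <- build_structural_network(filtered, study$iface)

  n_targets <- lengths(drugs$targets)
  with_t <- drugs[n_targets > 0L, ]
  rownames(with_t) <- NULL
  n_ess <- count_essential(with_t, study$annotations)
  counts <- drugs$side_effect_count

  report <- list(meta = list(
    stratum = cfg$strata, seed = cfg$seed,
    n_drugs = nrow(drugs), n_drugs_with_targets = nrow(with_t),
    n_drugs_no_targets = nrow(drugs) - nrow(with_t),
    network = list(n_proteins = igraph::vcount(net),
                   n_interactions = igraph::ecount(net),
                   n_records_input = nrow(study$interactions),
                   n_records_dropped = nrow(study$interactions) -
                     nrow(filtered)),
    structural_network = list(n_proteins = igraph::vcount(snet),
                              n_interactions = igraph::ecount(snet))))

  # (a) group comparisons of side-effect and target counts
  report$group_comparisons <- list(
    side_effects = list(
      nutraceutical_vs_approved = group_comparison(
        drugs, counts, "nutraceutical", "approved"),
      withdrawn_vs_approved = group_comparison(
        drugs, counts, "withdrawn", "approved")),
    n_targets = list(
      nutraceutical_vs_approved = group_comparison(
        drugs, n_targets, "nutraceutical", "approved"),
      withdrawn_vs_approved = group_comparison(
        drugs, n_targets, "withdrawn", "approved")))

  # (b) fatal vs non-fatal side-effect burden
  fa <- counts[drugs$has_fatal_effect]
  nf <- counts[!drugs$has_fatal_effect]
  report$fatal_comparison <- if (length(fa) && length(nf)) list(
    n = c(fatal = length(fa), non_fatal = length(nf)),
    median = c(fatal = stats::median(fa), non_fatal = stats::median(nf)),
    p = wilcoxon_rank_sum(fa, nf)) else NULL

  # (c) target-count regressions
  y_t <- with_t$side_effect_count
  report$regressions <- list(
    total_targets = fit_analysis(lengths(with_t$targets), y_t, cfg,
                                 "number of targets"),
    essential_targets = fit_analysis(n_ess, y_t, cfg,
                                     "number of essential targets"),
    targets_no_essential = fit_analysis(
      lengths(with_t$targets)[n_ess == 0], y_t[n_ess == 0], cfg,
      "number of targets (drugs with no essential target)"))

  # (d) degree on the single-non-essential-target subset; bottleneck-count
  # sweep on all drugs with targets
  single <- select_single_nonessential_target_drugs(with_t,
                                                    study$annotations)
  deg <- stats::setNames(cent$degree, cent$protein)
  sd_deg <- vapply(single$targets, function(ts)
    if (ts %in% names(deg)) deg[[ts]] else NA_real_, numeric(1))
  ok <- !is.na(sd_deg)
  zd <- (log(sd_deg[ok]) - mean(log(sd_deg[ok]))) /
    stats::sd(log(sd_deg[ok]))
  report$regressions$target_degree <- fit_analysis(
    zd, single$side_effect_count[ok], cfg,
    "target degree (log z-score, single non-essential target drugs)")

  btw <- stats::setNames(cent$betweenness, cent$protein)
  sweep <- sort(unique(c(cfg$bottleneck_fraction, cfg$bottleneck_sweep)))
  report$regressions$bottleneck_sweep <- lapply(sweep, function(f) {
    bn <- classify_bottlenecks(btw, f)
    n_btl <- vapply(with_t$targets, function(ts)
      sum(ts %in% bn), numeric(1))
    c(list(fraction = f),
      fit_analysis(n_btl, y_t, cfg,
                   sprintf("number of bottleneck targets (top %g%%)",
                           100 * f)))
  })
  names(report$regressions$bottleneck_sweep) <-
    sprintf("top_%g_pct", 100 * sweep)

  # (e) interface-sharing regression on the single-target subset
  share <- vapply(single$targets, function(ts)
    target_interface_sharing(ts, snet, study$iface), numeric(1))
  oks <- !is.na(share)
  report$regressions$interface_sharing <- fit_analysis(
    share[oks], single$side_effect_count[oks], cfg,
    "proportion of shared interaction interfaces")
  report$exclusions <- list(
    single_target_subset = nrow(single),
    single_target_without_sharing_score = sum(!oks))

  # (g) approval-year trend among approved drugs
  appr <- drugs[drugs$group == "approved" & !is.na(drugs$approval_year), ]
  report$regressions$approval_year <- fit_analysis(
    appr$approval_year, appr$side_effect_count, cfg, "approval year")

  # (f) distance classification and bootstrap
  dt <- distance_table(with_t, study$disease_map, net)
  cls <- classify_by_cutoff(
    stats::setNames(dt$dist_indicated, dt$drug_id), cfg$distance_cutoff)
  count_of <- stats::setNames(drugs$side_effect_count, drugs$drug_id)
  report$distance <- list(
    cutoff = cfg$distance_cutoff,
    n_defined = sum(!is.na(dt$dist_indicated)),
    n_undefined = sum(is.na(dt$dist_indicated)),
    mean_dist_indicated = mean(dt$dist_indicated, na.rm = TRUE),
    mean_dist_other = mean(dt$dist_other, na.rm = TRUE),
    overlap_coefficient = overlap_coefficient(dt$dist_indicated,
                                              dt$dist_other),
    n_near = length(cls$near), n_far = length(cls$far),
    table = dt)
  if (length(cls$near) && length(cls$far)) {
    boot <- bootstrap_median_compare(
      count_of[cls$near], count_of[cls$far],
      m = cfg$bootstrap_m, reps = cfg$bootstrap_reps,
      seed = substream_seed(cfg$seed, "pipeline_bootstrap"))
    report$distance$median_near <- stats::median(count_of[cls$near])
    report$distance$median_far <- stats::median(count_of[cls$far])
    report$distance$bootstrap <- list(
      m = boot$m, reps = boot$reps, p = boot$wilcoxon_p,
      median_of_medians = c(near = stats::median(boot$medians_a),
                            far = stats::median(boot$medians_b)))
  }

  # (h) randomization nulls of the distance-class median gap
  if (cfg$null_trials > 0L && length(cls$near) && length(cls$far)) {
    observed_gap <- report$distance$median_far -
      report$distance$median_near
    gap_analysis <- function(inputs) {
      d2 <- distance_table(inputs$drugs, inputs$disease_map, inputs$net)
      c2 <- classify_by_cutoff(
        stats::setNames(d2$dist_indicated, d2$drug_id),
        cfg$distance_cutoff)
      if (!length(c2$near) || !length(c2$far)) stop("empty class")
      stats::median(count_of[c2$far]) - stats::median(count_of[c2$near])
    }
    inputs <- list(net = net, drugs = with_t,
                   disease_map = study$disease_map)
    report$null_models <- list(observed_gap = observed_gap)
    for (nm in c("edge_swap", "target_shuffle", "disease_shuffle")) {
      rep_nm <- run_null_trials(gap_analysis, nm, inputs,
                                n_trials = cfg$null_trials,
                                seed = substream_seed(cfg$seed,
                                                      "pipeline_nulls"))
      report$null_models[[nm]] <- list(
        n_trials = rep_nm$n_trials, n_skipped = rep_nm$n_skipped,
        mean_gap = rep_nm$mean, standard_error = rep_nm$standard_error)
    }
  }

  class(report) <- c("sidefx_report", "list")
  report
}

#' Write a pipeline report to disk
#'
#' Writes the report as JSON plus per-regression binned-point TSVs and the
#' per-drug distance table TSV.
#'
#' @param report a `sidefx_report`.
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$regressions)) {
    r <- report$regressions[[nm]]
    if (nm == "bottleneck_sweep") next
    if (!is.null(r$binned_points))
      write_tsv_strict(r$binned_points,
                       file.path(dir, sprintf("binned_%s.tsv", nm)))
  }
  if (!is.null(report$distance$table))
    write_tsv_strict(report$distance$table,
                     file.path(dir, "distance_table.tsv"))
  json <- report
  json$distance$table <- NULL
  for (nm in names(json$regressions))
    if (nm != "bottleneck_sweep") json$regressions[[nm]]$binned_points <- NULL
  for (nm in names(json$regressions$bottleneck_sweep))
    json$regressions$bottleneck_sweep[[nm]]$binned_points <- NULL
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(json), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
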