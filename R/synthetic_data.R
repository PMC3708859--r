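# Synthetic study generator: emulates the six input tables (drugs with
# side-effect counts, drug-target map, target essentiality, interaction
# evidence, interaction interfaces, disease-gene associations) with known
# ground-truth effect sizes, so every stage and the end-to-end pipeline can
# be validated without database downloads.

#' Generator configuration
#'
#' Defaults define the simulated study conditions: a 3,000-protein
#' preferential-attachment interactome, 996 drugs, and injected effect
#' sizes on the log scale equal to the headline regression coefficients the
#' pipeline is designed to estimate (essential-target count 0.17, target
#' degree 0.31 per SD, bottleneck-target count 0.21, interface sharing 1.5),
#' negative binomial counts with shape `theta = 2`, and a far-from-disease
#' class excess of 0.8.
#'
#' @param seed master integer seed.
#' @param n_proteins number of proteins in the interactome.
#' @param attachment_edges_per_node preferential-attachment edges per node.
#' @param p_essential probability a protein is essential.
#' @param n_drugs number of drugs.
#' @param p_no_target fraction of drugs with no mapped protein target.
#' @param target_geom_p success parameter of the truncated geometric target
#'   count (p = 0.5 gives mean ~2).
#' @param max_targets truncation point of the target count.
#' @param true_beta named list of injected effects on the linear predictor:
#'   `intercept`, `essential`, `degree` (per SD of mean target degree),
#'   `bottleneck`, `iface_share`, `far` (far-class excess).
#' @param theta negative binomial shape of the side-effect counts.
#' @param n_domains_max per-protein interacting-domain count is uniform on
#'   1..`n_domains_max`.
#' @param iface_reuse_prob probability an interaction reuses the target's
#'   first domain; tunes the interface-sharing continuum.
#' @param p_iface_annotated probability a binary edge carries interface
#'   annotations (unannotated edges exercise the structural-network drop
#'   rule).
#' @param n_diseases number of background diseases.
#' @param disease_size_range integer range of disease gene-set sizes.
#' @param p_near_module probability a drug's indicated disease is seeded
#'   within network distance < 3 of its targets.
#' @param group_proportions named proportions for
#'   nutraceutical/approved/withdrawn/unknown.
#' @param p_fatal_intercept,p_fatal_slope logistic model of the fatal-effect
#'   flag in the side-effect count.
#' @param p_cancer probability a drug is a cancer drug.
#' @param bottleneck_fraction top-betweenness fraction used when computing
#'   the bottleneck covariate at generation time.
#' @param ht_quality_prob,pub_lambda,p_binary evidence-flag distributions:
#'   `ht_quality ~ Bernoulli(ht_quality_prob)`,
#'   `publication_count ~ 1 + Poisson(pub_lambda)`,
#'   `is_binary ~ Bernoulli(p_binary)`.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_proteins = 3000L,
                             attachment_edges_per_node = 3L,
                             p_essential = 0.15,
                             n_drugs = 996L,
                             p_no_target = 0.35,
                             target_geom_p = 0.5,
                             max_targets = 20L,
                             true_beta = list(intercept = log(40),
                                              essential = 0.17,
                                              degree = 0.31,
                                              bottleneck = 0.21,
                                              iface_share = 1.5,
                                              far = 0.8),
                             theta = 2,
                             n_domains_max = 4L,
                             iface_reuse_prob = 0.5,
                             p_iface_annotated = 0.9,
                             n_diseases = 150L,
                             disease_size_range = c(5L, 25L),
                             p_near_module = 0.05,
                             group_proportions = c(nutraceutical = 0.08,
                                                   approved = 0.78,
                                                   withdrawn = 0.04,
                                                   unknown = 0.10),
                             p_fatal_intercept = -3,
                             p_fatal_slope = 0.02,
                             p_cancer = 0.15,
                             bottleneck_fraction = 0.20,
                             ht_quality_prob = 0.6,
                             pub_lambda = 0.8,
                             p_binary = 0.5) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_essential, cfg$p_no_target, cfg$target_geom_p,
             cfg$iface_reuse_prob, cfg$p_iface_annotated,
             cfg$p_near_module, cfg$p_cancer, cfg$ht_quality_prob,
             cfg$p_binary, unname(cfg$group_proportions))
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$group_proportions) - 1) > 1e-8)
    stop("group_proportions must sum to 1", call. = FALSE)
  if (cfg$theta <= 0) stop("theta must be positive", call. = FALSE)
  defaults <- eval(formals(generator_config)$true_beta)
  cfg$true_beta <- utils::modifyList(defaults, cfg$true_beta)
  class(cfg) <- "generator_config"
  cfg
}

#' Generate interaction-evidence records
#'
#' Draws a preferential-attachment (heavy-tailed degree) protein network
#' and annotates each edge with evidence flags so that a realistic minority
#' of records fails the quality filter.
#'
#' @param cfg a `generator_config`.
#' @return an `interaction_table` (canonicalized).
#' @export
generate_interactome <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "interactome"), {
    g <- igraph::sample_pa(cfg$n_proteins, m = cfg$attachment_edges_per_node,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("P%04d", seq_len(cfg$n_proteins))
    el <- igraph::as_edgelist(g)
    n_e <- nrow(el)
    canonicalize_interactions(data.frame(
      protein_a = el[, 1L], protein_b = el[, 2L],
      ht_quality = stats::runif(n_e) < cfg$ht_quality_prob,
      publication_count = 1L + stats::rpois(n_e, cfg$pub_lambda),
      is_binary = stats::runif(n_e) < cfg$p_binary,
      stringsAsFactors = FALSE))
  })
}

#' Generate essentiality annotations and interface assignments
#'
#' Essential flags are i.i.d. Bernoulli. Each protein carries 1..k
#' interacting domains; each of its binary, quality-passing interactions
#' uses the first domain with probability `iface_reuse_prob` and a domain
#' drawn uniformly from all k otherwise, so the expected interface-sharing
#' score increases monotonically in `iface_reuse_prob`. A fraction of
#' binary edges is left unannotated.
#'
#' @param cfg a `generator_config`.
#' @param records an `interaction_table`.
#' @return list with `annotations` (named logical vector) and `iface`
#'   (an `interface_map`).
#' @export
generate_annotations <- function(cfg, records) {
  proteins <- sort(unique(c(records$protein_a, records$protein_b)))
  with_seed(substream_seed(cfg$seed, "annotations"), {
    ess <- stats::setNames(stats::runif(length(proteins)) < cfg$p_essential,
                           proteins)
    k <- stats::setNames(sample.int(cfg$n_domains_max, length(proteins),
                                    replace = TRUE), proteins)
    filt <- filter_interactions(records)
    bin <- filt[filt$is_binary, , drop = FALSE]
    annotate <- stats::runif(nrow(bin)) < cfg$p_iface_annotated
    bin <- bin[annotate, , drop = FALSE]
    # with prob reuse the interaction uses the first domain; otherwise a
    # uniform draw over all k domains, so the expected sharing score is
    # monotone in iface_reuse_prob
    pick_domains <- function(p) {
      kk <- k[p]
      reuse <- stats::runif(length(p)) < cfg$iface_reuse_prob
      idx <- ifelse(kk == 1L | reuse, 1L,
                    1L + floor(stats::runif(length(p)) * kk))
      paste0(p, "_d", idx)
    }
    iface_df <- data.frame(
      target = c(bin$protein_a, bin$protein_b),
      partner = c(bin$protein_b, bin$protein_a),
      domains = c(pick_domains(bin$protein_a), pick_domains(bin$protein_b)),
      stringsAsFactors = FALSE)
    list(annotations = ess, iface = interface_map(iface_df))
  })
}

# Truncated geometric target count on 1..max (mean ~ 1/p for small p).
rtrunc_geom <- function(n, p, max) {
  probs <- p * (1 - p)^(0:(max - 1L))
  sample.int(max, n, replace = TRUE, prob = probs / sum(probs))
}

#' Generate drugs with side-effect counts
#'
#' Samples each drug's target set, computes its covariates (essential
#' target count, standardized mean target degree, bottleneck target count,
#' interface-sharing score, latent near-disease flag), and draws the
#' side-effect count from a negative binomial whose log mean is the linear
#' predictor with the configured effects. Fatal flags follow a logistic
#' model in the count; withdrawn drugs are sampled from the upper count
#' quantiles and nutraceuticals from the lower ones; approval years are a
#' noisy increasing function of the count (recently approved drugs carry
#' more recorded side effects).
#'
#' @param cfg a `generator_config`.
#' @param records an `interaction_table` (pre-filter).
#' @param annotations named logical essentiality vector.
#' @param iface an `interface_map`.
#' @param centrality a [centrality_table()] of the filtered network.
#' @return a `drug_table`; attribute `"truth"` holds the per-drug
#'   ground-truth covariates and near flags.
#' @export
generate_drugs_and_side_effects <- function(cfg, records, annotations,
                                            iface, centrality) {
  filt <- filter_interactions(records)
  snet <- build_structural_network(filt, iface)
  proteins <- centrality$protein
  deg <- stats::setNames(centrality$degree, proteins)
  btl <- stats::setNames(centrality$is_bottleneck, proteins)

  with_seed(substream_seed(cfg$seed, "drugs"), {
    n <- cfg$n_drugs
    has_t <- stats::runif(n) >= cfg$p_no_target
    k <- ifelse(has_t, rtrunc_geom(n, cfg$target_geom_p, cfg$max_targets), 0L)
    targets <- lapply(seq_len(n), function(i)
      if (k[i] == 0L) character(0) else sample(proteins, k[i]))

    share_cache <- new.env(parent = emptyenv())
    share_of <- function(p) {
      if (is.null(share_cache[[p]]))
        share_cache[[p]] <- target_interface_sharing(p, snet, iface)
      share_cache[[p]]
    }

    n_ess <- vapply(targets, function(ts) sum(annotations[ts]), numeric(1))
    # mean log degree: degrees are heavy-tailed, so standardizing the log
    # keeps hub multipliers bounded and counts in the tens-to-hundreds
    deg_mean <- vapply(targets, function(ts)
      if (length(ts)) mean(log(deg[ts])) else NA_real_, numeric(1))
    z_deg <- (deg_mean - mean(deg_mean, na.rm = TRUE)) /
      stats::sd(deg_mean, na.rm = TRUE)
    z_deg[is.na(z_deg)] <- 0
    n_btl <- vapply(targets, function(ts) sum(btl[ts]), numeric(1))
    share <- vapply(targets, function(ts) {
      if (!length(ts)) return(NA_real_)
      s <- vapply(ts, share_of, numeric(1))
      if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    }, numeric(1))
    share_c <- share - mean(share, na.rm = TRUE)
    share_c[is.na(share_c)] <- 0

    near <- has_t & stats::runif(n) < cfg$p_near_module

    b <- cfg$true_beta
    eta <- b$intercept + b$essential * n_ess + b$degree * z_deg +
      b$bottleneck * n_btl + b$iface_share * share_c + b$far * (!near)
    eta <- pmin(pmax(eta, -10), 12)
    y <- stats::rnbinom(n, size = cfg$theta, mu = exp(eta))

    fatal <- stats::runif(n) <
      stats::plogis(cfg$p_fatal_intercept + cfg$p_fatal_slope * y)

    # group assignment: withdrawn from the top count tercile,
    # nutraceuticals from the bottom one
    gp <- cfg$group_proportions
    n_w <- round(gp[["withdrawn"]] * n)
    n_nu <- round(gp[["nutraceutical"]] * n)
    n_un <- round(gp[["unknown"]] * n)
    ord <- order(y + stats::runif(n))   # random tie-break, count-ordered
    group <- rep("approved", n)
    top <- ord[seq.int(n - floor(n / 3) + 1L, n)]
    bottom <- ord[seq_len(floor(n / 3))]
    group[sample(top, min(n_w, length(top)))] <- "withdrawn"
    nb_pool <- setdiff(bottom, which(group != "approved"))
    group[sample(nb_pool, min(n_nu, length(nb_pool)))] <- "nutraceutical"
    un_pool <- which(group == "approved")
    group[sample(un_pool, min(n_un, length(un_pool)))] <- "unknown"

    r <- rank(log1p(y) + stats::rnorm(n), ties.method = "first")
    year <- 1950L + as.integer(round(61 * (r - 1) / (n - 1)))
    year[!group %in% c("approved", "withdrawn")] <- NA_integer_

    drugs <- data.frame(drug_id = sprintf("D%04d", seq_len(n)),
                        side_effect_count = as.integer(y),
                        stringsAsFactors = FALSE)
    drugs$group <- factor(group, levels = c("nutraceutical", "approved",
                                            "withdrawn", "unknown"))
    drugs$has_fatal_effect <- fatal
    drugs$approval_year <- year
    drugs$targets <- targets
    drugs$indicated_diseases <- rep(list(character(0)), n)
    drugs$is_cancer_drug <- stats::runif(n) < cfg$p_cancer
    class(drugs) <- c("drug_table", "data.frame")
    attr(drugs, "truth") <- data.frame(
      drug_id = drugs$drug_id, n_targets = k, n_essential = n_ess,
      z_degree = z_deg, n_bottleneck = n_btl, iface_share = share,
      near = near, stringsAsFactors = FALSE)
    drugs
  })
}

#' Generate the disease-gene map and indicated-disease assignments
#'
#' Background diseases are connected network neighbourhoods (breadth-first
#' gene sets around a random seed protein). For each drug carrying the
#' latent near flag, a dedicated indicated disease is seeded inside the
#' 2-neighbourhood of one of its targets (with shrinking fallbacks), so the
#' drug's average target-to-indicated-gene distance falls below 3; other
#' drugs receive randomly chosen background diseases, re-drawn (up to 10
#' attempts) when the draw accidentally lands within distance 3 of the
#' targets, so the realized near/far classes follow the latent flags.
#' Drugs whose targets are so central that every disease is nearby keep
#' their last draw and constitute genuine residual near-class members.
#'
#' @param cfg a `generator_config`.
#' @param records an `interaction_table` (pre-filter).
#' @param drugs the `drug_table` from [generate_drugs_and_side_effects()]
#'   (its `"truth"` attribute carries the near flags).
#' @return list with `disease_map` (named list) and `drugs` (indicated
#'   diseases filled in).
#' @export
generate_disease_map <- function(cfg, records, drugs) {
  net <- build_network(filter_interactions(records))
  nn <- igraph::V(net)$name
  truth <- attr(drugs, "truth")
  with_seed(substream_seed(cfg$seed, "diseases"), {
    sizes <- sample(seq.int(cfg$disease_size_range[1L],
                            cfg$disease_size_range[2L]),
                    cfg$n_diseases, replace = TRUE)
    dmap <- list()
    for (j in seq_len(cfg$n_diseases)) {
      seed_p <- sample(nn, 1L)
      d <- igraph::distances(net, v = seed_p)[1L, ]
      ord <- order(d, names(d))
      dmap[[sprintf("DIS%03d", j)]] <- nn[ord[seq_len(min(sizes[j],
                                                          sum(is.finite(d))))]]
    }
    # one batch shortest-path matrix: all drug targets x background genes
    bg_ids <- names(dmap)
    all_targets <- intersect(unique(unlist(drugs$targets,
                                           use.names = FALSE)), nn)
    bg_genes <- unique(unlist(dmap, use.names = FALSE))
    D <- if (length(all_targets))
      igraph::distances(net, v = all_targets, to = bg_genes)
    else matrix(numeric(0), 0L, 0L)
    avg_bg_dist <- function(ts, dis) {
      v <- D[ts, unique(unlist(dmap[dis], use.names = FALSE)),
             drop = FALSE]
      v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else mean(v)
    }
    for (i in seq_len(nrow(drugs))) {
      ts <- intersect(drugs$targets[[i]], nn)
      if (!length(ts)) next
      if (isTRUE(truth$near[i])) {
        t_star <- if (length(ts) == 1L) ts else sample(ts, 1L)
        d <- igraph::distances(net, v = t_star)[1L, ]
        near_nodes <- nn[order(d, names(d))]
        near_nodes <- near_nodes[d[near_nodes] <= 2]
        s <- sample(seq.int(cfg$disease_size_range[1L],
                            cfg$disease_size_range[2L]), 1L)
        genes <- near_nodes[seq_len(min(s, length(near_nodes)))]
        if (avg_set_distance(net, ts, genes) >= 3)
          genes <- near_nodes[d[near_nodes] <= 1]
        if (avg_set_distance(net, ts, genes) >= 3)
          genes <- t_star
        id <- sprintf("DNEAR_%s", drugs$drug_id[i])
        dmap[[id]] <- genes
        drugs$indicated_diseases[[i]] <- id
      } else {
        n_ind <- 1L + stats::rbinom(1L, 1L, 0.3)
        for (try in seq_len(10L)) {
          dis <- sample(bg_ids, n_ind)
          dd <- avg_bg_dist(ts, dis)
          if (is.na(dd) || dd >= 3) break
        }
        drugs$indicated_diseases[[i]] <- dis
      }
    }
    list(disease_map = dmap, drugs = drugs)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator (interactome, annotations and interfaces,
#' centrality, drugs with side-effect counts, disease map) and optionally
#' writes the six input TSVs plus a ground-truth JSON to a directory.
#'
#' @param cfg a `generator_config`.
#' @param dir optional output directory (created if needed).
#' @return list of class `synthetic_study` with `drugs`, `interactions`,
#'   `annotations`, `iface`, `disease_map`, `centrality`, `truth`, `cfg`,
#'   and (if written) `paths`.
#' @export
simulate_study <- function(cfg = generator_config(), dir = NULL) {
  records <- generate_interactome(cfg)
  ann <- generate_annotations(cfg, records)
  net <- build_network(filter_interactions(records))
  cent <- centrality_table(net, cfg$bottleneck_fraction)
  drugs <- generate_drugs_and_side_effects(cfg, records, ann$annotations,
                                           ann$iface, cent)
  dm <- generate_disease_map(cfg, records, drugs)
  study <- list(drugs = dm$drugs, interactions = records,
                annotations = ann$annotations, iface = ann$iface,
                disease_map = dm$disease_map, centrality = cent,
                truth = attr(drugs, "truth"), cfg = cfg)
  class(study) <- "synthetic_study"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    study$paths <- write_study_tables(study, dir)
  }
  study
}

# Write the six study TSVs plus ground truth JSON; returns the paths.
write_study_tables <- function(study, dir) {
  drugs <- study$drugs
  drug_df <- data.frame(
    drug_id = drugs$drug_id,
    group = as.character(drugs$group),
    side_effect_count = drugs$side_effect_count,
    fatal = drugs$has_fatal_effect,
    approval_year = drugs$approval_year,
    targets = vapply(drugs$targets, join_list_cell, character(1)),
    diseases = vapply(drugs$indicated_diseases, join_list_cell, character(1)),
    cancer = drugs$is_cancer_drug,
    stringsAsFactors = FALSE)
  tmap <- data.frame(
    drug_id = rep(drugs$drug_id, lengths(drugs$targets)),
    target = unlist(drugs$targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  ann_df <- data.frame(protein_id = names(study$annotations),
                       is_essential = unname(study$annotations),
                       stringsAsFactors = FALSE)
  keys <- do.call(rbind, strsplit(names(study$iface), "\t", fixed = TRUE))
  iface_df <- data.frame(
    target = keys[, 1L], partner = keys[, 2L],
    domains = vapply(study$iface, join_list_cell, character(1),
                     USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  dis_df <- data.frame(
    disease_id = names(study$disease_map),
    genes = vapply(study$disease_map, join_list_cell, character(1),
                   USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  paths <- list(
    drugs = write_tsv_strict(drug_df, file.path(dir, "drugs.tsv")),
    drug_targets = write_tsv_strict(tmap, file.path(dir, "drug_targets.tsv")),
    target_annotations = write_tsv_strict(
      ann_df, file.path(dir, "target_annotations.tsv")),
    interactions = write_tsv_strict(
      study$interactions, file.path(dir, "interactions.tsv")),
    interfaces = write_tsv_strict(iface_df, file.path(dir, "interfaces.tsv")),
    disease_genes = write_tsv_strict(dis_df,
                                     file.path(dir, "disease_genes.tsv")))
  truth <- list(seed = study$cfg$seed, theta = study$cfg$theta,
                true_beta = study$cfg$true_beta,
                near_drugs = study$truth$drug_id[study$truth$near])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  paths
}

#' Load a study from a directory of TSVs
#'
#' Reads the tables written by [simulate_study()] (or equivalently
#' formatted real data) back into the in-memory study representation
#' consumed by [run_pipeline()].
#'
#' @param dir directory containing `drugs.tsv`, `target_annotations.tsv`,
#'   `interactions.tsv`, `interfaces.tsv`, `disease_genes.tsv`.
#' @return list with `drugs`, `interactions`, `annotations`, `iface`,
#'   `disease_map`.
#' @export
load_study <- function(dir) {
  list(drugs = read_drug_table(file.path(dir, "drugs.tsv")),
       interactions = read_interaction_table(file.path(dir, "interactions.tsv")),
       annotations = read_target_annotations(
         file.path(dir, "target_annotations.tsv")),
       iface = read_interface_table(file.path(dir, "interfaces.tsv")),
       disease_map = read_disease_gene_table(
         file.path(dir, "disease_genes.tsv")))
}
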