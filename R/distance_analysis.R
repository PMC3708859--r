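# Target-to-disease-gene network distances, the near/far classification of
# drugs, and the bootstrap comparison of class medians.

#' Average target-to-disease-gene distance for one drug
#'
#' Average shortest distance on the interactome between a drug's targets
#' and either the genes of its indicated diseases (`which = "indicated"`)
#' or the genes of all other diseases (`which = "other"`, the set
#' difference: other-disease genes minus indicated-disease genes).
#'
#' @param drug one-row slice of a `drug_table` (or list with `targets`,
#'   `indicated_diseases`).
#' @param disease_map named list: disease id -> character vector of genes.
#' @param net interactome (igraph).
#' @param which `"indicated"` or `"other"`.
#' @return numeric distance or `NA_real_` when undefined (no targets or
#'   genes on the network, or no indicated disease).
#' @export
drug_disease_distance <- function(drug, disease_map, net,
                                  which = c("indicated", "other")) {
  which <- match.arg(which)
  targets <- if (is.data.frame(drug)) drug$targets[[1L]] else drug$targets
  ind <- if (is.data.frame(drug)) drug$indicated_diseases[[1L]] else
    drug$indicated_diseases
  ind <- intersect(ind, names(disease_map))
  ind_genes <- unique(unlist(disease_map[ind], use.names = FALSE))
  genes <- if (which == "indicated") {
    if (length(ind) == 0L) return(NA_real_)
    ind_genes
  } else {
    setdiff(unique(unlist(disease_map, use.names = FALSE)), ind_genes)
  }
  if (length(genes) == 0L) return(NA_real_)
  avg_set_distance(net, targets, genes)
}

#' Per-drug distance table
#'
#' Batch computation of indicated and other-disease distances for every
#' drug with at least one target on the network, using a single
#' all-targets-to-all-genes shortest-path matrix.
#'
#' @param drugs a `drug_table`.
#' @param disease_map named list: disease id -> gene vector.
#' @param net interactome (igraph).
#' @return data frame with columns `drug_id`, `n_targets_mapped`,
#'   `dist_indicated`, `dist_other`.
#' @export
distance_table <- function(drugs, disease_map, net) {
  nn <- igraph::V(net)$name
  all_genes <- intersect(unique(unlist(disease_map, use.names = FALSE)), nn)
  all_targets <- intersect(unique(unlist(drugs$targets, use.names = FALSE)), nn)
  D <- if (length(all_targets) && length(all_genes))
    igraph::distances(net, v = all_targets, to = all_genes)
  else matrix(numeric(0), 0L, 0L)

  avg_from_matrix <- function(ts, gs) {
    ts <- intersect(ts, rownames(D)); gs <- intersect(gs, colnames(D))
    if (!length(ts) || !length(gs)) return(NA_real_)
    v <- D[ts, gs, drop = FALSE]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }

  n <- nrow(drugs)
  di <- dother <- rep(NA_real_, n)
  nt <- integer(n)
  for (i in seq_len(n)) {
    ts <- intersect(drugs$targets[[i]], nn)
    nt[i] <- length(ts)
    if (!length(ts)) next
    ind <- intersect(drugs$indicated_diseases[[i]], names(disease_map))
    ind_genes <- unique(unlist(disease_map[ind], use.names = FALSE))
    if (length(ind)) di[i] <- avg_from_matrix(ts, ind_genes)
    dother[i] <- avg_from_matrix(ts, setdiff(all_genes, ind_genes))
  }
  data.frame(drug_id = drugs$drug_id, n_targets_mapped = nt,
             dist_indicated = di, dist_other = dother,
             stringsAsFactors = FALSE)
}

#' Classify drugs by a distance cutoff
#'
#' Splits drugs into a near class (distance strictly below the cutoff) and
#' a far class (distance at or above it). Drugs with undefined (`NA`)
#' distance are excluded.
#'
#' @param distances named numeric vector, drug id -> average distance.
#' @param cutoff numeric cutoff (default 3).
#' @return list with character vectors `near` and `far`.
#' @export
classify_by_cutoff <- function(distances, cutoff = 3) {
  distances <- distances[!is.na(distances)]
  list(near = names(distances)[distances < cutoff],
       far = names(distances)[distances >= cutoff])
}

#' Bootstrap comparison of class medians
#'
#' For each class independently, draws `reps` resamples of size `m` with
#' replacement and records each resample's median (even-sized resamples:
#' mean of the central pair), then compares the two median distributions
#' with a two-sided Wilcoxon rank-sum test. Designed for classes with very
#' unequal sizes and variances. The two classes use independent seed
#' substreams, so class-A draws do not depend on the size of class B.
#'
#' @param a,b numeric side-effect counts for the two classes.
#' @param m resample size (default 10).
#' @param reps number of resamples (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_result`: list with `medians_a`,
#'   `medians_b`, `wilcoxon_p`, `m`, `reps`, `seed`.
#' @export
bootstrap_median_compare <- function(a, b, m = 10L, reps = 1000L, seed = 1L) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both classes must be non-empty", call. = FALSE)
  draw <- function(x, sub) with_seed(substream_seed(seed, sub), {
    s <- matrix(sample(x, m * reps, replace = TRUE), nrow = reps)
    apply(s, 1L, stats::median)
  })
  ma <- draw(a, "bootstrap_a")
  mb <- draw(b, "bootstrap_b")
  structure(list(medians_a = ma, medians_b = mb,
                 wilcoxon_p = wilcoxon_rank_sum(ma, mb),
                 m = m, reps = reps, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap median comparison (m = %d, reps = %d, seed = %d)\n",
    x$m, x$reps, x$seed))
  cat(sprintf("  median of medians: %.3g vs %.3g; Wilcoxon p = %.3g\n",
              stats::median(x$medians_a), stats::median(x$medians_b),
              x$wilcoxon_p))
  invisible(x)
}

#' Overlap coefficient of two distance distributions
#'
#' Descriptive summary of how much the indicated-disease and other-disease
#' distance distributions overlap: the shared area of the two normalized
#' histograms on common breaks.
#'
#' @param a,b numeric samples.
#' @param n_breaks number of histogram bins.
#' @return numeric in [0, 1].
#' @export
overlap_coefficient <- function(a, b, n_breaks = 30L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(1)
  breaks <- seq(rng[1L], rng[2L], length.out = n_breaks + 1L)
  pa <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
  pb <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
  sum(pmin(pa, pb))
}
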