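# Randomization null models: degree-preserving edge swaps of the
# interactome, shuffling of drug-target associations, shuffling of
# disease-gene associations, and the trial runner that re-executes a
# downstream statistic under a null.

#' Degree-preserving edge-swap randomization
#'
#' Randomizes the interactome by repeated double-edge swaps: two distinct
#' edges are picked uniformly and their endpoints exchanged; a proposal is
#' applied only if the result stays a simple graph (no self-loops, no
#' duplicate edges). Every node's degree is preserved exactly. Invalid
#' proposals are rejected (not retried), so runtime is bounded.
#'
#' @param net interactome (igraph).
#' @param n_attempts number of swap attempts (default 10x the edge count).
#' @param seed integer seed.
#' @return randomized igraph with the same degree sequence.
#' @export
edge_swap_randomize <- function(net, n_attempts = 10L * igraph::ecount(net),
                                seed = 1L) {
  if (igraph::ecount(net) < 2L) {
    warning("graph has fewer than 2 edges; returned unchanged",
            call. = FALSE)
    return(net)
  }
  if (n_attempts == 0L) return(net)
  with_seed(substream_seed(seed, "edge_swap"),
            igraph::rewire(net, igraph::keeping_degseq(
              loops = FALSE, niter = n_attempts)))
}

# Shuffle an incidence structure: permute the pooled (entity, member)
# incidence list while preserving every entity's set size and keeping
# per-entity sets duplicate-free (collisions repaired by random swaps).
shuffle_incidence <- function(sets, seed, stream) {
  sizes <- lengths(sets)
  pool <- unlist(sets, use.names = FALSE)
  n <- length(pool)
  if (n < 2L) return(sets)
  grp <- rep(seq_along(sets), sizes)
  with_seed(substream_seed(seed, stream), {
    perm <- sample(pool, n)
    # repair duplicates within an entity by swapping with random positions
    for (pass in seq_len(200L)) {
      dup <- which(vapply(split(perm, grp), anyDuplicated, integer(1)) > 0L)
      if (!length(dup)) break
      bad <- unlist(lapply(dup, function(g) {
        ix <- which(grp == g)
        ix[duplicated(perm[ix])]
      }), use.names = FALSE)
      other <- sample.int(n, length(bad), replace = TRUE)
      tmp <- perm[bad]; perm[bad] <- perm[other]; perm[other] <- tmp
    }
    if (length(which(vapply(split(perm, grp), anyDuplicated,
                            integer(1)) > 0L)))
      warning("incidence shuffle left duplicate members after repair",
              call. = FALSE)
    out <- rep(list(pool[0L]), length(sets))
    sp <- split(perm, grp)
    out[as.integer(names(sp))] <- sp
    stats::setNames(out, names(sets))
  })
}

#' Shuffle drug-target associations
#'
#' Null model that permutes the pooled (drug, target) incidence list,
#' preserving every drug's number of targets and the total incidence count,
#' while keeping per-drug target sets duplicate-free.
#'
#' @param drugs a `drug_table`.
#' @param seed integer seed.
#' @return the `drug_table` with shuffled `targets`.
#' @export
shuffle_drug_targets <- function(drugs, seed = 1L) {
  sets <- stats::setNames(drugs$targets, drugs$drug_id)
  drugs$targets <- unname(shuffle_incidence(sets, seed, "target_shuffle"))
  drugs
}

#' Shuffle disease-gene associations
#'
#' Null model that permutes the pooled (disease, gene) incidence list,
#' preserving every disease's gene-set size.
#'
#' @param disease_map named list: disease id -> gene vector.
#' @param seed integer seed.
#' @return shuffled disease map.
#' @export
shuffle_disease_genes <- function(disease_map, seed = 1L) {
  shuffle_incidence(disease_map, seed, "disease_shuffle")
}

#' Run randomization null trials
#'
#' Re-executes a downstream analysis under repeated randomizations of one
#' input component and summarizes the per-trial statistic.
#'
#' @param analysis function taking the (possibly randomized) `inputs` list
#'   and returning one real statistic.
#' @param null_model one of `"edge_swap"`, `"target_shuffle"`,
#'   `"disease_shuffle"`.
#' @param inputs list with components `net` (igraph), `drugs`
#'   (`drug_table`), `disease_map` (named list); the component named by
#'   `null_model` is randomized each trial, the others pass through.
#' @param n_trials number of randomization trials (default 100).
#' @param seed integer seed; trial t uses an independent substream.
#' @return object of class `randomization_report`: list with `null_model`,
#'   `n_trials`, `per_trial_statistics`, `n_skipped`, `mean`,
#'   `standard_error` (sample SD / sqrt(trials); `NA` for a single trial),
#'   `seed`.
#' @export
run_null_trials <- function(analysis, null_model = c("edge_swap",
                                                     "target_shuffle",
                                                     "disease_shuffle"),
                            inputs, n_trials = 100L, seed = 1L) {
  null_model <- match.arg(null_model)
  stats_out <- rep(NA_real_, n_trials)
  for (t in seq_len(n_trials)) {
    st <- substream_seed(seed, paste0("null_", null_model, "_", t))
    rin <- inputs
    if (null_model == "edge_swap") {
      rin$net <- edge_swap_randomize(inputs$net, seed = st)
    } else if (null_model == "target_shuffle") {
      rin$drugs <- shuffle_drug_targets(inputs$drugs, seed = st)
    } else {
      rin$disease_map <- shuffle_disease_genes(inputs$disease_map, seed = st)
    }
    stats_out[t] <- tryCatch(analysis(rin), error = function(e) NA_real_)
  }
  ok <- stats_out[!is.na(stats_out)]
  if (length(ok) < n_trials / 2)
    stop(sprintf("more than half of the %d null trials failed", n_trials),
         call. = FALSE)
  structure(list(
    null_model = null_model,
    n_trials = n_trials,
    per_trial_statistics = stats_out,
    n_skipped = sum(is.na(stats_out)),
    mean = mean(ok),
    standard_error = if (length(ok) >= 2L)
      stats::sd(ok) / sqrt(length(ok)) else NA_real_,
    seed = seed), class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf(
    "Null model '%s': %d trials (%d skipped), mean = %.4g, SE = %.3g\n",
    x$null_model, x$n_trials, x$n_skipped, x$mean, x$standard_error))
  invisible(x)
}
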