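# The structurally resolved sub-network and interface-sharing scores:
# Jaccard similarity of target-side interacting-domain sets across partner
# pairs, and single- vs multi-interface classification.

iface_key <- function(target, partner) paste(target, partner, sep = "\t")

#' Build an interface map
#'
#' An interface map records, for each (target, partner) interaction side,
#' the set of interacting domains on the target.
#'
#' @param df data frame with columns `target`, `partner`, `domains`
#'   (semicolon-separated domain ids), one row per oriented pair.
#' @return a named list of class `interface_map`: key `"target\tpartner"`,
#'   value a character vector of domain ids.
#' @export
interface_map <- function(df) {
  require_columns(df, c("target", "partner", "domains"), "interface table")
  doms <- lapply(as.character(df$domains), split_list_cell)
  if (any(lengths(doms) == 0L))
    stop("interface table: empty domain set", call. = FALSE)
  keys <- iface_key(as.character(df$target), as.character(df$partner))
  if (anyDuplicated(keys))
    stop("interface table: duplicate (target, partner) entry", call. = FALSE)
  out <- stats::setNames(doms, keys)
  class(out) <- "interface_map"
  out
}

#' Read an interface table
#'
#' @param path TSV with columns `target`, `partner`, `domains`.
#' @return an `interface_map`.
#' @export
read_interface_table <- function(path) {
  interface_map(read_tsv_strict(path))
}

#' Build the structurally resolved sub-network
#'
#' Restricts quality-filtered interactions to those with binary evidence
#' codes (direct physical binding, where an interaction interface is
#' meaningful) that additionally carry an interface annotation for at least
#' one orientation. Every interface entry must reference an existing
#' interaction pair.
#'
#' @param records a quality-filtered `interaction_table`.
#' @param iface an `interface_map`.
#' @return an igraph object (the structural network).
#' @export
build_structural_network <- function(records, iface) {
  pair_keys <- c(iface_key(records$protein_a, records$protein_b),
                 iface_key(records$protein_b, records$protein_a))
  orphan <- setdiff(names(iface), pair_keys)
  if (length(orphan))
    stop(sprintf("interface entry references a non-existent edge: %s",
                 gsub("\t", "-", orphan[1L])), call. = FALSE)
  annotated <- iface_key(records$protein_a, records$protein_b) %in% names(iface) |
    iface_key(records$protein_b, records$protein_a) %in% names(iface)
  keep <- records$is_binary & annotated
  build_network(records[keep, , drop = FALSE])
}

#' Jaccard similarity of two partners' interfaces on a target
#'
#' For target T and partners A, B: |D_A intersect D_B| / |D_A union D_B|,
#' where D_X is the set of interacting domains on T used in the T-X
#' interaction.
#'
#' @param target,partner_a,partner_b protein ids.
#' @param iface an `interface_map` containing both (target, partner) entries.
#' @return numeric in [0, 1].
#' @export
pairwise_jaccard <- function(target, partner_a, partner_b, iface) {
  ka <- iface_key(target, partner_a); kb <- iface_key(target, partner_b)
  if (is.null(iface[[ka]]) || is.null(iface[[kb]]))
    stop(sprintf("missing interface entry for target %s", target),
         call. = FALSE)
  da <- iface[[ka]]; db <- iface[[kb]]
  length(intersect(da, db)) / length(union(da, db))
}

# Annotated partners of a target in the structural network.
annotated_partners <- function(target, net, iface) {
  if (!target %in% igraph::V(net)$name) return(character(0))
  nb <- igraph::V(net)$name[igraph::neighbors(net, target)]
  nb[iface_key(target, nb) %in% names(iface)]
}

#' Interface-sharing score of a target
#'
#' Mean pairwise Jaccard similarity of the target-side domain sets over all
#' unordered pairs of annotated interaction partners. Targets with fewer
#' than two annotated partners are excluded (`NA`).
#'
#' @param target protein id.
#' @param net structural network (igraph).
#' @param iface an `interface_map`.
#' @return numeric in [0, 1], or `NA_real_` if undefined.
#' @export
target_interface_sharing <- function(target, net, iface) {
  prt <- annotated_partners(target, net, iface)
  if (length(prt) < 2L) return(NA_real_)
  prs <- utils::combn(sort(prt), 2L)
  mean(vapply(seq_len(ncol(prs)), function(i)
    pairwise_jaccard(target, prs[1L, i], prs[2L, i], iface), numeric(1)))
}

#' Classify a target as single- or multi-interface
#'
#' A single-interface target binds all its partners through identical
#' domain sets; a multi-interface target uses at least two distinct
#' interfaces. Targets with fewer than two annotated partners are
#' `"undefined"`.
#'
#' @inheritParams target_interface_sharing
#' @return one of `"single_interface"`, `"multi_interface"`, `"undefined"`.
#' @export
classify_interface_mode <- function(target, net, iface) {
  prt <- annotated_partners(target, net, iface)
  if (length(prt) < 2L) return("undefined")
  sets <- lapply(prt, function(p) sort(unique(iface[[iface_key(target, p)]])))
  if (all(vapply(sets[-1L], identical, logical(1), y = sets[[1L]])))
    "single_interface" else "multi_interface"
}

#' Interface-sharing table for a set of targets
#'
#' @param targets character vector of protein ids.
#' @inheritParams target_interface_sharing
#' @return data frame with columns `target`, `n_partners`, `mean_jaccard`,
#'   `mode`.
#' @export
interface_sharing_table <- function(targets, net, iface) {
  targets <- unique(targets)
  data.frame(
    target = targets,
    n_partners = vapply(targets, function(t)
      length(annotated_partners(t, net, iface)), integer(1),
      USE.NAMES = FALSE),
    mean_jaccard = vapply(targets, target_interface_sharing, numeric(1),
                          net = net, iface = iface, USE.NAMES = FALSE),
    mode = vapply(targets, classify_interface_mode, character(1),
                  net = net, iface = iface, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
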