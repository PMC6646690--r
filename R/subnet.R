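# Per-disease walk-graph extraction and eligibility checks.

#' Extract the disease-specific walk subnetwork
#'
#' Builds the graph the random walker runs on for one disease: the
#' disease's seed genes (its associated proteins that are present in the
#' PPI layer), their first PPI neighbours, and every lncRNA with at least
#' one interaction to a member protein. The disease node itself is not
#' part of the walk graph; the disease enters only through the seed set.
#'
#' Two rules decide which PPI edges are kept:
#' \describe{
#'   \item{`"induced"` (default)}{all PPI edges with both endpoints in the
#'     member protein set, including neighbour-neighbour edges. This
#'     preserves the local topology around the seeds.}
#'   \item{`"star"`}{only PPI edges incident to at least one seed.}
#' }
#'
#' @param net a `tripartite_network`.
#' @param disease_id disease identifier (normalized internally).
#' @param edge_rule `"induced"` or `"star"`.
#' @return a `disease_subnetwork`: list with `disease_id`, `seeds`,
#'   `proteins`, `lncrnas` (identifier vectors), `walk_edges` (data frame
#'   `from`, `to` of kind-qualified node keys), and `node_order` (data
#'   frame `kind`, `identifier`, `key` in fixed lexicographic order).
#' @export
extract_subnetwork <- function(net, disease_id,
                               edge_rule = c("induced", "star")) {
  stopifnot(inherits(net, "tripartite_network"))
  edge_rule <- match.arg(edge_rule)
  disease_id <- normalize_id(disease_id)
  dp <- net$disease_protein$edges
  genes <- dp$target[dp$source == disease_id]
  if (length(genes) == 0) {
    stop("unknown disease (no disease-protein edges): ", disease_id,
         call. = FALSE)
  }
  ppi <- net$ppi$edges
  ppi_nodes <- unique(c(ppi$source, ppi$target))
  seeds <- radix_sort(intersect(genes, ppi_nodes))
  missing <- setdiff(genes, seeds)
  if (length(missing) > 0) {
    warning(sprintf("%s: %d seed gene(s) absent from the PPI layer dropped",
                    disease_id, length(missing)), call. = FALSE)
  }
  if (length(seeds) == 0) {
    stop("no seed genes of disease ", disease_id, " are present in the PPI layer",
         call. = FALSE)
  }
  incident <- ppi$source %in% seeds | ppi$target %in% seeds
  neighbours <- unique(c(ppi$source[incident], ppi$target[incident]))
  proteins <- radix_sort(union(seeds, neighbours))

  keep <- if (edge_rule == "induced") {
    ppi$source %in% proteins & ppi$target %in% proteins
  } else {
    incident
  }
  ppi_edges <- ppi[keep, , drop = FALSE]

  lp <- net$lnc_protein$edges
  lp_edges <- lp[lp$target %in% proteins, , drop = FALSE]
  lncrnas <- radix_sort(unique(lp_edges$source))

  walk_edges <- rbind(
    data.frame(from = node_key("PROTEIN", ppi_edges$source),
               to = node_key("PROTEIN", ppi_edges$target),
               stringsAsFactors = FALSE),
    data.frame(from = node_key("LNCRNA", lp_edges$source),
               to = node_key("PROTEIN", lp_edges$target),
               stringsAsFactors = FALSE)
  )
  node_order <- rbind(
    data.frame(kind = "LNCRNA", identifier = lncrnas,
               stringsAsFactors = FALSE),
    data.frame(kind = "PROTEIN", identifier = proteins,
               stringsAsFactors = FALSE)
  )
  node_order <- node_order[radix_order(node_order$kind, node_order$identifier),
                           , drop = FALSE]
  node_order$key <- node_key(node_order$kind, node_order$identifier)
  rownames(node_order) <- NULL

  structure(
    list(disease_id = disease_id, seeds = seeds, proteins = proteins,
         lncrnas = lncrnas, walk_edges = walk_edges, node_order = node_order,
         edge_rule = edge_rule),
    class = "disease_subnetwork"
  )
}

#' @export
print.disease_subnetwork <- function(x, ...) {
  cat(sprintf(paste0(
    "<disease_subnetwork> %s: %d seeds, %d proteins, %d lncRNAs, ",
    "%d walk edges (%s rule)\n"),
    x$disease_id, length(x$seeds), length(x$proteins), length(x$lncrnas),
    nrow(x$walk_edges), x$edge_rule))
  invisible(x)
}

# One BFS pass over an undirected graph: counts connected components and
# attempts a 2-colouring; a colour conflict proves an odd cycle, i.e. a
# non-bipartite graph.
traverse_graph <- function(n, from_idx, to_idx) {
  adj <- vector("list", n)
  if (length(from_idx) > 0) {
    nb <- split(c(to_idx, from_idx), c(from_idx, to_idx))
    adj[as.integer(names(nb))] <- nb
  }
  colour <- rep(NA_integer_, n)
  n_components <- 0L
  bipartite <- TRUE
  for (s in seq_len(n)) {
    if (!is.na(colour[s])) next
    n_components <- n_components + 1L
    colour[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(colour[u])) {
          colour[u] <- 1L - colour[v]
          queue <- c(queue, u)
        } else if (colour[u] == colour[v]) {
          bipartite <- FALSE
        }
      }
    }
  }
  list(n_components = n_components, bipartite = bipartite)
}

#' Check whether a disease subnetwork supports the diffusion
#'
#' A subnetwork is used for ranking only when its walk graph (proteins
#' plus attached lncRNAs) is connected and non-bipartite and the seed set
#' is non-empty: the conditions under which the walk's limiting
#' distribution is unique and supported on the whole graph.
#' Connectivity is tested by traversal and bipartiteness by 2-colouring.
#'
#' @param sub a `disease_subnetwork`.
#' @return an `eligibility_report`: list with logicals `eligible`,
#'   `connected`, `bipartite`, counts `n_nodes`, `n_edges`, and a
#'   human-readable `reason`.
#' @export
check_eligibility <- function(sub) {
  stopifnot(inherits(sub, "disease_subnetwork"))
  n_nodes <- nrow(sub$node_order)
  n_edges <- nrow(sub$walk_edges)
  if (n_nodes == 0) {
    return(structure(list(eligible = FALSE, connected = FALSE,
                          bipartite = TRUE, n_nodes = 0L, n_edges = 0L,
                          reason = "empty walk graph"),
                     class = "eligibility_report"))
  }
  trav <- traverse_graph(
    n_nodes,
    match(sub$walk_edges$from, sub$node_order$key),
    match(sub$walk_edges$to, sub$node_order$key)
  )
  connected <- trav$n_components == 1L
  bipartite <- trav$bipartite
  has_seeds <- length(sub$seeds) > 0
  eligible <- connected && !bipartite && has_seeds
  reason <- if (eligible) {
    "eligible"
  } else if (!has_seeds) {
    "no seed genes in the walk graph"
  } else if (!connected) {
    "disconnected"
  } else {
    "bipartite"
  }
  structure(
    list(eligible = eligible, connected = connected, bipartite = bipartite,
         n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
         reason = reason),
    class = "eligibility_report"
  )
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("<eligibility_report> %s (%d nodes, %d edges; connected=%s, bipartite=%s)\n",
              x$reason, x$n_nodes, x$n_edges, x$connected, x$bipartite))
  invisible(x)
}

#' Write a subnetwork's walk edges and eligibility report
#'
#' @param sub a `disease_subnetwork`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_eligibility.tsv`.
#' @return the eligibility report, invisibly.
#' @export
write_subnetwork <- function(sub, prefix) {
  rep <- check_eligibility(sub)
  write.table(sub$walk_edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  df <- data.frame(disease_id = sub$disease_id, eligible = rep$eligible,
                   connected = rep$connected, bipartite = rep$bipartite,
                   n_nodes = rep$n_nodes, n_edges = rep$n_edges,
                   reason = rep$reason)
  write.table(df, paste0(prefix, "_eligibility.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(rep)
}
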