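# Reading, validating and assembling the three interaction layers.

check_kind <- function(kind) {
  if (!(is.character(kind) && length(kind) == 1 && kind %in% NODE_KINDS)) {
    stop("node kind must be one of ", paste(NODE_KINDS, collapse = ", "),
         call. = FALSE)
  }
  kind
}

new_edge_layer <- function(source_kind, target_kind, source, target,
                           dropped_duplicates = 0L, dropped_self_loops = 0L) {
  structure(
    list(
      source_kind = source_kind,
      target_kind = target_kind,
      edges = data.frame(source = as.character(source),
                         target = as.character(target),
                         stringsAsFactors = FALSE),
      dropped_duplicates = as.integer(dropped_duplicates),
      dropped_self_loops = as.integer(dropped_self_loops)
    ),
    class = "edge_layer"
  )
}

#' Canonicalize and deduplicate an edge layer
#'
#' Same-kind (protein-protein) pairs are stored sorted so that reversed
#' duplicates collapse to a single undirected edge, and self-loops are
#' dropped. Cross-kind layers keep their (source, target) orientation.
#' Deduplication is idempotent.
#'
#' @param layer an `edge_layer`.
#' @return the layer with canonical, unique edges and updated drop counters.
#' @export
canonicalize_layer <- function(layer) {
  stopifnot(inherits(layer, "edge_layer"))
  src <- layer$edges$source
  tgt <- layer$edges$target
  n_self <- 0L
  if (layer$source_kind == layer$target_kind) {
    self <- src == tgt
    n_self <- sum(self)
    src <- src[!self]
    tgt <- tgt[!self]
    flip <- src > tgt
    tmp <- src[flip]
    src[flip] <- tgt[flip]
    tgt[flip] <- tmp
  }
  keys <- paste(src, tgt, sep = "\t")
  keep <- !duplicated(keys)
  n_dup <- sum(!keep)
  new_edge_layer(layer$source_kind, layer$target_kind,
                 src[keep], tgt[keep],
                 dropped_duplicates = layer$dropped_duplicates + n_dup,
                 dropped_self_loops = layer$dropped_self_loops + n_self)
}

#' Read a tab-separated edge list
#'
#' Parses a two-plus-column TSV interaction file into an edge layer.
#' Field 1 is the source identifier and field 2 the target identifier;
#' extra columns are ignored and lines starting with `#` are comments.
#' Identifiers are normalized with [normalize_id()], self-loops and
#' (reversed) duplicates are collapsed, and the number of dropped records
#' is reported on standard error.
#'
#' @param path path to a UTF-8 TSV file.
#' @param source_kind,target_kind node kinds of columns 1 and 2, each one
#'   of `"PROTEIN"`, `"LNCRNA"`, `"DISEASE"`.
#' @return an `edge_layer` with fields `source_kind`, `target_kind`,
#'   `edges` (a data frame of unique canonical pairs), and the counters
#'   `dropped_duplicates` and `dropped_self_loops`.
#' @export
read_edge_list <- function(path, source_kind, target_kind) {
  check_kind(source_kind)
  check_kind(target_kind)
  if (!file.exists(path)) {
    stop("edge list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- line_no[which(nf < 2)[1]]
    stop(sprintf("parse error at line %d of %s: expected >= 2 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  src <- normalize_id(vapply(fields, `[[`, "", 1L))
  tgt <- normalize_id(vapply(fields, `[[`, "", 2L))
  empty <- !nzchar(src) | !nzchar(tgt)
  if (any(empty)) {
    bad <- line_no[which(empty)[1]]
    stop(sprintf("parse error at line %d of %s: empty identifier", bad, path),
         call. = FALSE)
  }
  layer <- canonicalize_layer(new_edge_layer(source_kind, target_kind, src, tgt))
  if (layer$dropped_duplicates > 0 || layer$dropped_self_loops > 0) {
    message(sprintf("%s: dropped %d duplicate edge(s) and %d self-loop(s)",
                    basename(path), layer$dropped_duplicates,
                    layer$dropped_self_loops))
  }
  layer
}

#' Write an edge layer as TSV
#'
#' Inverse of [read_edge_list()]: writing then re-reading recovers the
#' same edge set.
#'
#' @param layer an `edge_layer`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(layer, path) {
  stopifnot(inherits(layer, "edge_layer"))
  write.table(layer$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.edge_layer <- function(x, ...) {
  cat(sprintf("<edge_layer> %s-%s: %d edges\n",
              x$source_kind, x$target_kind, nrow(x$edges)))
  invisible(x)
}

layer_nodes <- function(layer) {
  n <- nrow(layer$edges)
  rbind(
    data.frame(kind = rep(layer$source_kind, n),
               identifier = layer$edges$source, stringsAsFactors = FALSE),
    data.frame(kind = rep(layer$target_kind, n),
               identifier = layer$edges$target, stringsAsFactors = FALSE)
  )
}

#' Assemble a tripartite lncRNA-protein-disease network
#'
#' Combines the three interaction layers into one network whose node set
#' is the union of all edge endpoints, keyed by (kind, identifier) so the
#' same string may legitimately name both a protein and a lncRNA.
#'
#' @param lnc_protein `edge_layer` with kinds LNCRNA -> PROTEIN.
#' @param ppi `edge_layer` with kinds PROTEIN -> PROTEIN.
#' @param disease_protein `edge_layer` with kinds DISEASE -> PROTEIN.
#' @return a `tripartite_network`: list with `nodes` (data frame of kind,
#'   identifier) and the three layers.
#' @export
build_tripartite <- function(lnc_protein, ppi, disease_protein) {
  stopifnot(inherits(lnc_protein, "edge_layer"),
            inherits(ppi, "edge_layer"),
            inherits(disease_protein, "edge_layer"))
  if (lnc_protein$source_kind != "LNCRNA" || lnc_protein$target_kind != "PROTEIN")
    stop("lnc_protein layer must be declared LNCRNA -> PROTEIN", call. = FALSE)
  if (ppi$source_kind != "PROTEIN" || ppi$target_kind != "PROTEIN")
    stop("ppi layer must be declared PROTEIN -> PROTEIN", call. = FALSE)
  if (disease_protein$source_kind != "DISEASE" ||
      disease_protein$target_kind != "PROTEIN")
    stop("disease_protein layer must be declared DISEASE -> PROTEIN",
         call. = FALSE)
  for (nm in c("lnc_protein", "ppi", "disease_protein")) {
    if (nrow(get(nm)$edges) == 0) warning("layer '", nm, "' is empty",
                                          call. = FALSE)
  }
  nodes <- rbind(layer_nodes(lnc_protein), layer_nodes(ppi),
                 layer_nodes(disease_protein))
  nodes <- unique(nodes)
  nodes <- nodes[radix_order(nodes$kind, nodes$identifier), , drop = FALSE]
  rownames(nodes) <- NULL
  shared <- intersect(nodes$identifier[nodes$kind == "LNCRNA"],
                      nodes$identifier[nodes$kind == "PROTEIN"])
  if (length(shared) > 0) {
    warning(length(shared), " identifier(s) appear as both PROTEIN and ",
            "LNCRNA (kept as distinct nodes): ",
            paste(head(shared, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(nodes = nodes, lnc_protein = lnc_protein, ppi = ppi,
         disease_protein = disease_protein),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf(paste0(
    "<tripartite_network> %d nodes; %d lncRNA-protein, %d PPI, ",
    "%d disease-protein edges\n"),
    nrow(x$nodes), nrow(x$lnc_protein$edges), nrow(x$ppi$edges),
    nrow(x$disease_protein$edges)))
  invisible(x)
}

degree_summary <- function(ids) {
  if (length(ids) == 0) {
    return(c(min = 0, median = 0, max = 0))
  }
  d <- table(ids)
  c(min = as.numeric(min(d)), median = as.numeric(median(as.numeric(d))),
    max = as.numeric(max(d)))
}

#' Summarize a tripartite network
#'
#' Counts nodes per kind and edges per layer, and summarizes node degree
#' (min/median/max, over the whole network) per kind.
#'
#' @param object a `tripartite_network`.
#' @param ... unused.
#' @return a `tripartite_summary` list with `node_counts`, `edge_counts`
#'   and a `degree` data frame.
#' @export
summary.tripartite_network <- function(object, ...) {
  node_counts <- vapply(NODE_KINDS, function(k) {
    sum(object$nodes$kind == k)
  }, integer(1))
  edge_counts <- c(
    lnc_protein = nrow(object$lnc_protein$edges),
    ppi = nrow(object$ppi$edges),
    disease_protein = nrow(object$disease_protein$edges)
  )
  # endpoint occurrences by kind across all layers
  occ <- list(
    PROTEIN = c(object$lnc_protein$edges$target,
                object$ppi$edges$source, object$ppi$edges$target,
                object$disease_protein$edges$target),
    LNCRNA = object$lnc_protein$edges$source,
    DISEASE = object$disease_protein$edges$source
  )
  deg <- t(vapply(NODE_KINDS, function(k) degree_summary(occ[[k]]),
                  numeric(3)))
  structure(
    list(node_counts = node_counts, edge_counts = edge_counts,
         degree = data.frame(kind = rownames(deg), deg,
                             row.names = NULL, stringsAsFactors = FALSE)),
    class = "tripartite_summary"
  )
}

#' @export
print.tripartite_summary <- function(x, ...) {
  cat("Nodes:\n")
  for (k in names(x$node_counts)) {
    cat(sprintf("  %-8s %d\n", k, x$node_counts[[k]]))
  }
  cat("Edges:\n")
  for (k in names(x$edge_counts)) {
    cat(sprintf("  %-16s %d\n", k, x$edge_counts[[k]]))
  }
  cat("Degree (min/median/max):\n")
  for (i in seq_len(nrow(x$degree))) {
    cat(sprintf("  %-8s %g/%g/%g\n", x$degree$kind[i], x$degree$min[i],
                x$degree$median[i], x$degree$max[i]))
  }
  invisible(x)
}

#' Write a tripartite network summary as TSV
#'
#' @param object a `tripartite_network`.
#' @param path output path, or `""` for stdout.
#' @return the summary, invisibly.
#' @export
write_summary <- function(object, path = "") {
  s <- summary(object)
  df <- rbind(
    data.frame(metric = paste0("nodes_", tolower(names(s$node_counts))),
               value = as.numeric(s$node_counts)),
    data.frame(metric = paste0("edges_", names(s$edge_counts)),
               value = as.numeric(s$edge_counts))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(s)
}
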