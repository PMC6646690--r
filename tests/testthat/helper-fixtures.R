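# In-code fixtures shared across test files.

# Write lines to a temp TSV and return its path (cleaned up by caller's
# test env through withr).
write_tsv_lines <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(lines, path)
  path
}

make_layer <- function(source_kind, target_kind, pairs) {
  # pairs: list of c(source, target)
  lines <- vapply(pairs, function(p) paste(p, collapse = "\t"), "")
  path <- write_tsv_lines(lines, env = parent.frame())
  read_edge_list(path, source_kind, target_kind)
}

# A small hand-checkable network:
#   PPI: triangle g1-g2-g3 plus pendant g3-g4
#   lncRNAs: L1 on g2, L2 on g4
#   diseases: DA -> {g1}, DB -> {g4}
toy_network <- function() {
  suppressWarnings(build_tripartite(
    make_layer("LNCRNA", "PROTEIN", list(c("L1", "g2"), c("L2", "g4"))),
    make_layer("PROTEIN", "PROTEIN",
               list(c("g1", "g2"), c("g2", "g3"), c("g1", "g3"),
                    c("g3", "g4"))),
    make_layer("DISEASE", "PROTEIN", list(c("DA", "g1"), c("DB", "g4")))
  ))
}

# Random connected undirected graph as an edge data frame: a random
# spanning tree plus extra random edges.
random_connected_edges <- function(n, extra = n) {
  stopifnot(n >= 2)
  to <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
  edges <- data.frame(from = paste0("N", sprintf("%02d", 2:n)),
                      to = paste0("N", sprintf("%02d", to)))
  if (extra > 0) {
    i <- sample.int(n, extra, replace = TRUE)
    j <- sample.int(n, extra, replace = TRUE)
    keep <- i != j
    edges <- rbind(edges,
                   data.frame(from = paste0("N", sprintf("%02d", pmin(i, j)[keep])),
                              to = paste0("N", sprintf("%02d", pmax(i, j)[keep])))
    )
  }
  unique(edges)
}

# Brute-force AUC oracle: average pairwise concordance over all
# positive x negative score pairs, ties counting one half.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Small fast generator configuration for property tests that need many
# replicates; the package defaults remain the benchmark of record.
small_synth_config <- function(...) {
  synth_config(n_proteins = 120L, n_diseases = 4L, genes_per_disease = 8L,
               n_lncrnas = 40L, planted_per_disease = 2L, ...)
}

make_ldn <- function(disease_id, lncrna_id, weight, rank = NULL) {
  edges <- data.frame(disease_id = disease_id, lncrna_id = lncrna_id,
                      weight = weight, stringsAsFactors = FALSE)
  if (is.null(rank)) {
    rank <- stats::ave(-edges$weight, edges$disease_id,
                       FUN = function(x) base::rank(x, ties.method = "first"))
  }
  edges$rank <- as.integer(rank)
  lncrwr:::new_ldn(edges)
}
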