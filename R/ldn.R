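# Assembling the predicted weighted bipartite lncRNA-disease network.

new_ldn <- function(edges, skipped = NULL) {
  if (is.null(skipped)) {
    skipped <- data.frame(disease_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, skipped = skipped),
            class = "lnc_disease_network")
}

empty_ldn_edges <- function() {
  data.frame(disease_id = character(), lncrna_id = character(),
             weight = numeric(), rank = integer(), stringsAsFactors = FALSE)
}

#' Predict lncRNA-disease associations for every disease
#'
#' Runs the full pipeline over the disease-protein layer: for each
#' disease (in lexicographic order) the walk subnetwork is extracted and,
#' if eligible, diffused; each ranked lncRNA contributes one weighted
#' edge to the bipartite lncRNA-disease network. Diseases whose
#' subnetwork cannot be built or is ineligible are skipped with a
#' machine-readable reason (`no_seeds`, `disconnected`, `bipartite`, or
#' `not_converged`). Deterministic given inputs and parameters.
#'
#' @param net a `tripartite_network`.
#' @param params a `diffusion_params`.
#' @param edge_rule passed to [extract_subnetwork()].
#' @return a `lnc_disease_network`: list with `edges` (data frame
#'   `disease_id`, `lncrna_id`, `weight`, `rank`) and `skipped` (data
#'   frame `disease_id`, `reason`).
#' @export
predict_all <- function(net, params = diffusion_params(),
                        edge_rule = c("induced", "star")) {
  stopifnot(inherits(net, "tripartite_network"))
  edge_rule <- match.arg(edge_rule)
  diseases <- radix_sort(unique(net$disease_protein$edges$source))
  if (length(diseases) == 0) {
    warning("disease-protein layer is empty: returning an empty network",
            call. = FALSE)
    return(new_ldn(empty_ldn_edges()))
  }
  parts <- vector("list", length(diseases))
  skipped <- list()
  for (i in seq_along(diseases)) {
    d <- diseases[i]
    sub <- tryCatch(
      suppressWarnings(extract_subnetwork(net, d, edge_rule = edge_rule)),
      error = function(e) NULL
    )
    if (is.null(sub)) {
      skipped[[length(skipped) + 1]] <- c(d, "no_seeds")
      next
    }
    rep <- check_eligibility(sub)
    if (!rep$eligible) {
      reason <- if (!rep$connected) "disconnected" else "bipartite"
      skipped[[length(skipped) + 1]] <- c(d, reason)
      next
    }
    W <- column_normalize(sub)
    p0 <- uniform_restart(node_key("PROTEIN", sub$seeds), sub$node_order$key)
    scores <- tryCatch(diffuse(W, p0, params), error = function(e) NULL)
    if (is.null(scores)) {
      skipped[[length(skipped) + 1]] <- c(d, "not_converged")
      next
    }
    ranked <- rank_lncrnas(scores, sub)
    if (nrow(ranked) > 0) {
      parts[[i]] <- data.frame(disease_id = d, lncrna_id = ranked$lncrna_id,
                               weight = ranked$score, rank = ranked$rank,
                               stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, c(list(empty_ldn_edges()), parts))
  skipped_df <- if (length(skipped) > 0) {
    m <- do.call(rbind, skipped)
    data.frame(disease_id = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else {
    NULL
  }
  new_ldn(edges, skipped_df)
}

#' @export
print.lnc_disease_network <- function(x, ...) {
  cat(sprintf("<lnc_disease_network> %d edges, %d diseases, %d lncRNAs (%d skipped)\n",
              nrow(x$edges), length(unique(x$edges$disease_id)),
              length(unique(x$edges$lncrna_id)), nrow(x$skipped)))
  invisible(x)
}

#' Summary statistics of a predicted lncRNA-disease network
#'
#' @param ldn a `lnc_disease_network`.
#' @return an `ldn_summary` list: `n_edges`, `n_diseases`, `n_lncrnas`,
#'   `median_lncrnas_per_disease`, `median_diseases_per_lncrna` (medians
#'   over the bipartite degree multisets; the mean of the two central
#'   values for even counts; `NA` for an empty network).
#' @export
ldn_summary <- function(ldn) {
  stopifnot(inherits(ldn, "lnc_disease_network"))
  e <- ldn$edges
  structure(
    list(
      n_edges = nrow(e),
      n_diseases = length(unique(e$disease_id)),
      n_lncrnas = length(unique(e$lncrna_id)),
      median_lncrnas_per_disease =
        if (nrow(e) == 0) NA_real_
        else median(as.numeric(table(e$disease_id))),
      median_diseases_per_lncrna =
        if (nrow(e) == 0) NA_real_
        else median(as.numeric(table(e$lncrna_id)))
    ),
    class = "ldn_summary"
  )
}

#' @export
print.ldn_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<ldn_summary> %d edges; %d diseases, %d lncRNAs; ",
    "median lncRNAs/disease %s, median diseases/lncRNA %s\n"),
    x$n_edges, x$n_diseases, x$n_lncrnas,
    format(x$median_lncrnas_per_disease),
    format(x$median_diseases_per_lncrna)))
  invisible(x)
}

#' Write / read a predicted lncRNA-disease network
#'
#' Four-column TSV (`disease_id`, `lncrna_id`, `weight`, `rank`) with a
#' header. Weights are written as 17-significant-digit decimal text so
#' they round-trip bit-identically.
#'
#' @param ldn a `lnc_disease_network`.
#' @param path file path.
#' @return `write_ldn`: `path`, invisibly. `read_ldn`: a
#'   `lnc_disease_network` (with an empty skip report).
#' @export
write_ldn <- function(ldn, path) {
  stopifnot(inherits(ldn, "lnc_disease_network"))
  e <- ldn$edges
  lines <- c("disease_id\tlncrna_id\tweight\trank",
             if (nrow(e) > 0) {
               sprintf("%s\t%s\t%.17g\t%d", e$disease_id, e$lncrna_id,
                       e$weight, as.integer(e$rank))
             })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ldn
#' @export
read_ldn <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 ||
      !identical(lines[1], "disease_id\tlncrna_id\tweight\trank")) {
    stop("malformed header in ", path, call. = FALSE)
  }
  body <- lines[-1]
  body_no <- seq_along(body) + 1L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_no <- body_no[keep]
  if (length(body) == 0) return(new_ldn(empty_ldn_edges()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    stop(sprintf("parse error at line %d of %s: expected 4 fields",
                 body_no[which(nf != 4)[1]], path), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  weight <- suppressWarnings(as.numeric(m[, 3]))
  rank <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(weight) || anyNA(rank)) {
    bad <- which(is.na(weight) | is.na(rank))[1]
    stop(sprintf("parse error at line %d of %s: non-numeric weight or rank",
                 body_no[bad], path), call. = FALSE)
  }
  new_ldn(data.frame(disease_id = normalize_id(m[, 1]),
                     lncrna_id = normalize_id(m[, 2]),
                     weight = weight, rank = rank, stringsAsFactors = FALSE))
}

#' Write the per-disease skip report
#'
#' @param ldn a `lnc_disease_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_skip_report <- function(ldn, path) {
  stopifnot(inherits(ldn, "lnc_disease_network"))
  write.table(ldn$skipped, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
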