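# Random walk with restart on a disease subnetwork.

#' Diffusion parameters
#'
#' @param r restart probability in (0, 1]: the per-step probability that
#'   the walker teleports back to the seed distribution. Default 0.5.
#' @param tol L1 convergence tolerance on successive probability vectors.
#'   Default 1e-6.
#' @param max_iter iteration cap. Default 1000.
#' @return a validated `diffusion_params` list.
#' @export
diffusion_params <- function(r = 0.5, tol = 1e-6, max_iter = 1000L) {
  stopifnot(is.numeric(r), length(r) == 1, r > 0, r <= 1,
            is.numeric(tol), length(tol) == 1, tol > 0,
            is.numeric(max_iter), length(max_iter) == 1, max_iter >= 1)
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter)),
            class = "diffusion_params")
}

#' Column-normalized transition matrix of a walk graph
#'
#' Builds the column-stochastic matrix W with `W[i, j] = 1/degree(j)` for
#' every undirected walk edge i-j. Column j is then the walker's
#' transition distribution out of node j. Small graphs use a dense
#' matrix; above `dense_limit` nodes a sparse `Matrix` representation is
#' used (the two give identical results).
#'
#' @param x a `disease_subnetwork`, or a two-column data frame / matrix
#'   of undirected edges.
#' @param node_order character vector of node names fixing the index
#'   order; taken from the subnetwork when `x` is one.
#' @param sparse logical; `NULL` (default) picks dense for
#'   `n <= dense_limit` and sparse otherwise.
#' @param dense_limit size threshold for the automatic choice.
#' @return a `walk_matrix`: list with `W`, `nodes`, `n`.
#' @export
column_normalize <- function(x, node_order = NULL, sparse = NULL,
                             dense_limit = 500L) {
  if (inherits(x, "disease_subnetwork")) {
    edges <- x$walk_edges
    if (is.null(node_order)) node_order <- x$node_order$key
  } else {
    edges <- as.data.frame(x, stringsAsFactors = FALSE)
    if (is.null(node_order)) {
      node_order <- radix_sort(unique(c(as.character(edges[[1]]),
                                        as.character(edges[[2]]))))
    }
  }
  n <- length(node_order)
  stopifnot(n >= 1, !anyDuplicated(node_order))
  i <- match(as.character(edges[[1]]), node_order)
  j <- match(as.character(edges[[2]]), node_order)
  if (anyNA(i) || anyNA(j)) {
    stop("walk edge endpoint not present in node_order", call. = FALSE)
  }
  if (any(i == j)) stop("self-loop in walk edges", call. = FALSE)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), use.last.ij = TRUE)
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    bad <- node_order[which(deg == 0)[1]]
    stop("cannot column-normalize: node has degree 0: ", bad, call. = FALSE)
  }
  W <- A %*% Matrix::Diagonal(n, x = 1 / deg)
  if (is.null(sparse)) sparse <- n > dense_limit
  W <- if (sparse) methods::as(W, "CsparseMatrix") else as.matrix(W)
  structure(list(W = W, nodes = node_order, n = n, sparse = sparse),
            class = "walk_matrix")
}

#' @export
print.walk_matrix <- function(x, ...) {
  cat(sprintf("<walk_matrix> %d nodes (%s)\n", x$n,
              if (x$sparse) "sparse" else "dense"))
  invisible(x)
}

#' Uniform restart distribution over seed nodes
#'
#' @param seeds non-empty character vector of seed node names.
#' @param node_order character vector of all node names in index order.
#' @return numeric vector over `node_order`, `1/|seeds|` at each seed and
#'   0 elsewhere, named by node.
#' @export
uniform_restart <- function(seeds, node_order) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("empty seed set", call. = FALSE)
  idx <- match(seeds, node_order)
  if (anyNA(idx)) {
    stop("seed not present in node_order: ", seeds[which(is.na(idx))[1]],
         call. = FALSE)
  }
  p0 <- setNames(numeric(length(node_order)), node_order)
  p0[idx] <- 1 / length(seeds)
  p0
}

walk_W <- function(W) if (inherits(W, "walk_matrix")) W$W else W

walk_nodes <- function(W, p0) {
  if (inherits(W, "walk_matrix")) W$nodes else names(p0)
}

#' Random walk with restart by power iteration
#'
#' Iterates `p_{k+1} = (1 - r) W p_k + r p_0` from `p_0` until the L1
#' change between successive iterates falls below `tol`, and returns the
#' steady-state probability vector. Because W is column-stochastic and
#' `p_0` sums to one, every iterate is a probability vector, and the map
#' is a contraction with factor `1 - r`, so convergence is geometric.
#'
#' @param W a `walk_matrix` (or plain matrix).
#' @param p0 restart vector from [uniform_restart()].
#' @param params a `diffusion_params` object.
#' @param trace if `TRUE`, also return the full iterate trajectory
#'   (`trajectory`: one row per iterate including `p0`) for diagnostics.
#' @return a `score_vector`: list with `p` (named steady-state vector),
#'   `iterations`, `final_residual`, `residuals` (L1 change per
#'   iteration), `converged`, and optionally `trajectory`.
#' @export
diffuse <- function(W, p0, params = diffusion_params(), trace = FALSE) {
  stopifnot(inherits(params, "diffusion_params"))
  M <- walk_W(W)
  nodes <- walk_nodes(W, p0)
  stopifnot(length(p0) == nrow(M))
  r <- params$r
  p <- as.numeric(p0)
  residuals <- numeric(0)
  traj <- if (trace) list(p) else NULL
  for (k in seq_len(params$max_iter)) {
    p_new <- as.numeric((1 - r) * (M %*% p) + r * as.numeric(p0))
    resid <- sum(abs(p_new - p))
    residuals[k] <- resid
    p <- p_new
    if (trace) traj[[k + 1]] <- p
    if (isTRUE(getOption("lncrwr.verbose")) && k %% 10 == 0) {
      message(sprintf("iteration %d: L1 residual %.3e", k, resid))
    }
    if (resid < params$tol) {
      out <- list(p = setNames(p, nodes), iterations = k,
                  final_residual = resid, residuals = residuals,
                  converged = TRUE)
      if (trace) out$trajectory <- do.call(rbind, traj)
      return(structure(out, class = "score_vector"))
    }
  }
  stop(sprintf("diffusion did not converge in %d iterations (residual %.3e)",
               params$max_iter, resid), call. = FALSE)
}

#' Steady state by direct linear solve
#'
#' Solves the fixed-point equation `(I - (1 - r) W) p = r p_0` exactly.
#' Intended as an independent cross-check of [diffuse()] on small graphs;
#' for `r > 0` with a column-stochastic W the system is always
#' non-singular.
#'
#' @inheritParams diffuse
#' @param r restart probability in (0, 1].
#' @return a `score_vector` with `iterations = NA`.
#' @export
diffuse_closed_form <- function(W, p0, r = 0.5) {
  stopifnot(is.numeric(r), length(r) == 1, r > 0, r <= 1)
  M <- as.matrix(walk_W(W))
  nodes <- walk_nodes(W, p0)
  n <- nrow(M)
  stopifnot(length(p0) == n)
  p <- solve(diag(n) - (1 - r) * M, r * as.numeric(p0))
  structure(list(p = setNames(as.numeric(p), nodes), iterations = NA_integer_,
                 final_residual = 0, converged = TRUE),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %d nodes; %s iterations, final L1 residual %.3e\n",
              length(x$p),
              if (is.na(x$iterations)) "direct solve, no" else x$iterations,
              x$final_residual))
  invisible(x)
}

#' Rank the subnetwork's lncRNAs by steady-state probability
#'
#' Keeps only lncRNA nodes, sorts by score descending with ties broken by
#' identifier ascending, and assigns 1-based ordinal ranks. Scores are
#' the raw steady-state probabilities, not renormalized over lncRNAs.
#'
#' @param scores a `score_vector` aligned with `sub$node_order`.
#' @param sub the `disease_subnetwork` the scores were computed on.
#' @return data frame with columns `lncrna_id`, `score`, `rank`.
#' @export
rank_lncrnas <- function(scores, sub) {
  stopifnot(inherits(scores, "score_vector"),
            inherits(sub, "disease_subnetwork"))
  ord <- sub$node_order
  stopifnot(identical(names(scores$p), ord$key))
  is_lnc <- ord$kind == "LNCRNA"
  df <- data.frame(lncrna_id = ord$identifier[is_lnc],
                   score = as.numeric(scores$p[is_lnc]),
                   stringsAsFactors = FALSE)
  df <- df[radix_order(-df$score, df$lncrna_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Rank lncRNAs for one disease
#'
#' Convenience wrapper: extract the disease subnetwork, check
#' eligibility, diffuse, and rank.
#'
#' @param net a `tripartite_network`.
#' @param disease_id disease identifier.
#' @param params a `diffusion_params`.
#' @param edge_rule passed to [extract_subnetwork()].
#' @param force run the diffusion even on an ineligible subnetwork
#'   (logged prominently); the restart term makes the iteration a
#'   contraction on any graph, so it still converges.
#' @return data frame `disease_id`, `lncrna_id`, `score`, `rank`.
#' @export
rank_disease <- function(net, disease_id, params = diffusion_params(),
                         edge_rule = c("induced", "star"), force = FALSE) {
  sub <- extract_subnetwork(net, disease_id, edge_rule = match.arg(edge_rule))
  rep <- check_eligibility(sub)
  if (!rep$eligible) {
    if (!force) {
      stop("subnetwork for ", sub$disease_id, " is not eligible: ",
           rep$reason, call. = FALSE)
    }
    warning("FORCED: diffusing on an ineligible subnetwork for ",
            sub$disease_id, " (", rep$reason, ")", call. = FALSE)
  }
  W <- column_normalize(sub)
  p0 <- uniform_restart(node_key("PROTEIN", sub$seeds), sub$node_order$key)
  scores <- diffuse(W, p0, params)
  ranked <- rank_lncrnas(scores, sub)
  cbind(data.frame(disease_id = sub$disease_id, stringsAsFactors = FALSE),
        ranked)
}
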