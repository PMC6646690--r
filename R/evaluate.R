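# ROC/AUC evaluation, node-label-shuffled null model, rank-sum tests.

#' Read validated lncRNA-disease associations
#'
#' Two-column TSV: disease identifier, lncRNA identifier. Lines starting
#' with `#` are comments; identifiers are normalized and pairs
#' deduplicated.
#'
#' @param path file path.
#' @return a `ground_truth` data frame with columns `disease_id`,
#'   `lncrna_id`.
#' @export
read_ground_truth <- function(path) {
  layer <- read_edge_list(path, "DISEASE", "LNCRNA")
  truth <- data.frame(disease_id = layer$edges$source,
                      lncrna_id = layer$edges$target,
                      stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", class(truth))
  truth
}

as_ground_truth <- function(truth) {
  stopifnot(is.data.frame(truth),
            all(c("disease_id", "lncrna_id") %in% names(truth)))
  truth$disease_id <- normalize_id(truth$disease_id)
  truth$lncrna_id <- normalize_id(truth$lncrna_id)
  unique(truth[c("disease_id", "lncrna_id")])
}

#' Read a disease-group membership table
#'
#' Two-column TSV: disease identifier, group label (e.g. cancer,
#' cardiovascular).
#'
#' @param path file path.
#' @return data frame with columns `disease_id`, `group`.
#' @export
read_disease_groups <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("groups file needs 2 columns", call. = FALSE)
  data.frame(disease_id = normalize_id(df[[1]]), group = trimws(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Label predicted edges against the ground truth
#'
#' Every predicted edge (optionally restricted to diseases in one group)
#' becomes one labelled score: label 1 if the (disease, lncRNA) pair is a
#' validated association, 0 otherwise. Validated pairs that were never
#' predicted contribute nothing (they are reported as unscored
#' positives); diseases in the group without any validated pair
#' contribute only negatives.
#'
#' @param ldn a `lnc_disease_network`.
#' @param truth a `ground_truth` data frame (or any data frame with
#'   `disease_id`, `lncrna_id`).
#' @param group optional group label to restrict to.
#' @param groups data frame from [read_disease_groups()]; required when
#'   `group` is given.
#' @return data frame with columns `score`, `label`.
#' @export
label_edges <- function(ldn, truth, group = NULL, groups = NULL) {
  stopifnot(inherits(ldn, "lnc_disease_network"))
  truth <- as_ground_truth(truth)
  e <- ldn$edges
  if (!is.null(group)) {
    if (is.null(groups)) {
      stop("a groups table is required when filtering by group",
           call. = FALSE)
    }
    members <- groups$disease_id[groups$group == group]
    e <- e[e$disease_id %in% members, , drop = FALSE]
    truth <- truth[truth$disease_id %in% members, , drop = FALSE]
  }
  if (nrow(e) == 0) {
    stop("no predicted edges to evaluate",
         if (is.null(group)) "" else paste0(" in group '", group, "'"),
         call. = FALSE)
  }
  pred_keys <- paste(e$disease_id, e$lncrna_id, sep = "\t")
  truth_keys <- paste(truth$disease_id, truth$lncrna_id, sep = "\t")
  label <- as.integer(pred_keys %in% truth_keys)
  unscored <- sum(!(truth_keys %in% pred_keys))
  if (unscored > 0) {
    message(unscored, " validated pair(s) absent from the predictions (unscored positives)")
  }
  if (sum(label) == 0) {
    stop("no positives among the predicted edges: AUC undefined", call. = FALSE)
  }
  if (sum(label) == length(label)) {
    stop("no negatives among the predicted edges: AUC undefined", call. = FALSE)
  }
  data.frame(score = e$weight, label = label)
}

#' ROC curve and AUC from labelled scores
#'
#' Sweeps the distinct scores as thresholds (predict positive when
#' `score >= threshold`) to build the ROC curve, and computes the AUC as
#' the trapezoidal area, which equals the tie-corrected rank statistic
#' `(concordant + ties/2) / (n_pos * n_neg)`.
#'
#' @param labeled data frame with columns `score` (numeric) and `label`
#'   (0/1), as from [label_edges()].
#' @return a `roc_result`: list with `thresholds` (distinct scores,
#'   decreasing), `points` (data frame `fpr`, `tpr` from (0,0) to
#'   (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labeled) {
  stopifnot(is.data.frame(labeled),
            all(c("score", "label") %in% names(labeled)))
  score <- as.numeric(labeled$score)
  label <- as.integer(labeled$label)
  stopifnot(!anyNA(score), all(label %in% c(0L, 1L)))
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  # cumulative positives/negatives at score >= threshold
  ord <- order(score, decreasing = TRUE)
  s_sorted <- score[ord]
  l_sorted <- label[ord]
  cum_pos <- cumsum(l_sorted)
  cum_neg <- cumsum(1L - l_sorted)
  # last position of each run of tied scores = one ROC point per threshold
  n <- length(s_sorted)
  last_idx <- which(c(s_sorted[-n] != s_sorted[-1], TRUE))
  thresholds <- s_sorted[last_idx]
  tpr <- cum_pos[last_idx] / n_pos
  fpr <- cum_neg[last_idx] / n_neg
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  # trapezoid; ties in score give diagonal segments counted at half height
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + diff(points$tpr) / 2))
  structure(
    list(thresholds = thresholds, points = points, auc = auc,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Write a ROC curve as TSV
#'
#' Columns `threshold`, `fpr`, `tpr`; a trailing comment line carries the
#' AUC and label counts.
#'
#' @param roc a `roc_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  df <- data.frame(threshold = c(Inf, roc$thresholds),
                   fpr = roc$points$fpr, tpr = roc$points$tpr)
  lines <- c("threshold\tfpr\ttpr",
             sprintf("%.17g\t%.17g\t%.17g", df$threshold, df$fpr, df$tpr),
             sprintf("# AUC=%.6f n_pos=%d n_neg=%d", roc$auc, roc$n_pos,
                     roc$n_neg))
  writeLines(lines, path)
  invisible(path)
}

#' Node-label-shuffled null model of the predicted network
#'
#' Applies one uniform random permutation to the lncRNA labels and one to
#' the disease labels of the bipartite predicted network. The unlabelled
#' graph -- degree sequences and the weights attached to graph positions
#' -- is unchanged; only node identities move, which destroys any
#' biological signal while preserving connectivity structure.
#'
#' @param ldn a `lnc_disease_network`.
#' @param rng_seed integer seed; the shuffle is reproducible byte-for-byte.
#' @param lnc_perm,disease_perm optional explicit permutations (named
#'   character vectors mapping old label to new label), overriding the
#'   random draw; intended for tests.
#' @return a shuffled `lnc_disease_network`.
#' @export
shuffle_labels <- function(ldn, rng_seed, lnc_perm = NULL,
                           disease_perm = NULL) {
  stopifnot(inherits(ldn, "lnc_disease_network"))
  e <- ldn$edges
  lncs <- radix_sort(unique(e$lncrna_id))
  diseases <- radix_sort(unique(e$disease_id))
  if (is.null(lnc_perm) || is.null(disease_perm)) {
    withr::with_seed(as.integer(rng_seed), {
      if (is.null(lnc_perm)) lnc_perm <- setNames(sample(lncs), lncs)
      if (is.null(disease_perm)) {
        disease_perm <- setNames(sample(diseases), diseases)
      }
    })
  }
  stopifnot(setequal(names(lnc_perm), lncs), setequal(lnc_perm, lncs),
            setequal(names(disease_perm), diseases),
            setequal(disease_perm, diseases))
  e$lncrna_id <- unname(lnc_perm[e$lncrna_id])
  e$disease_id <- unname(disease_perm[e$disease_id])
  new_ldn(e)
}

#' Two-sided Wilcoxon rank-sum comparison of two weight samples
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration when both
#' samples are small (< 50) and tie-free, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b non-empty numeric vectors (e.g. two sets of predicted edge
#'   weights).
#' @return a `rank_sum_result`: list with `statistic` (the Mann-Whitney U
#'   of the first sample), `p_value`, `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @export
rank_sum <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) < 50 && length(b) < 50
  ht <- wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE)
  structure(
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal-approximation"),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> U = %g, two-sided p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}
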