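#' ROC curve and AUC
#'
#' Area under the ROC curve by the rank-sum (Mann-Whitney) statistic,
#' AUC = U / (n+ n-), which equals trapezoidal integration of the ROC
#' over all score thresholds and gives tied scores half credit.  ROC
#' points are returned per distinct threshold (ties collapse onto one
#' point, so the curve cuts diagonally through tie blocks).
#'
#' @param scores numeric vector of prediction scores.
#' @param labels binary vector (1 = known association) of the same
#'   length; both classes must be present.
#' @return List with `auc` and `roc_points` (data.frame of fpr, tpr,
#'   monotone non-decreasing, from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels != 0)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need at least one positive and one negative")
  r <- rank(scores)  # midranks give ties half credit
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie block
  tpr <- cumsum(l)[last] / n1
  fpr <- cumsum(1 - l)[last] / n0
  list(auc = unname(auc),
       roc_points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

# ROC/AUC from normalized candidate ranks: u[f] in [0,1] is the
# tie-adjusted fraction of candidate (negative) pairs scoring above the
# f-th held-out pair; AUC = mean(1 - u) (mean per-fold AUC, the pooled
# rank-threshold ROC of global cross-validation)
roc_from_ranks <- function(u) {
  u <- sort(u)
  n <- length(u)
  list(auc = 1 - mean(u),
       roc_points = data.frame(fpr = c(0, u, 1),
                               tpr = c(0, seq_len(n) / n, 1)))
}

# normalized rank of score s among candidate scores (0 = top)
normalized_rank <- function(s, candidates) {
  if (!length(candidates)) return(0)
  (sum(candidates > s) + 0.5 * sum(candidates == s)) / length(candidates)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is removed in turn, the kernels, functional
#' similarity and scores are recomputed without it (no leakage), and
#' the left-out pair's score is ranked against all pairs that are
#' unknown in the full association matrix, pooled across all diseases.
#' Ranks aggregate into a single ROC: the curve's threshold sweeps the
#' rank cutoff and the AUC is the mean tie-adjusted exceedance of
#' left-out pairs over candidates.
#'
#' @param adjacency full binary lncRNA x disease association matrix.
#' @param ss disease semantic similarity matrix.
#' @param config a [predictor_config()].
#' @param expression optional lncRNA expression similarity.
#' @param recompute recompute kernels/FS per fold (default TRUE).
#'   FALSE is a fast smoke-test mode that *leaks* the held-out
#'   association into the similarities; never use it for reported
#'   results.
#' @return List of class `cv_result`: `auc_values`, `mean_auc`,
#'   `std_auc`, `roc_points`, `ranks` (per-fold normalized ranks).
#' @export
global_loocv <- function(adjacency, ss, config = predictor_config(),
                         expression = NULL, recompute = TRUE) {
  known <- which(adjacency == 1L, arr.ind = TRUE)
  if (nrow(known) < 2L) stop("need at least 2 known associations")
  cand <- adjacency == 0L
  base_scores <- if (!recompute)
    score_associations(adjacency, ss, expression = expression,
                       config = config)
  u <- numeric(nrow(known))
  for (f in seq_len(nrow(known))) {
    y <- adjacency
    y[known[f, 1L], known[f, 2L]] <- 0L
    sc <- if (recompute) {
      tryCatch(
        score_associations(y, ss, expression = expression, config = config),
        error = function(e) stop("pipeline failure at fold ", f, ": ",
                                 conditionMessage(e)))
    } else base_scores
    u[f] <- normalized_rank(sc[known[f, 1L], known[f, 2L]], sc[cand])
  }
  r <- roc_from_ranks(u)
  structure(list(auc_values = r$auc, mean_auc = r$auc, std_auc = 0,
                 roc_points = r$roc_points, ranks = u),
            class = "cv_result")
}

#' Repeated k-fold cross-validation
#'
#' Per repetition the known associations are randomly partitioned into
#' `k` folds; each fold is held out once, the model retrained on the
#' rest, and each held-out pair ranked against the never-known pairs.
#' One AUC is recorded per repetition (folds pooled).  A single seed
#' drives all partitioning: repetition r uses the derived seed
#' `seed + r`, so any repetition is reproducible in isolation.
#'
#' @inheritParams global_loocv
#' @param k number of folds (>= 2).
#' @param repetitions number of random re-partitions.
#' @param seed integer RNG seed.
#' @return A `cv_result` with one AUC per repetition plus mean and sd.
#' @export
kfold_cv <- function(adjacency, ss, k = 5L, repetitions = 1L,
                     seed = 1L, config = predictor_config(),
                     expression = NULL, recompute = TRUE) {
  stopifnot(k >= 2L, repetitions >= 1L)
  known <- which(adjacency == 1L, arr.ind = TRUE)
  if (nrow(known) < k) stop("fewer associations than folds")
  cand <- adjacency == 0L
  aucs <- numeric(repetitions)
  roc <- NULL
  for (rep_i in seq_len(repetitions)) {
    set.seed(seed + rep_i)
    fold_of <- sample(rep_len(seq_len(k), nrow(known)))
    u <- numeric(nrow(known))
    base_scores <- if (!recompute)
      score_associations(adjacency, ss, expression = expression,
                         config = config)
    for (fold in seq_len(k)) {
      test <- which(fold_of == fold)
      y <- adjacency
      y[known[test, , drop = FALSE]] <- 0L
      sc <- if (recompute)
        score_associations(y, ss, expression = expression, config = config)
      else base_scores
      for (f in test)
        u[f] <- normalized_rank(sc[known[f, 1L], known[f, 2L]], sc[cand])
    }
    r <- roc_from_ranks(u)
    aucs[rep_i] <- r$auc
    if (is.null(roc)) roc <- r$roc_points  # representative first repetition
  }
  structure(list(auc_values = aucs, mean_auc = mean(aucs),
                 std_auc = if (repetitions > 1L) sd(aucs) else 0,
                 roc_points = roc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d AUC value(s), mean %.4f, sd %.4f\n",
              length(x$auc_values), x$mean_auc, x$std_auc))
  invisible(x)
}

#' Top-k candidate lncRNAs for a disease
#'
#' Candidates are lncRNAs not already known-associated with the
#' disease, sorted by descending score; ties break lexicographically
#' for determinism.
#'
#' @param scores score matrix (lncRNAs x diseases).
#' @param adjacency binary known-association matrix of the same shape.
#' @param disease a disease ID (column name).
#' @param top_k number of candidates to return.
#' @return data.frame (disease, lncrna, score, rank), ranks from 1.
#' @export
rank_candidates <- function(scores, adjacency, disease, top_k = 20L) {
  if (!disease %in% colnames(scores)) stop("unknown disease: ", disease)
  is_cand <- adjacency[, disease] == 0L
  ids <- rownames(scores)[is_cand]
  sc <- scores[is_cand, disease]
  ord <- order(-sc, ids)
  n <- min(top_k, length(ids))
  if (n == 0L)
    return(data.frame(disease = character(0), lncrna = character(0),
                      score = numeric(0), rank = integer(0)))
  data.frame(disease = disease, lncrna = ids[ord][seq_len(n)],
             score = sc[ord][seq_len(n)], rank = seq_len(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a cross-validation result
#'
#' Writes `<prefix>.json` (summary), `<prefix>_auc.tsv` (per-run AUCs)
#' and `<prefix>_roc.tsv` (ROC points).
#'
#' @param cv a `cv_result`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_cv_result <- function(cv, prefix) {
  jp <- paste0(prefix, ".json")
  jsonlite::write_json(list(mean_auc = cv$mean_auc, std_auc = cv$std_auc,
                            n_runs = length(cv$auc_values)),
                       jp, auto_unbox = TRUE, digits = NA)
  ap <- paste0(prefix, "_auc.tsv")
  write.table(data.frame(run = seq_along(cv$auc_values),
                         auc = cv$auc_values),
              ap, sep = "\t", quote = FALSE, row.names = FALSE)
  rp <- paste0(prefix, "_roc.tsv")
  write.table(cv$roc_points, rp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(json = jp, auc = ap, roc = rp))
}
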