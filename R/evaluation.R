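#' Select the most abundant species
#'
#' Returns the indices of the `k` species with the largest time-averaged
#' abundance in the analyzed window, in descending order of abundance;
#' ties are broken towards the lower species index.
#'
#' @param series numeric matrix, time points by species.
#' @param k number of species to keep.
#' @return Integer vector of length `k`.
#' @export
top_k_species <- function(series, k = 5) {
  x <- unclass(series)
  n <- ncol(x)
  if (k > n) stop("k exceeds the number of species")
  m <- colMeans(x)
  order(-m, seq_len(n))[seq_len(k)]
}

#' ROC-AUC with midrank tie handling
#'
#' The rank (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive is scored above a randomly chosen negative, with ties
#' counted half.  Larger scores must indicate presence; rank p-value
#' classifiers by passing their negation.
#'
#' @param scores numeric classifier scores, one per candidate pair.
#' @param labels logical (or 0/1) truth per pair.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when the truth is
#'   degenerate (all positive or all negative).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) {
    warning("degenerate truth: all positive or all negative")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision when half of the candidates are selected
#'
#' Ranks the candidate pairs by score (descending; ties broken by lower
#' index, i.e. row-major order of the pair list) and reports the fraction
#' of true interactions among the selected top half.
#'
#' @inheritParams roc_auc
#' @param k number of selected pairs (default half, rounded down).
#' @return Precision in `[0, 1]`, or `NA` for degenerate truth.
#' @export
precision_at_half <- function(scores, labels, k = floor(length(scores) / 2)) {
  labels <- as.logical(labels)
  if (sum(labels) == 0 || sum(!labels) == 0) {
    warning("degenerate truth: all positive or all negative")
    return(NA_real_)
  }
  ord <- order(-scores, seq_along(scores))
  sum(labels[ord[seq_len(k)]]) / k
}

# Flatten the off-diagonal entries of an n x n matrix in row-major order
# (the canonical candidate-pair ordering used throughout evaluation).
offdiag_pairs <- function(mat) {
  n <- nrow(mat)
  idx <- which(row(mat) != col(mat))
  ord <- order(row(mat)[idx], col(mat)[idx])
  list(values = mat[idx][ord],
       i = row(mat)[idx][ord], j = col(mat)[idx][ord])
}

#' Build classifier scores for one community and method
#'
#' Restricts the truth and the inferred matrices to the `top_k` most
#' abundant species and flattens the off-diagonal entries (row-major) into
#' parallel score/label vectors.  Statistic classifiers are ranked by
#' absolute value by default (detection, not sign); p-value classifiers
#' are ranked ascending (scores are negated p-values).
#'
#' @param series the sampled series the inference ran on.
#' @param truth_presence logical full-community presence matrix.
#' @param result an `inference_result`.
#' @param classifier `"stat"` or `"pval"`.
#' @param top_k number of most abundant species retained.
#' @param abs_stat rank statistics by absolute value.
#' @return A list with `scores`, `labels`, `species` (the retained
#'   indices) and `n_positive`.
#' @export
evaluation_task <- function(series, truth_presence, result,
                            classifier = c("stat", "pval"), top_k = 5,
                            abs_stat = TRUE) {
  classifier <- match.arg(classifier)
  sel <- sort(top_k_species(series, top_k))
  truth <- truth_presence[sel, sel, drop = FALSE]
  mat <- if (classifier == "stat") {
    s <- result$stat[sel, sel, drop = FALSE]
    if (abs_stat) abs(s) else s
  } else {
    -result$pval[sel, sel, drop = FALSE]
  }
  labels <- offdiag_pairs(truth)$values
  scores <- offdiag_pairs(mat)$values
  list(scores = scores, labels = as.logical(labels), species = sel,
       n_positive = sum(labels))
}

#' Score one community with one inference result
#'
#' @inheritParams evaluation_task
#' @return A one-row data.frame with `auc`, `precision_half` and
#'   `positives`, or NA metrics when the top-k truth is degenerate.
#' @export
evaluate_community <- function(series, truth_presence, result,
                               classifier = "stat", top_k = 5,
                               abs_stat = TRUE) {
  task <- evaluation_task(series, truth_presence, result, classifier,
                          top_k, abs_stat)
  degenerate <- task$n_positive == 0 ||
    task$n_positive == length(task$labels)
  if (degenerate) {
    auc <- NA_real_; prec <- NA_real_
  } else {
    auc <- roc_auc(task$scores, task$labels)
    prec <- precision_at_half(task$scores, task$labels)
  }
  data.frame(classifier = classifier, auc = auc, precision_half = prec,
             positives = task$n_positive, degenerate = degenerate)
}

#' Run inference methods over a benchmark dataset and score them
#'
#' For every community in the dataset and every requested method, runs the
#' inference on the sampled series and scores both the statistic and the
#' p-value classifier against the community's ground-truth presence on the
#' top-5 submatrix.
#'
#' @param ds a `benchmark_dataset`.
#' @param methods character vector of method names (see [infer_network()]).
#' @param cfgs named list of per-method configuration objects.
#' @param seed master seed; per-community, per-method seeds are derived
#'   from it.
#' @param top_k evaluated submatrix size.
#' @return A data.frame of benchmark records (one row per community,
#'   method and classifier).
#' @export
evaluate_dataset <- function(ds, methods = c("pearson", "spearman", "lsa",
                                             "ccm", "limits"),
                             cfgs = list(), seed = 1L, top_k = 5) {
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max,
                      length(ds$entries) * length(methods)),
           length(ds$entries), length(methods)))
  rows <- list()
  for (k in seq_along(ds$entries)) {
    e <- ds$entries[[k]]
    for (mi in seq_along(methods)) {
      method <- methods[mi]
      res <- infer_network(e$series, method, cfg = cfgs[[method]],
                           seed = seeds[k, mi])
      for (cl in c("stat", "pval")) {
        rec <- evaluate_community(e$series, e$truth$presence, res, cl, top_k)
        rec <- cbind(data.frame(model_id = ds$model_id, tau = ds$tau,
                                sigma = ds$sigma, community = k,
                                method = method), rec)
        rows[[length(rows) + 1]] <- rec
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize benchmark records
#'
#' Groups records by model, method and classifier kind; reports the group
#' medians of the chosen metric, all pairwise median differences
#' (antisymmetric: row minus column) and two-sided Mann-Whitney p-values
#' with a significance flag at p < 0.05.  No multiple-testing correction
#' is applied.
#'
#' @param records a data.frame from [evaluate_dataset()].
#' @param metric `"auc"` or `"precision_half"`.
#' @return A list of class `summary_table` with `medians` (data.frame),
#'   `diff` (matrix), `pval` (matrix) and `signif` (logical matrix).
#' @export
summarize_records <- function(records, metric = c("auc", "precision_half")) {
  metric <- match.arg(metric)
  records <- records[!is.na(records[[metric]]), , drop = FALSE]
  key <- interaction(records$model_id, records$method, records$classifier,
                     drop = TRUE, sep = ":")
  groups <- split(records[[metric]], key)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  g <- length(groups)
  meds <- vapply(groups, median, numeric(1))
  diff <- outer(meds, meds, "-")
  pmat <- matrix(NA_real_, g, g, dimnames = list(names(groups),
                                                 names(groups)))
  for (a in seq_len(g)) {
    for (b in seq_len(g)) {
      if (a == b) next
      if (length(groups[[a]]) >= 2 && length(groups[[b]]) >= 2) {
        pmat[a, b] <- suppressWarnings(
          wilcox.test(groups[[a]], groups[[b]], exact = FALSE)$p.value)
      }
    }
  }
  structure(list(medians = data.frame(group = names(groups),
                                      median = unname(meds)),
                 diff = diff, pval = pmat,
                 signif = !is.na(pmat) & pmat < 0.05,
                 metric = metric),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("summary_table (", x$metric, "):\n", sep = "")
  print(x$medians)
  invisible(x)
}

#' Write benchmark records and summaries to disk
#'
#' Records go to one CSV (a row per community/method/classifier); each
#' summary's median-difference and p-value matrices go to their own CSVs,
#' and a JSON manifest records what was run.
#'
#' @param records data.frame from [evaluate_dataset()].
#' @param summary a `summary_table` (optional).
#' @param dir output directory.
#' @export
write_records <- function(records, dir, summary = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  if (!is.null(summary)) {
    utils::write.csv(summary$medians, file.path(dir, "medians.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summary$diff),
                     file.path(dir, "median_diff.csv"))
    utils::write.csv(as.data.frame(summary$pval),
                     file.path(dir, "mann_whitney_p.csv"))
  }
  manifest <- list(n_records = nrow(records),
                   models = unique(records$model_id),
                   methods = unique(records$method))
  jsonlite::write_json(manifest, file.path(dir, "run.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
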