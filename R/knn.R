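#' Levenshtein edit distance
#'
#' Number of single-character insertions, deletions and substitutions needed
#' to turn one sequence into the other. Computed with [utils::adist()]
#' (generalized edit distance with unit costs); vectorized over both
#' arguments, returning the full distance matrix when both have length > 1.
#'
#' @param a,b Character vectors.
#' @return If both inputs have length 1, a single non-negative integer;
#'   otherwise a `length(a)` x `length(b)` integer matrix.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1L && length(b) == 1L) as.integer(d[1L, 1L])
  else structure(as.integer(d), dim = dim(d))
}

#' Combined length-normalized pair distance
#'
#' Distance between a stored (epitope, TCR) pair and a query pair: the
#' Levenshtein distance between the epitopes plus the Levenshtein distance
#' between the TCRs, each normalized by the length of the *query* sequence,
#' \deqn{D = Lev(e_1, e_2)/|e_2| + Lev(t_1, t_2)/|t_2|.}
#' The normalization by the query lengths makes the measure asymmetric when
#' lengths differ; `symmetric = TRUE` instead normalizes each term by the
#' mean of the two lengths.
#'
#' @param e1,t1 Epitope and TCR of the stored (training) pair.
#' @param e2,t2 Epitope and TCR of the query (test) pair; must be non-empty
#'   since their lengths are the normalizers.
#' @param symmetric Use the length-symmetric variant (default `FALSE`).
#' @return Non-negative numeric distance (vectorized over equal-length
#'   inputs).
#' @export
pair_distance <- function(e1, t1, e2, t2, symmetric = FALSE) {
  if (any(!nzchar(e2)) || any(!nzchar(t2)))
    stop("query sequences must be non-empty (their lengths normalize the distance)")
  de <- diag_adist(e1, e2)
  dt <- diag_adist(t1, t2)
  if (symmetric) {
    de / ((nchar(e1) + nchar(e2)) / 2) + dt / ((nchar(t1) + nchar(t2)) / 2)
  } else {
    de / nchar(e2) + dt / nchar(t2)
  }
}

# elementwise adist for equal-length (after recycling) vectors
#' @keywords internal
diag_adist <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- utils::adist(x[i], y[i])[1L, 1L]
  out
}

#' Fit the Levenshtein k-nearest-neighbour baseline
#'
#' A non-parametric classifier: the binding score of a query (epitope, TCR)
#' pair is the mean label of its `k` nearest training pairs under
#' [pair_distance()]. `k` is odd so that binary votes cannot tie.
#'
#' @param records Binding records: a data frame with columns `epitope`,
#'   `tcr` and `label` (0/1).
#' @param k Odd positive neighbourhood size, at most the number of records.
#' @param symmetric Use the symmetric distance variant (see
#'   [pair_distance()]).
#' @return An object of class `titan_knn`.
#' @seealso [predict.titan_knn()], [select_best_k()]
#' @export
knn_model <- function(records, k = 13L, symmetric = FALSE) {
  records <- validate_records(records, require_label = TRUE)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("'k' must be an odd positive integer")
  if (k > nrow(records))
    stop(sprintf("k = %d exceeds the number of training records (%d)", k, nrow(records)))
  structure(list(records = records, k = k, symmetric = symmetric),
            class = "titan_knn")
}

#' Predict binding scores with the K-NN baseline
#'
#' @param object A fitted [knn_model()].
#' @param newdata Data frame with columns `epitope` and `tcr`.
#' @param k Override the stored neighbourhood size (odd integer), or a
#'   vector of odd k values to score several neighbourhood sizes at once.
#' @param type `"score"` for the fraction of positive neighbours in [0, 1],
#'   `"class"` for the binary call at threshold 0.5.
#' @param ... Unused.
#' @return For a single `k`, a numeric vector of scores (or 0/1 calls);
#'   for several k values, a matrix with one column per k.
#' @details Neighbour ties at the k-th distance rank are broken by stable
#'   training order: among equidistant records the earlier training row wins.
#' @export
predict.titan_knn <- function(object, newdata, k = object$k,
                              type = c("score", "class"), ...) {
  type <- match.arg(type)
  k <- as.integer(k)
  if (any(k < 1L | k %% 2L == 0L)) stop("'k' must be odd and positive")
  if (any(k > nrow(object$records)))
    stop(sprintf("k exceeds the number of training records (%d)", nrow(object$records)))
  newdata <- validate_records(newdata, require_label = FALSE)
  D <- pair_distance_matrix(object$records, newdata, symmetric = object$symmetric)
  labels <- object$records$label
  kmax <- max(k)
  scores <- matrix(NA_real_, nrow(newdata), length(k),
                   dimnames = list(NULL, paste0("k", k)))
  for (j in seq_len(nrow(newdata))) {
    ord <- order(D[, j], seq_len(nrow(D)))[seq_len(kmax)]
    lab <- labels[ord]
    scores[j, ] <- cumsum(lab)[k] / k
  }
  if (length(k) == 1L) scores <- unname(drop(scores))
  if (type == "class") scores <- as.integer(scores > 0.5)
  scores
}

# Full training x query distance matrix under the combined normalized
# distance. Computes Levenshtein blocks on unique sequences only.
#' @keywords internal
pair_distance_matrix <- function(train, query, symmetric = FALSE) {
  ue_tr <- unique(train$epitope); ue_q <- unique(query$epitope)
  de <- utils::adist(ue_tr, ue_q)
  de_full <- de[match(train$epitope, ue_tr), match(query$epitope, ue_q), drop = FALSE]
  dt_full <- utils::adist(train$tcr, query$tcr)
  if (symmetric) {
    ne <- outer(nchar(train$epitope), nchar(query$epitope), `+`) / 2
    nt <- outer(nchar(train$tcr), nchar(query$tcr), `+`) / 2
    de_full / ne + dt_full / nt
  } else {
    sweep(de_full, 2L, nchar(query$epitope), `/`) +
      sweep(dt_full, 2L, nchar(query$tcr), `/`)
  }
}

#' @export
print.titan_knn <- function(x, ...) {
  cat(sprintf("Levenshtein K-NN binding classifier (k = %d%s)\n", x$k,
              if (x$symmetric) ", symmetric distance" else ""))
  cat(sprintf("  training records: %d (%d positive / %d negative), %d epitopes\n",
              nrow(x$records), sum(x$records$label == 1),
              sum(x$records$label == 0), length(unique(x$records$epitope))))
  invisible(x)
}

#' Sweep the neighbourhood size of the K-NN baseline
#'
#' Evaluates every odd k in `ks` by cross-validation (train on all folds but
#' one, score the held-out fold, ROC-AUC as the ranking metric) and returns
#' the k with the best mean ROC-AUC; ties go to the smaller k.
#'
#' @param records Labelled binding records (data frame with `epitope`,
#'   `tcr`, `label`).
#' @param folds Integer fold id per record (e.g. from [make_folds()] via
#'   [apply_folds()]).
#' @param ks Candidate neighbourhood sizes; default all odd k from 1 to 25.
#' @param symmetric Passed to [knn_model()].
#' @return A list with `best_k` and `table`, a data frame with one row per
#'   k giving the mean and population SD of the fold ROC-AUCs.
#' @export
select_best_k <- function(records, folds, ks = seq(1L, 25L, by = 2L),
                          symmetric = FALSE) {
  records <- validate_records(records, require_label = TRUE)
  stopifnot(length(folds) == nrow(records))
  fold_ids <- sort(unique(folds))
  if (length(fold_ids) < 2L) stop("need at least two folds to sweep k")
  aucs <- matrix(NA_real_, length(fold_ids), length(ks))
  for (i in seq_along(fold_ids)) {
    f <- fold_ids[i]
    tr <- records[folds != f, , drop = FALSE]
    te <- records[folds == f, , drop = FALSE]
    if (length(unique(te$label)) < 2L) next
    m <- knn_model(tr, k = max(ks[ks <= nrow(tr)]), symmetric = symmetric)
    sc <- predict(m, te, k = ks[ks <= nrow(tr)])
    if (is.null(dim(sc))) sc <- matrix(sc, ncol = 1L)
    for (j in seq_len(ncol(sc)))
      aucs[i, j] <- evaluate(sc[, j], te$label)$roc_auc
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  tab <- data.frame(k = ks, mean_roc_auc = mean_auc,
                    sd_roc_auc = apply(aucs, 2L, pop_sd_na))
  best_k <- ks[which.max(mean_auc)]  # which.max takes the first (smallest k) on ties
  list(best_k = best_k, table = tab)
}

#' @keywords internal
pop_sd_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
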