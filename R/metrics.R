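# Correlation, ranking and classification metrics, stratified by
# mutation category and aggregated across predictor replicates.
# Undefined metrics (zero variance, degenerate marginals) are NA, never 0.

check_paired <- function(exp, pred, min_n = 3) {
  if (length(exp) != length(pred)) {
    stop("exp and pred must have equal length", call. = FALSE)
  }
  if (any(!is.finite(exp)) || any(!is.finite(pred))) {
    stop("exp and pred must be finite", call. = FALSE)
  }
  if (length(exp) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  invisible(NULL)
}

#' Pearson correlation between experiment and prediction
#'
#' Sample Pearson correlation; returns `NA` (the undefined-metric marker)
#' when either vector has zero variance.
#'
#' @param exp,pred Equal-length finite numeric vectors (n >= 3).
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(exp, pred) {
  check_paired(exp, pred)
  if (sd(exp) == 0 || sd(pred) == 0) return(NA_real_)
  cor(exp, pred)
}

#' Pearson correlation after dropping the largest errors
#'
#' Removes the `drop_fraction` of entries with the largest absolute
#' prediction error |pred - exp| (`floor(n * drop_fraction)` entries;
#' ties at the cut resolved in record order) and recomputes the Pearson
#' correlation. A robustified view that discounts a few gross outliers.
#'
#' @param exp,pred Equal-length finite numeric vectors.
#' @param drop_fraction Fraction of entries to drop (default 0.10).
#' @return Correlation of the retained entries, or `NA` when undefined.
#' @export
filtered_pearson <- function(exp, pred, drop_fraction = 0.10) {
  check_paired(exp, pred)
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  k <- floor(length(exp) * drop_fraction)
  if (k > 0) {
    drop <- order(abs(pred - exp), decreasing = TRUE)[seq_len(k)]
    exp <- exp[-drop]
    pred <- pred[-drop]
  }
  if (length(exp) < 3) {
    stop("fewer than 3 entries remain after filtering", call. = FALSE)
  }
  if (sd(exp) == 0 || sd(pred) == 0) return(NA_real_)
  cor(exp, pred)
}

#' Predictive Index
#'
#' Pairwise ranking metric: every pair (i, j) is weighted by the
#' experimental difference |exp_j - exp_i| and scores +1 when prediction
#' and experiment rank the pair the same way, -1 when opposite, and 0
#' when the predictions tie. PI = sum(w * c) / sum(w), in \[-1, 1\];
#' large experimental differences dominate, so getting the big
#' separations right matters most.
#'
#' @param exp,pred Equal-length finite numeric vectors (n >= 2).
#' @return PI in \[-1, 1\], or `NA` when all `exp` values are equal.
#' @export
#' @examples
#' predictive_index(c(0, 1, 3), c(0, 2, 1))  # 1/3
predictive_index <- function(exp, pred) {
  check_paired(exp, pred, min_n = 2)
  de <- outer(exp, exp, "-")
  dp <- outer(pred, pred, "-")
  up <- upper.tri(de)
  w <- abs(de[up])
  if (sum(w) == 0) return(NA_real_)
  cc <- sign(de[up]) * sign(dp[up])
  sum(w * cc) / sum(w)
}

#' Matthews correlation coefficient over stability classes
#'
#' Multiclass (3x3) MCC over the ordinal stability classes
#' (destabilizing 0 / neutral 1 / stabilizing 2): with confusion matrix
#' C, sample count s, trace c, and true/predicted marginals t_k / p_k,
#' MCC = (c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2))).
#' `mode = "binary"` instead collapses to stabilizing vs not and applies
#' the classical two-class formula.
#'
#' @param truth,pred Equal-length integer vectors of classes in
#'   `{0, 1, 2}` (see [classify_ddg()]).
#' @param mode `"multiclass"` (default) or `"binary"`.
#' @return MCC in \[-1, 1\], or `NA` when a marginal degenerates.
#' @export
mcc <- function(truth, pred, mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  if (length(truth) != length(pred) || length(truth) < 2) {
    stop("truth and pred must have equal length >= 2", call. = FALSE)
  }
  if (!all(truth %in% 0:2) || !all(pred %in% 0:2)) {
    stop("classes must be in {0, 1, 2}", call. = FALSE)
  }
  if (mode == "binary") {
    truth <- as.integer(truth == 2L)
    pred <- as.integer(pred == 2L)
    lev <- 0:1
  } else {
    lev <- 0:2
  }
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  denom2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (denom2 <= 0) return(NA_real_)
  (c_ * s - sum(p_k * t_k)) / sqrt(denom2)
}

join_predictions <- function(records, predictions) {
  miss <- setdiff(records$record_id, predictions$record_id)
  if (length(miss)) {
    stop("no prediction for record(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(predictions$record_id, records$record_id)
  if (length(orphan)) {
    stop("prediction(s) with no matching record: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  predictions[match(records$record_id, predictions$record_id), , drop = FALSE]
}

#' Per-category classification-error table
#'
#' For every category of the benchmark, the percentage of entries whose
#' prediction lands in the same stability class (error 0), one class off
#' (error 1), or on the opposite extreme (error 2, "egregious").
#'
#' @param benchmark A `benchmark_set`.
#' @param predictions Data frame (`record_id`, `ddg_pred`) covering every
#'   benchmark record; a single replicate.
#' @param scale Optional `c(slope, intercept)` applied to `ddg_pred`
#'   before classification (default identity).
#' @return Data frame with columns `category`, `n_entries`,
#'   `pct_same_class`, `pct_off_by_one`, `pct_off_by_two` in report
#'   order (categories with entries only).
#' @export
classification_table <- function(benchmark, predictions,
                                 scale = c(1, 0)) {
  stopifnot(inherits(benchmark, "benchmark_set"))
  rec <- benchmark$records
  pr <- join_predictions(rec, predictions)
  pred <- scale[1] * pr$ddg_pred + scale[2]
  err <- classification_error(rec$ddg_exp, pred)
  names(err) <- rec$record_id
  rows <- lapply(names(benchmark$category_index), function(cat) {
    ids <- benchmark$category_index[[cat]]
    if (!length(ids)) return(NULL)
    e <- err[ids]
    data.frame(category = cat, n_entries = length(ids),
               pct_same_class = 100 * mean(e == 0),
               pct_off_by_one = 100 * mean(e == 1),
               pct_off_by_two = 100 * mean(e == 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

metric_row <- function(category, exp, pred, drop_fraction, mcc_mode) {
  n <- length(exp)
  safe <- function(f) tryCatch(f, error = function(e) NA_real_)
  err <- classification_error(exp, pred)
  data.frame(
    category = category,
    pearson_r = safe(pearson_r(exp, pred)),
    pearson_r_filtered = safe(filtered_pearson(exp, pred, drop_fraction)),
    predictive_index = safe(predictive_index(exp, pred)),
    mcc = safe(mcc(classify_ddg(exp), classify_ddg(pred), mode = mcc_mode)),
    pct_same_class = 100 * mean(err == 0),
    pct_off_by_one = 100 * mean(err == 1),
    pct_off_by_two = 100 * mean(err == 2),
    n_entries = n,
    stringsAsFactors = FALSE)
}

#' Evaluate predictions against a benchmark, by category and replicate
#'
#' Computes, for every category with entries and every replicate, the
#' full metric row (Pearson's R, filtered Pearson's R, Predictive Index,
#' MCC, and the same/off-by-one/off-by-two percentages), then summarises
#' across replicates as mean and standard deviation per metric. Also
#' tallies the global off-by-one and egregious (off-by-two) error counts
#' per replicate.
#'
#' @param benchmark A `benchmark_set`.
#' @param predictions Data frame (`record_id`, `ddg_pred`, `replicate`)
#'   covering every benchmark record in every replicate.
#' @param scale `c(slope, intercept)` rescaling predictions to kcal/mol
#'   before classification (default identity: predictors already on the
#'   experimental scale).
#' @param drop_fraction Outlier fraction for the filtered Pearson
#'   (default 0.10).
#' @param mcc_mode `"multiclass"` or `"binary"`, see [mcc()].
#' @return A `ddg_evaluation`: list with `per_replicate` (metric rows per
#'   replicate), `summary` (per-category mean and sd columns `<metric>`
#'   and `<metric>_sd`), `error_counts` (per replicate off-by-one /
#'   off-by-two totals plus their means), and `n_replicates`.
#' @export
evaluate_predictions <- function(benchmark, predictions, scale = c(1, 0),
                                 drop_fraction = 0.10,
                                 mcc_mode = c("multiclass", "binary")) {
  stopifnot(inherits(benchmark, "benchmark_set"))
  mcc_mode <- match.arg(mcc_mode)
  if (!"replicate" %in% names(predictions)) predictions$replicate <- 1L
  reps <- sort(unique(predictions$replicate))
  rec <- benchmark$records
  per_rep <- list()
  counts <- list()
  for (r in reps) {
    pr <- join_predictions(rec,
                           predictions[predictions$replicate == r, ,
                                       drop = FALSE])
    pred <- scale[1] * pr$ddg_pred + scale[2]
    exp <- rec$ddg_exp
    names(pred) <- rec$record_id
    names(exp) <- rec$record_id
    rows <- lapply(names(benchmark$category_index), function(cat) {
      ids <- benchmark$category_index[[cat]]
      if (!length(ids)) return(NULL)
      metric_row(cat, unname(exp[ids]), unname(pred[ids]),
                 drop_fraction, mcc_mode)
    })
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    tab$replicate <- r
    per_rep[[as.character(r)]] <- tab
    err <- classification_error(exp, pred)
    counts[[as.character(r)]] <- data.frame(
      replicate = r, off_by_one = sum(err == 1), off_by_two = sum(err == 2),
      stringsAsFactors = FALSE)
  }
  per_rep <- do.call(rbind, c(per_rep, list(make.row.names = FALSE)))
  counts <- do.call(rbind, c(counts, list(make.row.names = FALSE)))
  metrics <- c("pearson_r", "pearson_r_filtered", "predictive_index", "mcc",
               "pct_same_class", "pct_off_by_one", "pct_off_by_two")
  cats <- unique(per_rep$category)
  summ <- lapply(cats, function(cat) {
    sub <- per_rep[per_rep$category == cat, , drop = FALSE]
    out <- data.frame(category = cat, stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- sub[[m]]
      out[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- if (length(reps) == 1 || all(is.na(v))) {
        if (all(is.na(v))) NA_real_ else 0
      } else {
        sd(v, na.rm = TRUE)
      }
    }
    out$n_entries <- sub$n_entries[1]
    out
  })
  summ <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  structure(list(per_replicate = per_rep, summary = summ,
                 error_counts = list(
                   per_replicate = counts,
                   mean_off_by_one = mean(counts$off_by_one),
                   mean_off_by_two = mean(counts$off_by_two)),
                 n_replicates = length(reps)),
            class = "ddg_evaluation")
}

#' @export
print.ddg_evaluation <- function(x, ...) {
  cat(sprintf("<ddg_evaluation> %d categories x %d replicate(s)\n",
              length(unique(x$summary$category)), x$n_replicates))
  cat(sprintf("mean off-by-one errors: %.1f, mean egregious errors: %.1f\n",
              x$error_counts$mean_off_by_one,
              x$error_counts$mean_off_by_two))
  cat(render_report(x, format = "tsv"))
  invisible(x)
}
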