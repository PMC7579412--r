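# Report rendering: evaluation tables in the fixed category order,
# correlations to 2 decimals with replicate sd after a plus-minus sign,
# percentages to 1 decimal, undefined metrics printed as NA.

fmt_metric <- function(mean, sd, n_reps, digits = 2) {
  val <- ifelse(is.na(mean), "NA", sprintf(paste0("%.", digits, "f"), mean))
  if (n_reps > 1) {
    ifelse(is.na(mean), "NA",
           paste0(val, " ± ", sprintf("%.4f", sd)))
  } else {
    val
  }
}

#' Render an evaluation report
#'
#' Formats the cross-replicate summary of a [evaluate_predictions()]
#' result as TSV or Markdown. Rows follow the fixed category display
#' order and always end with Buried, Surface, Everything (categories
#' without entries are omitted). Correlation-type metrics are printed to
#' 2 decimals with "mean ± sd" when several replicates were
#' evaluated; percentages to 1 decimal; undefined metrics as "NA".
#'
#' @param report A `ddg_evaluation`.
#' @param format `"tsv"` or `"markdown"`.
#' @return A single string (the rendered table).
#' @export
render_report <- function(report, format = c("tsv", "markdown")) {
  stopifnot(inherits(report, "ddg_evaluation"))
  format <- match.arg(format)
  s <- report$summary
  if (nrow(s) == 0) stop("empty report", call. = FALSE)
  s <- s[order(match(s$category, CATEGORY_ORDER)), , drop = FALSE]
  n_reps <- report$n_replicates
  cols <- c("Mutation type" = "category")
  out <- data.frame(`Mutation type` = s$category, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[["Pearson's R"]] <- fmt_metric(s$pearson_r, s$pearson_r_sd, n_reps)
  out[["Pearson's R Filtered"]] <- fmt_metric(s$pearson_r_filtered,
                                              s$pearson_r_filtered_sd, n_reps)
  out[["Predictive Index"]] <- fmt_metric(s$predictive_index,
                                          s$predictive_index_sd, n_reps)
  out[["MCC"]] <- fmt_metric(s$mcc, s$mcc_sd, n_reps)
  out[["Same class (%)"]] <- sprintf("%.1f", s$pct_same_class)
  out[["Off by one (%)"]] <- sprintf("%.1f", s$pct_off_by_one)
  out[["Off by two (%)"]] <- sprintf("%.1f", s$pct_off_by_two)
  out[["Total entries"]] <- as.character(s$n_entries)
  if (format == "tsv") {
    lines <- c(paste(names(out), collapse = "\t"),
               apply(out, 1, paste, collapse = "\t"))
  } else {
    header <- paste0("| ", paste(names(out), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
    body <- apply(out, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
    lines <- c(header, sep, body)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write an evaluation report to a file
#'
#' @param report A `ddg_evaluation`.
#' @param path Output path.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "markdown")) {
  cat(render_report(report, format = format), file = path)
  invisible(path)
}
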