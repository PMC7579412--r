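# A benchmark set couples a mutation table with its multi-label category
# index and the curation parameters that produced it.

#' Construct a benchmark set
#'
#' Classifies every record with [classify_mutation()] and builds the
#' category index (category label -> record ids). Burial labels, which
#' need a structure, are attached through `burial`.
#'
#' @param records A `mutation_table`.
#' @param burial Optional named character vector (`record_id` ->
#'   `"Buried"`/`"Surface"`), e.g. from [burial_labels()].
#' @param provenance Optional list of curation parameters to carry along.
#' @return A `benchmark_set`: list with elements `records`,
#'   `category_index`, `provenance`.
#' @export
benchmark_set <- function(records, burial = NULL, provenance = list()) {
  validate_mutation_table(records)
  idx <- lapply(CATEGORY_ORDER, function(lab) character(0))
  names(idx) <- CATEGORY_ORDER
  for (i in seq_len(nrow(records))) {
    b <- NA_character_
    if (!is.null(burial) && records$record_id[i] %in% names(burial)) {
      b <- burial[[records$record_id[i]]]
    }
    labs <- classify_mutation(records$wt_aa[i], records$mut_aa[i], burial = b)
    for (lab in labs) idx[[lab]] <- c(idx[[lab]], records$record_id[i])
  }
  structure(list(records = records,
                 category_index = idx,
                 provenance = provenance),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set> %d entries\n", nrow(x$records)))
  n <- vapply(x$category_index, length, integer(1))
  shown <- n[n > 0]
  for (lab in names(shown)) cat(sprintf("  %-40s %4d\n", lab, shown[[lab]]))
  invisible(x)
}

#' @export
summary.benchmark_set <- function(object, ...) {
  data.frame(category = names(object$category_index),
             n = vapply(object$category_index, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a benchmark set to TSV
#'
#' One row per record in stable (curation) order, with all mutation-table
#' columns plus a `categories` column holding the record's
#' semicolon-joined category labels.
#'
#' @param set A `benchmark_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(set, path) {
  stopifnot(inherits(set, "benchmark_set"))
  df <- as.data.frame(set$records)
  cats <- vapply(df$record_id, function(id) {
    labs <- names(set$category_index)[vapply(set$category_index,
                                             function(v) id %in% v,
                                             logical(1))]
    paste(labs, collapse = ";")
  }, character(1))
  df$categories <- cats
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a benchmark set written by [write_benchmark()]
#'
#' Rebuilds the category index from the `categories` column (burial labels
#' survive the round trip this way; sequence-derived labels are checked
#' against a fresh classification).
#'
#' @param path Path to the TSV.
#' @return A `benchmark_set`.
#' @export
read_benchmark <- function(path) {
  raw <- read_delim_auto(path)
  if (!"categories" %in% names(raw)) {
    stop("not a benchmark file: missing `categories` column", call. = FALSE)
  }
  rec <- mutation_table(pdb_id = raw$pdb_id, chain = raw$chain,
                        position = raw$position, wt_aa = raw$wt_aa,
                        mut_aa = raw$mut_aa,
                        ddg_exp = as.numeric(raw$ddg_exp),
                        ph = suppressWarnings(as.numeric(raw$ph)),
                        source_ref = ifelse(!is.na(raw$source_ref) &
                                              raw$source_ref == "",
                                            NA_character_, raw$source_ref),
                        record_id = raw$record_id)
  labsets <- strsplit(raw$categories, ";", fixed = TRUE)
  burial <- character(0)
  for (i in seq_along(labsets)) {
    b <- intersect(labsets[[i]], c("Buried", "Surface"))
    if (length(b) == 1L) burial[rec$record_id[i]] <- b
  }
  set <- benchmark_set(rec, burial = if (length(burial)) burial else NULL)
  # cross-check: stored labels must match a fresh classification
  for (i in seq_along(labsets)) {
    fresh <- names(set$category_index)[vapply(set$category_index,
                                              function(v) rec$record_id[i] %in% v,
                                              logical(1))]
    if (!setequal(fresh, labsets[[i]])) {
      stop("category index inconsistent for record ", rec$record_id[i],
           call. = FALSE)
    }
  }
  set
}
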