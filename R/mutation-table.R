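# Mutation tables: one row per experimental point mutation.
# Positions are stored as character so PDB insertion codes survive as an
# opaque suffix; comparisons are string-exact.

MUTATION_FIELDS <- c("record_id", "pdb_id", "chain", "position",
                     "wt_aa", "mut_aa", "ddg_exp", "ph", "source_ref")
REQUIRED_FIELDS <- c("pdb_id", "chain", "position", "wt_aa", "mut_aa",
                     "ddg_exp")

#' Column dialect for mutation tables
#'
#' ProTherm exports and derived tables name their columns differently; a
#' dialect maps the canonical field names to the column names of a
#' particular file. Fields omitted from the call keep their canonical
#' name. `record_id`, `ph` and `source_ref` are optional in the file;
#' missing record ids are synthesised as `PDBID_CHAIN_WTPOSMUT`
#' (e.g. `1ABC_A_L56Q`).
#'
#' @param ... Named overrides, e.g. `ddg_exp = "ddG"` declares that the
#'   file stores the experimental ddG under a column named `ddG`.
#' @return Named character vector mapping canonical field -> file column.
#' @export
#' @examples
#' mutation_dialect(pdb_id = "PDB", ddg_exp = "ddG_exp")
mutation_dialect <- function(...) {
  d <- setNames(MUTATION_FIELDS, MUTATION_FIELDS)
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), MUTATION_FIELDS)
    if (length(unknown)) {
      stop("unknown dialect fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    d[names(over)] <- over
  }
  d
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character")
}

default_record_id <- function(pdb_id, chain, wt_aa, position, mut_aa) {
  sprintf("%s_%s_%s%s%s", pdb_id, chain, wt_aa, position, mut_aa)
}

new_mutation_table <- function(df) {
  rownames(df) <- NULL
  structure(df[, MUTATION_FIELDS], class = c("mutation_table", "data.frame"))
}

#' Validate a mutation table
#'
#' Checks the mutation-table invariants: unique record ids, canonical and
#' differing wild-type/mutant codes, finite experimental ddG.
#'
#' @param x A `mutation_table` (or data frame with its columns).
#' @return `x` invisibly; errors describe every offending row.
#' @export
validate_mutation_table <- function(x) {
  stopifnot(is.data.frame(x), all(MUTATION_FIELDS %in% names(x)))
  probs <- character(0)
  bad_aa <- !(x$wt_aa %in% AA_CODES) | !(x$mut_aa %in% AA_CODES)
  if (any(bad_aa)) {
    probs <- c(probs, sprintf(
      "row %d (%s): non-canonical amino-acid code %s -> %s",
      which(bad_aa), x$record_id[bad_aa], x$wt_aa[bad_aa], x$mut_aa[bad_aa]))
  }
  same <- !bad_aa & x$wt_aa == x$mut_aa
  if (any(same)) {
    probs <- c(probs, sprintf("row %d (%s): wt_aa equals mut_aa",
                              which(same), x$record_id[same]))
  }
  if (any(!is.finite(x$ddg_exp))) {
    bad <- !is.finite(x$ddg_exp)
    probs <- c(probs, sprintf("row %d (%s): ddg_exp is not finite",
                              which(bad), x$record_id[bad]))
  }
  if (anyDuplicated(x$record_id)) {
    dup <- unique(x$record_id[duplicated(x$record_id)])
    probs <- c(probs, paste("duplicated record_id:",
                            paste(dup, collapse = ", ")))
  }
  if (length(probs)) {
    stop("invalid mutation table:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(x)
}

#' Build a mutation table from vectors
#'
#' @param pdb_id,chain,position,wt_aa,mut_aa,ddg_exp Required fields
#'   (position may carry an insertion-code suffix and is kept as text).
#' @param ph Optional pH at which the ddG was measured (`NA` if unknown).
#' @param source_ref Optional free-text provenance.
#' @param record_id Optional ids; defaults to `PDBID_CHAIN_WTPOSMUT`.
#' @return A validated `mutation_table` (a data frame subclass).
#' @export
#' @examples
#' mutation_table(pdb_id = "1ABC", chain = "A", position = 56,
#'                wt_aa = "L", mut_aa = "Q", ddg_exp = 1.2, ph = 7)
mutation_table <- function(pdb_id, chain, position, wt_aa, mut_aa, ddg_exp,
                           ph = NA_real_, source_ref = NA_character_,
                           record_id = NULL) {
  n <- max(length(pdb_id), length(chain), length(position),
           length(wt_aa), length(mut_aa), length(ddg_exp))
  position <- rep_len(as.character(position), n)
  pdb_id <- rep_len(as.character(pdb_id), n)
  chain <- rep_len(as.character(chain), n)
  wt_aa <- rep_len(as.character(wt_aa), n)
  mut_aa <- rep_len(as.character(mut_aa), n)
  if (is.null(record_id)) {
    record_id <- default_record_id(pdb_id, chain, wt_aa, position, mut_aa)
  }
  df <- data.frame(record_id = rep_len(as.character(record_id), n),
                   pdb_id = pdb_id,
                   chain = chain,
                   position = position,
                   wt_aa = wt_aa,
                   mut_aa = mut_aa,
                   ddg_exp = rep_len(as.numeric(ddg_exp), n),
                   ph = rep_len(as.numeric(ph), n),
                   source_ref = rep_len(as.character(source_ref), n),
                   stringsAsFactors = FALSE)
  validate_mutation_table(df)
  new_mutation_table(df)
}

#' Read a ProTherm-style mutation table
#'
#' Reads a TSV or CSV of experimental point mutations (delimiter sniffed
#' from the header line). Column names are resolved through a
#' [mutation_dialect()]. Rows failing validation (non-canonical codes,
#' wt == mut, non-finite ddG) are reported with their row numbers rather
#' than silently dropped; with `on_invalid = "drop"` they are removed and
#' attached as the `"rejected"` attribute instead.
#'
#' @param path Path to the table.
#' @param dialect A [mutation_dialect()] mapping canonical fields to the
#'   file's column names.
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return A `mutation_table` in file row order.
#' @export
read_mutation_table <- function(path, dialect = mutation_dialect(),
                                on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  raw <- read_delim_auto(path)
  missing_cols <- setdiff(dialect[REQUIRED_FIELDS], names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  get_col <- function(field, default) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  df <- data.frame(
    record_id = as.character(get_col("record_id", NA_character_)),
    pdb_id = as.character(get_col("pdb_id", NA_character_)),
    chain = as.character(get_col("chain", NA_character_)),
    position = as.character(get_col("position", NA_character_)),
    wt_aa = toupper(as.character(get_col("wt_aa", NA_character_))),
    mut_aa = toupper(as.character(get_col("mut_aa", NA_character_))),
    ddg_exp = suppressWarnings(as.numeric(get_col("ddg_exp", NA_real_))),
    ph = suppressWarnings(as.numeric(get_col("ph", NA_real_))),
    source_ref = as.character(get_col("source_ref", NA_character_)),
    stringsAsFactors = FALSE)
  df$source_ref[!is.na(df$source_ref) & df$source_ref == ""] <- NA_character_
  no_id <- is.na(df$record_id) | df$record_id == ""
  df$record_id[no_id] <- default_record_id(
    df$pdb_id[no_id], df$chain[no_id], df$wt_aa[no_id],
    df$position[no_id], df$mut_aa[no_id])
  if (on_invalid == "drop") {
    ok <- df$wt_aa %in% AA_CODES & df$mut_aa %in% AA_CODES &
      df$wt_aa != df$mut_aa & is.finite(df$ddg_exp)
    rejected <- df[!ok, , drop = FALSE]
    df <- df[ok, , drop = FALSE]
    validate_mutation_table(df)
    out <- new_mutation_table(df)
    attr(out, "rejected") <- rejected
    return(out)
  }
  validate_mutation_table(df)
  new_mutation_table(df)
}

#' Write a mutation table to TSV
#'
#' @param x A `mutation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(x, path) {
  validate_mutation_table(x)
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("<mutation_table> %d record(s), %d parent structure(s)\n",
              nrow(x), length(unique(x$pdb_id))))
  print(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more row(s)\n")
  invisible(x)
}

#' Read a predictor output table
#'
#' Reads a TSV/CSV with columns `record_id`, `ddg_pred` and optionally
#' `replicate` (defaulting to 1). Predictions from several independent
#' runs of a stochastic predictor carry distinct replicate numbers.
#'
#' @param path Path to the table.
#' @return Data frame with columns `record_id`, `ddg_pred`, `replicate`.
#' @export
read_predictions <- function(path) {
  raw <- read_delim_auto(path)
  need <- setdiff(c("record_id", "ddg_pred"), names(raw))
  if (length(need)) {
    stop("missing required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    record_id = as.character(raw$record_id),
    ddg_pred = suppressWarnings(as.numeric(raw$ddg_pred)),
    replicate = if ("replicate" %in% names(raw)) {
      as.integer(raw$replicate)
    } else 1L,
    stringsAsFactors = FALSE)
  if (any(!is.finite(out$ddg_pred))) {
    stop("non-finite ddg_pred in row(s): ",
         paste(which(!is.finite(out$ddg_pred)), collapse = ", "),
         call. = FALSE)
  }
  if (any(out$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  out
}
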