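# Multi-run energy aggregation for Rosetta-style ddG protocols: the
# convergence criterion over streams of per-model energies, and ddG
# assembly from a wild-type and a mutant stream.

#' Converge a stream of model energies
#'
#' Consumes per-model energies (Rosetta Energy Units) one at a time in
#' generation order. After at least two models, generation stops as soon
#' as the two lowest energies seen so far agree to within `tol`;
#' otherwise it stops at `max_models`. Either way the result is the
#' lowest (not the average) energy among the models consumed.
#'
#' @param energies Numeric vector of model energies in generation order;
#'   must supply at least as many values as the stopping rule consumes.
#' @param tol Convergence tolerance in REU (default 1.0).
#' @param max_models Hard cap on models consumed (default 5).
#' @return List with `final_energy` (the minimum consumed) and
#'   `models_used`.
#' @export
#' @examples
#' converge_energies(c(3.0, 3.5, 9, 9, 9))    # 3.0 after 2 models
#' converge_energies(c(10, 8, 6, 4, 2))       # never converges: best of 5
converge_energies <- function(energies, tol = 1.0, max_models = 5) {
  stopifnot(is.numeric(energies), tol >= 0, max_models >= 2)
  if (any(!is.finite(energies))) {
    stop("energies must be finite", call. = FALSE)
  }
  for (k in 2:max_models) {
    if (k > length(energies)) {
      stop(sprintf(
        "energy stream exhausted after %d model(s) before stopping rule",
        length(energies)), call. = FALSE)
    }
    two <- sort(energies[seq_len(k)])[1:2]
    if (two[2] - two[1] <= tol) {
      return(list(final_energy = two[1], models_used = k))
    }
  }
  list(final_energy = min(energies[seq_len(max_models)]),
       models_used = max_models)
}

#' ddG from wild-type and mutant energy streams
#'
#' Applies the convergence rule to both streams and returns the mutant
#' minus wild-type energy difference, optionally rescaled to kcal/mol.
#' `legacy = TRUE` instead averages exactly the first three models of
#' each stream (the earlier fixed-replicate protocol).
#'
#' @param wt,mut Numeric energy streams for the unmutated and mutated
#'   sequence.
#' @param tol,max_models Convergence parameters, see
#'   [converge_energies()].
#' @param legacy Use the fixed mean-of-3 rule instead of convergence.
#' @param scale `c(slope, intercept)` applied to the REU difference
#'   (default identity; REU are not natively kcal/mol).
#' @return List with `ddg`, `wt_models_used`, `mut_models_used`.
#' @export
ddg_from_streams <- function(wt, mut, tol = 1.0, max_models = 5,
                             legacy = FALSE, scale = c(1, 0)) {
  if (legacy) {
    if (length(wt) < 3 || length(mut) < 3) {
      stop("legacy mode needs at least 3 models per stream", call. = FALSE)
    }
    ddg <- mean(mut[1:3]) - mean(wt[1:3])
    return(list(ddg = scale[1] * ddg + scale[2],
                wt_models_used = 3L, mut_models_used = 3L))
  }
  cw <- converge_energies(wt, tol = tol, max_models = max_models)
  cm <- converge_energies(mut, tol = tol, max_models = max_models)
  ddg <- cm$final_energy - cw$final_energy
  list(ddg = scale[1] * ddg + scale[2],
       wt_models_used = cw$models_used, mut_models_used = cm$models_used)
}

#' Read a per-model energy table
#'
#' TSV/CSV with columns `model_index`, `variant` (`wt` or `mut`),
#' `energy`, and optionally `record_id` when one file carries several
#' mutations.
#'
#' @param path Path to the table.
#' @return Data frame sorted by (`record_id`,) `variant`, `model_index`.
#' @export
read_energy_table <- function(path) {
  raw <- read_delim_auto(path)
  need <- setdiff(c("model_index", "variant", "energy"), names(raw))
  if (length(need)) {
    stop("missing required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    record_id = if ("record_id" %in% names(raw)) {
      as.character(raw$record_id)
    } else "all",
    model_index = as.integer(raw$model_index),
    variant = tolower(as.character(raw$variant)),
    energy = suppressWarnings(as.numeric(raw$energy)),
    stringsAsFactors = FALSE)
  if (!all(df$variant %in% c("wt", "mut"))) {
    stop("variant must be 'wt' or 'mut'", call. = FALSE)
  }
  if (any(!is.finite(df$energy))) {
    stop("non-finite energy values", call. = FALSE)
  }
  df[order(df$record_id, df$variant, df$model_index), , drop = FALSE]
}

#' Aggregate an energy table into per-mutation ddG predictions
#'
#' Applies [ddg_from_streams()] to every `record_id` of an energy table.
#'
#' @param energies Data frame from [read_energy_table()].
#' @param ... Passed to [ddg_from_streams()].
#' @return Data frame (`record_id`, `ddg_pred`, `wt_models_used`,
#'   `mut_models_used`).
#' @export
aggregate_energies <- function(energies, ...) {
  rows <- lapply(unique(energies$record_id), function(id) {
    sub <- energies[energies$record_id == id, , drop = FALSE]
    wt <- sub$energy[sub$variant == "wt"]
    mut <- sub$energy[sub$variant == "mut"]
    if (!length(wt) || !length(mut)) {
      stop("record ", id, " is missing a wt or mut stream", call. = FALSE)
    }
    r <- ddg_from_streams(wt, mut, ...)
    data.frame(record_id = id, ddg_pred = r$ddg,
               wt_models_used = r$wt_models_used,
               mut_models_used = r$mut_models_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
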