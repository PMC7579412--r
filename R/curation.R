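# Benchmark construction: sequence-identity clustering, deduplication
# with pH-nearest-7 selection, structure-based filters, capped category
# balancing, and composition statistics.

parent_key <- function(records) paste(records$pdb_id, records$chain, sep = "_")

#' Global sequence identity between two protein sequences
#'
#' Fraction of identical positions in an optimal global alignment,
#' divided by the alignment length (matches + mismatches + gap columns).
#' Alignment scoring: match 1, mismatch 0, gap open -1, gap extend -0.1
#' (Biostrings Needleman-Wunsch).
#'
#' @param a,b Protein sequences (character scalars, one-letter codes).
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' sequence_identity("ACDEFGHIKL", "TTDEFGHIKT")  # 0.7
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  sm <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sm,
                                      gapOpening = 1, gapExtension = 0.1,
                                      type = "global")
  aligned <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  len <- nchar(a) + nchar(b) - aligned
  Biostrings::nmatch(al) / len
}

#' Cluster parent sequences by identity (single linkage)
#'
#' Builds the graph with an edge between every pair of sequences at
#' identity >= `threshold` and returns its connected components, so that
#' any chain of pairwise-similar parents lands in one cluster.
#'
#' @param sequences Named character vector of parent sequences (names are
#'   parent keys, e.g. `"1ABC_A"`).
#' @param threshold Identity threshold, default 0.60.
#' @return A `sequence_clusters` object: list with `membership` (named
#'   integer vector) and `identity` (the pairwise identity matrix).
#' @export
cluster_parents <- function(sequences, threshold = 0.60) {
  if (length(sequences) < 1) stop("need at least one sequence", call. = FALSE)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  n <- length(sequences)
  idm <- diag(1, n)
  dimnames(idm) <- list(names(sequences), names(sequences))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        idm[i, j] <- idm[j, i] <- sequence_identity(sequences[[i]],
                                                    sequences[[j]])
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(idm >= threshold, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  names(memb) <- names(sequences)
  structure(list(membership = memb, identity = idm, threshold = threshold,
                 sequences = sequences),
            class = "sequence_clusters")
}

# Map a 1-based sequence position of `seq` onto the coordinates of the
# cluster representative via global alignment; NA when the position falls
# in a gap or out of range.
map_position <- function(seq, rep_seq, pos) {
  if (identical(seq, rep_seq)) return(pos)
  sm <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(seq, rep_seq, substitutionMatrix = sm,
                                      gapOpening = 1, gapExtension = 0.1,
                                      type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pi_ <- cumsum(p != "-")
  si <- cumsum(s != "-")
  col <- match(pos, ifelse(p != "-", pi_, NA))
  if (is.na(col) || s[col] == "-") return(NA_integer_)
  si[col]
}

#' Remove duplicate mutations across similar parents
#'
#' Within a sequence cluster, records describing the identical mutation
#' (same position, same wild-type, same mutant) collapse to a single
#' survivor: the one measured at the pH closest to 7, ties broken toward
#' the lower pH, then first occurrence. Records with unknown pH are
#' treated as pH 7 for selection only (they are flagged in the log).
#' Different mutations at the same position always survive independently.
#' When cluster sequences are available, positions are compared after
#' mapping through the alignment to the cluster representative; otherwise
#' raw position strings are compared.
#'
#' @param records A `mutation_table`.
#' @param clusters A `sequence_clusters` from [cluster_parents()]; every
#'   record's parent key (`pdb_id_chain`) must be assigned. `NULL` treats
#'   every parent as its own cluster.
#' @return The surviving records (original order), with a `"dropped"`
#'   attribute logging removed record ids and reasons.
#' @export
deduplicate <- function(records, clusters = NULL) {
  validate_mutation_table(records)
  keys <- parent_key(records)
  if (is.null(clusters)) {
    memb <- setNames(as.integer(factor(unique(keys))), unique(keys))
  } else {
    stopifnot(inherits(clusters, "sequence_clusters"))
    memb <- clusters$membership
    missing <- setdiff(unique(keys), names(memb))
    if (length(missing)) {
      stop("parents not assigned to any cluster: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  cl <- memb[keys]
  # position mapped to cluster representative where sequences are known
  mpos <- records$position
  if (!is.null(clusters) && !is.null(clusters$sequences)) {
    seqs <- clusters$sequences
    for (c_id in unique(cl)) {
      members <- names(memb)[memb == c_id]
      rep_key <- sort(members)[1]
      idx <- which(cl == c_id)
      for (i in idx) {
        sq <- seqs[[keys[i]]]
        posn <- suppressWarnings(as.integer(records$position[i]))
        if (is.null(sq) || is.na(posn) || posn < 1 || posn > nchar(sq)) next
        m <- map_position(sq, seqs[[rep_key]], posn)
        if (!is.na(m)) mpos[i] <- paste0("@", m)
      }
    }
  }
  dkey <- paste(cl, mpos, records$wt_aa, records$mut_aa, sep = "|")
  ph <- records$ph
  ph_imputed <- is.na(ph)
  ph[ph_imputed] <- 7
  keep <- logical(nrow(records))
  for (k in unique(dkey)) {
    idx <- which(dkey == k)
    # nearest pH 7, ties toward lower pH, then first occurrence
    best <- idx[order(abs(ph[idx] - 7), ph[idx], idx)][1]
    keep[best] <- TRUE
  }
  n_drop <- sum(!keep)
  dropped <- data.frame(record_id = records$record_id[!keep],
                        stage = rep("deduplicate", n_drop),
                        reason = rep("duplicate mutation in sequence cluster",
                                     n_drop),
                        stringsAsFactors = FALSE)
  out <- new_mutation_table(as.data.frame(records)[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  attr(out, "ph_imputed") <- records$record_id[ph_imputed & keep]
  out
}

#' Remove mutations at interfaces or near ligands
#'
#' Drops records whose mutated residue has a heavy atom within `cutoff`
#' of another chain or of a non-water HETATM (see
#' [has_foreign_contact()]). Records whose parent structure is missing or
#' whose residue cannot be located are removed with an explanatory log
#' entry rather than raising.
#'
#' @param records A `mutation_table`.
#' @param structures Named list of `pdb_structure` objects keyed by
#'   `pdb_id`.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @return List with `records` (survivors, original order) and `log`
#'   (data frame `record_id`, `stage`, `reason`).
#' @export
apply_structure_filters <- function(records, structures, cutoff = 5.0) {
  validate_mutation_table(records)
  keep <- logical(nrow(records))
  log <- list()
  for (i in seq_len(nrow(records))) {
    st <- structures[[records$pdb_id[i]]]
    if (is.null(st)) {
      log[[length(log) + 1]] <- c(records$record_id[i], "structure_filter",
                                  "missing structure")
      next
    }
    res <- tryCatch(
      has_foreign_contact(st, records$chain[i], records$position[i],
                          cutoff = cutoff),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      log[[length(log) + 1]] <- c(records$record_id[i], "structure_filter",
                                  res)
    } else if (res) {
      log[[length(log) + 1]] <- c(records$record_id[i], "structure_filter",
                                  sprintf("foreign contact within %g A", cutoff))
    } else {
      keep[i] <- TRUE
    }
  }
  log <- if (length(log)) {
    as.data.frame(do.call(rbind, log), stringsAsFactors = FALSE) |>
      setNames(c("record_id", "stage", "reason"))
  } else {
    data.frame(record_id = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  list(records = new_mutation_table(
    as.data.frame(records)[keep, , drop = FALSE]), log = log)
}

#' Populate mutation categories up to a cap
#'
#' Fills each of the 17 narrowly defined categories with up to `cap`
#' entries; categories with fewer candidates keep everything. The size
#' and burial superset categories (Small to large, Large to small,
#' Buried, Surface) plus Same size and Everything receive no dedicated
#' fill — they are populated by whatever the narrow categories select.
#' When a category holds more than `cap` candidates, a seeded sample is
#' drawn round-robin across parent clusters so the selection spreads over
#' proteins; the result is deterministic given `seed`.
#'
#' @param records A `mutation_table` of curated candidates.
#' @param cap Maximum entries per narrow category (default 50).
#' @param seed Integer seed fixing the selection.
#' @param clusters Optional `sequence_clusters` used for the stratified
#'   draw; parents missing from it form singleton strata.
#' @param burial Optional named burial vector passed to [benchmark_set()].
#' @param provenance Extra provenance entries to record.
#' @return A `benchmark_set` whose records appear in their original
#'   table order.
#' @export
balance_categories <- function(records, cap = 50, seed = 1, clusters = NULL,
                               burial = NULL, provenance = list()) {
  validate_mutation_table(records)
  stopifnot(cap >= 1)
  keys <- parent_key(records)
  strata <- if (!is.null(clusters)) {
    m <- clusters$membership[keys]
    ifelse(is.na(m), paste0("solo_", keys), paste0("c", m))
  } else {
    keys
  }
  labsets <- mapply(function(w, m) list(classify_mutation(w, m)),
                    records$wt_aa, records$mut_aa)
  narrow_of <- lapply(labsets, function(l) intersect(l, NARROW_CATEGORIES))
  sel <- logical(nrow(records))
  counts <- setNames(integer(length(NARROW_CATEGORIES)), NARROW_CATEGORIES)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  # a record is admitted only while none of its narrow categories is at
  # the cap, so records shared between overlapping narrow categories
  # (proline/cysteine pairs) can never push a category past `cap`
  try_add <- function(i) {
    labs <- narrow_of[[i]]
    if (any(counts[labs] >= cap)) return(FALSE)
    sel[i] <<- TRUE
    counts[labs] <<- counts[labs] + 1L
    TRUE
  }
  for (cat in NARROW_CATEGORIES) {
    cand <- which(vapply(narrow_of, function(l) cat %in% l, logical(1)))
    pool <- cand[!sel[cand]]
    if (counts[[cat]] + length(pool) > cap) {
      # round-robin over parent strata, random order within and across
      perm <- sample(pool)
      by_stratum <- split(perm, strata[perm])
      by_stratum <- by_stratum[sample(names(by_stratum))]
      pool <- integer(0)
      while (any(lengths(by_stratum) > 0)) {
        for (snm in names(by_stratum)) {
          if (length(by_stratum[[snm]])) {
            pool <- c(pool, by_stratum[[snm]][1])
            by_stratum[[snm]] <- by_stratum[[snm]][-1]
          }
        }
      }
    }
    for (i in pool) {
      if (counts[[cat]] >= cap) break
      try_add(i)
    }
  }
  keep <- sel
  out <- new_mutation_table(as.data.frame(records)[keep, , drop = FALSE])
  benchmark_set(out, burial = burial,
                provenance = c(list(cap = cap, seed = seed), provenance))
}

#' Observed vs expected mutation-category composition
#'
#' Tabulates the observed fraction of records in each sequence-defined
#' category and the fraction expected under a random-mutation null: the
#' wild-type residue is drawn from `residue_composition` and the mutant
#' uniformly from the 19 remaining residues. Also reports the fraction of
#' mutations *to* a hydrophobic residue under both views.
#'
#' @param records A `mutation_table`.
#' @param residue_composition Named numeric vector of amino-acid
#'   frequencies over the 20 canonical codes (normalised internally);
#'   default uniform.
#' @return A `composition_report`: list with `table` (data frame
#'   `category`, `observed_count`, `observed_fraction`,
#'   `expected_fraction`) and `to_hydrophobic` (named vector `observed`,
#'   `expected`).
#' @export
composition_stats <- function(records, residue_composition = NULL) {
  validate_mutation_table(records)
  if (nrow(records) == 0) stop("empty mutation table", call. = FALSE)
  if (is.null(residue_composition)) {
    residue_composition <- setNames(rep(1 / 20, 20), AA_CODES)
  }
  if (!all(AA_CODES %in% names(residue_composition))) {
    stop("residue_composition must cover all 20 canonical codes",
         call. = FALSE)
  }
  comp <- residue_composition[AA_CODES]
  comp <- comp / sum(comp)
  tl <- pair_label_table()
  pair_p <- comp[tl$pairs$wt] / 19
  seq_cats <- setdiff(CATEGORY_ORDER, c("Buried", "Surface"))
  expected <- vapply(seq_cats, function(cat) {
    hit <- vapply(tl$labels, function(l) cat %in% l, logical(1))
    sum(pair_p[hit])
  }, numeric(1))
  labsets <- mapply(function(w, m) list(classify_mutation(w, m)),
                    records$wt_aa, records$mut_aa)
  observed <- vapply(seq_cats, function(cat) {
    sum(vapply(labsets, function(l) cat %in% l, logical(1)))
  }, numeric(1))
  tab <- data.frame(category = seq_cats,
                    observed_count = as.integer(observed),
                    observed_fraction = observed / nrow(records),
                    expected_fraction = unname(expected),
                    row.names = NULL, stringsAsFactors = FALSE)
  to_h <- c(
    observed = mean(records$mut_aa %in% RESIDUE_CLASSES$Hydrophobic),
    expected = sum(pair_p[tl$pairs$mut %in% RESIDUE_CLASSES$Hydrophobic]))
  structure(list(table = tab, to_hydrophobic = to_h,
                 n = nrow(records)), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %d records\n", x$n))
  tab <- x$table
  tab$observed_fraction <- sprintf("%.1f%%", 100 * tab$observed_fraction)
  tab$expected_fraction <- sprintf("%.1f%%", 100 * tab$expected_fraction)
  print(tab, row.names = FALSE)
  cat(sprintf("mutations to hydrophobic: observed %.1f%%, expected %.1f%%\n",
              100 * x$to_hydrophobic[["observed"]],
              100 * x$to_hydrophobic[["expected"]]))
  invisible(x)
}

#' Run the full benchmark-curation pipeline
#'
#' Fixed stage order: structure filters (interface/ligand contacts) ->
#' sequence clustering -> deduplication with pH-nearest-7 selection ->
#' capped category balancing. Stages whose inputs are not supplied
#' (structures, sequences) are skipped and recorded as such in the
#' provenance. The input table is single-mutation by schema; rows that
#' are not valid single point mutations are rejected at read time.
#'
#' @param records A `mutation_table` of candidate entries.
#' @param structures Optional named list of `pdb_structure` objects keyed
#'   by `pdb_id` for the contact filter and burial labels.
#' @param sequences Optional named character vector of parent sequences
#'   keyed `pdb_chain` (e.g. `"1ABC_A"`) for identity clustering.
#' @param cap Per-category cap (default 50).
#' @param identity_threshold Sequence-identity clustering threshold
#'   (default 0.60).
#' @param contact_cutoff Foreign-contact cutoff in Angstrom (default 5).
#' @param seed Integer seed for the balanced selection.
#' @param compute_burial Compute burial labels from `structures`
#'   (default `TRUE` when structures are given).
#' @return A `benchmark_set` with a `rejections` element in its
#'   provenance logging every removed record.
#' @export
curate_benchmark <- function(records, structures = NULL, sequences = NULL,
                             cap = 50, identity_threshold = 0.60,
                             contact_cutoff = 5.0, seed = 1,
                             compute_burial = !is.null(structures)) {
  validate_mutation_table(records)
  log <- data.frame(record_id = character(0), stage = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  if (!is.null(structures)) {
    f <- apply_structure_filters(records, structures,
                                 cutoff = contact_cutoff)
    records <- f$records
    log <- rbind(log, f$log)
  }
  clusters <- NULL
  if (!is.null(sequences)) {
    clusters <- cluster_parents(sequences, threshold = identity_threshold)
  }
  records <- deduplicate(records, clusters)
  log <- rbind(log, attr(records, "dropped"))
  burial <- NULL
  if (compute_burial && !is.null(structures)) {
    burial <- burial_labels(records, structures)
  }
  balance_categories(records, cap = cap, seed = seed, clusters = clusters,
                     burial = burial,
                     provenance = list(identity_threshold = identity_threshold,
                                       contact_cutoff = contact_cutoff,
                                       rejections = log))
}
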