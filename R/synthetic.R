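# Synthetic-data generators: mutation tables with controlled category
# mixes and a three-component ddG mixture, noisy predictions, and toy
# structures exercising the contact and burial rules. Everything is a
# pure function of its parameters plus the seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Specification for a synthetic mutation table
#'
#' Defines the statistical shape of a generated benchmark: the number of
#' records, the target mix over mutation categories, and the
#' three-component Gaussian mixture of experimental ddG values. The
#' mixture defaults place one component in each stability class (means
#' -1.5 / 0 / +1.5 kcal/mol, sd 0.5) with weights skewed toward
#' destabilizing mutations, the dominant class in experimental
#' compilations.
#'
#' @param n_records Number of records to generate.
#' @param category_mix Named numeric vector of target fractions per
#'   category label (normalised internally); default uniform over the 17
#'   narrow categories. Only sequence-realizable categories are allowed.
#' @param ddg_means,ddg_sd,ddg_weights Mixture parameters (kcal/mol).
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_records = 500,
                           category_mix = NULL,
                           ddg_means = c(-1.5, 0, 1.5),
                           ddg_sd = 0.5,
                           ddg_weights = c(0.2, 0.3, 0.5),
                           seed = 1) {
  if (is.null(category_mix)) {
    category_mix <- setNames(rep(1 / length(NARROW_CATEGORIES),
                                 length(NARROW_CATEGORIES)),
                             NARROW_CATEGORIES)
  }
  stopifnot(n_records >= 1, all(category_mix >= 0), sum(category_mix) > 0,
            length(ddg_means) == length(ddg_weights), ddg_sd > 0,
            all(ddg_weights >= 0))
  unknown <- setdiff(names(category_mix), CATEGORY_ORDER)
  if (length(unknown)) {
    stop("unknown categories in mix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (cat in names(category_mix)[category_mix > 0]) {
    if (cat %in% c("Buried", "Surface")) {
      stop("category not realizable from sequence alone: ", cat,
           call. = FALSE)
    }
    if (nrow(pairs_for_label(cat)) == 0) {
      stop("no residue pair realizes category: ", cat, call. = FALSE)
    }
  }
  structure(list(n_records = as.integer(n_records),
                 category_mix = category_mix / sum(category_mix),
                 ddg_means = ddg_means, ddg_sd = ddg_sd,
                 ddg_weights = ddg_weights / sum(ddg_weights),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic mutation table
#'
#' Draws each record's category from the spec's mix, then a realizing
#' (wild-type, mutant) pair uniformly among the pairs carrying that
#' label, and a ddG from the three-component mixture. Records are spread
#' over eight synthetic parent structures. Deterministic given the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `mutation_table` with `n_records` rows.
#' @export
gen_mutation_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_records
    cats <- sample(names(spec$category_mix), n, replace = TRUE,
                   prob = spec$category_mix)
    wt <- character(n)
    mut <- character(n)
    for (i in seq_len(n)) {
      p <- pairs_for_label(cats[i])
      j <- sample.int(nrow(p), 1)
      wt[i] <- p$wt[j]
      mut[i] <- p$mut[j]
    }
    comp <- sample.int(length(spec$ddg_weights), n, replace = TRUE,
                       prob = spec$ddg_weights)
    ddg <- rnorm(n, mean = spec$ddg_means[comp], sd = spec$ddg_sd)
    parents <- sprintf("SY%02d", 1:8)
    mutation_table(pdb_id = sample(parents, n, replace = TRUE),
                   chain = "A", position = seq_len(n),
                   wt_aa = wt, mut_aa = mut, ddg_exp = round(ddg, 3),
                   ph = round(runif(n, 4, 9), 1),
                   source_ref = "synthetic")
  })
}

#' Generate synthetic predictions for a mutation table
#'
#' `pred = slope * ddg_exp + Normal(0, noise_sd^2)`, replicated
#' `n_replicates` times with independent noise.
#'
#' @param records A `mutation_table`.
#' @param slope Linear relation to the experimental values (default 1).
#' @param noise_sd Gaussian noise standard deviation in kcal/mol.
#' @param seed Integer seed.
#' @param n_replicates Number of independent prediction replicates.
#' @return Data frame (`record_id`, `ddg_pred`, `replicate`).
#' @export
gen_predictions <- function(records, slope = 1, noise_sd = 0.5, seed = 1,
                            n_replicates = 1) {
  validate_mutation_table(records)
  stopifnot(slope != 0 || noise_sd > 0, noise_sd >= 0, n_replicates >= 1)
  with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      data.frame(record_id = records$record_id,
                 ddg_pred = slope * records$ddg_exp +
                   rnorm(nrow(records), 0, noise_sd),
                 replicate = r, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# compact 5-atom alanine residue centred at `center`
ala_residue <- function(center, resno, chain) {
  offs <- rbind(N = c(-1.20, 0.80, 0.00),
                CA = c(0.00, 0.00, 0.00),
                C = c(1.25, 0.75, 0.00),
                O = c(1.40, 1.95, 0.15),
                CB = c(-0.10, -0.95, 1.15))
  data.frame(chain = chain, resno = resno, icode = "", resid = "ALA",
             elety = rownames(offs),
             element = substring(rownames(offs), 1, 1),
             x = offs[, 1] + center[1], y = offs[, 2] + center[2],
             z = offs[, 3] + center[3], type = "ATOM",
             stringsAsFactors = FALSE)
}

# idealized poly-alanine alpha helix along +z (rise 1.5 A, twist 100 deg,
# CA radius 2.3 A); backbone placed along the CA trace, CB pointing
# radially outward
poly_ala_helix <- function(n_res, chain, origin = c(0, 0, 0)) {
  phi <- (seq_len(n_res + 1) - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * (seq_len(n_res + 1) - 1))
  rows <- list()
  for (i in seq_len(n_res)) {
    cai <- ca[i, ]
    nxt <- ca[i + 1, ]
    prev <- if (i > 1) ca[i - 1, ] else cai - (nxt - cai)
    to_prev <- (prev - cai) / sqrt(sum((prev - cai)^2))
    to_next <- (nxt - cai) / sqrt(sum((nxt - cai)^2))
    radial <- c(cai[1], cai[2], 0) / sqrt(sum(cai[1:2]^2))
    pos <- rbind(N = cai + 1.45 * to_prev,
                 CA = cai,
                 C = cai + 1.52 * to_next,
                 O = cai + 1.52 * to_next + 1.23 * radial,
                 CB = cai + 1.53 * radial)
    rows[[i]] <- data.frame(chain = chain, resno = i, icode = "",
                            resid = "ALA", elety = rownames(pos),
                            element = substring(rownames(pos), 1, 1),
                            x = pos[, 1] + origin[1],
                            y = pos[, 2] + origin[2],
                            z = pos[, 3] + origin[3],
                            type = "ATOM", stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

icosahedron_dirs <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
             c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
             c(g, 0, 1), c(-g, 0, 1), c(g, 0, -1), c(-g, 0, -1))
  v / sqrt(rowSums(v^2))
}

#' Generate toy structures for contact and burial tests
#'
#' Builds two deterministic fixtures: `helix_pair`, two idealized
#' poly-alanine helices (chains A and B) whose axes sit `separation`
#' Angstrom apart, for exercising the foreign-contact rule; and
#' `packed_core`, a single chain whose first residue is enclosed by a
#' shell of twelve residues so that it is Buried (relative SASA <= 0.20)
#' while at least one shell residue is clearly exposed (relative SASA >=
#' 0.5). Both properties are verified at generation time.
#'
#' @param separation Distance between the two helix axes in Angstrom.
#' @param chain_lengths Integer vector of length 2: residues per helix.
#' @param seed Integer seed (kept for interface uniformity; the geometry
#'   is deterministic).
#' @return List of two `pdb_structure` objects: `helix_pair`,
#'   `packed_core`.
#' @export
gen_toy_structures <- function(separation = 20, chain_lengths = c(12, 12),
                               seed = 1) {
  stopifnot(separation > 0, length(chain_lengths) == 2,
            all(chain_lengths >= 4))
  a <- poly_ala_helix(chain_lengths[1], "A")
  b <- poly_ala_helix(chain_lengths[2], "B", origin = c(separation, 0, 0))
  helix_pair <- new_pdb_structure(rbind(a, b))
  core <- ala_residue(c(0, 0, 0), 1, "A")
  dirs <- icosahedron_dirs()
  shell <- lapply(seq_len(nrow(dirs)), function(k) {
    ala_residue(4.6 * dirs[k, ], k + 1, "A")
  })
  packed_core <- new_pdb_structure(
    do.call(rbind, c(list(core), shell, list(make.row.names = FALSE))))
  central <- relative_sasa(packed_core, "A", 1)
  outer <- vapply(2:13, function(r) {
    relative_sasa(packed_core, "A", r)$relative_sasa
  }, numeric(1))
  if (central$relative_sasa > BURIAL_THRESHOLD || max(outer) < 0.5) {
    stop("packed-core fixture failed its burial invariant", call. = FALSE)
  }
  list(helix_pair = helix_pair, packed_core = packed_core)
}
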