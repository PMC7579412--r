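#' @importFrom stats cor rnorm runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

# Canonical one-letter amino-acid codes.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# The nine residue classes used for mutation categorisation.
RESIDUE_CLASSES <- list(
  Small            = c("G", "A", "V", "S", "T", "C"),
  Large            = c("F", "Y", "W", "K", "R", "H", "Q", "E"),
  Negative         = c("D", "E"),
  Positive         = c("R", "K"),
  Polar            = c("Y", "T", "S", "H", "K", "R", "E", "D", "Q", "N"),
  NonChargedPolar  = c("Y", "T", "S", "N", "Q", "H"),
  Hydrophobic      = c("F", "I", "L", "V", "A", "G", "M", "W"),
  Cysteine         = c("C"),
  Proline          = c("P")
)

# Disjoint polarity groups used for the directional cross-pair categories.
POLARITY_GROUPS <- c(Positive = "Positive", Negative = "Negative",
                     NonChargedPolar = "NonChargedPolar",
                     Hydrophobic = "Hydrophobic")

# Human-readable name of each polarity group as it appears in row labels.
POLARITY_DISPLAY <- c(Positive = "positive", Negative = "negative",
                      NonChargedPolar = "non-charged polar",
                      Hydrophobic = "hydrophobic")

# Fixed report order for all category labels; reports always end with
# Buried, Surface, Everything.
CATEGORY_ORDER <- c(
  "Small to large",
  "Large to small",
  "Positive to negative",
  "Negative to positive",
  "Negative to hydrophobic",
  "Hydrophobic to negative",
  "Positive to hydrophobic",
  "Hydrophobic to positive",
  "Non-charged polar to positive",
  "Positive to non-charged polar",
  "Non-charged polar to negative",
  "Negative to non-charged polar",
  "Non-charged polar to hydrophobic",
  "Hydrophobic to non-charged polar",
  "Non-charged polar to non-charged polar",
  "Hydrophobic to hydrophobic",
  "Charge to charge",
  "Involves cysteine",
  "Involves proline",
  "Same size",
  "Buried",
  "Surface",
  "Everything"
)

# Narrow categories that receive a dedicated fill during balancing.
# Small to large, Large to small, Buried and Surface are supersets of these
# and are populated as a side effect.
NARROW_CATEGORIES <- setdiff(
  CATEGORY_ORDER,
  c("Small to large", "Large to small", "Same size",
    "Buried", "Surface", "Everything")
)

#' Category labels for mutation types
#'
#' The closed set of mutation-category labels, in the fixed order used by
#' all reports: the twelve directional polarity cross pairs, the two
#' within-group pairs (non-charged polar and hydrophobic), like-charge
#' swaps, proline and cysteine involvement, the three size categories, the
#' two burial categories, and the catch-all `"Everything"`.
#'
#' @param narrow If `TRUE`, return only the 17 narrowly defined categories
#'   that receive a dedicated fill during benchmark balancing (the
#'   directional pairs, within-group pairs, charge swaps, and
#'   proline/cysteine categories).
#' @return Character vector of category labels.
#' @export
#' @examples
#' category_labels()
#' category_labels(narrow = TRUE)
category_labels <- function(narrow = FALSE) {
  if (narrow) NARROW_CATEGORIES else CATEGORY_ORDER
}

check_aa <- function(aa, arg = "aa") {
  if (!is.character(aa) || any(is.na(aa)) || !all(aa %in% AA_CODES)) {
    bad <- unique(aa[!(aa %in% AA_CODES)])
    stop(sprintf("non-canonical amino-acid code in `%s`: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}

#' Residue classes of an amino acid
#'
#' Looks up which of the nine residue classes (Small, Large, Negative,
#' Positive, Polar, NonChargedPolar, Hydrophobic, Cysteine, Proline) an
#' amino acid belongs to. Classes overlap: e.g. histidine is Large, Polar
#' and NonChargedPolar; proline belongs only to Proline.
#'
#' @param aa One-letter amino-acid code (one of the 20 canonical codes).
#' @return Character vector of class names containing `aa`.
#' @export
#' @examples
#' residue_classes("C")  # Small, Cysteine
#' residue_classes("H")  # Large, Polar, NonChargedPolar
residue_classes <- function(aa) {
  stopifnot(length(aa) == 1L)
  check_aa(aa)
  names(RESIDUE_CLASSES)[vapply(RESIDUE_CLASSES, function(s) aa %in% s,
                                logical(1))]
}

in_class <- function(aa, class_name) aa %in% RESIDUE_CLASSES[[class_name]]

polarity_group <- function(aa) {
  for (g in POLARITY_GROUPS) if (in_class(aa, g)) return(g)
  NA_character_
}

directional_label <- function(from, to) {
  lab <- paste0(toupper(substring(POLARITY_DISPLAY[[from]], 1, 1)),
                substring(POLARITY_DISPLAY[[from]], 2),
                " to ", POLARITY_DISPLAY[[to]])
  if (lab %in% CATEGORY_ORDER) lab else NA_character_
}

#' Classify a point mutation into mutation-type categories
#'
#' Assigns the multi-label set of categories for a wild-type to mutant
#' substitution. A directional polarity label ("X to Y") is assigned when
#' the wild type belongs to polarity group X and the mutant to group Y
#' (groups: Positive, Negative, NonChargedPolar, Hydrophobic; these are
#' disjoint, so at most one directional label applies). "Charge to charge"
#' marks same-sign charge swaps (K<->R, D<->E). "Involves proline" /
#' "Involves cysteine" fire when either residue is P / C. Size labels use
#' the Small and Large classes; residues in neither class (D, N, I, L, M,
#' P) carry no size label. Burial labels are copied from `burial` when
#' provided. `"Everything"` is always present.
#'
#' @param wt,mut One-letter codes of the wild-type and mutant residue;
#'   must differ.
#' @param burial Optional `"Buried"` or `"Surface"` flag from a structure
#'   analysis; `NA` (default) adds no burial label.
#' @return Character vector of category labels in report order.
#' @seealso [residue_classes()], [category_labels()]
#' @export
#' @examples
#' classify_mutation("E", "K")  # Negative to positive, Same size, Everything
#' classify_mutation("A", "P")  # Involves proline, Everything
classify_mutation <- function(wt, mut, burial = NA_character_) {
  stopifnot(length(wt) == 1L, length(mut) == 1L)
  check_aa(wt, "wt")
  check_aa(mut, "mut")
  if (wt == mut) stop("wt and mut must differ", call. = FALSE)
  if (!is.na(burial) && !burial %in% c("Buried", "Surface")) {
    stop("burial must be NA, \"Buried\" or \"Surface\"", call. = FALSE)
  }
  labs <- character(0)
  gw <- polarity_group(wt)
  gm <- polarity_group(mut)
  if (!is.na(gw) && !is.na(gm)) {
    if (gw != gm) {
      d <- directional_label(gw, gm)
      if (!is.na(d)) labs <- c(labs, d)
    } else if (gw %in% c("NonChargedPolar", "Hydrophobic")) {
      labs <- c(labs, directional_label(gw, gw))
    }
    both_pos <- in_class(wt, "Positive") && in_class(mut, "Positive")
    both_neg <- in_class(wt, "Negative") && in_class(mut, "Negative")
    if (both_pos || both_neg) labs <- c(labs, "Charge to charge")
  }
  if (wt == "P" || mut == "P") labs <- c(labs, "Involves proline")
  if (wt == "C" || mut == "C") labs <- c(labs, "Involves cysteine")
  if (in_class(wt, "Small") && in_class(mut, "Large")) {
    labs <- c(labs, "Small to large")
  }
  if (in_class(wt, "Large") && in_class(mut, "Small")) {
    labs <- c(labs, "Large to small")
  }
  if ((in_class(wt, "Small") && in_class(mut, "Small")) ||
      (in_class(wt, "Large") && in_class(mut, "Large"))) {
    labs <- c(labs, "Same size")
  }
  if (!is.na(burial)) labs <- c(labs, burial)
  labs <- c(labs, "Everything")
  CATEGORY_ORDER[CATEGORY_ORDER %in% labs]
}

#' Ordinal stability class of a ddG value
#'
#' Maps a free-energy change (kcal/mol, positive = destabilizing) to the
#' three-level ordinal stability scale: stabilizing when ddG <= -1
#' kcal/mol (value 2), destabilizing when ddG >= +1 kcal/mol (value 0),
#' neutral in between (value 1). Both boundaries are inclusive.
#'
#' @param ddg Numeric vector of ddG values in kcal/mol; must be finite.
#' @return Integer vector with values in `{0, 1, 2}` (destabilizing,
#'   neutral, stabilizing).
#' @export
#' @examples
#' classify_ddg(c(-1, 0, 1))  # 2, 1, 0
classify_ddg <- function(ddg) {
  if (!is.numeric(ddg) || any(!is.finite(ddg))) {
    stop("ddg must be finite numeric", call. = FALSE)
  }
  ifelse(ddg <= -1, 2L, ifelse(ddg >= 1, 0L, 1L))
}

#' Ordinal classification error between experiment and prediction
#'
#' The absolute difference between the ordinal stability classes of the
#' experimental and predicted ddG. 0 = same class, 1 = off by one class
#' (e.g. destabilizing predicted neutral), 2 = egregious (stabilizing
#' predicted destabilizing or vice versa).
#'
#' @param ddg_exp,ddg_pred Numeric vectors of experimental and predicted
#'   ddG (kcal/mol); recycled to a common length.
#' @return Integer vector with values in `{0, 1, 2}`.
#' @export
#' @examples
#' classification_error(-2, 2)    # 2
#' classification_error(1.5, 0.2) # 1
classification_error <- function(ddg_exp, ddg_pred) {
  abs(classify_ddg(ddg_exp) - classify_ddg(ddg_pred))
}

# Label sets for all 380 ordered (wt, mut) pairs, sequence-only (no burial).
# Memoised: the table is small and classification is pure.
pair_label_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      pairs <- expand.grid(wt = AA_CODES, mut = AA_CODES,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$wt != pairs$mut, ]
      labs <- mapply(function(w, m) list(classify_mutation(w, m)),
                     pairs$wt, pairs$mut)
      tab <<- list(pairs = pairs, labels = labs)
    }
    tab
  }
})

# All (wt, mut) pairs whose label set includes `label` (sequence-only).
pairs_for_label <- function(label) {
  tl <- pair_label_table()
  hit <- vapply(tl$labels, function(l) label %in% l, logical(1))
  tl$pairs[hit, , drop = FALSE]
}
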