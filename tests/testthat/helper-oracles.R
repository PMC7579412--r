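# Independent brute-force oracles used to cross-check the production
# implementations. These deliberately share no code with R/.

# Predictive Index by explicit double loop over all pairs.
pi_bruteforce <- function(exp, pred) {
  num <- 0
  den <- 0
  n <- length(exp)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- abs(exp[j] - exp[i])
      cc <- if (pred[j] == pred[i]) {
        0
      } else if ((exp[j] - exp[i]) * (pred[j] - pred[i]) > 0) {
        1
      } else {
        -1
      }
      num <- num + w * cc
      den <- den + w
    }
  }
  num / den
}

# Multiclass MCC evaluated directly from a confusion matrix.
mcc_from_confusion <- function(cm) {
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  (c_ * s - sum(p_k * t_k)) /
    sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
}

# Binary MCC by the classical TP/TN/FP/FN formula.
mcc_binary_classic <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# Monte-Carlo SASA oracle: random (not quasi-uniform) sphere sampling,
# plain loops, independent of the production Shrake-Rupley code.
sasa_mc_oracle <- function(s, probe = 1.4, n_points = 4000, seed = 99) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  atoms <- s$atoms[!(s$atoms$element %in% c("H", "D")), , drop = FALSE]
  set.seed(seed)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- unname(radii[atoms$element])
  r[is.na(r)] <- 1.70
  r <- r + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    g <- matrix(rnorm(3 * n_points), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    pts <- sweep(g * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 > r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  attr(out, "atoms") <- atoms
  out
}

# Minimum heavy-atom distance between one residue and all atoms of other
# chains, by exhaustive pair enumeration.
min_foreign_distance <- function(s, chain, resno) {
  a <- s$atoms[!(s$atoms$element %in% c("H", "D")), , drop = FALSE]
  res <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  other <- a[a$chain != chain & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
             drop = FALSE]
  if (!nrow(other)) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(other))) {
      d <- sqrt((res$x[i] - other$x[j])^2 + (res$y[i] - other$y[j])^2 +
                  (res$z[i] - other$z[j])^2)
      best <- min(best, d)
    }
  }
  best
}

# Single-linkage components by iterated merging of linked groups.
components_bruteforce <- function(idm, threshold) {
  n <- nrow(idm)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (idm[i, j] >= threshold && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Small hand-built mutation table for reader/curation tests.
tiny_mutation_table <- function() {
  mutation_table(
    pdb_id = c("1ABC", "1ABC", "2XYZ", "2XYZ", "3DEF"),
    chain = c("A", "A", "A", "B", "A"),
    position = c("56", "56", "10", "10", "7A"),
    wt_aa = c("L", "L", "K", "D", "A"),
    mut_aa = c("Q", "I", "R", "E", "P"),
    ddg_exp = c(1.2, -0.4, 0.1, 2.5, -1.6),
    ph = c(7.0, 5.0, 6.5, 7.4, NA))
}
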