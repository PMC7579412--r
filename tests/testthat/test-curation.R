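test_that("sequence identity matches hand-checked alignments", {
  expect_equal(sequence_identity("MKVLAT", "MKVLAT"), 1.0)
  expect_equal(sequence_identity("AAAA", "TTTT"), 0.0)
  expect_equal(sequence_identity("ACDEFGHIKL", "TTDEFGHIKT"), 0.7)
  # end gaps count toward the alignment length
  expect_equal(sequence_identity("ACDEF", "ACDEFGH"), 5 / 7)
  expect_error(sequence_identity("", "AAAA"), "empty")
})

test_that("single-linkage clustering matches a brute-force merge", {
  # a-b and b-c at ~0.67 identity, a-c at ~0.33: one transitive cluster
  s1 <- "ACDEFGHIKL"; s2 <- "MNQRSTVWYA"; s3 <- "CDEFGHIKLM"
  seqs <- c(a = paste0(s1, s2, s3),
            b = paste0("PPPPPPPPPP", s2, s3),
            c = paste0("PPPPPPPPPP", "GGGGGGGGGG", s3),
            d = "WWWWYYYYWWWWYYYYWWWWYYYYWWWWYY")
  cl <- cluster_parents(seqs, threshold = 0.6)
  expect_equal(unname(cl$membership["a"]), unname(cl$membership["b"]))
  expect_equal(unname(cl$membership["b"]), unname(cl$membership["c"]))
  expect_false(cl$membership[["d"]] == cl$membership[["a"]])
  oracle <- components_bruteforce(cl$identity, 0.6)
  expect_equal(as.integer(factor(cl$membership, levels = unique(cl$membership))),
               oracle)
  # all identical: one cluster
  same <- cluster_parents(c(x = "AAAA", y = "AAAA"), threshold = 0.6)
  expect_equal(length(unique(same$membership)), 1L)
})

test_that("deduplication keeps the measurement nearest neutral pH", {
  rec <- mutation_table(
    pdb_id = c("1AAA", "1BBB", "1AAA", "2CCC"),
    chain = "A", position = c("5", "5", "5", "5"),
    wt_aa = c("L", "L", "L", "L"),
    mut_aa = c("I", "I", "Q", "I"),
    ddg_exp = c(1.0, 1.1, 0.4, 2.0),
    ph = c(5.0, 7.0, 7.0, 4.0),
    record_id = c("dup_ph5", "dup_ph7", "other_mut", "unrelated"))
  seqs <- c("1AAA_A" = "MKLLVNSTAG", "1BBB_A" = "MKLLVNSTAG",
            "2CCC_A" = "WWPPWWPPWW")
  cl <- cluster_parents(seqs, threshold = 0.6)
  out <- deduplicate(rec, cl)
  # identical mutation in identical parents collapses to the pH-7 one;
  # a different mutation at the same position survives, as does the
  # same mutation in an unrelated parent
  expect_setequal(out$record_id, c("dup_ph7", "other_mut", "unrelated"))
  expect_equal(attr(out, "dropped")$record_id, "dup_ph5")
  # idempotent
  again <- deduplicate(out, cl)
  expect_equal(again$record_id, out$record_id)
  expect_equal(nrow(attr(again, "dropped")), 0)
})

test_that("pH ties break toward the lower pH and missing pH acts as 7", {
  rec <- mutation_table(
    pdb_id = "1AAA", chain = "A", position = c("5", "5"),
    wt_aa = "L", mut_aa = "I", ddg_exp = c(1, 2), ph = c(7.5, 6.5),
    record_id = c("hi", "lo"))
  expect_equal(deduplicate(rec)$record_id, "lo")
  rec2 <- mutation_table(
    pdb_id = "1AAA", chain = "A", position = c("5", "5"),
    wt_aa = "L", mut_aa = "I", ddg_exp = c(1, 2), ph = c(NA, 5),
    record_id = c("noph", "ph5"))
  out2 <- deduplicate(rec2)
  expect_equal(out2$record_id, "noph")
  expect_equal(attr(out2, "ph_imputed"), "noph")
})

test_that("deduplication maps positions through the cluster alignment", {
  # same protein with a one-residue N-terminal extension: position 5 in
  # one parent is position 6 in the other
  rec <- mutation_table(
    pdb_id = c("1AAA", "1BBB"), chain = "A", position = c("5", "6"),
    wt_aa = "F", mut_aa = "Y", ddg_exp = c(1, 1.2), ph = c(6, 7),
    record_id = c("short", "long"))
  seqs <- c("1AAA_A" = "MKLWFNSTAG", "1BBB_A" = "GMKLWFNSTAG")
  cl <- cluster_parents(seqs, threshold = 0.6)
  out <- deduplicate(rec, cl)
  expect_equal(out$record_id, "long")  # pH 7 beats pH 6
})

test_that("structure filters drop interface records with a logged reason", {
  toys_far <- gen_toy_structures(separation = 50)
  toys_near <- gen_toy_structures(separation = 6)
  rec <- mutation_table(
    pdb_id = c("FARX", "NEAR", "MISS"), chain = "A",
    position = c("6", "6", "6"), wt_aa = "A", mut_aa = "V",
    ddg_exp = c(1, 1, 1),
    record_id = c("mono", "interface", "no_structure"))
  res <- apply_structure_filters(
    rec, list(FARX = toys_far$helix_pair, NEAR = toys_near$helix_pair))
  expect_equal(res$records$record_id, "mono")
  expect_setequal(res$log$record_id, c("interface", "no_structure"))
  expect_match(res$log$reason[res$log$record_id == "interface"],
               "foreign contact")
  expect_match(res$log$reason[res$log$record_id == "no_structure"],
               "missing structure")
})

test_that("category balancing respects the cap and is deterministic", {
  mix <- setNames(c(0.6, 0.4), c("Hydrophobic to hydrophobic",
                                 "Positive to negative"))
  rec <- gen_mutation_table(synthetic_spec(n_records = 150,
                                           category_mix = mix, seed = 4))
  set <- balance_categories(rec, cap = 50, seed = 9)
  counts <- vapply(set$category_index, length, integer(1))
  # the oversubscribed category is cut to the cap exactly
  expect_equal(counts[["Hydrophobic to hydrophobic"]], 50L)
  narrow <- counts[category_labels(narrow = TRUE)]
  expect_true(all(narrow <= 50))
  # categories keep min(cap, available) entries
  n_pn <- sum(vapply(seq_len(nrow(rec)), function(i) {
    "Positive to negative" %in% classify_mutation(rec$wt_aa[i],
                                                  rec$mut_aa[i])
  }, logical(1)))
  expect_equal(counts[["Positive to negative"]], min(n_pn, 50L))
  # same seed, same selection; selection never invents records
  set2 <- balance_categories(rec, cap = 50, seed = 9)
  expect_equal(as.data.frame(set2$records), as.data.frame(set$records))
  expect_lte(nrow(set$records), nrow(rec))
})

test_that("the full curation pipeline is a no-op on its own output", {
  rec <- gen_mutation_table(synthetic_spec(n_records = 400, seed = 21))
  set <- curate_benchmark(rec, cap = 25, seed = 5)
  again <- curate_benchmark(set$records, cap = 25, seed = 5)
  expect_equal(as.data.frame(again$records), as.data.frame(set$records))
})

test_that("composition statistics match the closed-form null", {
  rec <- gen_mutation_table(synthetic_spec(n_records = 100, seed = 2))
  cs <- composition_stats(rec)
  tab <- cs$table
  # uniform wild type, mutant uniform over the 19 alternatives
  expect_equal(tab$expected_fraction[
    tab$category == "Hydrophobic to hydrophobic"], (8 / 20) * (7 / 19))
  expect_equal(tab$expected_fraction[tab$category == "Everything"], 1.0)
  expect_equal(tab$observed_fraction[tab$category == "Everything"], 1.0)
  expect_equal(unname(cs$to_hydrophobic["expected"]),
               (12 * 8 + 8 * 7) / 380)
  # a pure A->V table is 100% hydrophobic-to-hydrophobic
  pure <- mutation_table(pdb_id = "1AAA", chain = "A",
                         position = as.character(1:5), wt_aa = "A",
                         mut_aa = "V", ddg_exp = rnorm(5))
  cp <- composition_stats(pure)
  expect_equal(cp$table$observed_fraction[
    cp$table$category == "Hydrophobic to hydrophobic"], 1.0)
})

test_that("expected fractions over polarity pairs partition to one", {
  cs <- composition_stats(gen_mutation_table(synthetic_spec(50, seed = 6)))
  tab <- cs$table
  directional <- grep(" to ", category_labels(narrow = TRUE), value = TRUE)
  directional <- setdiff(directional, "Charge to charge")
  covered <- sum(tab$expected_fraction[tab$category %in%
                                         c(directional, "Charge to charge")])
  # residual: pairs where either residue lacks a polarity group (C or P)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  residual <- 0
  for (wt in aa) for (mut in setdiff(aa, wt)) {
    labs <- classify_mutation(wt, mut)
    if (!any(labs %in% c(directional, "Charge to charge"))) {
      residual <- residual + (1 / 20) * (1 / 19)
    }
  }
  expect_equal(covered + residual, 1.0)
})
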