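# brute-force region counts by per-gene membership enumeration
venn_oracle <- function(sets) {
  universe <- unique(toupper(unlist(sets)))
  pat <- sapply(sets, function(s) universe %in% toupper(s))
  apply(pat, 1, paste, collapse = ",")
}

test_that("venn regions cover disjoint, identical and random inputs", {
  disj <- list(a = c("G1", "G2"), b = c("G3"), c = c("G4", "G5"))
  v <- venn_counts(disj)
  expect_equal(sum(v$count[rowSums(v[, 1:3]) > 1]), 0)
  expect_equal(sum(v$count), 5)

  same <- list(a = c("X", "Y", "Z"), b = c("X", "Y", "Z"), c = c("X", "Y", "Z"))
  v <- venn_counts(same)
  expect_equal(v$count[v$a & v$b & v$c], 3)
  expect_equal(sum(v$count), 3)

  expect_error(venn_counts(list(a = "G1")), "2 or 3 sets")

  set.seed(30)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i) sample(sprintf("G%02d", 1:20),
                                           sample(5:15, 1)))
    names(sets) <- c("a", "b", "c")
    v <- venn_counts(sets)
    expect_equal(nrow(v), 7)
    key <- venn_oracle(sets)
    pkey <- apply(v[, 1:3], 1, paste, collapse = ",")
    expect_equal(v$count, as.integer(table(factor(key, levels = pkey))))
    # region sums reconstruct each input set's size
    for (nm in names(sets))
      expect_equal(sum(v$count[v[[nm]]]), length(unique(sets[[nm]])))
  }
})

worked_candidates <- function() {
  ex <- make_worked_example()
  names(ex)[names(ex) == "uv_senescence"] <- "senescence_A"
  names(ex)[names(ex) == "h2o2_senescence"] <- "senescence_B"
  ex
}

test_that("consistency filter keeps the rule-consistent trio", {
  filt <- consistency_filter(worked_candidates(), consistency_rule("down"))
  expect_identical(filt$kept, c("DDIT4", "GINS2", "PGAP6"))
  expect_identical(filt$excluded$gene_id, c("MCM7", "OAF"))
  expect_true(all(grepl("^inconsistent:senescence_[AB]$", filt$excluded$reason)))
})

test_that("consistency filter handles edge inputs and enforces ALL-sets", {
  empty <- consistency_filter(worked_candidates()[0, ], consistency_rule("down"))
  expect_length(empty$kept, 0)

  # consistent in one senescence set, opposite in the other -> excluded
  cand <- data.frame(gene_id = "G1", regulator_direction = "induced",
                     s1 = "down", s2 = "up")
  filt <- consistency_filter(cand, consistency_rule("down"))
  expect_length(filt$kept, 0)
  expect_identical(filt$excluded$reason, "inconsistent:s2")

  cand$s2 <- NA_character_
  expect_error(consistency_filter(cand, consistency_rule("down")),
               "G1 missing direction in comparison s2")
})

test_that("filter is order-independent, idempotent and sign-flip invariant", {
  cand <- worked_candidates()
  base <- consistency_filter(cand, consistency_rule("down"))
  set.seed(2)
  shuffled <- consistency_filter(cand[sample(nrow(cand)), ],
                                 consistency_rule("down"))
  expect_identical(shuffled$kept, base$kept)

  # rerunning on the kept subset keeps everything
  again <- consistency_filter(cand[cand$gene_id %in% base$kept, ],
                              consistency_rule("down"))
  expect_identical(again$kept, base$kept)

  # flipping every direction in every comparison preserves the subset
  flip_rd <- c(induced = "suppressed", suppressed = "induced")
  flip_ud <- c(up = "down", down = "up")
  flipped <- cand
  flipped$regulator_direction <- flip_rd[cand$regulator_direction]
  flipped$senescence_A <- flip_ud[cand$senescence_A]
  flipped$senescence_B <- flip_ud[cand$senescence_B]
  expect_identical(consistency_filter(flipped, consistency_rule("down"))$kept,
                   base$kept)
})

test_that("nominate_targets composes venn, intersection and filter", {
  reg <- deg_set(c("DDIT4", "GINS2", "MCM7", "OAF", "PGAP6", "EXTRA1"),
                 c("induced", "induced", "induced", "suppressed",
                   "suppressed", "induced"), label = "regulator")
  ex <- make_worked_example()
  uv <- deg_set(c(ex$gene_id, "UVONLY"), c(ex$uv_senescence, "up"),
                label = "uv")
  h2o2 <- deg_set(c(ex$gene_id, "H2O2ONLY"), c(ex$h2o2_senescence, "down"),
                  label = "h2o2")
  rep <- nominate_targets(reg, list(uv = uv, h2o2 = h2o2),
                          consistency_rule("down"))
  expect_identical(rep$intersection, sort(ex$gene_id))
  expect_identical(rep$nominated, c("DDIT4", "GINS2", "PGAP6"))
  # nominated subset of intersection subset of every input set
  expect_true(all(rep$nominated %in% rep$intersection))
  expect_true(all(rep$intersection %in% reg$gene_id))
  expect_true(all(rep$intersection %in% uv$gene_id))

  # single senescence set: consistency judged against it alone (both
  # MCM7 and OAF conflict only in the uv dataset)
  rep1 <- nominate_targets(reg, list(h2o2 = h2o2), consistency_rule("down"))
  expect_identical(rep1$nominated,
                   c("DDIT4", "GINS2", "MCM7", "OAF", "PGAP6"))
  rep2 <- nominate_targets(reg, list(uv = uv), consistency_rule("down"))
  expect_identical(rep2$nominated, c("DDIT4", "GINS2", "PGAP6"))

  # disjoint inputs: empty nomination, complete venn
  rep0 <- nominate_targets(deg_set("A1", "induced"),
                           list(s = deg_set("B1", "up")),
                           consistency_rule("down"))
  expect_length(rep0$nominated, 0)
  expect_equal(sum(rep0$venn$count), 2)
})
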