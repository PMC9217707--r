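# --- ratios ------------------------------------------------------------

test_that("per-subject ratios follow the pseudocount arithmetic", {
  d <- tiny_paired_design(2)
  m <- matrix(1, 3, 8, dimnames = list(paste0("g", 1:3),
                                       design_samples_for_test(d)))
  m["g1", "S1_OE"] <- 9; m["g1", "S1_OE_control"] <- 4   # (9+1)/(4+1) = 2
  m["g2", "S1_OE"] <- 0; m["g2", "S1_OE_control"] <- 0   # (0+1)/(0+1) = 1
  r <- compute_ratios(m, d, pseudocount = 1)
  expect_equal(r$oe["g1", "S1"], 2.0)
  expect_equal(r$oe["g2", "S1"], 1.0)
  expect_true(all(r$kd == 1))  # KD columns identical to their controls

  m2 <- m[, -1]
  expect_error(compute_ratios(m2, d), "absent.*S1_OE")
})

# --- paired statistics --------------------------------------------------

ratio_table_from_d <- function(D) {
  # oe ratio 2^d against a flat kd ratio of 1
  structure(list(oe = 2^D, kd = D * 0 + 1, pseudocount = 1),
            class = "ratio_table")
}

test_that("paired t and log2FC match the closed form", {
  D <- matrix(c(0.8, 1.0, 1.2), 1, 3,
              dimnames = list("g1", paste0("S", 1:3)))
  st <- paired_statistics(ratio_table_from_d(D))
  expect_equal(st$log2FC, 1.0)
  expect_equal(st$T, 1.0 / (0.2 / sqrt(3)), tolerance = 1e-12)  # ~8.660
  expect_false(st$degenerate)
})

test_that("paired statistics are antisymmetric and null at equality", {
  D <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  st <- paired_statistics(ratio_table_from_d(D))
  st_neg <- paired_statistics(ratio_table_from_d(-D))
  expect_equal(st_neg$T, -st$T)
  expect_equal(st_neg$log2FC, -st$log2FC)

  st0 <- paired_statistics(ratio_table_from_d(D * 0))
  expect_true(all(st0$T == 0) && all(st0$log2FC == 0))

  expect_error(paired_statistics(ratio_table_from_d(D[, 1, drop = FALSE])),
               "single subject")
})

test_that("zero-variance nonzero contrasts are flagged degenerate", {
  D <- matrix(0.7, 2, 3, dimnames = list(c("g1", "g2"), NULL))
  st <- paired_statistics(ratio_table_from_d(D))
  expect_true(all(st$degenerate))
  expect_true(all(st$T == Inf))
})

# --- unpaired statistics ------------------------------------------------

test_that("unpaired t matches the pooled-variance closed form", {
  des <- unpaired_design(c("c1", "c2"), c("k1", "k2"))
  # linear values chosen so log2(x + 1) is exactly (5, 6, 3, 4)
  m <- matrix(c(31, 63, 7, 15), 1, 4,
              dimnames = list("g1", c("c1", "c2", "k1", "k2")))
  st <- unpaired_statistics(m, des, pseudocount = 1)
  expect_equal(st$log2FC, 2.0)
  expect_equal(st$T, 2 / (sqrt(0.5) * sqrt(1)), tolerance = 1e-12)  # ~2.828
})

test_that("scaling in log space shifts no contrast and leaves T unchanged", {
  des <- unpaired_design(c("c1", "c2", "c3"), c("k1", "k2", "k3"))
  m <- rand_expr_matrix(40, 6, seed = 2,
                        sample_ids = c("c1", "c2", "c3", "k1", "k2", "k3"))
  st <- unpaired_statistics(m, des, pseudocount = 1)
  m2 <- 8 * (m + 1) - 1  # log2(m2 + 1) = 3 + log2(m + 1)
  st2 <- unpaired_statistics(m2, des, pseudocount = 1)
  expect_equal(st2$T, st$T, tolerance = 1e-9)
  expect_equal(st2$log2FC, st$log2FC, tolerance = 1e-9)
})

# --- empirical p-values -------------------------------------------------

test_that("empirical p-values count |null| >= |obs| with plus-one correction", {
  null <- c(-2, -1, 0, 1, 2)
  expect_equal(empirical_pvalue(1.5, null), 0.5)            # (1+2)/(1+5)
  expect_equal(empirical_pvalue(0, null), 1)                # every |v| >= 0
  expect_equal(empirical_pvalue(10, rnorm(999)), 1 / 1000)  # estimator floor
  expect_error(empirical_pvalue(1, numeric()), "empty null")

  # vectorized and monotone non-increasing in |obs|
  set.seed(5)
  null <- rnorm(200)
  obs <- seq(0, 4, length.out = 30)
  p <- empirical_pvalue(obs, null)
  expect_equal(p, sapply(obs, function(o) (1 + sum(abs(null) >= o)) / 201))
  expect_true(all(diff(p) <= 0))
})

# --- null construction --------------------------------------------------

test_that("null bookkeeping: B x G values, seed-reproducible", {
  d <- tiny_paired_design(3)
  m <- rand_paired_matrix(5, 3, seed = 4)
  n1 <- build_null(m, d, B = 2, seed = 42)
  expect_length(n1$T, 10)
  expect_length(n1$log2FC, 10)
  expect_identical(build_null(m, d, B = 2, seed = 42), n1)
  expect_false(identical(build_null(m, d, B = 2, seed = 43)$T, n1$T))
})

test_that("B beyond the distinct relabelings warns and recycles", {
  des <- unpaired_design(c("c1", "c2"), c("k1", "k2"))  # choose(4,2) = 6
  m <- rand_expr_matrix(3, 4, seed = 1, sample_ids = c("c1", "c2", "k1", "k2"))
  expect_warning(n <- build_null(m, des, B = 10, seed = 1), "6 distinct")
  expect_length(n$T, 30)
})

test_that("sampling without replacement reproduces exhaustive enumeration", {
  # 2-subject paired design: 24^2 = 576 distinct within-subject relabelings
  d <- tiny_paired_design(2)
  G <- 6
  m <- rand_paired_matrix(G, 2, seed = 8)
  nulls <- build_null(m, d, B = 576, seed = 3)

  # independent oracle: enumerate every pair of role permutations
  oracle <- enum_paired_null(m, d)
  expect_equal(sort(unname(nulls$T)), sort(unname(oracle$T)),
               tolerance = 1e-12)
  expect_equal(sort(unname(nulls$log2FC)), sort(unname(oracle$log2FC)),
               tolerance = 1e-12)

  # p-values from the sampled stream equal brute-force enumeration counts
  obs <- paired_statistics(compute_ratios(m, d, 1))
  p_impl <- empirical_pvalue(obs$T, nulls$T)
  p_oracle <- sapply(obs$T, function(t)
    (1 + sum(abs(oracle$T) >= abs(t))) / (1 + length(oracle$T)))
  expect_equal(p_impl, p_oracle, tolerance = 1e-12)
})

test_that("flipping the contrast flips directions but not p-values", {
  # at full enumeration the null is permutation-complete, so swapping
  # OE <-> OE_control and KD <-> KD_control negates T/log2FC and leaves
  # Pt/Pf unchanged up to floating-point resolution of permutation ties
  # at the |observed| boundary
  d <- tiny_paired_design(2)
  m <- rand_paired_matrix(8, 2, seed = 12)
  flip <- unclass(d)[, c(2, 1, 4, 3)]
  colnames(flip) <- colnames(unclass(d))
  d_flip <- structure(flip, class = "paired_design")

  r1 <- deg_test(m, d, deg_thresholds(B = 576, pt_cutoff = 0.3,
                                      pf_cutoff = 0.3), seed = 5)
  r2 <- deg_test(m, d_flip, deg_thresholds(B = 576, pt_cutoff = 0.3,
                                           pf_cutoff = 0.3), seed = 5)
  expect_equal(r2$stats$T, -r1$stats$T, tolerance = 1e-9)
  expect_equal(r2$stats$log2FC, -r1$stats$log2FC, tolerance = 1e-9)
  expect_lt(max(abs(r2$stats$Pt - r1$stats$Pt)), 0.01)
  expect_lt(max(abs(r2$stats$Pf - r1$stats$Pf)), 0.01)
  both <- merge(r1$deg, r2$deg, by = "gene_id")
  expect_true(all(both$direction.x != both$direction.y))
})

# --- DEG calling --------------------------------------------------------

test_that("DEG thresholds are inclusive and directions follow log2FC sign", {
  stats <- data.frame(gene_id = c("A", "B", "C", "D"),
                      T = c(5, -4, 1, 2), log2FC = c(2, -1, 0.1, 1),
                      Pt = c(0.05, 0.01, 0.5, 0.04),
                      Pf = c(0.10, 0.03, 0.9, 0.25))
  deg <- call_degs(stats, deg_thresholds(), vocabulary = "paired")
  expect_identical(deg$gene_id, c("A", "B"))  # boundary gene A included
  expect_identical(deg$direction, c("induced", "suppressed"))

  stats$Pt <- 1
  expect_equal(nrow(call_degs(stats, deg_thresholds())), 0)
  stats$Pt <- NA_real_
  expect_error(call_degs(stats, deg_thresholds()), "populated")
})

test_that("p-value bounds hold across a full test run", {
  d <- tiny_paired_design(3)
  m <- rand_paired_matrix(60, 3, seed = 21)
  res <- deg_test(m, d, deg_thresholds(B = 50), seed = 2)
  lo <- 1 / (1 + 50 * nrow(res$stats))
  expect_true(all(res$stats$Pt >= lo & res$stats$Pt <= 1))
  expect_true(all(res$stats$Pf >= lo & res$stats$Pf <= 1))
  # Pt monotone non-increasing in |T|
  ord <- order(abs(res$stats$T))
  expect_true(all(diff(res$stats$Pt[ord]) <= 0))
})

test_that("concordance report flags discordant subjects without filtering", {
  d <- tiny_paired_design(3)
  D <- matrix(c(1.1, 0.9, 1.3,
                1.1, -0.2, 1.3), 2, 3, byrow = TRUE,
              dimnames = list(c("G1", "G2"), paste0("S", 1:3)))
  ratios <- structure(list(oe = 2^D, kd = D * 0 + 1, pseudocount = 1),
                      class = "ratio_table")
  deg <- deg_set(c("G1", "G2"), c("induced", "induced"))
  rep <- concordance_report(ratios, deg)
  expect_equal(nrow(rep), 2)
  expect_identical(rep$concordant, c(TRUE, FALSE))
  expect_equal(rep$sign_S2, c(1, -1))
})
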