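# Shared fixture builders; everything is generated in code.

# Random positive expression matrix with gene/sample dimnames.
rand_expr_matrix <- function(n_genes, n_samples, seed = 1,
                             sample_ids = sprintf("SMP%d", seq_len(n_samples))) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 5, 2), n_genes, n_samples,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)), sample_ids))
  m
}

# Paired design over S subjects with samples named <subject>_<role>.
tiny_paired_design <- function(n_subjects = 3) {
  subjects <- sprintf("S%d", seq_len(n_subjects))
  roles <- c("OE", "OE_control", "KD", "KD_control")
  paired_design(sample_id = as.vector(t(outer(subjects, roles, paste, sep = "_"))),
                subject = rep(subjects, each = 4),
                condition = rep(roles, times = n_subjects))
}

# Matrix whose columns match tiny_paired_design(n_subjects).
rand_paired_matrix <- function(n_genes, n_subjects = 3, seed = 1) {
  d <- tiny_paired_design(n_subjects)
  rand_expr_matrix(n_genes, 4 * n_subjects, seed = seed,
                   sample_ids = design_samples_for_test(d))
}

design_samples_for_test <- function(design) {
  if (inherits(design, "paired_design")) as.vector(t(unclass(design)))
  else c(design$case, design$control)
}

# Independent enumeration of all permutations of a vector (recursive;
# deliberately different from the package's generator).
enum_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(enum_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# Exhaustive paired null for a 2-subject design by brute-force enumeration
# of every within-subject role relabeling (24^2 = 576). The t formula
# mirrors the implementation's operation order so that relabelings which
# are algebraically tied resolve ties identically at the bit level.
enum_paired_null <- function(m, design, eps = 1) {
  perms <- enum_perms(1:4)
  samples <- unclass(design)
  stopifnot(nrow(samples) == 2)
  oracle_T <- numeric(0); oracle_F <- numeric(0)
  for (p1 in perms) for (p2 in perms) {
    D <- cbind(
      log2((m[, samples[1, p1[1]]] + eps) / (m[, samples[1, p1[2]]] + eps)) -
        log2((m[, samples[1, p1[3]]] + eps) / (m[, samples[1, p1[4]]] + eps)),
      log2((m[, samples[2, p2[1]]] + eps) / (m[, samples[2, p2[2]]] + eps)) -
        log2((m[, samples[2, p2[3]]] + eps) / (m[, samples[2, p2[4]]] + eps)))
    mu <- rowMeans(D)
    s <- sqrt(rowSums((D - mu)^2) / 1)
    oracle_T <- c(oracle_T, ifelse(s > 0, mu / (s / sqrt(2)),
                                   ifelse(mu == 0, 0, sign(mu) * Inf)))
    oracle_F <- c(oracle_F, mu)
  }
  list(T = oracle_T, log2FC = oracle_F)
}
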