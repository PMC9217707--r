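#' Simulation configuration
#'
#' Describes a synthetic tri-dataset study mirroring the structure of the
#' integrative analysis this package implements: one paired regulator
#' perturbation experiment (each of \code{n_subjects} subjects contributes
#' overexpression, knockdown and matched control samples) and two unpaired
#' case/control senescence datasets. Differential expression is planted
#' with known directions, including genes shared across all three datasets
#' that are either consistent or deliberately inconsistent with the
#' regulator-down direction rule.
#'
#' Expression is log-normal: log2 values are baseline(gene) +
#' subject effect + condition effect + Gaussian noise, exponentiated to
#' the linear scale the pipeline consumes.
#'
#' @param n_genes total genes.
#' @param n_subjects subjects in the paired regulator study.
#' @param n_sen_case,n_sen_control samples per group in each senescence
#'   dataset.
#' @param n_regulator_de regulator-only planted DE genes (split evenly
#'   induced/suppressed).
#' @param n_senescence_de dataset-specific planted DE genes per senescence
#'   dataset.
#' @param n_shared_consistent genes planted DE in all three datasets with
#'   rule-consistent directions.
#' @param n_shared_inconsistent genes planted DE in all three datasets
#'   with a conflicting direction in exactly one senescence dataset.
#' @param effect_size planted |log2 fold change| (log2 units).
#' @param noise_sd within-gene Gaussian noise sd (log2 units).
#' @param subject_sd subject-effect sd (log2 units), shared by all four of
#'   a subject's samples.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression
#'   distribution.
#' @param seed integer seed; the whole study is a deterministic function
#'   of the configuration.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, n_subjects = 3L,
                       n_sen_case = 3L, n_sen_control = 3L,
                       n_regulator_de = 200L, n_senescence_de = 300L,
                       n_shared_consistent = 5L, n_shared_inconsistent = 2L,
                       effect_size = 1.0, noise_sd = 0.25,
                       subject_sd = 0.1,
                       baseline_mean = 5.0, baseline_sd = 2.0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_subjects = as.integer(n_subjects),
              n_sen_case = as.integer(n_sen_case),
              n_sen_control = as.integer(n_sen_control),
              n_regulator_de = as.integer(n_regulator_de),
              n_senescence_de = as.integer(n_senescence_de),
              n_shared_consistent = as.integer(n_shared_consistent),
              n_shared_inconsistent = as.integer(n_shared_inconsistent),
              effect_size = effect_size, noise_sd = noise_sd,
              subject_sd = subject_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, seed = as.integer(seed))
  n_shared <- cfg$n_shared_consistent + cfg$n_shared_inconsistent
  n_planted <- n_shared + cfg$n_regulator_de + 2L * cfg$n_senescence_de
  if (n_planted > cfg$n_genes)
    stop("planted gene counts (", n_planted, ") exceed n_genes (",
         cfg$n_genes, ")")
  if (cfg$n_subjects < 2L) stop("need at least 2 subjects")
  if (cfg$n_sen_case < 2L || cfg$n_sen_control < 2L)
    stop("each senescence group needs at least 2 samples")
  if (cfg$noise_sd <= 0 || cfg$subject_sd < 0 || cfg$baseline_sd <= 0)
    stop("noise/baseline sds must be positive")
  structure(cfg, class = "sim_config")
}

# Alternating direction labels for a planted block.
alt_dirs <- function(n, pos, neg) {
  if (n == 0L) return(character())
  rep_len(c(pos, neg), n)
}

#' Generate a synthetic tri-dataset study
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{simulated_study}: list with
#'   \code{regulator} (matrix + \code{paired_design}), \code{senescence}
#'   (two elements, each matrix + \code{unpaired_design}), \code{truth}
#'   (per-gene ground-truth data.frame) and \code{config}.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  # disjoint planted blocks
  i <- 0L
  take <- function(n) { out <- genes[seq_len(n) + i]; i <<- i + n; out }
  shared_cons <- take(cfg$n_shared_consistent)
  shared_inc <- take(cfg$n_shared_inconsistent)
  reg_only <- take(cfg$n_regulator_de)
  sen1_only <- take(cfg$n_senescence_de)
  sen2_only <- take(cfg$n_senescence_de)

  truth <- data.frame(gene_id = genes,
                      regulator_de = FALSE, regulator_direction = NA_character_,
                      sen1_de = FALSE, sen1_direction = NA_character_,
                      sen2_de = FALSE, sen2_direction = NA_character_,
                      shared_consistent = genes %in% shared_cons,
                      shared_inconsistent = genes %in% shared_inc,
                      row.names = NULL)
  set_dir <- function(truth, ids, comp, dirs) {
    idx <- match(ids, truth$gene_id)
    truth[[paste0(comp, "_de")]][idx] <- TRUE
    truth[[paste0(comp, "_direction")]][idx] <- dirs
    truth
  }
  rule <- consistency_rule("down")
  reg_dir_cons <- alt_dirs(length(shared_cons), "induced", "suppressed")
  reg_dir_inc <- alt_dirs(length(shared_inc), "induced", "suppressed")
  truth <- set_dir(truth, shared_cons, "regulator", reg_dir_cons)
  truth <- set_dir(truth, shared_inc, "regulator", reg_dir_inc)
  truth <- set_dir(truth, reg_only, "regulator",
                   alt_dirs(length(reg_only), "induced", "suppressed"))
  # consistent shared genes follow the rule in both senescence datasets
  truth <- set_dir(truth, shared_cons, "sen1", unclass(rule)[reg_dir_cons])
  truth <- set_dir(truth, shared_cons, "sen2", unclass(rule)[reg_dir_cons])
  # inconsistent shared genes conflict in exactly one dataset (alternating)
  flip <- function(d) ifelse(d == "up", "down", "up")
  exp_inc <- unclass(rule)[reg_dir_inc]
  conflict_in_1 <- seq_along(shared_inc) %% 2L == 1L
  truth <- set_dir(truth, shared_inc, "sen1",
                   ifelse(conflict_in_1, flip(exp_inc), exp_inc))
  truth <- set_dir(truth, shared_inc, "sen2",
                   ifelse(conflict_in_1, exp_inc, flip(exp_inc)))
  truth <- set_dir(truth, sen1_only, "sen1",
                   alt_dirs(length(sen1_only), "up", "down"))
  truth <- set_dir(truth, sen2_only, "sen2",
                   alt_dirs(length(sen2_only), "up", "down"))

  with_seed(cfg$seed, {
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

    # paired regulator study: subjects x roles
    subjects <- sprintf("S%d", seq_len(cfg$n_subjects))
    reg_samples <- as.vector(t(outer(subjects, PAIRED_ROLES, paste, sep = "_")))
    reg_design <- paired_design(
      sample_id = reg_samples,
      subject = rep(subjects, each = 4L),
      condition = rep(PAIRED_ROLES, times = cfg$n_subjects))
    subj_eff <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    reg_sign <- ifelse(is.na(truth$regulator_direction), 0,
                       ifelse(truth$regulator_direction == "induced", 1, -1))
    reg_log2 <- matrix(0, cfg$n_genes, length(reg_samples),
                       dimnames = list(genes, reg_samples))
    for (s in seq_len(cfg$n_subjects)) for (r in seq_len(4L)) {
      smp <- paste(subjects[s], PAIRED_ROLES[r], sep = "_")
      effect <- switch(PAIRED_ROLES[r],
                       OE = reg_sign * cfg$effect_size,
                       KD = -reg_sign * cfg$effect_size,
                       0)
      reg_log2[, smp] <- baseline + subj_eff[s] + effect +
        stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
    }

    make_sen <- function(k) {
      dirs <- truth[[paste0("sen", k, "_direction")]]
      sgn <- ifelse(is.na(dirs), 0, ifelse(dirs == "up", 1, -1))
      cases <- sprintf("sen%d_case_%d", k, seq_len(cfg$n_sen_case))
      ctrls <- sprintf("sen%d_ctrl_%d", k, seq_len(cfg$n_sen_control))
      m <- matrix(0, cfg$n_genes, length(cases) + length(ctrls),
                  dimnames = list(genes, c(cases, ctrls)))
      for (smp in cases)
        m[, smp] <- baseline + sgn * cfg$effect_size +
          stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      for (smp in ctrls)
        m[, smp] <- baseline + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      list(matrix = 2^m, design = unpaired_design(cases, ctrls))
    }
    sen1 <- make_sen(1L)
    sen2 <- make_sen(2L)
  })

  structure(list(
    regulator = list(matrix = 2^reg_log2, design = reg_design),
    senescence = list(sen1 = sen1, sen2 = sen2),
    truth = truth, config = cfg), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat("Simulated tri-dataset study: ", cfg$n_genes, " genes; paired ",
      cfg$n_subjects, "-subject regulator study + 2 senescence datasets (",
      cfg$n_sen_case, "v", cfg$n_sen_control, ")\n", sep = "")
  cat("  planted: ", sum(x$truth$regulator_de), " regulator DE, ",
      sum(x$truth$sen1_de), "/", sum(x$truth$sen2_de), " senescence DE, ",
      sum(x$truth$shared_consistent), " shared-consistent, ",
      sum(x$truth$shared_inconsistent), " shared-inconsistent\n", sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the three expression matrices, the design tables and the
#' ground-truth table as TSV files.
#'
#' @param study a \code{\link{generate_study}} result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of paths written.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(regulator_matrix = file.path(dir, "regulator_matrix.tsv"),
         regulator_design = file.path(dir, "regulator_design.tsv"),
         sen1_matrix = file.path(dir, "senescence1_matrix.tsv"),
         sen1_design = file.path(dir, "senescence1_design.tsv"),
         sen2_matrix = file.path(dir, "senescence2_matrix.tsv"),
         sen2_design = file.path(dir, "senescence2_design.tsv"),
         truth = file.path(dir, "ground_truth.tsv"))
  write_expression_matrix(study$regulator$matrix, p["regulator_matrix"])
  d <- unclass(study$regulator$design)
  utils::write.table(
    data.frame(sample_id = as.vector(t(d)),
               subject = rep(rownames(d), each = 4L),
               condition = rep(colnames(d), times = nrow(d))),
    p["regulator_design"], sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in 1:2) {
    sen <- study$senescence[[k]]
    write_expression_matrix(sen$matrix, p[paste0("sen", k, "_matrix")])
    utils::write.table(
      data.frame(sample_id = c(sen$design$case, sen$design$control),
                 group = rep(c("case", "control"),
                             c(length(sen$design$case),
                               length(sen$design$control)))),
      p[paste0("sen", k, "_design")], sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  utils::write.table(study$truth, p["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(p)
}

#' The five-gene worked example
#'
#' The fixed candidate table for the integrative workflow's documented
#' example: five genes shared by the regulator comparison and both
#' senescence datasets, with their per-comparison directions. Under the
#' regulator-down consistency rule, three of them (DDIT4, GINS2, PGAP6)
#' are direction-consistent and two (MCM7, OAF) are not.
#'
#' @return data.frame with columns \code{gene_id},
#'   \code{regulator_direction}, \code{uv_senescence},
#'   \code{h2o2_senescence}.
#' @export
make_worked_example <- function() {
  data.frame(
    gene_id = c("DDIT4", "GINS2", "MCM7", "OAF", "PGAP6"),
    regulator_direction = c("induced", "induced", "induced",
                            "suppressed", "suppressed"),
    uv_senescence = c("down", "down", "up", "down", "up"),
    h2o2_senescence = c("down", "down", "down", "up", "up"),
    row.names = NULL)
}
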