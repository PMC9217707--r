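#' Run the full integrative DEG workflow
#'
#' End-to-end orchestration: quantile-normalize each input matrix, run the
#' paired permutation DEG test on the regulator perturbation study and the
#' unpaired test on each senescence dataset, intersect the three DEG sets,
#' and nominate direction-consistent regulator targets. Deterministic
#' given the seed.
#'
#' @param study either a \code{\link{generate_study}} result or a list of
#'   the same shape: \code{regulator = list(matrix, design)} (paired) and
#'   \code{senescence} = named list of \code{list(matrix, design)}
#'   (unpaired).
#' @param thresholds a \code{\link{deg_thresholds}} object, applied to
#'   every comparison.
#' @param rule a \code{\link{consistency_rule}}.
#' @param seed integer seed; per-comparison permutation seeds are derived
#'   from it deterministically.
#' @param outdir optional output directory; when given, normalized
#'   matrices, per-comparison results tables, Venn counts and the
#'   nomination table are written there as TSVs.
#' @param normalize quantile-normalize the input matrices first (set
#'   \code{FALSE} for pre-normalized inputs).
#' @return object of class \code{pipeline_result}: list with
#'   \code{regulator} and \code{senescence} \code{deg_result}s,
#'   \code{nomination} (a \code{nomination_report}), and \code{paths}.
#' @export
run_full <- function(study, thresholds = deg_thresholds(),
                     rule = consistency_rule("down"), seed = 1L,
                     outdir = NULL, normalize = TRUE) {
  if (!is.list(study) || is.null(study$regulator) || is.null(study$senescence))
    stop("stage input: 'study' must carry $regulator and $senescence components")
  sen_names <- names(study$senescence)
  if (is.null(sen_names) || any(!nzchar(sen_names)))
    sen_names <- names(study$senescence) <- paste0("sen", seq_along(study$senescence))

  prep <- function(m) if (normalize) quantile_normalize(m) else m
  reg_mat <- prep(study$regulator$matrix)
  reg <- deg_test(reg_mat, study$regulator$design, thresholds,
                  seed = seed, label = "regulator")
  sen <- vector("list", length(study$senescence))
  names(sen) <- sen_names
  sen_mats <- vector("list", length(study$senescence))
  for (k in seq_along(study$senescence)) {
    sen_mats[[k]] <- prep(study$senescence[[k]]$matrix)
    sen[[k]] <- deg_test(sen_mats[[k]], study$senescence[[k]]$design,
                         thresholds, seed = seed + k,
                         label = sen_names[k])
  }
  nomination <- nominate_targets(reg$deg, lapply(sen, `[[`, "deg"), rule)

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(regulator_matrix = file.path(outdir, "regulator_matrix.qn.tsv"),
               regulator_results = file.path(outdir, "regulator_results.tsv"),
               venn = file.path(outdir, "venn_counts.tsv"),
               nominations = file.path(outdir, "nominations.tsv"))
    write_expression_matrix(reg_mat, paths["regulator_matrix"])
    write_results_table(reg$stats, paths["regulator_results"])
    for (k in seq_along(sen)) {
      pm <- file.path(outdir, paste0(sen_names[k], "_matrix.qn.tsv"))
      pr <- file.path(outdir, paste0(sen_names[k], "_results.tsv"))
      write_expression_matrix(sen_mats[[k]], pm)
      write_results_table(sen[[k]]$stats, pr)
      paths[paste0(sen_names[k], "_matrix")] <- pm
      paths[paste0(sen_names[k], "_results")] <- pr
    }
    utils::write.table(nomination$venn, paths["venn"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nom_tab <- nomination$candidates
    nom_tab$nominated <- nom_tab$gene_id %in% nomination$nominated
    nom_tab$reason <- nomination$excluded$reason[
      match(nom_tab$gene_id, nomination$excluded$gene_id)]
    utils::write.table(nom_tab, paths["nominations"], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  structure(list(regulator = reg, senescence = sen,
                 nomination = nomination, paths = paths,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$regulator)
  for (s in x$senescence) print(s)
  print(x$nomination)
  invisible(x)
}
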