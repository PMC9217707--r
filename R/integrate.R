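#' Venn region counts for 2-3 DEG sets
#'
#' Partitions the union of the input gene sets into exclusive membership
#' regions (3 regions for 2 sets, 7 for 3) and counts each. Region sums
#' reconstruct every input set's size.
#'
#' @param sets named list of 2-3 character vectors of gene ids (or
#'   \code{deg_set} objects), canonicalized identically.
#' @return data.frame with one row per nonempty-pattern region: logical
#'   membership columns (one per set) and \code{count}; attribute
#'   \code{set_sizes} carries the input sizes.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L)
    stop("venn_counts needs 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  ids <- lapply(sets, function(s) {
    unique(canonicalize_gene_ids(if (is.data.frame(s)) s$gene_id else s))
  })
  universe <- unique(unlist(ids))
  member <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(ids),
                   dimnames = list(NULL, names(ids)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(ids)))[-2^length(ids), , drop = FALSE]
  colnames(patterns) <- names(ids)
  patterns <- patterns[do.call(order, as.list(-patterns)), , drop = FALSE]
  key <- apply(member, 1L, paste, collapse = ",")
  pkey <- apply(patterns, 1L, paste, collapse = ",")
  out <- data.frame(patterns, count = as.integer(table(factor(key, levels = pkey))),
                    row.names = NULL, check.names = FALSE)
  structure(out, set_sizes = lengths(ids))
}

#' Genes present in every set
#'
#' @param sets named list of gene id vectors or \code{deg_set}s.
#' @return sorted character vector of the full intersection.
#' @export
intersect_all <- function(sets) {
  ids <- lapply(sets, function(s) {
    unique(canonicalize_gene_ids(if (is.data.frame(s)) s$gene_id else s))
  })
  sort(Reduce(intersect, ids))
}

#' Direction-consistency rule for regulator targets
#'
#' Encodes the biological expectation linking a regulator's own behavior in
#' a condition to its targets' behavior there. With the regulator DOWN in
#' senescence (the study's case: HDAC4 falls in senescent cells), genes the
#' regulator induces should be down in senescence and genes it suppresses
#' should be up; with the regulator up, the expectations flip.
#'
#' @param regulator_change \code{"down"} or \code{"up"}: the regulator's
#'   change in the condition datasets.
#' @return object of class \code{consistency_rule}: named character vector
#'   mapping regulator directions (induced/suppressed) to expected
#'   condition directions (down/up).
#' @export
consistency_rule <- function(regulator_change = c("down", "up")) {
  regulator_change <- match.arg(regulator_change)
  expected <- if (regulator_change == "down")
    c(induced = "down", suppressed = "up")
  else
    c(induced = "up", suppressed = "down")
  structure(expected, class = "consistency_rule",
            regulator_change = regulator_change)
}

#' Filter shared DEGs by cross-dataset direction consistency
#'
#' Retains exactly the candidate genes whose direction in EVERY condition
#' (senescence) dataset matches the expectation derived from their
#' regulator direction under the given rule; the rest are excluded with a
#' machine-readable reason (\code{"inconsistent:<set label>"}).
#'
#' @param candidates data.frame with columns \code{gene_id},
#'   \code{regulator_direction} (induced/suppressed), and one direction
#'   column (up/down) per condition dataset (every remaining column is
#'   treated as one).
#' @param rule a \code{\link{consistency_rule}}.
#' @return list with \code{kept} (sorted gene ids) and \code{excluded}
#'   (data.frame gene_id, reason).
#' @export
consistency_filter <- function(candidates, rule = consistency_rule("down")) {
  stopifnot(inherits(rule, "consistency_rule"))
  need <- c("gene_id", "regulator_direction")
  if (!all(need %in% colnames(candidates)))
    stop("candidates need columns: ", paste(need, collapse = ", "))
  sen_cols <- setdiff(colnames(candidates), need)
  if (nrow(candidates) == 0L)
    return(list(kept = character(), excluded = data.frame(
      gene_id = character(), reason = character())))
  if (length(sen_cols) == 0L)
    stop("candidates carry no condition-dataset direction columns")
  bad_reg <- is.na(candidates$regulator_direction) |
    !candidates$regulator_direction %in% names(rule)
  if (any(bad_reg))
    stop("candidate ", candidates$gene_id[which(bad_reg)[1L]],
         " missing/invalid direction in the regulator comparison")
  expected <- unclass(rule)[candidates$regulator_direction]
  reasons <- rep(NA_character_, nrow(candidates))
  for (col in sen_cols) {
    dirs <- candidates[[col]]
    if (anyNA(dirs))
      stop("candidate ", candidates$gene_id[which(is.na(dirs))[1L]],
           " missing direction in comparison ", col)
    mismatch <- dirs != expected & is.na(reasons)
    reasons[mismatch] <- paste0("inconsistent:", col)
  }
  kept <- sort(canonicalize_gene_ids(candidates$gene_id[is.na(reasons)]))
  excluded <- data.frame(
    gene_id = canonicalize_gene_ids(candidates$gene_id[!is.na(reasons)]),
    reason = reasons[!is.na(reasons)], row.names = NULL)
  excluded <- excluded[order(excluded$gene_id), , drop = FALSE]
  rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Nominate regulator targets from overlapping DEG sets
#'
#' The integrative workflow: intersect the regulator-perturbation DEG set
#' with one or more condition (senescence) DEG sets, then keep the genes in
#' the full intersection whose directions are consistent with the rule in
#' every condition dataset. Output ordering is deterministic
#' (alphabetical).
#'
#' @param regulator_set \code{deg_set} from the paired regulator
#'   comparison (directions induced/suppressed).
#' @param senescence_sets named list of \code{deg_set}s from the condition
#'   comparisons (directions up/down).
#' @param rule a \code{\link{consistency_rule}}.
#' @return object of class \code{nomination_report}: list with
#'   \code{venn} (region counts), \code{intersection} (genes in all sets),
#'   \code{nominated} (consistent subset), \code{excluded} (reasons), and
#'   \code{candidates} (the direction table the filter saw).
#' @export
nominate_targets <- function(regulator_set, senescence_sets,
                             rule = consistency_rule("down")) {
  stopifnot(inherits(regulator_set, "deg_set"))
  if (!is.list(senescence_sets) || inherits(senescence_sets, "deg_set"))
    senescence_sets <- list(senescence = senescence_sets)
  if (length(senescence_sets) < 1L)
    stop("at least one condition dataset is required")
  if (is.null(names(senescence_sets)) || any(!nzchar(names(senescence_sets))))
    names(senescence_sets) <- paste0("senescence_", seq_along(senescence_sets))
  all_sets <- c(list(regulator = regulator_set), senescence_sets)
  venn <- if (length(all_sets) >= 2L && length(all_sets) <= 3L)
    venn_counts(all_sets) else NULL
  shared <- intersect_all(all_sets)
  candidates <- data.frame(
    gene_id = shared,
    regulator_direction = regulator_set$direction[
      match(shared, regulator_set$gene_id)],
    row.names = NULL)
  for (nm in names(senescence_sets)) {
    s <- senescence_sets[[nm]]
    candidates[[nm]] <- s$direction[match(shared, s$gene_id)]
  }
  filt <- consistency_filter(candidates, rule)
  structure(list(venn = venn, intersection = shared,
                 nominated = filt$kept, excluded = filt$excluded,
                 candidates = candidates, rule = rule),
            class = "nomination_report")
}

#' @export
print.nomination_report <- function(x, ...) {
  cat("Target nomination (regulator ", attr(x$rule, "regulator_change"),
      " in condition):\n", sep = "")
  cat("  genes in all sets: ", length(x$intersection),
      if (length(x$intersection))
        paste0(" (", paste(x$intersection, collapse = ", "), ")"), "\n",
      sep = "")
  cat("  nominated (direction-consistent): ", length(x$nominated),
      if (length(x$nominated))
        paste0(" (", paste(x$nominated, collapse = ", "), ")"), "\n",
      sep = "")
  if (nrow(x$excluded))
    cat("  excluded: ",
        paste(paste0(x$excluded$gene_id, " [", x$excluded$reason, "]"),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}
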