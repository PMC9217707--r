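#' Canonicalize gene identifiers
#'
#' Gene symbols are matched across datasets after uppercasing and stripping
#' surrounding whitespace, the usual convention when intersecting symbol-keyed
#' lists from different platforms.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of canonical identifiers.
#' @export
canonicalize_gene_ids <- function(ids) {
  toupper(trimws(as.character(ids)))
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a delimited text file whose first column holds gene identifiers
#' (header \code{gene_id}) and whose remaining columns are samples. Values
#' must be finite and nonnegative (FPKM-like or normalized array
#' intensities). Gene identifiers are canonicalized (uppercase, trimmed);
#' rows that collide after canonicalization are collapsed by their mean, the
#' common probe-collapse convention.
#'
#' @param path path to the file.
#' @param sep field delimiter; tab by default, use \code{","} for CSV.
#' @return numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expression matrix needs a gene_id column and at least one sample column")
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  gene_ids <- canonicalize_gene_ids(raw[[1L]])
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), sample column '%s'",
                   col[bad[1L]], bad[1L], gene_ids[bad[1L]], sample_ids[j]))
    vals[, j] <- num
  }
  rownames(vals) <- gene_ids
  validate_expression_matrix(collapse_duplicate_genes(vals))
}

# Collapse rows sharing a canonical gene id by their per-sample mean.
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  ids <- rownames(mat)
  n_dup <- sum(duplicated(ids))
  out <- rowsum(mat, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  message(n_dup, " duplicate gene row(s) collapsed by mean")
  out
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, unique gene and sample
#' identifiers, all values finite and nonnegative.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @return the matrix, invisibly unchanged, or an error.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  if (any(!is.finite(mat)))
    stop("expression matrix contains non-finite values")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene %s, sample %s",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  mat
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{read_expression_matrix}}; numbers are written with
#' 6 significant digits.
#'
#' @param mat numeric expression matrix (genes x samples).
#' @param path output path.
#' @param sep field delimiter.
#' @return invisibly, \code{path}.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t") {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat),
                   signif(mat, 6L), check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Paired designs describe a per-subject four-arm perturbation: each subject
#' contributes one sample in each of the roles \code{OE} (regulator
#' overexpression), \code{OE_control}, \code{KD} (knockdown) and
#' \code{KD_control}. Unpaired designs are plain case/control tables.
#'
#' @param path TSV with header \code{sample_id<TAB>subject<TAB>condition}
#'   (paired) or \code{sample_id<TAB>group} (unpaired; a 3-column table with
#'   a \code{condition} column is also accepted).
#' @param kind \code{"paired"} or \code{"unpaired"}.
#' @return a \code{paired_design} or \code{unpaired_design} object.
#' @export
read_design <- function(path, kind = c("paired", "unpaired")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (kind == "paired") {
    need <- c("sample_id", "subject", "condition")
    if (!all(need %in% colnames(df)))
      stop("paired design needs columns: ", paste(need, collapse = ", "))
    paired_design(df$sample_id, df$subject, df$condition)
  } else {
    grp_col <- if ("group" %in% colnames(df)) "group" else "condition"
    if (!all(c("sample_id", grp_col) %in% colnames(df)))
      stop("unpaired design needs columns sample_id and group")
    unpaired_design(df$sample_id[df[[grp_col]] == "case"],
                    df$sample_id[df[[grp_col]] == "control"],
                    unknown = setdiff(unique(df[[grp_col]]),
                                      c("case", "control")))
  }
}

PAIRED_ROLES <- c("OE", "OE_control", "KD", "KD_control")

#' Construct a paired four-arm design
#'
#' @param sample_id,subject,condition parallel vectors; \code{condition}
#'   must use the vocabulary \code{OE}, \code{OE_control}, \code{KD},
#'   \code{KD_control}.
#' @return object of class \code{paired_design}: a subjects-by-roles
#'   character matrix of sample ids (rows sorted by subject).
#' @export
paired_design <- function(sample_id, subject, condition) {
  unknown <- setdiff(unique(condition), PAIRED_ROLES)
  if (length(unknown))
    stop("unknown condition token(s): ", paste(unknown, collapse = ", "),
         " (expected ", paste(PAIRED_ROLES, collapse = "/"), ")")
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in design")
  subjects <- sort(unique(subject))
  m <- matrix(NA_character_, length(subjects), 4L,
              dimnames = list(subjects, PAIRED_ROLES))
  for (i in seq_along(sample_id)) {
    if (!is.na(m[subject[i], condition[i]]))
      stop(sprintf("subject %s has more than one %s sample",
                   subject[i], condition[i]))
    m[subject[i], condition[i]] <- sample_id[i]
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss))
    stop(sprintf("incomplete paired design: subject %s is missing role %s",
                 rownames(m)[miss[1L, 1L]], colnames(m)[miss[1L, 2L]]))
  if (nrow(m) < 2L)
    stop("paired design needs at least 2 subjects for a paired t-statistic")
  structure(m, class = "paired_design")
}

#' Construct an unpaired case/control design
#'
#' @param case_sample_ids,control_sample_ids sample identifier vectors.
#' @param unknown internal: unrecognized group tokens to report.
#' @return object of class \code{unpaired_design}: a list with elements
#'   \code{case} and \code{control}.
#' @export
unpaired_design <- function(case_sample_ids, control_sample_ids,
                            unknown = character()) {
  if (length(unknown))
    stop("unknown group token(s): ", paste(unknown, collapse = ", "),
         " (expected case/control)")
  case <- sort(unique(as.character(case_sample_ids)))
  control <- sort(unique(as.character(control_sample_ids)))
  if (length(intersect(case, control)))
    stop("case and control groups overlap: ",
         paste(intersect(case, control), collapse = ", "))
  if (length(case) < 2L || length(control) < 2L)
    stop("each group needs at least 2 samples (got ", length(case), " case, ",
         length(control), " control)")
  structure(list(case = case, control = control), class = "unpaired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat("Paired four-arm design:", nrow(x), "subjects x",
      ncol(x), "roles\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.unpaired_design <- function(x, ...) {
  cat("Unpaired design:", length(x$case), "case vs",
      length(x$control), "control samples\n")
  invisible(x)
}

# All sample ids referenced by a design, in a fixed order.
design_samples <- function(design) {
  if (inherits(design, "paired_design")) as.vector(t(unclass(design)))
  else c(design$case, design$control)
}

check_design_in_matrix <- function(design, mat) {
  missing <- setdiff(design_samples(design), colnames(mat))
  if (length(missing))
    stop("design references sample(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a gene list
#'
#' One gene identifier per line; an optional second tab-separated column
#' carries a direction tag (\code{up}/\code{down}).
#'
#' @param path input path.
#' @return data.frame with columns \code{gene_id} and (if present)
#'   \code{direction}.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- canonicalize_gene_ids(vapply(parts, `[`, "", 1L))
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in list: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  has_dir <- lengths(parts) >= 2L
  if (any(has_dir)) {
    if (!all(has_dir))
      stop("direction tags must cover all genes or none")
    dir <- tolower(trimws(vapply(parts, `[`, "", 2L)))
    bad <- setdiff(unique(dir), c("up", "down"))
    if (length(bad)) stop("invalid direction tag(s): ", paste(bad, collapse = ", "))
    data.frame(gene_id = ids, direction = dir)
  } else {
    data.frame(gene_id = ids)
  }
}

RESULTS_COLUMNS <- c("gene_id", "T", "log2FC", "Pt", "Pf", "is_deg", "direction")

#' Write a per-gene results table
#'
#' Fixed column order \code{gene_id, T, log2FC, Pt, Pf, is_deg, direction},
#' tab-separated, numbers at 6 significant digits.
#'
#' @param stats data.frame of per-gene statistics (as returned by
#'   \code{\link{deg_test}}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_results_table <- function(stats, path) {
  if (is.null(stats) || nrow(stats) == 0L)
    stop("results table must contain at least one gene")
  missing <- setdiff(RESULTS_COLUMNS, colnames(stats))
  if (length(missing))
    stop("stats table missing column(s): ", paste(missing, collapse = ", "))
  out <- stats[, RESULTS_COLUMNS]
  for (col in c("T", "log2FC", "Pt", "Pf")) out[[col]] <- signif(out[[col]], 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by \code{write_results_table}
#'
#' @param path input path.
#' @return data.frame with the fixed results columns.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(RESULTS_COLUMNS, colnames(df))
  if (length(missing))
    stop("results table missing column(s): ", paste(missing, collapse = ", "))
  df$is_deg <- as.logical(df$is_deg)
  df
}
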