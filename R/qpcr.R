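#' Read a qPCR Ct table
#'
#' Long-format TSV with header \code{sample_id<TAB>group<TAB>gene<TAB>Ct}:
#' one row per (sample, gene) cycle-threshold measurement. Groups label
#' treated vs control samples.
#'
#' @param path input path.
#' @return data.frame with columns sample_id, group, gene, Ct.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "Ct")
  if (!all(need %in% colnames(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  df$Ct <- as.numeric(df$Ct)
  if (any(!is.finite(df$Ct))) stop("non-finite Ct value(s)")
  df
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, dCt = Ct_target - Ct_reference; ddCt is the difference of
#' group-mean dCt between treated and control; the fold change is
#' 2^(-ddCt) (amplification efficiency fixed at 2, the method's defining
#' assumption). Per-replicate fold changes (each treated sample's dCt
#' against the control mean) are also returned for standard-error
#' reporting.
#'
#' @param ct long-format Ct data.frame (see \code{\link{read_ct_table}}).
#' @param target target gene name.
#' @param reference reference gene name (study default \code{"36B4"}).
#' @param treated,control group labels in \code{ct$group}.
#' @return list with \code{fold_change}, \code{ddct},
#'   \code{replicate_fold_changes} (named by treated sample), and
#'   \code{se} (standard error of the replicate fold changes).
#' @export
fold_change_ddct <- function(ct, target, reference = "36B4",
                             treated = "treated", control = "control") {
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "group", "gene", "Ct") %in% colnames(ct)))
  dct_of <- function(group) {
    sub <- ct[ct$group == group, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no samples in group '", group, "'")
    tgt <- sub[sub$gene == target, , drop = FALSE]
    ref <- sub[sub$gene == reference, , drop = FALSE]
    if (nrow(tgt) == 0L) stop("target gene '", target, "' not measured in group '", group, "'")
    if (nrow(ref) == 0L) stop("reference gene '", reference, "' not measured in group '", group, "'")
    idx <- match(tgt$sample_id, ref$sample_id)
    if (anyNA(idx))
      stop("sample(s) missing the reference measurement: ",
           paste(tgt$sample_id[is.na(idx)], collapse = ", "))
    stats::setNames(tgt$Ct - ref$Ct[idx], tgt$sample_id)
  }
  dct_treated <- dct_of(treated)
  dct_control <- dct_of(control)
  ddct <- mean(dct_treated) - mean(dct_control)
  rep_fc <- 2^(-(dct_treated - mean(dct_control)))
  list(fold_change = 2^(-ddct), ddct = ddct,
       replicate_fold_changes = rep_fc,
       se = if (length(rep_fc) > 1L)
         stats::sd(rep_fc) / sqrt(length(rep_fc)) else NA_real_)
}
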