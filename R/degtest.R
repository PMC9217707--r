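#' DEG-calling thresholds and permutation settings
#'
#' Bundles the dual p-value cutoffs, the permutation count and the
#' pseudocount used throughout the differential-expression test. The
#' defaults follow the study design this package implements: genes are
#' called at \code{Pt <= 0.05} and \code{Pf <= 0.10} (inclusive) against
#' empirical nulls built from 1000 sample-label permutations, with a
#' pseudocount of 1 expression unit stabilizing ratios of low-expressed
#' genes.
#'
#' @param pt_cutoff empirical p-value cutoff for the t-statistic.
#' @param pf_cutoff empirical p-value cutoff for the log2 fold change.
#' @param B number of permutations for the null distributions.
#' @param pseudocount linear-scale offset added before ratios/logs.
#' @return object of class \code{deg_thresholds}.
#' @export
deg_thresholds <- function(pt_cutoff = 0.05, pf_cutoff = 0.10,
                           B = 1000L, pseudocount = 1.0) {
  stopifnot(pt_cutoff > 0, pt_cutoff < 1, pf_cutoff > 0, pf_cutoff < 1,
            B >= 1, pseudocount > 0)
  structure(list(pt_cutoff = pt_cutoff, pf_cutoff = pf_cutoff,
                 B = as.integer(B), pseudocount = pseudocount),
            class = "deg_thresholds")
}

#' Per-subject perturbation ratios
#'
#' For each subject, the overexpression ratio OE_ratio = (x_OE + eps) /
#' (x_OE_control + eps) and the knockdown ratio KD_ratio = (x_KD + eps) /
#' (x_KD_control + eps), where eps is the pseudocount. The pseudocount
#' keeps every ratio finite and positive, including genes with zero
#' expression in a control arm.
#'
#' @param mat expression matrix (genes x samples), normalized.
#' @param design a \code{\link{paired_design}}.
#' @param pseudocount linear-scale offset (expression units).
#' @return object of class \code{ratio_table}: list with genes-x-subjects
#'   matrices \code{oe} and \code{kd} and the pseudocount used.
#' @export
compute_ratios <- function(mat, design, pseudocount = 1.0) {
  stopifnot(inherits(design, "paired_design"), pseudocount > 0)
  validate_expression_matrix(mat)
  check_design_in_matrix(design, mat)
  d <- unclass(design)
  oe <- (mat[, d[, "OE"], drop = FALSE] + pseudocount) /
        (mat[, d[, "OE_control"], drop = FALSE] + pseudocount)
  kd <- (mat[, d[, "KD"], drop = FALSE] + pseudocount) /
        (mat[, d[, "KD_control"], drop = FALSE] + pseudocount)
  colnames(oe) <- colnames(kd) <- rownames(d)
  structure(list(oe = oe, kd = kd, pseudocount = pseudocount),
            class = "ratio_table")
}

# Paired t and mean from a genes-x-subjects matrix of per-subject
# log2-ratio differences. Zero-variance genes get T = 0 when the mean is
# also zero and +/-Inf otherwise (flagged degenerate by callers); the same
# rule is used for observed and permuted statistics so the exhaustive
# enumeration oracle matches exactly.
t_and_mean <- function(D) {
  n <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(rowSums((D - m)^2) / (n - 1))
  T <- ifelse(s > 0, m / (s / sqrt(n)),
              ifelse(m == 0, 0, sign(m) * Inf))
  list(T = T, log2FC = m)
}

#' Paired ratio-of-ratios statistics
#'
#' Contrasts overexpression against knockdown within each subject:
#' d_s = log2(OE_ratio) - log2(KD_ratio). The per-gene t-statistic is the
#' one-sample paired t across subjects, T = mean(d) / (sd(d) / sqrt(n)),
#' and the log2 fold change is mean(d). Genes whose d is constant across
#' subjects are flagged \code{degenerate} (T is 0 when d is identically 0,
#' +/-Inf otherwise).
#'
#' @param ratios a \code{\link{compute_ratios}} result.
#' @return data.frame with columns \code{gene_id}, \code{T}, \code{log2FC},
#'   \code{degenerate}.
#' @export
paired_statistics <- function(ratios) {
  stopifnot(inherits(ratios, "ratio_table"))
  if (ncol(ratios$oe) < 2L)
    stop("paired t-statistic undefined for a single subject")
  D <- log2(ratios$oe) - log2(ratios$kd)
  st <- t_and_mean(D)
  data.frame(gene_id = rownames(ratios$oe), T = st$T, log2FC = st$log2FC,
             degenerate = !is.finite(st$T) | (st$T == 0 & st$log2FC != 0),
             row.names = NULL)
}

# Equal-variance two-sample t on a log2 matrix given case/control column
# indices; same degenerate convention as t_and_mean.
two_sample_t <- function(L, idx_case, idx_ctl) {
  n1 <- length(idx_case); n2 <- length(idx_ctl)
  m1 <- rowMeans(L[, idx_case, drop = FALSE])
  m2 <- rowMeans(L[, idx_ctl, drop = FALSE])
  ss1 <- rowSums((L[, idx_case, drop = FALSE] - m1)^2)
  ss2 <- rowSums((L[, idx_ctl, drop = FALSE] - m2)^2)
  sp <- sqrt((ss1 + ss2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  T <- ifelse(sp > 0, diff / sp, ifelse(diff == 0, 0, sign(diff) * Inf))
  list(T = T, log2FC = diff)
}

#' Unpaired two-group statistics
#'
#' Equal-variance (Student) two-sample t-statistic on log2(x + eps) between
#' case and control samples; log2FC is the difference of group means in
#' log2 space.
#'
#' @param mat expression matrix (genes x samples).
#' @param design an \code{\link{unpaired_design}}.
#' @param pseudocount linear-scale offset before the log transform.
#' @return data.frame with columns \code{gene_id}, \code{T}, \code{log2FC},
#'   \code{degenerate}.
#' @export
unpaired_statistics <- function(mat, design, pseudocount = 1.0) {
  stopifnot(inherits(design, "unpaired_design"), pseudocount > 0)
  validate_expression_matrix(mat)
  check_design_in_matrix(design, mat)
  L <- log2(mat + pseudocount)
  st <- two_sample_t(L, match(design$case, colnames(mat)),
                     match(design$control, colnames(mat)))
  data.frame(gene_id = rownames(mat), T = st$T, log2FC = st$log2FC,
             degenerate = !is.finite(st$T) | (st$T == 0 & st$log2FC != 0),
             row.names = NULL)
}

# --- permutation machinery ---------------------------------------------

# All permutations of seq_len(n) in a fixed (lexicographic) order.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

PERMS4 <- all_perms(4L)  # 24 role permutations, row 1 = identity

# Deterministic stream of permutation indices: distinct relabelings are
# sampled WITHOUT replacement while any remain, so B equal to the number of
# distinct relabelings enumerates them all exactly; beyond that, duplicates
# are drawn with replacement (with a warning).
draw_perm_ids <- function(n_distinct, B) {
  if (B <= n_distinct) return(sample.int(n_distinct, B))
  warning("B = ", B, " exceeds the ", n_distinct,
          " distinct permutations; duplicates permitted")
  c(sample.int(n_distinct, n_distinct),
    sample.int(n_distinct, B - n_distinct, replace = TRUE))
}

# Decode a 1-based index into per-subject rows of PERMS4 (mixed radix 24).
decode_paired_perm <- function(id, n_subjects) {
  id <- id - 1
  rows <- integer(n_subjects)
  for (s in seq_len(n_subjects)) {
    rows[s] <- id %% 24 + 1
    id <- id %/% 24
  }
  rows
}

# Run fn(b) for each of B permutations while temporarily seeding the RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Empirical null distributions by sample-label permutation
#'
#' Rebuilds the per-gene statistics under B random relabelings of the
#' samples and pools all B x G values into one null per statistic (T and
#' log2FC). For a paired design the four role labels are permuted
#' independently within each subject, preserving the subject pairing the
#' observed statistic exploits; \code{scheme = "across_samples"} instead
#' shuffles all samples jointly across subjects and roles. For an unpaired
#' design the case/control labels are shuffled across all samples.
#'
#' Distinct relabelings are drawn without replacement (see Details), so on
#' a small design \code{B} equal to the number of distinct relabelings
#' reproduces the exhaustive enumeration exactly.
#'
#' @param mat expression matrix.
#' @param design paired or unpaired design.
#' @param B number of permutations.
#' @param seed integer seed; the permutation stream is a deterministic
#'   function of it.
#' @param pseudocount linear-scale offset.
#' @param scheme paired designs only: permute role labels within each
#'   subject (default) or across all samples.
#' @return object of class \code{null_distributions}: list with numeric
#'   vectors \code{T} and \code{log2FC} (each of length B x G), plus
#'   \code{B} and \code{seed}.
#' @export
build_null <- function(mat, design, B = 1000L, seed = 1L, pseudocount = 1.0,
                       scheme = c("within_subject", "across_samples")) {
  scheme <- match.arg(scheme)
  validate_expression_matrix(mat)
  check_design_in_matrix(design, mat)
  stopifnot(B >= 1)
  B <- as.integer(B)
  G <- nrow(mat)
  nullT <- vector("list", B)
  nullF <- vector("list", B)

  if (inherits(design, "paired_design")) {
    d <- unclass(design)
    S <- nrow(d)
    idx <- matrix(match(d, colnames(mat)), S, 4L)  # subjects x roles
    # d_s computed exactly as in paired_statistics (same operation order),
    # so the identity relabeling reproduces the observed statistic bit for
    # bit and ties in the empirical p-value are counted consistently
    d_of <- function(pidx) {
      eps <- pseudocount
      log2((mat[, pidx[, 1L], drop = FALSE] + eps) /
           (mat[, pidx[, 2L], drop = FALSE] + eps)) -
      log2((mat[, pidx[, 3L], drop = FALSE] + eps) /
           (mat[, pidx[, 4L], drop = FALSE] + eps))
    }
    if (scheme == "within_subject") {
      n_distinct <- 24^S
      with_seed(seed, {
        perm_rows <- if (n_distinct < 2^31) {
          ids <- draw_perm_ids(n_distinct, B)
          lapply(ids, decode_paired_perm, n_subjects = S)
        } else {
          lapply(seq_len(B), function(b) sample.int(24L, S, replace = TRUE))
        }
      })
      for (b in seq_len(B)) {
        pidx <- idx
        for (s in seq_len(S)) pidx[s, ] <- idx[s, PERMS4[perm_rows[[b]][s], ]]
        st <- t_and_mean(d_of(pidx))
        nullT[[b]] <- st$T; nullF[[b]] <- st$log2FC
      }
    } else {
      all_idx <- as.vector(idx)
      with_seed(seed, {
        shuffles <- lapply(seq_len(B), function(b) sample(all_idx))
      })
      for (b in seq_len(B)) {
        st <- t_and_mean(d_of(matrix(shuffles[[b]], S, 4L)))
        nullT[[b]] <- st$T; nullF[[b]] <- st$log2FC
      }
    }
  } else if (inherits(design, "unpaired_design")) {
    L <- log2(mat + pseudocount)
    all_idx <- match(c(design$case, design$control), colnames(mat))
    n1 <- length(design$case)
    n <- length(all_idx)
    n_distinct <- choose(n, n1)
    with_seed(seed, {
      case_sets <- if (n_distinct <= 2e5) {
        combos <- utils::combn(n, n1)
        ids <- draw_perm_ids(n_distinct, B)
        lapply(ids, function(i) combos[, i])
      } else {
        lapply(seq_len(B), function(b) sample.int(n, n1))
      }
    })
    for (b in seq_len(B)) {
      cs <- case_sets[[b]]
      st <- two_sample_t(L, all_idx[cs], all_idx[-cs])
      nullT[[b]] <- st$T; nullF[[b]] <- st$log2FC
    }
  } else stop("design must be a paired_design or unpaired_design")

  structure(list(T = unlist(nullT, use.names = FALSE),
                 log2FC = unlist(nullF, use.names = FALSE),
                 B = B, seed = as.integer(seed)),
            class = "null_distributions")
}

#' Empirical two-sided p-value against a permutation null
#'
#' p = (1 + #\{|v| >= |obs|\}) / (1 + N) over the pooled null values v.
#' The plus-one correction keeps p strictly positive (the observed
#' relabeling counts as one permutation); two-sidedness comes from the
#' absolute values, since both induced and suppressed genes are of
#' interest.
#'
#' @param obs observed statistic value(s); vectorized.
#' @param null numeric vector of pooled null values (or a
#'   \code{null_distributions} component).
#' @return p-value(s) in (0, 1], same length as \code{obs}.
#' @export
empirical_pvalue <- function(obs, null) {
  null <- as.numeric(null)
  if (length(null) == 0L) stop("empty null distribution")
  sa <- sort(abs(null))
  n_ge <- length(sa) - findInterval(abs(obs), sa, left.open = TRUE)
  (1 + n_ge) / (1 + length(sa))
}

#' Call DEGs from dual empirical p-values
#'
#' A gene is a DEG when both \code{Pt <= pt_cutoff} and
#' \code{Pf <= pf_cutoff} (inclusive). Direction follows the sign of
#' log2FC: positive means induced by the regulator (paired contrast) or up
#' in cases (unpaired), negative suppressed/down.
#'
#' @param stats data.frame with columns \code{gene_id}, \code{T},
#'   \code{log2FC}, \code{Pt}, \code{Pf}.
#' @param thresholds a \code{\link{deg_thresholds}} object.
#' @param label comparison label attached to the result.
#' @param vocabulary \code{"paired"} (induced/suppressed) or
#'   \code{"unpaired"} (up/down).
#' @return object of class \code{deg_set}: data.frame of member genes with
#'   \code{gene_id} and \code{direction}, with the label and thresholds as
#'   attributes.
#' @export
call_degs <- function(stats, thresholds = deg_thresholds(),
                      label = "comparison",
                      vocabulary = c("paired", "unpaired")) {
  vocabulary <- match.arg(vocabulary)
  stopifnot(all(c("gene_id", "log2FC", "Pt", "Pf") %in% colnames(stats)))
  if (anyNA(stats$Pt) || anyNA(stats$Pf))
    stop("Pt/Pf must be populated for all genes")
  hit <- stats$Pt <= thresholds$pt_cutoff & stats$Pf <= thresholds$pf_cutoff
  pos <- if (vocabulary == "paired") "induced" else "up"
  neg <- if (vocabulary == "paired") "suppressed" else "down"
  deg_set(stats$gene_id[hit],
          ifelse(stats$log2FC[hit] > 0, pos, neg),
          label = label, thresholds = thresholds)
}

#' Construct a DEG set
#'
#' @param gene_ids member gene identifiers (canonicalized).
#' @param directions per-gene direction labels.
#' @param label comparison label.
#' @param thresholds thresholds used for the call, if any.
#' @return data.frame of class \code{deg_set}.
#' @export
deg_set <- function(gene_ids, directions, label = "comparison",
                    thresholds = NULL) {
  gene_ids <- canonicalize_gene_ids(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate genes in DEG set")
  if (length(directions) != length(gene_ids))
    stop("directions must cover all member genes")
  df <- data.frame(gene_id = gene_ids, direction = as.character(directions),
                   row.names = NULL)
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("deg_set", "data.frame"),
            label = label, thresholds = thresholds)
}

#' @export
print.deg_set <- function(x, ...) {
  cat("DEG set '", attr(x, "label"), "': ", nrow(x), " genes (",
      sum(x$direction %in% c("induced", "up")), " positive, ",
      sum(x$direction %in% c("suppressed", "down")), " negative)\n", sep = "")
  NextMethod()
}

#' Per-subject concordance report for called DEGs
#'
#' For each DEG, reports the per-subject signs of the paired contrast
#' d_s = log2(OE_ratio) - log2(KD_ratio) and flags genes whose subjects do
#' not all agree in sign. This automates, as an annotation, the manual
#' between-subject inspection step of the original workflow; no gene is
#' removed.
#'
#' @param ratios a \code{\link{compute_ratios}} result.
#' @param deg a \code{deg_set} from the paired comparison.
#' @return data.frame with one row per DEG: gene_id, per-subject signs
#'   (\code{sign_<subject>}), and \code{concordant}.
#' @export
concordance_report <- function(ratios, deg) {
  stopifnot(inherits(ratios, "ratio_table"), inherits(deg, "deg_set"))
  D <- log2(ratios$oe) - log2(ratios$kd)
  idx <- match(deg$gene_id, rownames(D))
  if (anyNA(idx)) stop("DEG gene(s) absent from ratio table")
  signs <- sign(D[idx, , drop = FALSE])
  out <- data.frame(gene_id = deg$gene_id, signs, row.names = NULL,
                    check.names = FALSE)
  colnames(out)[-1L] <- paste0("sign_", colnames(D))
  out$concordant <- apply(signs, 1L, function(z) all(z > 0) || all(z < 0))
  out
}

#' Run the full permutation DEG test on one comparison
#'
#' One-stop wrapper: drops genes below the pseudocount in every design
#' sample (which could otherwise only produce pseudocount artifacts),
#' computes the observed statistics (paired ratio-of-ratios t and log2FC,
#' or the unpaired two-sample t), builds pooled empirical nulls by
#' permutation, converts to two-sided empirical p-values Pt and Pf, and
#' calls DEGs at the dual thresholds.
#'
#' For genes flagged degenerate (zero variance of the paired differences),
#' Pt falls back to the log2FC null, with a warning.
#'
#' @param mat normalized expression matrix.
#' @param design paired or unpaired design.
#' @param thresholds a \code{\link{deg_thresholds}} object.
#' @param seed integer seed for the permutation stream.
#' @param label comparison label.
#' @param scheme permutation scheme for paired designs (see
#'   \code{\link{build_null}}).
#' @return object of class \code{deg_result}: list with \code{stats} (the
#'   per-gene results table), \code{deg} (the \code{deg_set}),
#'   \code{nulls}, \code{ratios} (paired only), \code{n_dropped}.
#' @export
deg_test <- function(mat, design, thresholds = deg_thresholds(),
                     seed = 1L, label = "comparison",
                     scheme = c("within_subject", "across_samples")) {
  scheme <- match.arg(scheme)
  validate_expression_matrix(mat)
  check_design_in_matrix(design, mat)
  paired <- inherits(design, "paired_design")
  eps <- thresholds$pseudocount

  sub <- mat[, design_samples(design), drop = FALSE]
  keep <- rowSums(sub >= eps) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " gene(s) below the pseudocount in every sample dropped before testing")
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no genes left after low-expression filtering")

  ratios <- NULL
  if (paired) {
    ratios <- compute_ratios(sub, design, pseudocount = eps)
    stats <- paired_statistics(ratios)
  } else {
    stats <- unpaired_statistics(sub, design, pseudocount = eps)
  }
  nulls <- build_null(sub, design, B = thresholds$B, seed = seed,
                      pseudocount = eps, scheme = scheme)
  stats$Pt <- empirical_pvalue(stats$T, nulls$T)
  stats$Pf <- empirical_pvalue(stats$log2FC, nulls$log2FC)
  if (any(stats$degenerate)) {
    warning(sum(stats$degenerate),
            " zero-variance gene(s): Pt taken from the log2FC null")
    stats$Pt[stats$degenerate] <-
      empirical_pvalue(stats$log2FC[stats$degenerate], nulls$log2FC)
  }
  deg <- call_degs(stats, thresholds, label = label,
                   vocabulary = if (paired) "paired" else "unpaired")
  stats$is_deg <- stats$gene_id %in% deg$gene_id
  stats$direction <- deg$direction[match(stats$gene_id, deg$gene_id)]
  structure(list(stats = stats, deg = deg, nulls = nulls, ratios = ratios,
                 n_dropped = n_dropped, label = label,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("Permutation DEG test '", x$label, "': ", nrow(x$stats),
      " genes tested, ", nrow(x$deg), " DEGs (B = ", x$nulls$B,
      ", Pt <= ", x$thresholds$pt_cutoff, ", Pf <= ",
      x$thresholds$pf_cutoff, ")\n", sep = "")
  invisible(x)
}
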