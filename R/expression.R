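#' @include AllClasses.R ribo.R
#' @importFrom limma lmFit eBayes
#' @importFrom stats p.adjust
NULL

#' MA transform of per-gene abundances between two conditions
#'
#' With per-gene mean abundances `x` (condition A) and `y` (condition B) and
#' pseudo-abundance `eps`: `M = log2((y + eps)/(x + eps))` and
#' `A = 0.5 * log2((x + eps) * (y + eps))`. M is antisymmetric and A
#' symmetric under swapping the conditions.
#'
#' @param expr genes x samples non-negative matrix (FPKM or normalized
#'   counts), gene ids as rownames.
#' @param condition character vector of per-column condition labels.
#' @param condA,condB the two conditions to compare (B over A).
#' @param eps pseudo-abundance (default 1).
#' @return data.frame with columns `gene_id`, `A`, `M`.
#' @examples
#' m <- matrix(c(10, 5, 10, 5), 2, 2, dimnames = list(c("g1", "g2"), NULL))
#' maTransform(m, c("ctl", "kd"), "ctl", "kd")
#' @export
maTransform <- function(expr, condition, condA, condB, eps = 1) {
  stopifnot(is.matrix(expr), length(condition) == ncol(expr))
  for (cd in c(condA, condB))
    if (!cd %in% condition) stop("condition not present in table: ", cd)
  if (any(expr < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  x <- rowMeans(expr[, condition == condA, drop = FALSE])
  y <- rowMeans(expr[, condition == condB, drop = FALSE])
  bad <- is.na(x) | is.na(y)
  if (any(bad))
    stop("missing abundance for gene(s): ",
         paste(utils::head(rownames(expr)[bad], 10), collapse = ", "))
  data.frame(gene_id = rownames(expr),
             A = 0.5 * log2((x + eps) * (y + eps)),
             M = log2((y + eps) / (x + eps)),
             row.names = NULL)
}

#' Target/non-target expression stability assessment
#'
#' Flags genes whose abundance changes between the two conditions
#' (|M| above `mThreshold` and, when both conditions have replicates, BH
#' q-value at most `qThreshold` from a moderated t-test on log2 abundances),
#' and tests at group level whether target genes shift relative to
#' non-targets with a two-sample KS test on M.
#'
#' @inheritParams maTransform
#' @param targets character vector of target gene ids (>= 10 targets and
#'   >= 10 non-targets required).
#' @param mThreshold |M| cutoff for flagging (default 1, i.e. 2-fold).
#' @param qThreshold q-value cutoff for flagging when replicates exist.
#' @return list with `table` (per-gene `gene_id`, `A`, `M`, `is_target`,
#'   `q`, `flagged`), `groupD`, `groupP` (KS of M targets vs non-targets),
#'   `nFlagged` and `flaggedFraction`.
#' @export
targetStabilityTest <- function(expr, condition, condA, condB, targets,
                                mThreshold = 1, qThreshold = 0.05, eps = 1) {
  if (length(targets) == 0L) stop("empty target set")
  ma <- maTransform(expr, condition, condA, condB, eps = eps)
  ma$is_target <- ma$gene_id %in% targets
  if (sum(ma$is_target) < 10L || sum(!ma$is_target) < 10L)
    stop("need at least 10 target and 10 non-target genes")

  nA <- sum(condition == condA); nB <- sum(condition == condB)
  if (nA >= 2L && nB >= 2L) {
    sel <- condition %in% c(condA, condB)
    y <- log2(expr[, sel, drop = FALSE] + eps)
    design <- cbind(Intercept = 1,
                    condB = as.numeric(condition[sel] == condB))
    fit <- eBayes(lmFit(y, design))
    pv <- fit$p.value[, "condB"]
    ma$q <- p.adjust(pv, method = "BH")
    ma$flagged <- abs(ma$M) > mThreshold & ma$q <= qThreshold
  } else {
    ma$q <- NA_real_
    ma$flagged <- abs(ma$M) > mThreshold
  }
  kt <- suppressWarnings(stats::ks.test(ma$M[ma$is_target],
                                        ma$M[!ma$is_target], exact = FALSE))
  list(table = ma,
       groupD = unname(kt$statistic),
       groupP = unname(kt$p.value),
       nFlagged = sum(ma$flagged),
       flaggedFraction = mean(ma$flagged))
}

#' Convert raw fragment counts to FPKM
#'
#' `FPKM = fragments * 1e9 / (gene length * total fragments in sample)`.
#'
#' @param counts genes x samples count matrix.
#' @param lengths per-gene transcript lengths in nt (recycled across
#'   samples).
#' @return FPKM matrix of the same shape.
#' @export
countsToFpkm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths))
  tot <- colSums(counts)
  sweep(counts * 1e9 / lengths, 2, tot, "/")
}
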