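#' Relative quantification by the 2^-ddCt method
#'
#' ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl);
#' the fold change of the target in the test condition relative to the
#' control is 2^-ddCt. Each argument may carry technical replicates,
#' which are averaged (arithmetic mean of Ct) before differencing.
#' Invariant to any constant added to all four Ct values. No
#' amplification-efficiency correction is applied.
#'
#' @param ct_target_test,ct_ref_test Ct values of the target and
#'   reference gene in the test condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control condition.
#' @return The fold change 2^-ddCt (scalar).
#' @examples
#' delta_delta_ct(23, 15, 24, 15)  # 2
#' @export
delta_delta_ct <- function(ct_target_test, ct_ref_test,
                           ct_target_ctrl, ct_ref_ctrl) {
  vals <- list(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(vapply(vals, function(v) length(v) == 0 || anyNA(v), logical(1))))
    stop("all four Ct measurements must be present", call. = FALSE)
  m <- vapply(vals, mean, numeric(1))
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  2^(-ddct)
}

#' Per-gene 2^-ddCt fold changes from a Ct table
#'
#' @param ct_table Ct table (see [read_ct_table()]): columns
#'   \code{sample_id}, \code{condition} (control/test), \code{gene_id},
#'   \code{replicate}, \code{ct}.
#' @param reference_gene Reference gene id (default "18S").
#' @return Data.frame with \code{gene_id}, \code{fold_change},
#'   \code{log2_fold_change}.
#' @export
qpcr_fold_changes <- function(ct_table, reference_gene = "18S") {
  pick <- function(gene, condition) {
    v <- ct_table$ct[ct_table$gene_id == gene &
                       ct_table$condition == condition]
    if (length(v) == 0)
      stop("missing Ct measurement for gene '", gene, "' (", condition, ")",
           call. = FALSE)
    v
  }
  if (!reference_gene %in% ct_table$gene_id)
    stop("missing reference-gene measurement '", reference_gene, "'",
         call. = FALSE)
  genes <- setdiff(unique(ct_table$gene_id), reference_gene)
  fc <- vapply(genes, function(g) {
    delta_delta_ct(pick(g, "test"), pick(reference_gene, "test"),
                   pick(g, "control"), pick(reference_gene, "control"))
  }, numeric(1))
  data.frame(gene_id = genes, fold_change = unname(fc),
             log2_fold_change = log2(unname(fc)), stringsAsFactors = FALSE)
}

#' Concordance between sequencing and qPCR log2 fold changes
#'
#' Pearson product-moment correlation on the log2 scale over the genes
#' shared by the two named vectors (at least 3 required), with the paired
#' table returned alongside.
#'
#' @param rnaseq_lfc Named numeric vector of sequencing-based log2 fold
#'   changes.
#' @param qpcr_lfc Named numeric vector of qPCR log2 fold changes.
#' @return List with \code{r} (Pearson correlation), \code{n_genes} and
#'   \code{table} (gene_id, rnaseq_log2fc, qpcr_log2fc).
#' @export
concordance <- function(rnaseq_lfc, qpcr_lfc) {
  shared <- intersect(names(rnaseq_lfc), names(qpcr_lfc))
  if (length(shared) < 3)
    stop("concordance needs at least 3 shared genes, got ", length(shared),
         call. = FALSE)
  tbl <- data.frame(gene_id = shared,
                    rnaseq_log2fc = unname(rnaseq_lfc[shared]),
                    qpcr_log2fc = unname(qpcr_lfc[shared]),
                    stringsAsFactors = FALSE)
  list(r = cor(tbl$rnaseq_log2fc, tbl$qpcr_log2fc, method = "pearson"),
       n_genes = length(shared), table = tbl)
}
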