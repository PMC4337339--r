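#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = 1e9 * C / (N * L), where C is the number of reads uniquely
#' aligned to the gene, N the total number of reads uniquely aligned to
#' all genes in that library, and L the transcript length in nucleotides.
#' Zero iff C is zero; invariant to scaling C and N together.
#'
#' @param C Unique read count(s), non-negative.
#' @param N Library total of uniquely aligned reads, positive.
#' @param L Transcript length in nt, positive.
#' @return RPKM value(s), recycled to the common length.
#' @examples
#' compute_rpkm(100, 1e6, 1000)  # 100
#' @export
compute_rpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("library total N must be positive", call. = FALSE)
  if (any(L <= 0)) stop("gene length L must be positive", call. = FALSE)
  if (any(C < 0)) stop("count C must be non-negative", call. = FALSE)
  1e9 * C / (N * L)
}

#' RPKM matrix for a count table
#'
#' @param counts Count table (columns \code{gene_id}, \code{length_nt},
#'   one count column per library).
#' @param profiles Library profiles with \code{library_id} and
#'   \code{total_reads}.
#' @return Data.frame: \code{gene_id}, \code{length_nt}, one RPKM column
#'   per library (same names as the count columns).
#' @export
rpkm_matrix <- function(counts, profiles) {
  libs <- setdiff(names(counts), c("gene_id", "length_nt"))
  missing <- setdiff(libs, profiles$library_id)
  if (length(missing))
    stop("no profile for library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- counts[c("gene_id", "length_nt")]
  for (lib in libs) {
    N <- profiles$total_reads[match(lib, profiles$library_id)]
    out[[lib]] <- compute_rpkm(counts[[lib]], N, counts$length_nt)
  }
  out
}

#' Normalized log2 expression ratio between two libraries
#'
#' log2(((y + c) / N_b) / ((x + c) / N_a)): counts are library-size
#' normalized and offset by a pseudocount \code{c} so the ratio is finite
#' for zero counts. Antisymmetric under swapping the two libraries.
#'
#' @param count_b,count_a Counts y (test) and x (reference).
#' @param N_b,N_a Library totals of the test and reference libraries.
#' @param pseudocount Positive pseudocount, default 1.
#' @return log2 fold change(s) of b relative to a.
#' @examples
#' log2_ratio(200, 100, 1e6, 1e6)  # ~1
#' @export
log2_ratio <- function(count_b, count_a, N_b, N_a, pseudocount = 1) {
  if (any(pseudocount <= 0)) stop("pseudocount must be positive", call. = FALSE)
  if (any(N_a <= 0) || any(N_b <= 0))
    stop("library sizes must be positive", call. = FALSE)
  log2(((count_b + pseudocount) / N_b) / ((count_a + pseudocount) / N_a))
}
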