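#' Construct a flat category-to-gene annotation set
#'
#' Categories are flat gene sets (KEGG-pathway-like); every category must
#' be a subset of the annotation universe. No DAG structure is modelled.
#'
#' @param categories Named list of character vectors (category id -> gene
#'   ids).
#' @param universe Character vector of all annotated gene ids. Defaults to
#'   the union of all categories.
#' @param descriptions Optional named character vector of category
#'   descriptions.
#' @return An object of class \code{annotation_set}.
#' @export
annotation_set <- function(categories, universe = NULL, descriptions = NULL) {
  stopifnot(is.list(categories), length(categories) > 0)
  if (is.null(names(categories)) || anyDuplicated(names(categories)))
    stop("categories must be uniquely named", call. = FALSE)
  categories <- lapply(categories, unique)
  if (is.null(universe)) universe <- unique(unlist(categories, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty", call. = FALSE)
  for (id in names(categories)) {
    extra <- setdiff(categories[[id]], universe)
    if (length(extra))
      stop("category '", id, "' contains genes outside the universe: ",
           paste(head(extra, 3), collapse = ", "), call. = FALSE)
  }
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(categories)), names(categories))
  structure(list(categories = categories, universe = universe,
                 descriptions = descriptions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$categories), "categories over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Upper-tail hypergeometric over-representation probability
#'
#' P(X >= k) for X ~ Hypergeometric(N_univ, K, n): the probability that a
#' random draw of \code{n} genes from a universe of \code{N_univ} genes,
#' of which \code{K} belong to the category, contains at least \code{k}
#' category members. Evaluated through [stats::phyper()] in log space so
#' extreme tails (p well below 1e-50) keep full relative precision.
#'
#' @param k Observed category members among the drawn genes.
#' @param K Category size within the universe.
#' @param n Number of drawn genes (e.g. annotated DEGs).
#' @param N_univ Universe size.
#' @return The upper-tail probability, in (0, 1].
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N_univ) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N_univ <= 0))
    stop("counts must be non-negative and N_univ positive", call. = FALSE)
  if (any(k > K)) stop("k cannot exceed the category size K", call. = FALSE)
  if (any(k > n)) stop("k cannot exceed the draw size n", call. = FALSE)
  if (any(K > N_univ) || any(n > N_univ))
    stop("K and n cannot exceed the universe size N_univ", call. = FALSE)
  exp(phyper(k - 1, K, N_univ - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Category over-representation analysis of a DEG set
#'
#' Tests each annotated category for over-representation of differentially
#' expressed genes by the hypergeometric upper tail. The DEG set is first
#' intersected with the annotation universe, so the draw size \code{n} is
#' the number of DEGs that carry annotation; categories with no universe
#' genes are skipped. Q-values are computed across exactly the categories
#' tested in the run.
#'
#' @param deg_genes Character vector of DEG ids.
#' @param annotation An [annotation_set()].
#' @param q_method Multiple-testing method for the Q-values ("BH" default,
#'   or "BY").
#' @param q_cutoff Inclusive significance threshold on the Q-value.
#' @return A data.frame sorted by p-value ascending with columns
#'   \code{category_id}, \code{description}, \code{k}, \code{K}, \code{n},
#'   \code{N_univ}, \code{p_value}, \code{q_value}, \code{significant}.
#' @export
enrich_categories <- function(deg_genes, annotation, q_method = c("BH", "BY"),
                              q_cutoff = 0.05) {
  q_method <- match.arg(q_method)
  stopifnot(inherits(annotation, "annotation_set"))
  universe <- annotation$universe
  deg <- intersect(unique(deg_genes), universe)
  n <- length(deg)
  N_univ <- length(universe)
  ids <- names(annotation$categories)
  K <- vapply(annotation$categories, length, integer(1))
  keep <- K > 0
  ids <- ids[keep]; K <- K[keep]
  k <- vapply(annotation$categories[ids],
              function(g) length(intersect(g, deg)), integer(1))
  p <- hypergeom_upper_tail(k, K, n, N_univ)
  out <- data.frame(
    category_id = ids,
    description = unname(annotation$descriptions[ids]),
    k = unname(k), K = unname(K), n = n, N_univ = N_univ,
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
  out$q_value <- p.adjust(out$p_value, method = q_method)
  out$significant <- out$q_value <= q_cutoff
  out <- out[order(out$p_value, out$category_id), ]
  rownames(out) <- NULL
  out
}
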