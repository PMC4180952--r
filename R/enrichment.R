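#' Hypergeometric upper-tail probability
#'
#' One-sided overrepresentation p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` genes (a cluster) from a
#' universe of `N` genes of which `K` are annotated, the chance of seeing at
#' least `k` annotated genes. Computed in log space by a log-sum-exp over the
#' tail of log densities for numerical stability.
#'
#' @param k observed overlap count.
#' @param K annotated genes in the universe.
#' @param n cluster size.
#' @param N universe size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  ok <- all(is.finite(c(k, K, n, N))) && k >= 0 && K >= 0 && n >= 0 &&
    k <= min(n, K) && n <= N && K <= N
  if (!ok)
    stop("input error: need 0 <= k <= min(n, K) <= N (got k=", k, " K=", K,
         " n=", n, " N=", N, ")")
  if (k == 0) return(1)
  kk <- k:min(n, K)
  lp <- stats::dhyper(kk, K, N - K, n, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Transcription-factor gene-set annotation
#'
#' @param tf_name transcription factor name.
#' @param targets character vector of target gene ids (non-empty).
#' @return An object of class `gene_set_annotation`.
#' @export
gene_set_annotation <- function(tf_name, targets) {
  targets <- unique(as.character(targets))
  if (length(targets) == 0)
    stop("format error: empty target set for ", tf_name)
  structure(list(tf_name = tf_name, targets = targets),
            class = "gene_set_annotation")
}

#' Transcription-factor overrepresentation across behavior clusters
#'
#' One hypergeometric upper-tail test per (TF, cluster) pair, conditioning on
#' the analysis universe (all genes in the expression matrix, not the
#' genome). Annotation targets outside the universe are dropped with a
#' message. Benjamini-Hochberg q-values are computed jointly across all
#' pairs; rows are sorted by q, then p, then TF and cluster id.
#'
#' @param clusters named list of disjoint character vectors (gene sets), each
#'   a subset of `universe`.
#' @param annotations list of [gene_set_annotation()] objects.
#' @param universe character vector of all analyzed gene ids.
#' @param alpha FDR level for the `significant` column.
#' @return data.frame: tf_name, cluster_id, k, n, K, N, p_value, q_value,
#'   significant.
#' @export
cluster_overrepresentation <- function(clusters, annotations, universe,
                                       alpha = 0.05) {
  universe <- unique(universe)
  N <- length(universe)
  for (nm in names(clusters)) {
    extra <- setdiff(clusters[[nm]], universe)
    if (length(extra))
      stop("input error: cluster ", nm, " not contained in universe (",
           length(extra), " foreign ids)")
  }
  all_members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("input error: clusters must be disjoint")
  rows <- list()
  for (ann in annotations) {
    tgt <- intersect(ann$targets, universe)
    dropped <- length(ann$targets) - length(tgt)
    if (dropped > 0)
      message("enrichment: dropped ", dropped, " target(s) of ",
              ann$tf_name, " outside the universe")
    K <- length(tgt)
    for (nm in names(clusters)) {
      cl <- clusters[[nm]]
      k <- length(intersect(tgt, cl))
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = ann$tf_name, cluster_id = nm, k = k, n = length(cl),
        K = K, N = N, p_value = hypergeom_tail(k, K, length(cl), N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value <= alpha
  out <- out[order(out$q_value, out$p_value, out$tf_name, out$cluster_id), ]
  rownames(out) <- NULL
  out
}
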