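# Performance metrics against simulation truth and the downstream helper
# computations (assignment entropy, inter-cluster Hamming distances,
# reliable-call rule, genotype dendrogram).

#' Cell-to-clone assignment accuracy
#'
#' Fraction of cells whose MAP clone equals the true clone.  Clone labels
#' are anchored to the columns of the input genotype matrix, so no
#' partition matching is performed.
#'
#' @param map_assignment length-M predicted clone labels (1..K)
#' @param t_true length-M true hypercluster labels
#' @param i_true true hypercluster-to-clone labels
#' @return fraction in [0, 1]
#' @export
assignment_accuracy <- function(map_assignment, t_true, i_true) {
  if (length(map_assignment) != length(t_true))
    stop("predicted and true assignments differ in length")
  true_clone <- i_true[t_true]
  K <- max(true_clone)
  if (!any(map_assignment %in% seq_len(max(K, max(map_assignment)))))
    stop("predicted labels are not clone indices")
  mean(map_assignment == true_clone)
}

#' Genotype reconstruction accuracy
#'
#' Elementwise agreement between the MAP corrected genotypes and the hidden
#' true clone genotypes.
#'
#' @param map_genotypes,c_true binary N x K matrices
#' @return fraction in [0, 1]
#' @export
genotype_accuracy <- function(map_genotypes, c_true) {
  if (!identical(dim(as.matrix(map_genotypes)), dim(as.matrix(c_true))))
    stop("genotype matrices differ in shape")
  mean(map_genotypes == c_true)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected (permutation model) agreement between the inferred and
#' generating hyperclusterings.
#'
#' @param t_pred,t_true two label vectors over the same cells
#' @return ARI in [-1, 1]
#' @export
hypercluster_ari <- function(t_pred, t_true) {
  if (length(t_pred) != length(t_true))
    stop("partitions differ in length")
  # identical partitions score 1 even in the degenerate all-singleton case,
  # where the permutation-model correction is 0/0
  if (identical(match(t_pred, unique(t_pred)), match(t_true, unique(t_true))))
    return(1)
  mclust::adjustedRandIndex(t_pred, t_true)
}

#' Shannon entropy of cell-to-clone assignment probabilities
#'
#' Natural-log entropy per cell (0 log 0 = 0) and its mean over cells.
#'
#' @param assignment_probs M x K matrix with rows on the simplex
#' @return list with `per_cell` and `mean`
#' @export
assignment_entropy <- function(assignment_probs) {
  P <- as.matrix(assignment_probs)
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-6))
    stop("rows of assignment_probs must be probability vectors summing to 1")
  H <- -rowSums(ifelse(P > 0, P * log(P), 0))
  list(per_cell = H, mean = mean(H))
}

# Modal sequence (integer codes, NA where nothing observed) of each
# cluster over an alignment; ties broken A < C < G < T.
cluster_modal_codes <- function(X, labels) {
  Q <- max(labels)
  out <- matrix(NA_integer_, Q, ncol(X))
  for (q in seq_len(Q)) {
    sub <- X[labels == q, , drop = FALSE]
    for (l in seq_len(ncol(X))) {
      counts <- tabulate(sub[sub[, l] > 0, l], nbins = 4L)
      if (sum(counts) > 0) out[q, l] <- which.max(counts)
    }
  }
  out
}

#' Hamming distances between the hyperclusters of two samples
#'
#' For every pair of hyperclusters (one from each sample) counts the
#' nucleotide mismatches between the clusters' modal BCR sequences over
#' the shared positions; positions missing (unobserved) in either modal
#' sequence are skipped.  `method = "mean"` instead averages the pairwise
#' per-cell mismatch counts.
#'
#' @param bcr_a,bcr_b [bcr_alignment()] objects on a shared position
#'   coordinate system (matched by position id)
#' @param labels_a,labels_b hypercluster labels for the cells of each
#'   alignment
#' @param method `"modal"` (default) or `"mean"`
#' @return Qa x Qb matrix of distances
#' @export
hypercluster_hamming <- function(bcr_a, labels_a, bcr_b, labels_b,
                                 method = c("modal", "mean")) {
  method <- match.arg(method)
  shared <- intersect(bcr_a$position_ids, bcr_b$position_ids)
  if (length(shared) == 0)
    stop("the two alignments share no BCR positions")
  Xa <- encode_nucleotides(
    bcr_a$nucleotides[, match(shared, bcr_a$position_ids), drop = FALSE],
    bcr_a$missing_char)
  Xb <- encode_nucleotides(
    bcr_b$nucleotides[, match(shared, bcr_b$position_ids), drop = FALSE],
    bcr_b$missing_char)
  if (method == "modal") {
    ma <- cluster_modal_codes(Xa, labels_a)
    mb <- cluster_modal_codes(Xb, labels_b)
    out <- matrix(0, nrow(ma), nrow(mb))
    for (qa in seq_len(nrow(ma))) for (qb in seq_len(nrow(mb))) {
      ok <- !is.na(ma[qa, ]) & !is.na(mb[qb, ])
      out[qa, qb] <- sum(ma[qa, ok] != mb[qb, ok])
    }
  } else {
    Qa <- max(labels_a); Qb <- max(labels_b)
    out <- matrix(0, Qa, Qb)
    for (qa in seq_len(Qa)) for (qb in seq_len(Qb)) {
      ca <- which(labels_a == qa); cb <- which(labels_b == qb)
      tot <- 0; npairs <- 0
      for (i in ca) for (j in cb) {
        ok <- Xa[i, ] > 0 & Xb[j, ] > 0
        tot <- tot + sum(Xa[i, ok] != Xb[j, ok])
        npairs <- npairs + 1
      }
      out[qa, qb] <- tot / npairs
    }
  }
  out
}

#' Reliable genotype-call mask for one clone
#'
#' A variant's genotype call in a clone is considered reliable if the cells
#' assigned to that clone carry at least one alternate read or at least
#' three reference reads at the position.
#'
#' @param reads a [variant_read_data()]
#' @param map_assignment per-cell clone labels
#' @param clone clone index
#' @return logical vector over variants
#' @export
reliable_call_mask <- function(reads, map_assignment, clone) {
  cells <- which(map_assignment == clone)
  alt <- rowSums(reads$alt[, cells, drop = FALSE])
  ref <- rowSums(reads$total[, cells, drop = FALSE]) - alt
  alt >= 1 | ref >= 3
}

#' Single-linkage dendrogram of clone genotypes
#'
#' Agglomerative clustering of the clone genotype columns with Manhattan
#' distance and single linkage; also emitted as a Newick string.
#'
#' @param map_genotypes binary N x K genotype matrix (K >= 2)
#' @return list with the `hclust` object, `merge`, `height` and `newick`
#' @export
genotype_dendrogram <- function(map_genotypes) {
  geno <- as.matrix(map_genotypes)
  if (ncol(geno) < 2) stop("at least two clones are required")
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("clone_", seq_len(ncol(geno)))
  d <- dist(t(geno), method = "manhattan")
  hc <- hclust(d, method = "single")
  list(hclust = hc, merge = hc$merge, height = hc$height,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Evaluate a fit against simulation truth
#'
#' @param result a `bcrclone_result` (from [extract_results()] or
#'   `fit$result`)
#' @param truth the `truth` element of [simulate_dataset()]
#' @return object of class `eval_report` with assignment accuracy, genotype
#'   accuracy, hypercluster ARI, and assignment entropy summaries
#' @export
evaluate_fit <- function(result, truth) {
  ent <- assignment_entropy(result$assignment_probs)
  structure(list(
    assignment_accuracy = assignment_accuracy(
      result$map_assignment, truth$t_true, truth$i_true),
    genotype_accuracy = genotype_accuracy(result$map_genotypes,
                                          truth$c_true),
    hypercluster_ari = hypercluster_ari(result$ml_hyperclustering,
                                        truth$t_true),
    mean_assignment_entropy = ent$mean,
    per_cell_entropy = ent$per_cell),
    class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0(
    "assignment accuracy:     %.3f\n",
    "genotype accuracy:       %.3f\n",
    "hypercluster ARI:        %.3f\n",
    "mean assignment entropy: %.4f\n"),
    x$assignment_accuracy, x$genotype_accuracy, x$hypercluster_ari,
    x$mean_assignment_entropy))
  invisible(x)
}
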