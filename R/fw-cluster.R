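#' Uncentered correlation (cosine) similarity
#'
#' `sim(x, y) = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`: the similarity used by
#' classic clustering software when means are not subtracted. Symmetric,
#' bounded in \[-1, 1\], equal to 1 for any nonzero row with itself.
#'
#' @param mat numeric matrix, rows are profiles. Zero-norm rows are an error.
#' @return symmetric similarity matrix.
#' @export
uncentered_correlation <- function(mat) {
  mat <- as.matrix(mat)
  nrm <- sqrt(rowSums(mat^2))
  if (any(nrm == 0)) stop2("row(s) with zero norm: ",
                           paste(rownames(mat)[nrm == 0] %||% which(nrm == 0),
                                 collapse = ", "))
  s <- tcrossprod(mat / nrm)
  pmin(pmax(s, -1), 1)
}

#' Average-linkage hierarchical clustering on uncentered correlation
#'
#' Agglomerative clustering of probe binding profiles: the similarity between
#' two clusters is the unweighted mean of the pairwise uncentered correlations
#' between their members, and at each step the most similar pair is merged
#' (ties broken by the lexicographically smallest combined member-label set,
#' for determinism). Flat clusters are the maximal subtrees all of whose
#' merge similarities exceed `cutoff` (default 0.85).
#'
#' @param mat numeric matrix (rows = probes with unique rownames; unnamed
#'   rows are labeled row1..rowN). At least 2 rows, no all-zero rows.
#' @param cutoff similarity cutoff for flat clusters.
#' @return object of class `fw_dendrogram`: list with
#'   \describe{
#'     \item{merges}{data frame per merge: `step`, `similarity`, `members`.}
#'     \item{hclust}{an equivalent [stats::hclust] object with
#'       `height = 1 - similarity`.}
#'     \item{clusters}{named integer vector of flat cluster ids at `cutoff`.}
#'     \item{similarity}{the leaf similarity matrix.}
#'   }
#' @export
hcluster_uncentered <- function(mat, cutoff = 0.85) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop2("need at least 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(n))
  labels <- rownames(mat)
  S <- uncentered_correlation(mat)

  # active clusters: list of member leaf indices; id > 0 leaf, id < 0 merge
  members <- as.list(seq_len(n))
  node_id <- seq_len(n)              # hclust convention: leaves negative
  hc_merge <- matrix(0L, n - 1L, 2L)
  hc_height <- numeric(n - 1L)
  merges <- vector("list", n - 1L)

  avg_sim <- function(a, b) mean(S[a, b])

  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- NULL; best_sim <- -Inf; best_key <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      sim <- avg_sim(members[[i]], members[[j]])
      key <- paste(sort(labels[c(members[[i]], members[[j]])]),
                   collapse = "\r")
      if (sim > best_sim + 1e-12 ||
          (abs(sim - best_sim) <= 1e-12 &&
           (is.null(best_key) || key < best_key))) {
        best <- c(i, j); best_sim <- sim; best_key <- key
      }
    }
    i <- best[1]; j <- best[2]
    hc_merge[step, ] <- c(ifelse(node_id[i] <= n, -node_id[i], node_id[i] - n),
                          ifelse(node_id[j] <= n, -node_id[j], node_id[j] - n))
    hc_height[step] <- 1 - best_sim
    merges[[step]] <- data.frame(
      step = step, similarity = best_sim,
      members = paste(sort(labels[c(members[[i]], members[[j]])]),
                      collapse = ","))
    members[[i]] <- c(members[[i]], members[[j]])
    node_id[i] <- n + step
    members[[j]] <- NULL
    node_id <- node_id[-j]
  }

  hc <- structure(list(merge = hc_merge,
                       height = cummax(hc_height),  # guard tiny inversions
                       order = seq_len(n), labels = labels,
                       method = "average-uncentered",
                       call = match.call(),
                       dist.method = "1 - uncentered correlation"),
                  class = "hclust")
  hc$order <- stats::order.dendrogram(stats::as.dendrogram(hc))

  # flat clusters: union of leaves over merges with similarity > cutoff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  md <- do.call(rbind, merges)
  for (k in seq_len(nrow(md))) {
    if (md$similarity[k] > cutoff) {
      ms <- match(strsplit(md$members[k], ",")[[1]], labels)
      r <- find(ms[1])
      for (q in ms[-1]) parent[find(q)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- setNames(match(roots, unique(roots)), labels)

  structure(list(merges = md, hclust = hc, clusters = clusters,
                 similarity = S, cutoff = cutoff),
            class = "fw_dendrogram")
}

#' Export a far-Western dendrogram
#'
#' `fw_dendrogram_newick` writes the merge tree in Newick format with branch
#' lengths `1 - similarity` (node labels carry the merge similarity);
#' `fw_dendrogram_json` writes the nested-list representation with per-merge
#' similarities.
#'
#' @param dend a `fw_dendrogram` from [hcluster_uncentered()].
#' @param path output file path.
#' @export
fw_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "fw_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  # annotate each internal node with its merge similarity (1 - node height);
  # node heights recovered from root-to-node path lengths on the ultrametric
  # tree
  depth <- ape::node.depth.edgelength(phy)
  total <- max(depth[seq_along(phy$tip.label)])
  node_height <- total - depth[(length(phy$tip.label) + 1):length(depth)]
  phy$node.label <- sprintf("%.6f", 1 - node_height)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname fw_dendrogram_newick
#' @export
fw_dendrogram_json <- function(dend, path) {
  stopifnot(inherits(dend, "fw_dendrogram"))
  n <- length(dend$hclust$labels)
  build <- function(node) {
    if (node < 0) return(dend$hclust$labels[-node])
    list(similarity = dend$merges$similarity[node],
         children = list(build(dend$hclust$merge[node, 1]),
                         build(dend$hclust$merge[node, 2])))
  }
  jsonlite::write_json(build(n - 1L), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.fw_dendrogram <- function(x, ...) {
  cat("<fw_dendrogram>", length(x$clusters), "leaves,",
      max(x$clusters), "flat clusters at similarity >", x$cutoff, "\n")
  invisible(x)
}
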