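#' Label ranked hits as true or false positives by LD tagging
#'
#' A hit is a true positive when its squared Pearson correlation with at
#' least one (hidden) causal marker reaches `r2_threshold`; each true
#' positive is attributed to its best-correlated causal locus.
#'
#' @param hits data.frame with columns `id` and `score` (smaller = more
#'   significant), or a character vector of ids in rank order.
#' @param truth a `sim_truth` carrying `causal_dosages` for the analyzed
#'   individuals (see [simulate_phenotypes()]).
#' @param g the analysis [genotype_dataset()] the hits were drawn from.
#' @param r2_threshold tagging threshold (default 0.8).
#' @return data.frame: `id`, `chrom`, `bp`, `score`, `tp`, `causal_id`,
#'   `r2`, in rank order.
#' @export
classify_hits <- function(hits, truth, g, r2_threshold = 0.8) {
  if (is.character(hits)) {
    hits <- data.frame(id = hits, score = seq_along(hits),
                       stringsAsFactors = FALSE)
  }
  hits <- as.data.frame(hits)
  if (is.null(truth$causal_dosages)) {
    stop("truth lacks causal dosages; run simulate_phenotypes() first")
  }
  idx <- match(hits$id, g$map$id)
  if (anyNA(idx)) stop("hit id(s) absent from dataset: ",
                       paste(hits$id[is.na(idx)], collapse = ", "))
  D <- g$dosages[, idx, drop = FALSE]
  r2 <- cor(D, truth$causal_dosages)^2  # hits x causal
  r2[is.na(r2)] <- 0
  best <- max.col(r2, ties.method = "first")
  best_r2 <- r2[cbind(seq_len(nrow(r2)), best)]
  tp <- best_r2 >= r2_threshold
  data.frame(id = hits$id, chrom = g$map$chrom[idx], bp = g$map$bp[idx],
             score = hits$score, tp = tp,
             causal_id = ifelse(tp, truth$causal$id[best], NA_character_),
             r2 = best_r2, stringsAsFactors = FALSE)
}

#' Count tagged causal loci and false-positive clusters
#'
#' The true positive count is the number of distinct causal loci tagged by
#' any true positive hit. False positives are greedily clustered: the most
#' significant unclustered false positive seeds a cluster absorbing all
#' false positives within half of `cluster_bp` on the same chromosome;
#' the false positive count is the number of such clusters.
#'
#' @param labels output of [classify_hits()].
#' @param truth a `sim_truth`.
#' @param cluster_bp cluster width in bp (default 100000).
#' @return List with `tp` and `fp_clusters`.
#' @export
count_tp_fp <- function(labels, truth, cluster_bp = 1e5) {
  tp_count <- length(unique(labels$causal_id[labels$tp]))
  fp <- labels[!labels$tp, , drop = FALSE]
  fp <- fp[order(fp$score), , drop = FALSE]
  centers_chrom <- character(0); centers_bp <- numeric(0)
  half <- cluster_bp / 2
  for (i in seq_len(nrow(fp))) {
    near <- centers_chrom == fp$chrom[i] & abs(centers_bp - fp$bp[i]) <= half
    if (!any(near)) {
      centers_chrom <- c(centers_chrom, fp$chrom[i])
      centers_bp <- c(centers_bp, fp$bp[i])
    }
  }
  list(tp = tp_count, fp_clusters = length(centers_bp))
}

#' Power at a fixed false discovery rate
#'
#' Walks the ranked hit list; at each prefix the FDR is the number of
#' false-positive clusters over (false-positive clusters + distinct
#' causal loci tagged), and recall is tagged loci over the number of
#' causal loci. Power is the largest recall over prefixes whose FDR does
#' not exceed the target. Clustering is incremental, which reproduces the
#' greedy most-significant-first cluster definition.
#'
#' @inheritParams classify_hits
#' @param fdr_target FDR level (default 0.05).
#' @param cluster_bp false-positive cluster width in bp.
#' @param max_rank walk at most this many top hits (default all).
#' @return List: `power`, `curve` (data.frame rank, tp, fp_clusters,
#'   recall, precision, fdr).
#' @export
power_at_fdr <- function(hits, truth, g, fdr_target = 0.05,
                         r2_threshold = 0.8, cluster_bp = 1e5,
                         max_rank = Inf) {
  labels <- classify_hits(hits, truth, g, r2_threshold)
  labels <- labels[order(labels$score), , drop = FALSE]
  m <- nrow(truth$causal)
  n_walk <- min(nrow(labels), max_rank)
  tagged <- character(0)
  centers_chrom <- character(0); centers_bp <- numeric(0)
  half <- cluster_bp / 2
  tp_v <- fp_v <- integer(n_walk)
  for (i in seq_len(n_walk)) {
    if (labels$tp[i]) {
      tagged <- union(tagged, labels$causal_id[i])
    } else {
      near <- centers_chrom == labels$chrom[i] &
        abs(centers_bp - labels$bp[i]) <= half
      if (!any(near)) {
        centers_chrom <- c(centers_chrom, labels$chrom[i])
        centers_bp <- c(centers_bp, labels$bp[i])
      }
    }
    tp_v[i] <- length(tagged)
    fp_v[i] <- length(centers_bp)
  }
  denom <- tp_v + fp_v
  fdr <- ifelse(denom > 0, fp_v / denom, 0)
  recall <- tp_v / m
  precision <- ifelse(denom > 0, tp_v / denom, 1)
  ok <- fdr <= fdr_target
  power <- if (any(ok)) max(recall[ok]) else 0
  list(power = power,
       curve = data.frame(rank = seq_len(n_walk), tp = tp_v,
                          fp_clusters = fp_v, recall = recall,
                          precision = precision, fdr = fdr))
}
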