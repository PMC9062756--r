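#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif quantile sd cor shapiro.test cor.test
#'   t.test wilcox.test chisq.test p.adjust median IQR hclust cutree
#'   as.dist predict
#' @importFrom utils write.table read.table
#' @importFrom tools md5sum
NULL

# Deterministic child-seed scheme: one master seed expands into independent
# integer seeds per (stream, index).  Adding subjects (larger index) never
# changes seeds of existing subjects.  Kept below 2^31 - 1.
child_seed <- function(seed, stream, index = 0L) {
  as.integer((as.double(seed) + 1000003 * stream + 10007 * index) %% 2147483629)
}

# z-score a vector: subtract mean, divide by SD (population-style n-1 SD,
# matching R's sd()).  Constant vectors map to all zeros.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Rank-based AUC of scores for a binary label vector (positive class given
# by `positive`).  Equivalent to the Mann-Whitney U statistic / (n1*n0).
auc_score <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Stratified bootstrap indices: resample within each group, preserving
# group sizes, so both classes appear in every resample.
stratified_resample <- function(labels) {
  idx <- integer(length(labels))
  for (g in unique(labels)) {
    w <- which(labels == g)
    idx[w] <- sample(w, length(w), replace = TRUE)
  }
  idx
}

# Moving-average smoothing of the columns of a matrix (used for synthetic
# time courses); window is truncated at the edges.
ma_smooth <- function(x, window) {
  if (window <= 1L) return(x)
  k <- rep(1 / window, window)
  sm <- stats::filter(x, k, sides = 2)
  # fill edge NAs with the original values
  sm[is.na(sm)] <- x[is.na(sm)]
  as.matrix(sm)
}

stop_invalid <- function(...) {
  stop(structure(class = c("icapattern_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("icapattern_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
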