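#' Gini impurity of class counts
#'
#' \eqn{1 - \sum_i p_i^2} for class proportions \eqn{p_i}; 0 for a pure
#' node, 0.5 at maximal two-class impurity.
#'
#' @param counts non-negative class counts, not all zero.
#' @return scalar impurity.
#' @examples
#' giniImpurity(c(2, 2))   # 0.5
#' giniImpurity(c(3, 1))   # 0.375
#' @export
giniImpurity <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("all counts are zero")
  1 - sum((counts / n)^2)
}

# best Gini split of one numeric feature: candidate thresholds are midpoints
# between consecutive sorted unique values; returns weighted child impurity
# and the threshold (lowest threshold on ties); NULL if no legal split
.bestSplit1 <- function(x, y01, minLeaf) {
  o <- order(x)
  xs <- x[o]; ys <- y01[o]
  n <- length(xs)
  i <- seq_len(n - 1L)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  nl <- i; nr <- n - i
  p1l <- cum1[i] / nl; p1r <- (tot1 - cum1[i]) / nr
  g <- nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)   # n * weighted Gini
  legal <- xs[i] < xs[i + 1L] & nl >= minLeaf & nr >= minLeaf
  if (!any(legal)) return(NULL)
  g[!legal] <- Inf
  # ties (within fp tolerance): lowest threshold wins
  j <- which(g <= min(g) + 1e-9)[1]
  list(gini = g[j] / n, threshold = (xs[j] + xs[j + 1L]) / 2)
}

#' Fit a binary classification tree by recursive Gini partitioning
#'
#' Greedy binary recursive partitioning: at each node the split minimising
#' the weighted child Gini impurity is chosen among candidate thresholds at
#' midpoints between consecutive sorted unique feature values. Ties are
#' broken toward the lower feature index, then the lower threshold. A node
#' is not split when pure, deeper than \code{maxDepth}, smaller than
#' \code{2 * minLeaf}, or when no split decreases impurity.
#'
#' @param X data.frame or matrix of numeric features.
#' @param y binary labels (as in \code{\link{fitLogistic}}).
#' @param maxDepth maximum split depth (default 2; a depth-2 tree is how the
#'   diagnostic cut-offs are visualised).
#' @param minLeaf minimum observations per leaf (default 5).
#' @param positiveClass class of \code{y} treated as the disease class.
#' @return object of class \code{giniTree}: a node table (BFS order) with
#'   feature, threshold, children, class proportions.
#' @examples
#' X <- data.frame(x = c(1, 3, 5, 9, 11, 13))
#' fitTree(X, c(0, 0, 0, 1, 1, 1), maxDepth = 1, minLeaf = 1)  # threshold 7
#' @export
fitTree <- function(X, y, maxDepth = 2, minLeaf = 5, positiveClass = "ACM") {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, TRUE))) stop("features must be numeric")
  y01 <- if (is.logical(y)) as.integer(y)
  else if (is.numeric(y)) as.integer(y != 0)
  else as.integer(as.character(y) == positiveClass)
  if (nrow(X) < 2 * minLeaf) stop("need at least 2 * minLeaf observations")

  nodes <- data.frame(id = integer(), depth = integer(), n = integer(),
                      p1 = numeric(), feature = character(),
                      threshold = numeric(), left = integer(),
                      right = integer(), stringsAsFactors = FALSE)
  addNode <- function(depth, n, p1) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, depth, n, p1, NA_character_, NA_real_,
                         NA_integer_, NA_integer_)
    id
  }
  # breadth-first expansion so node ids follow BFS order
  queue <- list(list(id = addNode(0L, length(y01), mean(y01)),
                     idx = seq_along(y01)))
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    idx <- nd$idx
    depth <- nodes$depth[nd$id]
    p1 <- nodes$p1[nd$id]
    if (depth >= maxDepth || p1 == 0 || p1 == 1 || length(idx) < 2 * minLeaf)
      next
    best <- NULL
    for (f in names(X)) {              # column order = tie-break order
      s <- .bestSplit1(X[[f]][idx], y01[idx], minLeaf)
      if (!is.null(s) && (is.null(best) || s$gini < best$gini - 1e-12))
        best <- c(s, feature = f)
    }
    parentGini <- 2 * p1 * (1 - p1)
    if (is.null(best) || best$gini >= parentGini - 1e-12) next
    goLeft <- X[[best$feature]][idx] < best$threshold
    li <- idx[goLeft]; ri <- idx[!goLeft]
    lid <- addNode(depth + 1L, length(li), mean(y01[li]))
    rid <- addNode(depth + 1L, length(ri), mean(y01[ri]))
    nodes$feature[nd$id] <- best$feature
    nodes$threshold[nd$id] <- best$threshold
    nodes$left[nd$id] <- lid
    nodes$right[nd$id] <- rid
    queue <- c(queue, list(list(id = lid, idx = li)),
               list(list(id = rid, idx = ri)))
  }
  structure(list(nodes = nodes, positiveClass = positiveClass,
                 maxDepth = maxDepth, minLeaf = minLeaf),
            class = "giniTree")
}

#' Split table of a fitted tree
#'
#' @param tree a \code{\link{fitTree}} result.
#' @return data.frame of internal nodes in breadth-first order with
#'   \code{feature}, \code{threshold} and \code{depth}.
#' @export
treeSplits <- function(tree) {
  stopifnot(inherits(tree, "giniTree"))
  nd <- tree$nodes
  nd[!is.na(nd$feature), c("id", "depth", "feature", "threshold", "n")]
}

#' @export
predict.giniTree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  nd <- object$nodes
  newdata <- as.data.frame(newdata)
  p <- vapply(seq_len(nrow(newdata)), function(i) {
    id <- 1L
    while (!is.na(nd$feature[id])) {
      id <- if (newdata[[nd$feature[id]]][i] < nd$threshold[id])
        nd$left[id] else nd$right[id]
    }
    nd$p1[id]
  }, numeric(1))
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.giniTree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("Gini classification tree: %d nodes, %d splits\n", nrow(nd),
              sum(!is.na(nd$feature))))
  for (i in seq_len(nrow(nd))) {
    pad <- strrep("  ", nd$depth[i] + 1)
    if (is.na(nd$feature[i]))
      cat(sprintf("%sleaf: n = %d, p(pos) = %.2f\n", pad, nd$n[i], nd$p1[i]))
    else
      cat(sprintf("%s%s < %.4g ? (n = %d)\n", pad, nd$feature[i],
                  nd$threshold[i], nd$n[i]))
  }
  invisible(x)
}
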