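#' GC content of sequences
#'
#' `(count of C + count of G) / total sequence length`; the denominator is
#' the full length including `N` positions, and `N` never counts as G/C.
#'
#' @param seq character vector of canonical sequences.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' gc_content(c("GGCC", "AUAU", "ACGU"))
gc_content <- function(seq) {
  if (!length(seq) || any(!nzchar(seq)) || anyNA(seq)) {
    stop("sequences must be non-empty")
  }
  (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}

#' Kruskal-Wallis rank test
#'
#' All values are ranked jointly with mid-ranks for ties;
#' `H = (12 / (N (N + 1))) * sum_i n_i (Rbar_i - (N + 1) / 2)^2`, divided by
#' the tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`. `H` is defined
#' as 0 when all values are identical. The p-value is the chi-square upper
#' tail with `groups - 1` degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return A list of class `kruskal_wallis_result` with fields `H`, `p`,
#'   `df` and `group_sizes`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$H  # 7.2
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("values must be non-missing")
  N <- length(x)
  if (N < 3L) stop("need at least 3 values in total")
  g <- rep(seq_along(groups), sizes)
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  df <- length(groups) - 1L
  structure(list(H = H, p = pchisq(H, df = df, lower.tail = FALSE),
                 df = df, group_sizes = as.integer(sizes)),
            class = "kruskal_wallis_result")
}

#' @export
print.kruskal_wallis_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.3g (groups n = %s)\n",
              x$H, x$df, x$p, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

# codon index helper: 0..63 from three base codes, NA if any is N
ORF_START <- 14L                 # AUG
ORF_STOPS <- c(48L, 50L, 56L)    # UAA, UAG, UGA

#' Longest open reading frame
#'
#' Scans the given strand in all three frames. An ORF runs from an `AUG`
#' to the first in-frame stop codon (`UAA`/`UAG`/`UGA`) strictly
#' downstream; its length counts start through stop inclusive (so the
#' minimal ORF `AUGUAA` scores 6). Returns the maximum such length, or 0 if
#' no complete ORF exists. Codons containing `N` are neither starts nor
#' stops.
#'
#' @param seq a canonical sequence string.
#' @return Integer nucleotide length (a multiple of 3, or 0).
#' @export
#' @examples
#' longest_orf("AAUGGCGUGAUU")  # 9
longest_orf <- function(seq) {
  code <- kmer_codes(seq)
  L <- length(code)
  if (L < 6L) return(0L)
  best <- 0L
  for (f in 0:2) {
    s <- seq.int(1L + f, L - 2L, by = 3L)
    if (!length(s)) next
    codon <- code[s] * 16L + code[s + 1L] * 4L + code[s + 2L]
    starts <- s[!is.na(codon) & codon == ORF_START]
    stops <- s[!is.na(codon) & codon %in% ORF_STOPS]
    if (!length(starts) || !length(stops)) next
    j <- findInterval(starts, stops) + 1L
    ok <- j <= length(stops)
    if (!any(ok)) next
    lens <- stops[j[ok]] - starts[ok] + 3L
    best <- max(best, lens)
  }
  as.integer(best)
}

# Dense Chebyshev (or Euclidean) distance matrix; column-blocked to bound
# temporary allocations.
dense_dist <- function(X, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  n <- nrow(X)
  if (metric == "euclidean") return(as.matrix(dist(X)))
  D <- matrix(0, n, n)
  for (j in seq_len(ncol(X))) {
    D <- pmax(D, abs(outer(X[, j], X[, j], "-")))
  }
  D
}

#' Standardized 2-D UMAP embedding of a feature matrix
#'
#' Columns are standardized to zero mean and unit variance, a k-nearest-
#' neighbour graph is built under the Chebyshev metric, and the graph is
#' embedded to two dimensions with UMAP (via \pkg{uwot}, with the
#' neighbour graph precomputed here because the requested metric is not
#' built into its search backend). Defaults follow the analysis this
#' package reproduces: 80 neighbours, minimum distance 0.005, Chebyshev
#' distance. The dense distance computation targets feature sets up to a
#' few thousand rows.
#'
#' @param features a `feature_matrix` or numeric matrix.
#' @param n_neighbors neighbourhood size (default 80).
#' @param min_dist minimum embedding distance (default 0.005).
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @param seed integer seed; the embedding is deterministic given it.
#' @return A list of class `embedding_result`: `coords` (n x 2 matrix,
#'   rownames preserved) and `params`.
#' @export
embed_2d <- function(features, n_neighbors = 80L, min_dist = 0.005,
                     metric = "chebyshev", seed = 42L) {
  X <- unclass(features)
  stopifnot(is.matrix(X))
  n <- nrow(X)
  n_neighbors <- as.integer(n_neighbors)
  if (n < n_neighbors + 1L) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1L,
         " rows (got ", n, "); reduce n_neighbors")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  D <- dense_dist(Xs, metric)
  idx <- t(apply(D, 1L, order))[, seq_len(n_neighbors), drop = FALSE]
  # self is always first (distance 0 to itself)
  nnd <- matrix(D[cbind(rep(seq_len(n), n_neighbors), as.vector(idx))],
                n, n_neighbors)
  set.seed(seed)
  coords <- uwot::umap(X = Xs, nn_method = list(idx = idx, dist = nnd),
                       min_dist = min_dist, init = "pca", n_threads = 1,
                       n_sgd_threads = 0, verbose = FALSE)
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, metric = metric,
                               seed = as.integer(seed))),
            class = "embedding_result")
}

#' Flag class outliers in an embedding
#'
#' A record is an outlier for its class when the majority of its
#' `n_neighbors` nearest embedded neighbours (Euclidean distance in 2-D)
#' carry a different label.
#'
#' @param embedding an `embedding_result` from [embed_2d()].
#' @param labels label vector aligned with the embedding rows.
#' @param target_class optional single class; restrict the returned ids to
#'   it.
#' @param n_neighbors neighbourhood size (defaults to the embedding's).
#' @return Character vector of flagged record ids (row names, or row
#'   indices as character when unnamed).
#' @export
find_outlier_members <- function(embedding, labels, target_class = NULL,
                                 n_neighbors = NULL) {
  stopifnot(inherits(embedding, "embedding_result"))
  coords <- embedding$coords
  n <- nrow(coords)
  if (length(labels) != n) stop("labels must align with embedding rows")
  if (is.null(n_neighbors)) n_neighbors <- embedding$params$n_neighbors
  n_neighbors <- min(as.integer(n_neighbors), n - 1L)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  flagged <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(n_neighbors)]
    mean(labels[nb] != labels[i]) > 0.5
  }, TRUE)
  ids <- rownames(coords) %||% as.character(seq_len(n))
  if (!is.null(target_class)) flagged <- flagged & labels == target_class
  ids[flagged]
}

#' Per-class GC and ORF summaries with a Kruskal-Wallis test on GC
#'
#' @param dataset a labelled [rna_set()] (two or more classes).
#' @return A list of class `class_feature_report`: `per_record` data.frame
#'   (`id`, `label`, `gc`, `longest_orf`), `gc_summary` and `orf_summary`
#'   per-class tables, and `kruskal` ([kruskal_wallis()] over the per-class
#'   GC groups).
#' @export
class_feature_report <- function(dataset) {
  stopifnot(inherits(dataset, "rna_set"))
  labels <- dataset$label
  if (anyNA(labels) || length(unique(labels)) < 2L) {
    stop("need at least two labelled classes")
  }
  gc <- gc_content(dataset$sequence)
  orf <- vapply(dataset$sequence, longest_orf, 0L, USE.NAMES = FALSE)
  cls <- class_names(dataset)
  summarize <- function(v) {
    t(vapply(cls, function(cl) {
      x <- v[labels == cl]
      c(n = length(x), mean = mean(x), median = median(x),
        q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
    }, numeric(5)))
  }
  structure(list(
    per_record = data.frame(id = dataset$id, label = labels, gc = gc,
                            longest_orf = orf, stringsAsFactors = FALSE),
    gc_summary = summarize(gc),
    orf_summary = summarize(orf),
    kruskal = kruskal_wallis(split(gc, factor(labels, levels = cls)))
  ), class = "class_feature_report")
}

#' @importFrom stats median quantile dist
NULL
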