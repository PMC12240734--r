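#' Multi-scale k-mer specification
#'
#' @param ks ordered integer vector of k values (default `c(3, 4, 5)`); the
#'   fused feature row has length `sum(4^ks)` (1344 for the default).
#' @return A list of class `kmer_spec`.
#' @export
kmer_spec <- function(ks = c(3L, 4L, 5L)) {
  ks <- as.integer(ks)
  stopifnot(length(ks) >= 1L, all(ks >= 1L))
  structure(list(ks = ks, dims = 4L^ks), class = "kmer_spec")
}

#' k-mer frequency vector of a sequence
#'
#' Slides a width-`k` window with step 1; windows containing `N` are
#' skipped. Entries are counts divided by the number of valid windows, in
#' lexicographic k-mer order over (A, C, G, U). A sequence with no valid
#' window yields an all-zero vector (with a warning when `k` exceeds the
#' sequence length).
#'
#' @param seq canonical sequence string.
#' @param k word length (>= 1).
#' @return Named numeric vector of length `4^k`.
#' @export
#' @examples
#' kmer_frequencies("ACGU", 3)[c("ACG", "CGU")]
kmer_frequencies <- function(seq, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  dim <- 4L^k
  out <- numeric(dim)
  names(out) <- kmer_names(k)
  code <- kmer_codes(seq)
  if (length(code) < k) {
    warning("k (", k, ") exceeds sequence length (", length(code), ")")
    return(out)
  }
  idx <- kmer_indices(code, k)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(out)
  out[] <- tabulate(idx, nbins = dim) / length(idx)
  out
}

#' Fused multi-scale k-mer feature row
#'
#' Concatenates the per-scale frequency vectors of [kmer_frequencies()] in
#' the order given by `spec$ks`; each per-scale slice sums to 1 when the
#' sequence has at least one valid window at that scale.
#'
#' @param seq canonical sequence string.
#' @param spec a [kmer_spec()].
#' @return Named numeric vector of length `sum(4^spec$ks)` with attribute
#'   `scale_slices` (a named list of column index ranges per scale).
#' @export
multiscale_kmer <- function(seq, spec = kmer_spec()) {
  stopifnot(inherits(spec, "kmer_spec"))
  parts <- lapply(spec$ks, function(k) {
    v <- kmer_frequencies(seq, k)
    names(v) <- paste0(k, "mer:", names(v))
    v
  })
  out <- unlist(parts)
  attr(out, "scale_slices") <- scale_slices(spec)
  out
}

scale_slices <- function(spec) {
  ends <- cumsum(spec$dims)
  starts <- c(1L, head(ends, -1L) + 1L)
  setNames(Map(function(s, e) s:e, starts, ends),
           paste0(spec$ks, "mer"))
}

#' Nucleotide composition (NAC)
#'
#' Per-base frequency over non-`N` positions, in (A, C, G, U) order.
#'
#' @param seq canonical sequence string.
#' @return Named numeric 4-vector.
#' @export
nac <- function(seq) {
  code <- kmer_codes(seq)
  valid <- code[!is.na(code)]
  out <- setNames(numeric(4L), RNA_BASES)
  if (!length(valid)) {
    warning("sequence has no non-N position")
    return(out)
  }
  out[] <- tabulate(valid + 1L, nbins = 4L) / length(valid)
  out
}

#' Composition of k-spaced nucleotide pairs (CKSNAP)
#'
#' For each gap `g` in `0..max_gap`, the frequency of each ordered base
#' pair `(x, y)` at positions `(i, i + g + 1)` among all valid such
#' position pairs (pairs touching an `N` are skipped). Blocks are
#' concatenated by ascending gap.
#'
#' @param seq canonical sequence string, longer than `max_gap + 1`.
#' @param max_gap largest gap (default 5).
#' @return Named numeric vector of length `16 * (max_gap + 1)`; names are
#'   `"g<gap>:<pair>"`.
#' @export
cksnap <- function(seq, max_gap = 5L) {
  max_gap <- as.integer(max_gap)
  code <- kmer_codes(seq)
  L <- length(code)
  if (L <= max_gap + 1L) {
    stop("sequence length (", L, ") must exceed max_gap + 1 (", max_gap + 1L, ")")
  }
  pair_names <- kmer_names(2L)
  blocks <- lapply(0:max_gap, function(g) {
    n_pairs <- L - g - 1L
    out <- setNames(numeric(16L), paste0("g", g, ":", pair_names))
    if (n_pairs < 1L) {
      warning("sequence too short for gap ", g)
      return(out)
    }
    x <- code[seq_len(n_pairs)]
    y <- code[seq_len(n_pairs) + g + 1L]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) return(out)
    idx <- x[ok] * 4L + y[ok] + 1L
    out[] <- tabulate(idx, nbins = 16L) / sum(ok)
    out
  })
  unlist(blocks)
}

# Standardized property profiles P_u(i) along the dinucleotide positions of
# a sequence: (L-1) x n_properties matrix, NA rows where a dinucleotide
# contains N.
dinuc_profile <- function(seq, table) {
  code <- kmer_codes(seq)
  if (length(code) < 2L) stop("sequence has no dinucleotide")
  idx <- kmer_indices(code, 2L)
  table[idx, , drop = FALSE]
}

#' Dinucleotide auto-covariance (DAC)
#'
#' With `P_u(i)` the standardized property-`u` value of the dinucleotide at
#' position `i` (`i = 1..L-1`) and `Pbar_u` its mean over the sequence,
#' `DAC(u, lag) = (1/(L-1-lag)) * sum_i (P_u(i) - Pbar_u) (P_u(i+lag) - Pbar_u)`
#' for `lag = 1..max_lag`. Dinucleotides containing `N` are dropped from the
#' mean and the sum (the denominator then counts the valid pairs).
#'
#' @param seq canonical sequence string.
#' @param table standardized 16 x n_properties matrix
#'   (default [dinuc_property_table()]).
#' @param max_lag largest lag (default 2).
#' @return Named numeric vector of length `n_properties * max_lag`,
#'   ordered property-major (`"<property>:lag<j>"`).
#' @export
dac <- function(seq, table = dinuc_property_table(), max_lag = 2L) {
  max_lag <- as.integer(max_lag)
  P <- dinuc_profile(seq, table)
  n_pos <- nrow(P)
  if (n_pos < max_lag + 2L) {
    stop("sequence must yield at least max_lag + 2 = ", max_lag + 2L,
         " dinucleotide positions (got ", n_pos, ")")
  }
  props <- colnames(table)
  out <- numeric(0)
  for (u in props) {
    p <- P[, u]
    pbar <- mean(p, na.rm = TRUE)
    d <- p - pbar
    for (lag in seq_len(max_lag)) {
      a <- d[seq_len(n_pos - lag)]
      b <- d[seq_len(n_pos - lag) + lag]
      out <- c(out, setNames(sum(a * b, na.rm = TRUE) / sum(!is.na(a * b)),
                             paste0(u, ":lag", lag)))
    }
  }
  out
}

#' Dinucleotide cross-covariance (DCC)
#'
#' `DCC(u1, u2, lag) = (1/(L-1-lag)) * sum_i (P_u1(i) - Pbar_u1)
#' (P_u2(i+lag) - Pbar_u2)` for all ordered property pairs `u1 != u2` and
#' `lag = 1..max_lag`.
#'
#' @inheritParams dac
#' @return Named numeric vector of length
#'   `n_properties * (n_properties - 1) * max_lag`.
#' @export
dcc <- function(seq, table = dinuc_property_table(), max_lag = 2L) {
  max_lag <- as.integer(max_lag)
  P <- dinuc_profile(seq, table)
  n_pos <- nrow(P)
  if (n_pos < max_lag + 2L) {
    stop("sequence must yield at least max_lag + 2 = ", max_lag + 2L,
         " dinucleotide positions (got ", n_pos, ")")
  }
  props <- colnames(table)
  ctr <- sweep(P, 2L, colMeans(P, na.rm = TRUE))
  out <- numeric(0)
  for (u1 in props) for (u2 in props) {
    if (u1 == u2) next
    for (lag in seq_len(max_lag)) {
      a <- ctr[seq_len(n_pos - lag), u1]
      b <- ctr[seq_len(n_pos - lag) + lag, u2]
      out <- c(out, setNames(sum(a * b, na.rm = TRUE) / sum(!is.na(a * b)),
                             paste0(u1, "x", u2, ":lag", lag)))
    }
  }
  out
}

#' Dinucleotide auto-cross-covariance (DACC)
#'
#' Concatenation of [dac()] followed by [dcc()].
#'
#' @inheritParams dac
#' @return Named numeric vector.
#' @export
dacc <- function(seq, table = dinuc_property_table(), max_lag = 2L) {
  c(dac(seq, table, max_lag), dcc(seq, table, max_lag))
}

# theta_j used by the pseudo-composition descriptors; corr_fun takes the
# property rows at positions i and i+j and returns the coupling Theta(i,i+j).
pseudo_theta <- function(P, lambda, corr_fun) {
  n_pos <- nrow(P)
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(n_pos - j)
    vals <- corr_fun(P[i, , drop = FALSE], P[i + j, , drop = FALSE])
    mean(vals, na.rm = TRUE)
  }, 0)
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' First `4^k` entries are `f_v / (sum(f) + w * sum(theta))`, the last
#' `lambda` entries `w * theta_j / (sum(f) + w * sum(theta))`, where `f` are
#' the k-mer frequencies and `theta_j` is the mean over positions of the
#' squared-difference correlation
#' `Theta(i, i+j) = (1/n_props) * sum_u (P_u(i) - P_u(i+j))^2`.
#'
#' @param seq canonical sequence string.
#' @param k tuple length (default 3).
#' @param lambda number of correlation tiers (default 2).
#' @param weight correlation weight `w` (default 0.1).
#' @param table standardized dinucleotide property matrix.
#' @return Named numeric vector of length `4^k + lambda`.
#' @export
pseknc <- function(seq, k = 3L, lambda = 2L, weight = 0.1,
                   table = dinuc_property_table()) {
  lambda <- as.integer(lambda)
  P <- dinuc_profile(seq, table)
  if (nrow(P) < lambda + 2L) {
    stop("sequence must yield at least lambda + 2 = ", lambda + 2L,
         " dinucleotides (got ", nrow(P), ")")
  }
  f <- kmer_frequencies(seq, k)
  theta <- pseudo_theta(P, lambda, function(a, b) rowMeans((a - b)^2))
  denom <- sum(f) + weight * sum(theta)
  out <- c(f, setNames(weight * theta, paste0("theta", seq_len(lambda)))) / denom
  names(out)[seq_along(f)] <- names(f)
  out
}

#' Parallel-correlation pseudo-dinucleotide composition (PCPseDNC)
#'
#' As [pseknc()] with `k` fixed to 2 and the parallel-correlation coupling
#' `Theta(i, i+j) = (1/n_props) * sum_u P_u(i) * P_u(i+j)`.
#'
#' @inheritParams pseknc
#' @return Named numeric vector of length `16 + lambda`.
#' @export
pcpsednc <- function(seq, lambda = 2L, weight = 0.1,
                     table = dinuc_property_table()) {
  lambda <- as.integer(lambda)
  P <- dinuc_profile(seq, table)
  if (nrow(P) < lambda + 2L) {
    stop("sequence must yield at least lambda + 2 = ", lambda + 2L,
         " dinucleotides (got ", nrow(P), ")")
  }
  f <- kmer_frequencies(seq, 2L)
  theta <- pseudo_theta(P, lambda, function(a, b) rowMeans(a * b))
  denom <- sum(f) + weight * sum(theta)
  out <- c(f, setNames(weight * theta, paste0("theta", seq_len(lambda)))) / denom
  names(out)[seq_along(f)] <- names(f)
  out
}

#' Build a feature matrix for a sequence set
#'
#' Applies one descriptor to every record of an [rna_set()].
#'
#' @param dataset an [rna_set()].
#' @param descriptor one of `"multiscale"`, `"kmer"`, `"nac"`, `"cksnap"`,
#'   `"dac"`, `"dcc"`, `"dacc"`, `"pseknc"`, `"pcpsednc"`.
#' @param spec a [kmer_spec()]; used by `"multiscale"` (all scales) and
#'   `"kmer"` (first scale only).
#' @param ... further arguments passed to the descriptor function.
#' @return A `feature_matrix`: a numeric matrix with record ids as rownames,
#'   descriptor dimension names as colnames, and attributes `scale_slices`
#'   (multiscale/kmer only), `labels` and `splits` copied from the dataset.
#' @export
featurize <- function(dataset, descriptor = "multiscale", spec = kmer_spec(),
                      ...) {
  stopifnot(inherits(dataset, "rna_set"), nrow(dataset) > 0L)
  descriptor <- match.arg(descriptor,
                          c("multiscale", "kmer", "nac", "cksnap", "dac",
                            "dcc", "dacc", "pseknc", "pcpsednc"))
  fun <- switch(descriptor,
    multiscale = function(s) multiscale_kmer(s, spec = spec, ...),
    kmer = function(s) kmer_frequencies(s, k = spec$ks[1], ...),
    nac = function(s) nac(s, ...),
    cksnap = function(s) cksnap(s, ...),
    dac = function(s) dac(s, ...),
    dcc = function(s) dcc(s, ...),
    dacc = function(s) dacc(s, ...),
    pseknc = function(s) pseknc(s, ...),
    pcpsednc = function(s) pcpsednc(s, ...))
  first <- fun(dataset$sequence[1])
  vals <- t(vapply(dataset$sequence, fun, numeric(length(first)),
                   USE.NAMES = FALSE))
  rownames(vals) <- dataset$id
  colnames(vals) <- names(first)
  slices <- if (descriptor == "multiscale") {
    scale_slices(spec)
  } else if (descriptor == "kmer") {
    setNames(list(seq_along(first)), paste0(spec$ks[1], "mer"))
  } else {
    setNames(list(seq_along(first)), descriptor)
  }
  structure(vals, scale_slices = slices, labels = dataset$label,
            splits = dataset$split, class = c("feature_matrix", "matrix"))
}

# Subset a feature_matrix by row index, keeping attributes aligned.
fm_subset <- function(fm, rows) {
  structure(fm[rows, , drop = FALSE],
            scale_slices = attr(fm, "scale_slices"),
            labels = attr(fm, "labels")[rows],
            splits = attr(fm, "splits")[rows],
            class = class(fm))
}

#' Extract one split of a feature matrix
#'
#' Convenience subset of a `feature_matrix` by the split tags carried over
#' from the source [rna_set()], keeping labels and scale slices aligned.
#'
#' @param fm a `feature_matrix` from [featurize()].
#' @param split one of `"train"`, `"val"`, `"test"`, `"unassigned"`.
#' @return The subset `feature_matrix`.
#' @export
split_features <- function(fm, split) {
  spl <- attr(fm, "splits")
  if (is.null(spl)) stop("feature matrix carries no split tags")
  fm_subset(fm, spl == split)
}
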