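#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence string, preserving
#' record order otherwise.
#'
#' @param dataset an [rna_set()].
#' @return The deduplicated `rna_set`, with attribute `n_removed` giving the
#'   number of records dropped.
#' @export
deduplicate_exact <- function(dataset) {
  stopifnot(inherits(dataset, "rna_set"))
  keep <- !duplicated(dataset$sequence)
  out <- as_rna_set(dataset[keep, , drop = FALSE], class_names(dataset))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Filter out short sequences
#'
#' Records shorter than `min_len` nucleotides are removed; a record of
#' length exactly `min_len` is kept (mirrors removal of sequences
#' below 200 nt).
#'
#' @param dataset an [rna_set()].
#' @param min_len minimum retained length (default 200).
#' @return The filtered `rna_set`, with attribute `n_removed`.
#' @export
length_filter <- function(dataset, min_len = 200L) {
  stopifnot(inherits(dataset, "rna_set"), min_len >= 1L)
  keep <- nchar(dataset$sequence) >= min_len
  out <- as_rna_set(dataset[keep, , drop = FALSE], class_names(dataset))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Redundancy-reduction parameters
#'
#' @param identity_threshold fraction in (0, 1]; pairs at or above this
#'   estimated identity are collapsed (default 0.80).
#' @param word_size word length used by the k-mer containment identity
#'   estimate (default 8). The default keeps the background containment of
#'   unrelated sequences far below the threshold across the whole 200 nt to
#'   10 kb length range (short words saturate when a short sequence is
#'   compared against a much longer one), while near-identical pairs still
#'   score well above 0.8.
#' @return A list of class `redundancy_params`.
#' @export
redundancy_params <- function(identity_threshold = 0.80, word_size = 8L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1, word_size >= 2L,
            word_size <= 12L)
  structure(list(identity_threshold = identity_threshold,
                 word_size = as.integer(word_size)),
            class = "redundancy_params")
}

# Sparse word_size-mer count of one canonical sequence: list with sorted
# integer word codes and their counts. Windows containing N are skipped.
word_counts <- function(seq, k) {
  code <- kmer_codes(seq)
  n <- length(code)
  if (n < k) return(list(code = integer(), count = integer(), total = 0L))
  idx <- kmer_indices(code, k)
  idx <- idx[!is.na(idx)]
  tab <- sort(idx)
  runs <- rle(tab)
  list(code = runs$values, count = runs$lengths, total = length(idx))
}

# multiset intersection size of two sparse word-count objects
shared_words <- function(a, b) {
  m <- match(a$code, b$code)
  sel <- !is.na(m)
  if (!any(sel)) return(0L)
  sum(pmin(a$count[sel], b$count[m[sel]]))
}

#' Greedy redundancy reduction (CD-HIT-style)
#'
#' Emulates CD-HIT's greedy longest-first clustering with a k-mer
#' containment identity estimate: sequences are visited in decreasing
#' length order; each becomes a cluster representative unless its estimated
#' identity to an existing representative reaches
#' `params$identity_threshold`, in which case it is absorbed. The identity
#' estimate between two sequences is the multiset intersection of their
#' `word_size`-mers divided by the number of `word_size`-mers in the
#' shorter sequence, so a perfect substring scores 1. Output keeps the
#' representatives in their original relative order. Deterministic given
#' the input order and parameters.
#'
#' @param dataset an exact-deduplicated [rna_set()].
#' @param params a [redundancy_params()].
#' @return The reduced `rna_set`, with attribute `n_removed`.
#' @export
reduce_redundancy <- function(dataset, params = redundancy_params()) {
  stopifnot(inherits(dataset, "rna_set"), inherits(params, "redundancy_params"))
  n <- nrow(dataset)
  k <- params$word_size
  lens <- nchar(dataset$sequence)
  if (n >= 1L && min(lens) < k) {
    stop("word_size (", k, ") exceeds the shortest sequence length (",
         min(lens), ")")
  }
  if (n <= 1L) {
    out <- as_rna_set(dataset, class_names(dataset))
    attr(out, "n_removed") <- 0L
    return(out)
  }
  cnt <- lapply(dataset$sequence, word_counts, k = k)
  nwin <- vapply(cnt, `[[`, 0L, "total")
  ord <- order(lens, decreasing = TRUE)   # stable: ties keep input order
  reps <- integer(0)
  absorbed <- logical(n)
  thr <- params$identity_threshold
  for (i in ord) {
    ci <- cnt[[i]]
    hit <- FALSE
    for (j in reps) {
      shared <- shared_words(ci, cnt[[j]])
      if (shared / min(nwin[i], nwin[j]) >= thr) {
        hit <- TRUE
        break
      }
    }
    if (hit) absorbed[i] <- TRUE else reps <- c(reps, i)
  }
  keep <- !absorbed
  out <- as_rna_set(dataset[keep, , drop = FALSE], class_names(dataset))
  attr(out, "n_removed") <- sum(absorbed)
  out
}

#' Estimated pairwise identity used by [reduce_redundancy()]
#'
#' Exposed for inspection and testing: multiset `word_size`-mer
#' intersection divided by the `word_size`-mer count of the shorter
#' sequence.
#'
#' @param seq_a,seq_b canonical sequence strings.
#' @param word_size word length (default 8, matching [redundancy_params()]).
#' @return A fraction in \[0, 1\].
#' @export
identity_estimate <- function(seq_a, seq_b, word_size = 8L) {
  k <- as.integer(word_size)
  if (min(nchar(seq_a), nchar(seq_b)) < k) {
    stop("word_size exceeds a sequence length")
  }
  ca <- word_counts(seq_a, k)
  cb <- word_counts(seq_b, k)
  shared_words(ca, cb) / min(ca$total, cb$total)
}

#' Inter-group deduplication
#'
#' A sequence string occurring in more than one class dataset is removed
#' from all of them, so no class can claim it; within-class content is
#' otherwise untouched.
#'
#' @param datasets a list of two or more [rna_set()] objects.
#' @return A list of `rna_set` objects of the same length.
#' @export
intergroup_dedup <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  seq_by_set <- lapply(datasets, function(d) unique(d$sequence))
  all_seqs <- unlist(seq_by_set, use.names = FALSE)
  shared <- unique(all_seqs[duplicated(all_seqs)])
  lapply(datasets, function(d) {
    keep <- !(d$sequence %in% shared)
    out <- as_rna_set(d[keep, , drop = FALSE], class_names(d))
    attr(out, "n_removed") <- sum(!keep)
    out
  })
}

#' Train/validation/test split specification
#'
#' @param train_frac,val_frac,test_frac positive fractions summing to 1
#'   (defaults 0.70 / 0.15 / 0.15).
#' @param seed integer seed for the per-class shuffles.
#' @param stratified logical; per-class splitting (the only supported mode).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.70, val_frac = 0.15, test_frac = 0.15,
                       seed = 1L, stratified = TRUE) {
  stopifnot(train_frac > 0, val_frac > 0, test_frac > 0)
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9) {
    stop("split fractions must sum to 1")
  }
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Per class, records are shuffled with the spec seed, then the first
#' `floor(n * train_frac)` go to train, the next `floor(n * val_frac)` to
#' validation, and the remainder to test. Deterministic given the seed and
#' input order.
#'
#' @param datasets a single labelled [rna_set()] or a list of them (one per
#'   class); all records must carry a label.
#' @param spec a [split_spec()].
#' @return One combined `rna_set` with `split` tags assigned; attribute
#'   `split_counts` holds the per-class count table.
#' @export
stratified_split <- function(datasets, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (inherits(datasets, "rna_set")) datasets <- list(datasets)
  cls <- unique(unlist(lapply(datasets, class_names)))
  combined <- do.call(rbind, lapply(datasets, as.data.frame))
  combined <- as_rna_set(combined, cls)
  if (anyDuplicated(combined$id)) {
    stop("duplicate ids across datasets: ",
         paste(unique(combined$id[duplicated(combined$id)]), collapse = ", "))
  }
  if (anyNA(combined$label)) stop("every record must be labelled before splitting")
  combined$split <- NA_character_
  counts <- list()
  for (cl in cls) {
    idx <- which(combined$label == cl)
    n <- length(idx)
    if (n < 3L) stop("class '", cl, "' has fewer than 3 records (", n, ")")
    # independent per-class RNG stream keyed on (seed, class)
    set.seed(mix_seed(spec$seed, match(cl, cls)))
    idx <- idx[sample.int(n)]
    n_train <- floor(n * spec$train_frac)
    n_val <- floor(n * spec$val_frac)
    tags <- rep("test", n)
    tags[seq_len(n_train)] <- "train"
    if (n_val > 0) tags[n_train + seq_len(n_val)] <- "val"
    combined$split[idx] <- tags
    counts[[cl]] <- c(train = n_train, val = n_val, test = n - n_train - n_val)
  }
  attr(combined, "split_counts") <- do.call(rbind, counts)
  combined
}

#' Run the full curation pipeline on per-class sequence sets
#'
#' Applies, in order: exact deduplication, minimum-length filtering,
#' greedy redundancy reduction, inter-group deduplication, and a
#' stratified split.
#'
#' @param datasets a list of labelled [rna_set()] objects, one per class.
#' @param min_len minimum sequence length kept (default 200).
#' @param redundancy a [redundancy_params()].
#' @param spec a [split_spec()].
#' @return The curated, split `rna_set`; attribute `curation_report` is a
#'   `data.frame` of per-stage, per-class record counts.
#' @export
curate <- function(datasets, min_len = 200L,
                   redundancy = redundancy_params(), spec = split_spec()) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  labels <- vapply(datasets, function(d) d$label[1], "")
  report <- list()
  log_stage <- function(stage, sets) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, class = labels,
      count = vapply(sets, nrow, 0L), stringsAsFactors = FALSE)
  }
  log_stage("input", datasets)
  datasets <- lapply(datasets, deduplicate_exact)
  log_stage("deduplicate_exact", datasets)
  datasets <- lapply(datasets, length_filter, min_len = min_len)
  log_stage("length_filter", datasets)
  datasets <- lapply(datasets, reduce_redundancy, params = redundancy)
  log_stage("reduce_redundancy", datasets)
  datasets <- intergroup_dedup(datasets)
  log_stage("intergroup_dedup", datasets)
  out <- stratified_split(datasets, spec)
  attr(out, "curation_report") <- do.call(rbind, report)
  out
}
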