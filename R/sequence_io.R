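#' Construct a labelled RNA sequence set
#'
#' An `rna_set` is a plain `data.frame` with columns `id`, `sequence`,
#' `label` and `split`, plus a `class_names` attribute giving the ordered
#' class labels. Sequences are held in the canonical RNA alphabet
#' `{A, C, G, U, N}`; [normalize_sequence()] is applied on construction.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of sequences (any case, DNA or RNA
#'   alphabet; normalized internally).
#' @param label optional character vector of class labels (`NA` allowed for
#'   prediction-only records).
#' @param split character vector of split tags (`"train"`, `"val"`,
#'   `"test"` or `"unassigned"`).
#' @param class_names ordered character vector of class names. Defaults to
#'   the unique non-`NA` labels in order of first appearance.
#'
#' @return A `data.frame` of class `rna_set`.
#' @export
#' @examples
#' rna_set(c("a", "b"), c("acgt", "AC GU"), label = c("mRNA", "mRNA"))
rna_set <- function(id, sequence, label = NA_character_,
                    split = "unassigned", class_names = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- vapply(as.character(sequence), normalize_sequence, "",
                     USE.NAMES = FALSE)
  label <- rep_len(as.character(label), length(id))
  split <- rep_len(as.character(split), length(id))
  bad_split <- !split %in% c("train", "val", "test", "unassigned")
  if (any(bad_split)) stop("invalid split tag: ", split[bad_split][1])
  if (is.null(class_names)) {
    class_names <- unique(label[!is.na(label)])
  }
  unknown <- setdiff(label[!is.na(label)], class_names)
  if (length(unknown)) {
    stop("label(s) not in class_names: ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(id = id, sequence = sequence, label = label,
                    split = split, stringsAsFactors = FALSE)
  attr(out, "class_names") <- as.character(class_names)
  class(out) <- c("rna_set", "data.frame")
  out
}

#' @export
print.rna_set <- function(x, ...) {
  cat(sprintf("<rna_set> %d record(s), classes: %s\n", nrow(x),
              paste(class_names(x), collapse = ", ")))
  if (nrow(x)) {
    tab <- table(factor(x$label, levels = class_names(x)), x$split)
    print(tab)
  }
  invisible(x)
}

#' Ordered class names of an `rna_set`
#' @param x an `rna_set`.
#' @return Character vector of class names.
#' @export
class_names <- function(x) attr(x, "class_names")

# Rebuild the rna_set class/attributes after data.frame subsetting.
as_rna_set <- function(df, class_names) {
  rownames(df) <- NULL
  attr(df, "class_names") <- class_names
  class(df) <- c("rna_set", "data.frame")
  df
}

#' Normalize a raw sequence to the canonical RNA alphabet
#'
#' Uppercases, maps `T` to `U`, drops whitespace, and maps every other
#' non-`ACGU` character (ambiguity codes included) to `N`. Idempotent.
#'
#' @param raw a single non-empty string.
#' @return The canonical sequence string over `{A,C,G,U,N}`.
#' @export
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' normalize_sequence("ACXG")  # "ACNG"
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("raw must be a single string")
  }
  s <- gsub("[[:space:]]", "", raw)
  if (!nzchar(s)) stop("sequence is empty after removing whitespace")
  s <- chartr("t", "u", tolower(s))
  s <- toupper(s)
  s <- gsub("[^ACGU]", "N", s)
  if (!grepl("[ACGU]", s)) {
    warning("sequence is entirely N after normalization")
  }
  s
}

#' Read labelled RNA sequences from a FASTA file
#'
#' Headers have the form `>id [label=class]`; the first whitespace-separated
#' token is the record id and an optional `label=` token overrides the
#' file-level `label` argument. Sequences are normalized to `{A,C,G,U,N}`.
#' Plain and gzip-compressed files are accepted.
#'
#' @param path path to a FASTA file.
#' @param label optional class name applied to every record lacking a
#'   per-record `label=` token.
#' @param class_names optional ordered class names for the resulting set.
#' @return An [rna_set()].
#' @export
read_fasta <- function(path, label = NA_character_, class_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 50L)
  close(con)
  first <- first[nzchar(trimws(first))]
  if (!length(first)) stop("empty FASTA file: ", path)
  if (!startsWith(first[1], ">")) {
    stop("not FASTA: line 1 of ", path, " does not begin with '>'")
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  headers <- names(set)
  toks <- strsplit(headers, "[[:space:]]+")
  ids <- vapply(toks, `[[`, "", 1L)
  labels <- vapply(toks, function(tk) {
    hit <- grep("^label=", tk, value = TRUE)
    if (length(hit)) sub("^label=", "", hit[1]) else NA_character_
  }, "")
  labels[is.na(labels)] <- label
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rna_set(ids, as.character(set), label = labels, class_names = class_names)
}

#' Write an `rna_set` to FASTA
#'
#' Bodies are wrapped at 60 columns. Records carrying a label are written
#' with a `label=` header token so that [read_fasta()] round-trips ids,
#' sequences and labels exactly.
#'
#' @param dataset a non-empty [rna_set()].
#' @param path output path (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "rna_set"))
  if (!nrow(dataset)) stop("cannot write an empty rna_set")
  headers <- ifelse(is.na(dataset$label), dataset$id,
                    paste0(dataset$id, " label=", dataset$label))
  seqs <- Biostrings::BStringSet(dataset$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
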