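#' Generative profile for one synthetic RNA class
#'
#' Sequences are emitted i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(U) = (1 - gc)/2`, where the per-sequence `gc` is drawn from a
#' normal (or equal-weight mixture of normals when `gc_target` has several
#' components) clipped to (0.05, 0.95). Lengths follow a log-uniform law on
#' `[min_len, max_len]`. Motif biases then plant extra copies of short
#' motifs at `(multiplier - 1)` times the motif's expected background rate,
#' and the ORF model optionally plants one long `AUG ... stop` span free of
#' internal in-frame stops, covering a fraction `f ~ U(0.5, 0.9)` of the
#' sequence.
#'
#' @param name class label.
#' @param gc_target numeric vector of GC mixture component means.
#' @param gc_sd per-sequence GC spread (single value, recycled across
#'   components).
#' @param min_len,max_len length-law bounds; `min_len` must be >= 200.
#' @param orf_model `"long"` (planted ORF) or `"short"` (incidental ORFs
#'   only).
#' @param motif_biases list of `list(motif = <string>, multiplier = <x>)`
#'   entries; multipliers must be positive.
#' @return A list of class `class_profile`.
#' @export
class_profile <- function(name, gc_target = 0.5, gc_sd = 0.03,
                          min_len = 200L, max_len = 2000L,
                          orf_model = c("short", "long"),
                          motif_biases = list()) {
  orf_model <- match.arg(orf_model)
  stopifnot(all(gc_target > 0), all(gc_target < 1), gc_sd >= 0,
            min_len >= 200L, max_len >= min_len)
  for (mb in motif_biases) {
    stopifnot(is.character(mb$motif), mb$multiplier > 0)
  }
  structure(list(name = name, gc_target = gc_target, gc_sd = gc_sd,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 orf_model = orf_model, motif_biases = motif_biases),
            class = "class_profile")
}

#' Default three-class profiles
#'
#' Emulate the observed contrasts between the three transcript classes:
#' the mRNA-like class has the highest and broadest GC content and long
#' planted ORFs; the lncRNA-like class has the lowest, most concentrated GC
#' and no planted ORF; the circRNA-like class sits between them with a
#' bimodal (two-component) GC law. Each class additionally carries its own
#' k-mer motif enrichments so that composition separates the classes; the
#' 3-mer motifs come in GC-balanced pairs (one GC-rich, one AU-rich word at
#' equal enrichment) so that planting them leaves the class GC law intact.
#'
#' @return List of three [class_profile()] objects
#'   (circRNA_like, lncRNA_like, mRNA_like).
#' @export
default_profiles <- function() {
  list(
    class_profile("circRNA_like", gc_target = c(0.44, 0.52), gc_sd = 0.02,
                  orf_model = "short",
                  motif_biases = list(list(motif = "ACG", multiplier = 2),
                                      list(motif = "UUG", multiplier = 2),
                                      list(motif = "UUCGA", multiplier = 4))),
    class_profile("lncRNA_like", gc_target = 0.465, gc_sd = 0.025,
                  orf_model = "short",
                  motif_biases = list(list(motif = "AUA", multiplier = 2),
                                      list(motif = "GCG", multiplier = 2),
                                      list(motif = "GUUAG", multiplier = 4))),
    class_profile("mRNA_like", gc_target = 0.50, gc_sd = 0.06,
                  orf_model = "long",
                  motif_biases = list(list(motif = "GCC", multiplier = 2),
                                      list(motif = "UAU", multiplier = 2),
                                      list(motif = "GCCGC", multiplier = 4)))
  )
}

#' Profiles with complementary per-scale signals
#'
#' Three classes sharing one GC law, engineered so that class 1 and class 2
#' differ only through a 3-mer motif bias while class 2 and class 3 differ
#' only through 5-mer motif biases. No single k-mer scale carries the full
#' signal for all class pairs, which makes these profiles the fixture for
#' the scale-ablation experiment.
#'
#' @return List of three [class_profile()] objects.
#' @export
scale_split_profiles <- function() {
  m3 <- list(list(motif = "CGA", multiplier = 4),   # GC-balanced pair
             list(motif = "AGU", multiplier = 4))
  m5 <- list(list(motif = "GGAUC", multiplier = 5),
             list(motif = "CAUGG", multiplier = 5),
             list(motif = "UCCAG", multiplier = 5))
  list(
    class_profile("class1", gc_target = 0.48, gc_sd = 0.03,
                  orf_model = "short", motif_biases = list()),
    class_profile("class2", gc_target = 0.48, gc_sd = 0.03,
                  orf_model = "short", motif_biases = m3),
    class_profile("class3", gc_target = 0.48, gc_sd = 0.03,
                  orf_model = "short", motif_biases = c(m3, m5))
  )
}

#' Generator specification
#'
#' @param profiles list of [class_profile()] objects.
#' @param n_per_class records per class (>= 1).
#' @param seed master integer seed; each record derives its own substream
#'   from `(seed, class index, record index)`, so generation is
#'   order-independent.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(profiles = default_profiles(), n_per_class = 100L,
                           seed = 7L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L, n_per_class >= 1L)
  structure(list(profiles = profiles, n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# stop-free codon alphabet (indices 0..63 minus UAA/UAG/UGA), as base codes
nonstop_codons <- function() {
  all64 <- as.matrix(expand.grid(c3 = 0:3, c2 = 0:3, c1 = 0:3))[, 3:1]
  idx <- all64[, 1] * 16L + all64[, 2] * 4L + all64[, 3]
  all64[!idx %in% ORF_STOPS, , drop = FALSE]
}

# one synthetic record from its own RNG substream
generate_record <- function(profile, L, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G U
  code <- sample.int(4L, L, replace = TRUE, prob = p) - 1L

  for (mb in profile$motif_biases) {
    mcode <- kmer_codes(mb$motif)
    k <- length(mcode)
    if (L < k) stop("motif '", mb$motif, "' is longer than the sequence")
    p_motif <- prod(p[mcode + 1L])
    n_extra <- rpois(1L, (mb$multiplier - 1) * p_motif * (L - k + 1L))
    if (n_extra > 0L) {
      pos <- sample.int(L - k + 1L, min(n_extra, L - k + 1L))
      for (q in pos) code[q:(q + k - 1L)] <- mcode
    }
  }

  if (profile$orf_model == "long") {
    f <- runif(1L, 0.5, 0.9)
    n_codons <- max(2L, floor(f * L / 3))
    start <- sample.int(L - 3L * n_codons + 1L, 1L)
    body <- nonstop_codons()
    inner <- n_codons - 2L
    # codons drawn from the sequence's own base law (stops excluded), so
    # the planted ORF leaves the per-sequence GC distribution intact
    codon_p <- p[body[, 1] + 1L] * p[body[, 2] + 1L] * p[body[, 3] + 1L]
    orf <- c(c(0L, 3L, 2L),                                    # AUG
             if (inner > 0L) t(body[sample.int(nrow(body), inner,
                                               replace = TRUE,
                                               prob = codon_p), ]),
             c(3L, 0L, 0L))                                    # UAA
    code[start:(start + 3L * n_codons - 1L)] <- orf
  }
  paste(RNA_BASES[code + 1L], collapse = "")
}

#' Generate a labelled synthetic dataset
#'
#' Fully deterministic given `spec$seed`; per-record generation is keyed on
#' `(seed, class, record index)` so the same record is produced regardless
#' of generation order.
#'
#' @param spec a [generator_spec()].
#' @return A labelled [rna_set()] with ids `<class>_<index>`.
#' @export
generate_dataset <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  recs <- list()
  for (ci in seq_along(spec$profiles)) {
    profile <- spec$profiles[[ci]]
    for (ri in seq_len(spec$n_per_class)) {
      set.seed(mix_seed(spec$seed, ci, ri))
      L <- round(exp(runif(1L, log(profile$min_len), log(profile$max_len))))
      comp <- sample.int(length(profile$gc_target), 1L)
      gc <- rnorm(1L, profile$gc_target[comp], profile$gc_sd)
      gc <- min(max(gc, 0.05), 0.95)
      recs[[length(recs) + 1L]] <- list(
        id = sprintf("%s_%05d", profile$name, ri),
        sequence = generate_record(profile, L, gc),
        label = profile$name)
    }
  }
  rna_set(vapply(recs, `[[`, "", "id"),
          vapply(recs, `[[`, "", "sequence"),
          label = vapply(recs, `[[`, "", "label"),
          class_names = vapply(spec$profiles, `[[`, "", "name"))
}
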