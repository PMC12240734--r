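#' Standardized dinucleotide physicochemical property table (synthetic)
#'
#' Six structural step properties (Shift, Slide, Rise, Tilt, Roll, Twist)
#' for the 16 RNA dinucleotides, standardized per property to zero mean and
#' unit variance across the 16 dinucleotides. The raw values are a
#' *synthetic stand-in* with the magnitudes and qualitative ordering typical
#' of published A-form helix step-parameter tables; they are not a copy of
#' any specific published table. Because every covariance-type descriptor in
#' this package standardizes per property, only the relative values matter,
#' and all descriptor tests carry their own independent oracles computed
#' from this same fixture.
#'
#' @return A 16 x 6 numeric matrix; rownames are dinucleotides in
#'   lexicographic order (`AA` ... `UU`), colnames the property names.
#' @export
dinuc_property_table <- function() {
  raw <- cbind(
    Shift = c(-0.08, 0.23, -0.04, -0.06, 0.11, -0.01, 0.30, 0.23,
              0.07, 0.07, -0.01, 0.23, -0.02, 0.07, 0.11, -0.08),
    Slide = c(-1.27, -1.43, -1.50, -1.36, -1.46, -1.78, -1.89, -1.43,
              -1.70, -1.39, -1.78, -1.43, -1.45, -1.70, -1.46, -1.27),
    Rise  = c(3.18, 3.24, 3.30, 3.24, 3.09, 3.32, 3.30, 3.24,
              3.38, 3.22, 3.32, 3.24, 3.26, 3.38, 3.09, 3.18),
    Tilt  = c(-0.80, 0.80, 0.50, 1.10, 1.00, 0.30, -0.10, 0.80,
              1.30, 0.00, 0.30, 0.80, -0.40, 1.30, 1.00, -0.80),
    Roll  = c(7.0, 4.8, 8.5, 7.1, 9.9, 8.7, 12.1, 4.8,
              9.4, 6.1, 8.7, 4.8, 10.7, 9.4, 9.9, 7.0),
    Twist = c(31.0, 32.0, 30.0, 33.1, 31.0, 32.0, 27.0, 32.0,
              30.0, 31.0, 32.0, 32.0, 33.0, 30.0, 31.0, 31.0)
  )
  rownames(raw) <- kmer_names(2L)
  scale(raw)[, , drop = FALSE]
}
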