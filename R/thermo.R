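# Oligonucleotide thermodynamics: nearest-neighbor melting temperature
# (SantaLucia 1998 unified parameters, monovalent-salt entropy correction)
# plus the simple sequence summaries used by the primer filters.

# Unified nearest-neighbor parameters: dH kcal/mol, dS cal/(mol K).
# Keyed by the top-strand dinucleotide; complementary stacks share values.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.GAS_CONSTANT <- 1.987  # cal/(mol K)

# Character-level reverse complement; cheap enough for per-window use in
# the design scans (Biostrings object construction is too heavy there).
revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))
}

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Duplex Tm from the unified nearest-neighbor parameter set (SantaLucia,
#' PNAS 1998) with terminal A/T and G/C initiation terms, the symmetry
#' correction for self-complementary oligos, and the monovalent-salt entropy
#' correction `dS + 0.368 (N-1) ln[Na+]`. The concentration term uses
#' `CT/4` for two distinct strands at equal concentration and `CT/2` for a
#' self-complementary oligo, where `CT` is the total strand concentration.
#'
#' @param seq Fully specified DNA string, length >= 8 (no `N` or degenerate
#'   bases).
#' @param salt_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Total oligo strand concentration in nM (default 250).
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(seq, salt_mM = 50, oligo_nM = 250) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8L) stop(sprintf("sequence too short for NN Tm (%d < 8 nt)", n))
  if (grepl("[^ACGT]", seq)) {
    stop("Tm requires fully specified bases (A,C,G,T only)")
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  stacks <- paste0(bases[-n], bases[-1L])
  dh <- sum(.NN_DH[stacks])
  ds <- sum(.NN_DS[stacks])
  for (term in c(bases[[1L]], bases[[n]])) {
    if (term %in% c("A", "T")) {
      dh <- dh + 2.3; ds <- ds + 4.1
    } else {
      dh <- dh + 0.1; ds <- ds - 2.8
    }
  }
  selfcomp <- n %% 2L == 0L && identical(seq, revcomp_chr(seq))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1L) * log(salt_mM * 1e-3)
  ct <- oligo_nM * 1e-9
  k <- if (selfcomp) ct / 2 else ct / 4
  dh * 1000 / (ds + .GAS_CONSTANT * log(k)) - 273.15
}

#' GC content of a DNA string, in percent
#' @param seq DNA string.
#' @return Percentage of G/C bases.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  100 * lengths(regmatches(seq, gregexpr("[GC]", seq))) / n
}

#' Longest homopolymer run in a DNA string
#' @param seq DNA string.
#' @return Length of the longest run of one base.
#' @export
max_homopolymer_run <- function(seq) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  max(r$lengths)
}
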