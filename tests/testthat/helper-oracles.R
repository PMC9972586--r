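# Independent oracles and fixture builders shared across the suite.
# These deliberately use different code paths (plain character vectors,
# explicit loops) than the package implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# O(n*m) sliding-window exact-match starts (0-based), vectorized over
# offsets one pattern position at a time.
naive_sites <- function(query, template_chars) {
  qv <- strsplit(query, "", fixed = TRUE)[[1L]]
  L <- length(qv)
  n <- length(template_chars)
  if (n < L) return(integer())
  hits <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    hits <- hits & template_chars[k:(n - L + k)] == qv[k]
  }
  which(hits) - 1L
}

# Sliding-window in-silico PCR oracle mirroring the documented product
# rule: any oligo may prime either end, sites must be disjoint and
# convergent, product length = reverse-site end - forward-site start.
naive_ispcr <- function(fwd_seq, rev_seq, template, max_product_len = 2000L) {
  tc <- strsplit(template, "", fixed = TRUE)[[1L]]
  primers <- unique(c(fwd_seq, rev_seq))
  fwd_hits <- list()
  rev_hits <- list()
  for (p in primers) {
    for (s in naive_sites(p, tc)) {
      fwd_hits[[length(fwd_hits) + 1L]] <- c(start = s, len = nchar(p))
    }
    for (s in naive_sites(naive_revcomp(p), tc)) {
      rev_hits[[length(rev_hits) + 1L]] <- c(start = s, len = nchar(p))
    }
  }
  out <- list()
  for (f in fwd_hits) {
    for (r in rev_hits) {
      if (r[["start"]] < f[["start"]] + f[["len"]]) next
      len <- r[["start"]] + r[["len"]] - f[["start"]]
      if (len > max_product_len) next
      out[[length(out) + 1L]] <- c(start = f[["start"]],
                                   end = r[["start"]] + r[["len"]],
                                   length = len)
    }
  }
  if (length(out) == 0L) return(data.frame(start = integer(), end = integer(),
                                           length = integer()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start, df$end), , drop = FALSE]
}

# Brute-force nearest-neighbor Tm oracle: builds the duplex stack list
# explicitly and sums published unified parameters term by term.
oracle_tm <- function(seq, salt_mM, oligo_nM) {
  tab <- list(
    "AA/TT" = c(-7.9, -22.2), "AT/TA" = c(-7.2, -20.4),
    "TA/AT" = c(-7.2, -21.3), "CA/GT" = c(-8.5, -22.7),
    "GT/CA" = c(-8.4, -22.4), "CT/GA" = c(-7.8, -21.0),
    "GA/CT" = c(-8.2, -22.2), "CG/GC" = c(-10.6, -27.2),
    "GC/CG" = c(-9.8, -24.4), "GG/CC" = c(-8.0, -19.9))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(b) - 1L)) {
    x <- b[i]; y <- b[i + 1L]
    key <- paste0(x, y, "/", comp[x], comp[y])
    if (is.null(tab[[key]])) {
      # same stack read from the complementary strand
      key <- paste0(comp[y], comp[x], "/", y, x)
    }
    stopifnot(!is.null(tab[[key]]))
    dh <- dh + tab[[key]][1L]
    ds <- ds + tab[[key]][2L]
  }
  for (end in c(b[1L], b[length(b)])) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfcomp <- identical(seq, naive_revcomp(seq))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (length(b) - 1L) * log(salt_mM / 1000)
  conc <- oligo_nM * 1e-9 / (if (selfcomp) 2 else 4)
  dh * 1000 / (ds + 1.987 * log(conc)) - 273.15
}

# Gene model builder for hand-specified exon coordinates.
make_gene_model <- function(exons_start, exons_end, gene_id = "g",
                            chrom = "chr", strand = "+") {
  exons <- data.frame(start = exons_start, end = exons_end)
  n <- nrow(exons)
  introns <- if (n > 1L) data.frame(start = exons$end[-n], end = exons$start[-1L])
             else data.frame(start = integer(), end = integer())
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, introns = introns),
            class = "gene_model")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
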