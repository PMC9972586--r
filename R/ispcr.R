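# In-silico PCR: locate primer binding sites on a template, pair convergent
# sites within a product-length bound, and report predicted amplicons.
# On-target prediction demands perfect annealing; the cross-species
# specificity scan relaxes this to a bounded number of mismatches outside a
# perfect 3'-terminal seed, since polymerase extension is dominated by the
# 3' end of the primer.

# Perfect-match occurrences of `pattern` (0-based starts) on a template.
match_starts <- function(pattern, template_dna, max_mismatch = 0L) {
  m <- Biostrings::matchPattern(pattern, template_dna,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  BiocGenerics::start(m) - 1L
}

# Sites where `primer` can prime synthesis on `template`.
#  role = "forward": primer text matches the plus strand, extends rightward.
#  role = "reverse": reverse complement of the primer matches the plus
#  strand, extends leftward; the primer's 3' end maps to the match start.
# With mismatch tolerance, a site qualifies when total mismatches are at
# most `max_mismatch` AND the `seed_len` bases at the primer 3' end match
# perfectly.
priming_sites <- function(primer, template_dna, role,
                          max_mismatch = 0L, seed_len = 12L) {
  query <- if (role == "forward") primer else reverse_complement(primer)
  starts <- match_starts(query, template_dna, max_mismatch)
  if (max_mismatch == 0L || length(starts) == 0L) return(starts)
  L <- nchar(query)
  qv <- strsplit(query, "", fixed = TRUE)[[1L]]
  keep <- vapply(starts, function(s) {
    hit <- as.character(Biostrings::subseq(template_dna, s + 1L, s + L))
    mm <- which(strsplit(hit, "", fixed = TRUE)[[1L]] != qv)
    # primer 3'-terminal bases sit at the right end of a forward-role match
    # and at the left end of a reverse-role match
    seed <- if (role == "forward") (L - seed_len + 1L):L else 1L:seed_len
    !any(mm %in% seed)
  }, logical(1))
  starts[keep]
}

# Pair forward-role and reverse-role site tables into products.
pair_sites <- function(fwd, rev, template, max_product_len) {
  out <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      f_start <- fwd$start[i]; f_end <- f_start + fwd$len[i]
      r_start <- rev$start[j]; r_end <- r_start + rev$len[j]
      if (r_start < f_end) next            # sites must be disjoint, convergent
      len <- r_end - f_start               # forward 5' to reverse 5', inclusive
      if (len > max_product_len) next
      out[[length(out) + 1L]] <- list(
        start = f_start, end = r_end, length = len,
        forward_primer = fwd$primer[i], reverse_primer = rev$primer[j])
    }
  }
  out
}

#' Predict PCR products of a primer pair on a template
#'
#' Finds every perfect-match binding site of both oligos in both priming
#' orientations, pairs convergent non-overlapping sites, and keeps products
#' no longer than `max_product_len`. All four role combinations are
#' examined (either oligo may prime either end, including single-oligo
#' products). Product length is counted from the forward primer's 5' end to
#' the reverse primer's 5' end inclusive. Output is ordered by product
#' start, then end.
#'
#' @param pair A `primer_pair`, or any list with `forward_seq` and
#'   `reverse_seq`.
#' @param template A [genome_sequence()] or DNA string.
#' @param max_product_len Longest product reported (default 2000 nt, a
#'   generous bound for qPCR-scale amplicons).
#' @return List of amplicons: `start`, `end` (0-based half-open on the
#'   template plus strand), `length`, `sequence`, `forward_primer`,
#'   `reverse_primer`.
#' @export
insilico_pcr <- function(pair, template, max_product_len = 2000L) {
  seq <- if (inherits(template, "genome_sequence")) template$seq else toupper(template)
  dna <- Biostrings::DNAString(seq)
  primers <- unique(c(pair$forward_seq, pair$reverse_seq))
  site_tab <- function(role) {
    rows <- lapply(primers, function(p) {
      s <- priming_sites(p, dna, role)
      if (length(s)) data.frame(start = s, len = nchar(p), primer = p,
                                stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else
      data.frame(start = integer(), len = integer(), primer = character(),
                 stringsAsFactors = FALSE)
  }
  products <- pair_sites(site_tab("forward"), site_tab("reverse"),
                         seq, max_product_len)
  if (length(products)) {
    ord <- order(vapply(products, `[[`, numeric(1), "start"),
                 vapply(products, `[[`, numeric(1), "end"))
    products <- products[ord]
    products <- lapply(products, function(p) {
      p$sequence <- substr(seq, p$start + 1L, p$end)
      p
    })
  }
  products
}

#' Scan an off-target genome for cross-species amplification
#'
#' Runs the in-silico PCR search against the sibling genome under a relaxed
#' annealing model: a binding site tolerates up to `allowed_mismatches`
#' total mismatches but must match perfectly over the `seed_len` bases at
#' the primer's 3' end. The assay passes iff no productive convergent pair
#' exists within `max_product_len`.
#'
#' @param pair A `primer_pair`.
#' @param off_target_genome A [genome_sequence()] or DNA string for the
#'   other species.
#' @param max_product_len Longest off-target product considered (default
#'   2000 nt).
#' @param allowed_mismatches Mismatch budget outside the seed (default 2).
#' @param seed_len Perfect-match 3'-terminal seed length (default 12 nt).
#' @return A `specificity_report`: `off_target_products` (list as in
#'   [insilico_pcr()], without sequences), `verdict` (`"pass"`/`"fail"`),
#'   `notes`.
#' @export
cross_species_specificity <- function(pair, off_target_genome,
                                      max_product_len = 2000L,
                                      allowed_mismatches = 2L,
                                      seed_len = 12L) {
  seq <- if (inherits(off_target_genome, "genome_sequence"))
    off_target_genome$seq else toupper(off_target_genome)
  dna <- Biostrings::DNAString(seq)
  primers <- unique(c(pair$forward_seq, pair$reverse_seq))
  site_tab <- function(role) {
    rows <- lapply(primers, function(p) {
      s <- priming_sites(p, dna, role, max_mismatch = allowed_mismatches,
                         seed_len = seed_len)
      if (length(s)) data.frame(start = s, len = nchar(p), primer = p,
                                stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else
      data.frame(start = integer(), len = integer(), primer = character(),
                 stringsAsFactors = FALSE)
  }
  products <- pair_sites(site_tab("forward"), site_tab("reverse"),
                         seq, max_product_len)
  verdict <- if (length(products) == 0L) "pass" else "fail"
  notes <- sprintf(
    "relaxed annealing: <=%d mismatches outside a perfect %d nt 3' seed; %d off-target product(s)",
    allowed_mismatches, seed_len, length(products))
  structure(list(off_target_products = products, verdict = verdict,
                 notes = notes),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity_report> %s (%d off-target products)\n",
              x$verdict, length(x$off_target_products)))
  invisible(x)
}
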