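# Genome and annotation input: FASTA records, GFF3 exon features, gene
# models with derived introns, and strand-aware subsequence extraction.
#
# Internal coordinates are 0-based half-open [start, end); GFF3 (1-based
# inclusive) is converted at the I/O boundary and nowhere else.

#' Construct a genome sequence record
#'
#' @param id Non-empty sequence identifier.
#' @param seq DNA string over the alphabet `{A,C,G,T,N}` (case-insensitive on
#'   input; stored uppercase).
#' @return An object of class `genome_sequence` with fields `id`, `seq`,
#'   `length`.
#' @export
genome_sequence <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("genome sequence id must be a non-empty string")
  }
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    ch <- substr(seq, bad, bad)
    if (ch == "U") {
      stop(sprintf("RNA base 'U' at position %d in record '%s': DNA input required", bad, id))
    }
    stop(sprintf("invalid base '%s' at position %d in record '%s' (allowed: A,C,G,T,N)", ch, bad, id))
  }
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Read a FASTA file into genome sequence records
#'
#' Sequences are uppercased; only `A,C,G,T,N` are accepted (`U` is rejected
#' with a pointer to DNA input). Record ids are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return Named list of [genome_sequence()] records in file order.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("FASTA format error in %s: %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("FASTA format error in %s: no records", path))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate FASTA id: '%s'", dup[[1L]]))
  recs <- lapply(seq_along(set), function(i) {
    genome_sequence(ids[[i]], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Read GFF3 features of one type
#'
#' Coordinates are converted from GFF3 1-based inclusive to internal 0-based
#' half-open on read. The grouping key is taken from the `Parent` attribute,
#' falling back to `gene_id`; a `gene_id` attribute, when present, is carried
#' alongside for gene-level selection.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (column 3) to keep, default `"exon"`.
#' @return A data.frame with columns `seqid`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, `group`, `gene`, `line`.
#' @export
parse_gff3 <- function(path, feature_type = "exon") {
  if (!file.exists(path)) stop(sprintf("GFF3 file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- list()
  for (ln in keep) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 9L) {
      stop(sprintf("GFF3 line %d: expected 9 tab-separated columns, got %d", ln, length(fields)))
    }
    if (fields[[3L]] != feature_type) next
    start1 <- suppressWarnings(as.integer(fields[[4L]]))
    end1 <- suppressWarnings(as.integer(fields[[5L]]))
    if (is.na(start1) || is.na(end1)) {
      stop(sprintf("GFF3 line %d: non-numeric coordinates", ln))
    }
    if (end1 < start1) {
      stop(sprintf("GFF3 line %d: end (%d) < start (%d)", ln, end1, start1))
    }
    attrs <- gff3_attributes(fields[[9L]])
    group <- attrs[["Parent"]]
    if (is.null(group)) group <- attrs[["gene_id"]]
    if (is.null(group)) {
      stop(sprintf("GFF3 line %d: no Parent or gene_id attribute to group by", ln))
    }
    gene <- attrs[["gene_id"]]
    if (is.null(gene)) gene <- NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = fields[[1L]], type = fields[[3L]],
      start = start1 - 1L, end = end1,
      strand = fields[[7L]], group = group, gene = gene, line = ln,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), group = character(),
                      gene = character(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

gff3_attributes <- function(field9) {
  parts <- strsplit(field9, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) >= 2L) utils::URLdecode(paste(p[-1L], collapse = "=")) else NA_character_)
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

#' Assemble gene models from grouped exon features
#'
#' Exons in each group are sorted by start and must be pairwise disjoint and
#' on one chromosome and strand. Introns are derived as the gaps
#' `[prev_end, next_start)` between consecutive exons, so a gene with `n`
#' exons has `n - 1` introns that exactly tile the space between them.
#'
#' @param features Data.frame as returned by [parse_gff3()].
#' @return Named list of `gene_model` objects (one per group), each with
#'   fields `gene_id`, `chrom`, `strand`, `exons`, `introns` (data.frames
#'   with `start`, `end`, 0-based half-open).
#' @export
build_gene_models <- function(features) {
  if (nrow(features) == 0L) return(list())
  groups <- split(features, features$group)
  models <- lapply(names(groups), function(g) {
    f <- groups[[g]]
    if (length(unique(f$seqid)) != 1L) {
      stop(sprintf("group '%s': exons on multiple chromosomes", g))
    }
    if (length(unique(f$strand)) != 1L) {
      stop(sprintf("group '%s': exons on mixed strands", g))
    }
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)])) {
      stop(sprintf("group '%s': overlapping exons", g))
    }
    exons <- data.frame(start = f$start, end = f$end)
    introns <- if (nrow(f) > 1L) {
      data.frame(start = f$end[-nrow(f)], end = f$start[-1L])
    } else {
      data.frame(start = integer(), end = integer())
    }
    structure(list(gene_id = g, chrom = f$seqid[[1L]], strand = f$strand[[1L]],
                   exons = exons, introns = introns),
              class = "gene_model")
  })
  names(models) <- names(groups)
  models
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s(%s): %d exons, %d introns\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Load one gene model from FASTA + GFF3
#'
#' Convenience wrapper: reads exon features, restricts to those whose
#' `gene_id` (or grouping key) matches `gene_id`, and when several
#' transcripts remain picks the one with the most exons (ties broken by
#' transcript id) unless `transcript_id` is given.
#'
#' @param gff_path GFF3 annotation path.
#' @param gene_id Gene identifier to select.
#' @param transcript_id Optional explicit transcript (grouping key).
#' @return A `gene_model`.
#' @export
load_gene_model <- function(gff_path, gene_id, transcript_id = NULL) {
  feats <- parse_gff3(gff_path)
  sel <- feats[(!is.na(feats$gene) & feats$gene == gene_id) | feats$group == gene_id, ,
               drop = FALSE]
  if (nrow(sel) == 0L) {
    avail <- sort(unique(c(feats$gene[!is.na(feats$gene)], feats$group)))
    stop(sprintf("gene '%s' not found in %s; available: %s",
                 gene_id, gff_path, paste(avail, collapse = ", ")))
  }
  models <- build_gene_models(sel)
  if (!is.null(transcript_id)) {
    if (is.null(models[[transcript_id]])) {
      stop(sprintf("transcript '%s' not found for gene '%s'", transcript_id, gene_id))
    }
    return(models[[transcript_id]])
  }
  n_ex <- vapply(models, function(m) nrow(m$exons), integer(1))
  m <- models[[order(-n_ex, names(models))[[1L]]]]
  m$gene_id <- gene_id
  m
}

#' Extract the sequence of an interval, strand-aware
#'
#' @param genome A [genome_sequence()].
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"` for the forward strand, `"-"` for the reverse
#'   complement of that substring.
#' @return DNA string.
#' @export
extract_interval_sequence <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_sequence"))
  if (start < 0L || end > genome$length || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for '%s' (length %d)",
                 start, end, genome$id, genome$length))
  }
  s <- substr(genome$seq, start + 1L, end)
  if (strand == "-") reverse_complement(s) else s
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`.
#'
#' @param seq DNA string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
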