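#' Genome database: scaffolds decomposed into contigs
#'
#' A `GenomeDB` holds a genome as an ordered set of scaffolds, each split
#' into contigs at runs of Ns.  Contig sequences are stored 2 bits per base;
#' N-runs are recorded only by their lengths so that scaffold coordinates
#' can be reconstructed, and are never indexed or aligned through.
#' Lower-case (soft-masked) stretches are recorded as mask intervals but are
#' not used by the seeder.
#'
#' @param path path to a FASTA or gzip-compressed FASTA file with sequences
#'   over `{A,C,G,T,N}`, case-insensitive.
#' @param min_gap minimum N-run length treated as an inter-contig gap.
#'   Contigs hold pure 2-bit DNA, so every N-run splits; runs shorter than
#'   `min_gap` also split but provoke a warning.  Default 1 (any N splits).
#' @return an object of class `GenomeDB` with components `scaffolds`
#'   (data.frame: `name`, `length`), `contigs` (data.frame: `scaffold`,
#'   `ordinal`, `offset`, `length`), `seq` (list of packed raw vectors),
#'   `mask` (list of 0-based half-open soft-mask intervals) and `gaps`
#'   (per-scaffold N-run lengths, in order).
#' @details Coordinates are 0-based and half-open throughout: position *i*
#'   is the boundary between characters *i* and *i+1*, so the substring
#'   `A[i,j]` has length `j - i`.
#' @seealso [gdb_to_fasta()], [build_index()]
#' @export
fasta_to_gdb <- function(path, min_gap = 1L) {
  fa <- read_fasta(path)
  if (length(fa) == 0L)
    stop("no sequences found in '", path, "'")
  gdb_from_sequences(fa, min_gap = min_gap)
}

#' Build a GenomeDB from in-memory sequences
#'
#' Same decomposition as [fasta_to_gdb()] but from a named character vector
#' of scaffold sequences (useful for simulations and tests).
#'
#' @param seqs named character vector over `{A,C,G,T,N}`,
#'   case-insensitive.
#' @inheritParams fasta_to_gdb
#' @return a `GenomeDB`.
#' @export
gdb_from_sequences <- function(seqs, min_gap = 1L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  scafs <- data.frame(name = names(seqs), length = unname(nchar(seqs)),
                      row.names = NULL, stringsAsFactors = FALSE)
  contigs <- list()
  seqraw <- list()
  masks <- list()
  gaps <- vector("list", length(seqs))
  short_run <- FALSE
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    bad <- regexpr("[^ACGTNacgtn]", s)
    if (bad > 0L)
      stop("non-IUPAC character '", substr(s, bad, bad), "' in scaffold '",
           scafs$name[si], "' at offset ", bad - 1L)
    runs <- gregexpr("[Nn]+", s)[[1L]]
    if (runs[1L] == -1L) {
      rstart <- integer(0); rlen <- integer(0)
    } else {
      rstart <- as.integer(runs)
      rlen <- attr(runs, "match.length")
      if (any(rlen < min_gap)) short_run <- TRUE
    }
    gaps[[si]] <- rlen
    # contig intervals between N-runs (1-based closed for substr)
    cstart <- c(1L, rstart + rlen)
    cend <- c(rstart - 1L, nchar(s))
    keep <- cend >= cstart
    cstart <- cstart[keep]; cend <- cend[keep]
    for (ci in seq_along(cstart)) {
      sub <- substr(s, cstart[ci], cend[ci])
      mr <- gregexpr("[acgt]+", sub)[[1L]]
      if (mr[1L] == -1L) {
        mint <- matrix(integer(0), ncol = 2L)
      } else {
        mint <- cbind(as.integer(mr) - 1L,
                      as.integer(mr) - 1L + attr(mr, "match.length"))
      }
      contigs[[length(contigs) + 1L]] <-
        data.frame(scaffold = si, ordinal = ci, offset = cstart[ci] - 1L,
                   length = cend[ci] - cstart[ci] + 1L)
      seqraw[[length(seqraw) + 1L]] <- dna_pack(sub)
      masks[[length(masks) + 1L]] <- mint
    }
  }
  if (short_run)
    warning("N-run(s) shorter than min_gap = ", min_gap,
            " also split contigs (contigs hold pure 2-bit DNA)")
  ctab <- if (length(contigs)) do.call(rbind, contigs) else
    data.frame(scaffold = integer(0), ordinal = integer(0),
               offset = integer(0), length = integer(0))
  structure(list(scaffolds = scafs, contigs = ctab, seq = seqraw,
                 mask = masks, gaps = gaps),
            class = "GenomeDB")
}

#' @export
print.GenomeDB <- function(x, ...) {
  cat("GenomeDB:", nrow(x$scaffolds), "scaffold(s),",
      nrow(x$contigs), "contig(s),",
      format(total_contig_bases(x), big.mark = ","), "contig bases\n")
  invisible(x)
}

#' Total number of contig bases in a GenomeDB
#' @param gdb a [fasta_to_gdb()] object.
#' @return integer sum of contig lengths (excludes N gaps).
#' @export
total_contig_bases <- function(gdb) sum(gdb$contigs$length)

#' Extract a contig sequence
#' @param gdb a `GenomeDB`.
#' @param i global contig number (row of `gdb$contigs`).
#' @return the contig DNA string, lower case.
#' @export
contig_seq <- function(gdb, i) {
  dna_unpack(gdb$seq[[i]], gdb$contigs$length[i])
}

#' Write a GenomeDB back to FASTA
#'
#' Reconstructs each scaffold (contigs re-interleaved with their N-runs,
#' soft-masked stretches in lower case, everything else upper case) and
#' returns or writes FASTA text.  Round-trips [fasta_to_gdb()] up to the
#' case of N-runs.
#'
#' @param gdb a `GenomeDB`.
#' @param path output file, or `NULL` to return the lines.
#' @param width line width for sequence wrapping.
#' @return invisibly, the FASTA lines.
#' @export
gdb_to_fasta <- function(gdb, path = NULL, width = 80L) {
  lines <- character(0)
  for (si in seq_len(nrow(gdb$scaffolds))) {
    rows <- which(gdb$contigs$scaffold == si)
    glen <- gdb$gaps[[si]]
    parts <- character(0)
    gi <- 1L
    pos <- 0L
    # leading gap(s)
    emit_gaps_until <- function(limit) {
      while (gi <= length(glen) && pos < limit) {
        parts[[length(parts) + 1L]] <<- strrep("N", glen[gi])
        pos <<- pos + glen[gi]
        gi <<- gi + 1L
      }
    }
    for (ci in rows) {
      emit_gaps_until(gdb$contigs$offset[ci])
      sq <- toupper(contig_seq(gdb, ci))
      m <- gdb$mask[[ci]]
      if (nrow(m)) {
        ch <- strsplit(sq, "")[[1L]]
        for (r in seq_len(nrow(m))) {
          idx <- (m[r, 1L] + 1L):m[r, 2L]
          ch[idx] <- tolower(ch[idx])
        }
        sq <- paste(ch, collapse = "")
      }
      parts[[length(parts) + 1L]] <- sq
      pos <- pos + nchar(sq)
    }
    emit_gaps_until(gdb$scaffolds$length[si])
    full <- paste(parts, collapse = "")
    lines <- c(lines, paste0(">", gdb$scaffolds$name[si]),
               substring(full, seq(1L, max(nchar(full), 1L), width),
                         pmin(seq(1L, max(nchar(full), 1L), width) +
                                width - 1L, nchar(full))))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# internal FASTA reader (plain or gzip); returns named character vector
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (no leading '>'): ", path)
  id <- cumsum(hdr)
  names_all <- sub("^>\\s*", "", lines[hdr])
  names_all <- sub("\\s.*$", "", names_all)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # records with no sequence lines
  out <- character(length(names_all))
  names(out) <- names_all
  out[as.integer(names(seqs))] <- seqs
  out
}
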