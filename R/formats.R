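# scaffold-coordinate view of an alignment list
# (reverse-strand B intervals are mapped to forward coordinates here)
alignment_table <- function(alignments, gdbG, gdbH) {
  n <- length(alignments)
  get <- function(f, what = integer(1)) vapply(alignments, `[[`, what, f)
  cg <- get("contig_g"); ch <- get("contig_h")
  st <- get("strand", character(1))
  ab <- get("ab"); ae <- get("ae"); bb <- get("bb"); be <- get("be")
  diffs <- get("diffs")
  sg <- gdbG$contigs$scaffold[cg]
  sh <- gdbH$contigs$scaffold[ch]
  offg <- gdbG$contigs$offset[cg]
  offh <- gdbH$contigs$offset[ch]
  clen_h <- gdbH$contigs$length[ch]
  tb <- ifelse(st == "+", bb, clen_h - be)
  te <- ifelse(st == "+", be, clen_h - bb)
  data.frame(
    qname = gdbG$scaffolds$name[sg], qlen = gdbG$scaffolds$length[sg],
    qstart = offg + ab, qend = offg + ae, strand = st,
    tname = gdbH$scaffolds$name[sh], tlen = gdbH$scaffolds$length[sh],
    tstart = offh + tb, tend = offh + te, diffs = diffs,
    contig_g = cg, contig_h = ch, stringsAsFactors = FALSE)
}

# decoded (possibly refined) path of one alignment; B is in strand frame
alignment_path <- function(aln, gdbG, gdbH, refine = TRUE, R = 50L) {
  A <- cpp_seq_to_codes(contig_seq(gdbG, aln$contig_g))
  Bs <- contig_seq(gdbH, aln$contig_h)
  if (aln$strand == "-") Bs <- reverse_complement(Bs)
  B <- cpp_seq_to_codes(Bs)
  if (!is.null(aln$tracepoints)) {
    dec <- decode_tracepoints(aln$tracepoints, aln$ab, aln$ae, aln$bb,
                              aln$be, A, B)
    ops <- dec$ops
  } else if (!is.null(aln$ops)) {
    ops <- aln$ops
  } else {
    stop("alignment carries neither trace points nor a path")
  }
  if (refine) {
    rf <- refine_path(ops, A, B, aln$ab, aln$bb, R = R)
    ops <- rf$ops
  }
  list(ops = ops, A = A, B = B)
}

#' Write alignments as PAF
#'
#' Emits the 12 mandatory PAF columns (query = first genome, coordinates on
#' scaffolds, 0-based half-open; reverse-strand target intervals in forward
#' coordinates) plus `NM:i` and optionally a `cg:Z` CIGAR tag.  Paths are
#' reconstructed from the trace-point encoding and, by default, gap-refined
#' before CIGAR conversion.  The mapping-quality column is 255
#' (unavailable).
#'
#' @param alignments list of `Alignment` objects from [align_genomes()].
#' @param gdbG,gdbH the two `GenomeDB`s.
#' @param file output path or connection; `NULL` returns the lines.
#' @param cigar `"=X"` (default), `"M"`, or `"none"`.
#' @param refine gap-refine paths before output (default `TRUE`).
#' @return invisibly (or visibly for `file = NULL`) the PAF lines.
#' @export
write_paf <- function(alignments, gdbG, gdbH, file = NULL,
                      cigar = c("=X", "M", "none"), refine = TRUE) {
  cigar <- match.arg(cigar)
  if (!length(alignments)) {
    if (!is.null(file)) writeLines(character(0), file)
    return(invisible(character(0)))
  }
  tab <- alignment_table(alignments, gdbG, gdbH)
  lines <- character(length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    pth <- alignment_path(aln, gdbG, gdbH, refine = refine)
    ops <- pth$ops
    ia <- aln$ab + cumsum(ops != OP_INSB)
    jb <- aln$bb + cumsum(ops != OP_DELB)
    dg <- ops == OP_DIAG
    matches <- sum(pth$A[ia[dg]] == pth$B[jb[dg]])
    blocklen <- length(ops)
    flds <- c(tab$qname[i], tab$qlen[i], tab$qstart[i], tab$qend[i],
              tab$strand[i], tab$tname[i], tab$tlen[i], tab$tstart[i],
              tab$tend[i], matches, blocklen, 255L,
              paste0("NM:i:", sum(!dg) + sum(pth$A[ia[dg]] != pth$B[jb[dg]])))
    if (cigar != "none") {
      cg <- alignment_to_cigar(ops, pth$A, pth$B, aln$ab, aln$bb,
                               dialect = cigar)
      if (tab$strand[i] == "-" && cigar != "none") {
        # PAF convention: CIGAR is given in the forward orientation of the
        # query against the reverse-complemented target; our path is
        # already in that frame
      }
      flds <- c(flds, paste0("cg:Z:", cg))
    }
    lines[i] <- paste(flds, collapse = "\t")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a PAF file into a data.frame
#'
#' Parses the 12 mandatory columns (and keeps any tags in `tags`).
#'
#' @param file path or connection, or a character vector of PAF lines via
#'   `text`.
#' @param text optional character vector of lines.
#' @return data.frame with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, matches, blocklen, mapq, tags`.
#' @export
read_paf <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  if (!length(lines))
    return(data.frame(qname = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), tname = character(0),
                      tlen = integer(0), tstart = integer(0),
                      tend = integer(0), matches = integer(0),
                      blocklen = integer(0), mapq = integer(0),
                      tags = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gf <- function(k) vapply(parts, `[[`, character(1), k)
  data.frame(qname = gf(1), qlen = as.integer(gf(2)),
             qstart = as.integer(gf(3)), qend = as.integer(gf(4)),
             strand = gf(5), tname = gf(6), tlen = as.integer(gf(7)),
             tstart = as.integer(gf(8)), tend = as.integer(gf(9)),
             matches = as.integer(gf(10)), blocklen = as.integer(gf(11)),
             mapq = as.integer(gf(12)),
             tags = vapply(parts, function(p)
               paste(p[-(1:12)], collapse = "\t"), character(1)),
             stringsAsFactors = FALSE)
}

#' Write alignments as PSL
#'
#' Emits the 21-column PSL format.  Blocks are the gap-free segments of the
#' (refined) path.  For reverse-strand alignments the query block starts
#' follow the PSL convention of coordinates on the reverse-complemented
#' query, with the target kept forward.
#'
#' @inheritParams write_paf
#' @return invisibly (or visibly for `file = NULL`) the PSL lines.
#' @export
write_psl <- function(alignments, gdbG, gdbH, file = NULL, refine = TRUE) {
  if (!length(alignments)) {
    if (!is.null(file)) writeLines(character(0), file)
    return(invisible(character(0)))
  }
  tab <- alignment_table(alignments, gdbG, gdbH)
  lines <- character(length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    pth <- alignment_path(aln, gdbG, gdbH, refine = refine)
    ops <- pth$ops
    ia <- aln$ab + cumsum(ops != OP_INSB)
    jb <- aln$bb + cumsum(ops != OP_DELB)
    dg <- ops == OP_DIAG
    matches <- sum(pth$A[ia[dg]] == pth$B[jb[dg]])
    mism <- sum(dg) - matches
    r <- rle(ops)
    qnum <- sum(r$values == OP_DELB)   # gaps consuming query only
    qbase <- sum(r$lengths[r$values == OP_DELB])
    tnum <- sum(r$values == OP_INSB)
    tbase <- sum(r$lengths[r$values == OP_INSB])
    # gap-free blocks (maximal diagonal runs), contig coordinates
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    bi <- which(r$values == OP_DIAG)
    blk_len <- r$lengths[bi]
    ia0 <- c(aln$ab, aln$ab + cumsum(ops != OP_INSB))
    jb0 <- c(aln$bb, aln$bb + cumsum(ops != OP_DELB))
    blk_q <- ia0[starts[bi] + 1L]      # contig-G coordinates
    blk_t <- jb0[starts[bi] + 1L]      # strand-frame contig-H coordinates
    offg <- gdbG$contigs$offset[aln$contig_g]
    offh <- gdbH$contigs$offset[aln$contig_h]
    clen_h <- gdbH$contigs$length[aln$contig_h]
    if (tab$strand[i] == "+") {
      qstarts <- offg + blk_q
      tstarts <- offh + blk_t
    } else {
      # query starts in reverse-complement coordinates; target forward:
      # reverse the block order so target starts increase
      ordb <- rev(seq_along(bi))
      qstarts <- (tab$qlen[i] - (offg + blk_q + blk_len))[ordb]
      tstarts <- (offh + clen_h - (blk_t + blk_len))[ordb]
      blk_len <- blk_len[ordb]
    }
    lines[i] <- paste(c(matches, mism, 0L, 0L, qnum, qbase, tnum, tbase,
                        tab$strand[i], tab$qname[i], tab$qlen[i],
                        tab$qstart[i], tab$qend[i], tab$tname[i],
                        tab$tlen[i], tab$tstart[i], tab$tend[i],
                        length(bi),
                        paste0(paste(blk_len, collapse = ","), ","),
                        paste0(paste(qstarts, collapse = ","), ","),
                        paste0(paste(tstarts, collapse = ","), ",")),
                      collapse = "\t")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write and read an ALN document
#'
#' Alignments with their trace-point arrays are stored as an ASCII
#' ONEcode-style document: strongly typed lines, each led by a one-letter
#' code declared in the header schema, with provenance, per-type count and
#' maximum-size lines, and a global trace spacing.  Trace-point lists are
#' stored as their first value followed by forward differences.  The
#' document round-trips losslessly through `read_aln()`.
#'
#' @param alignments list of `Alignment` objects carrying trace points.
#' @param path file path.
#' @param meta optional named character vector added as provenance lines.
#' @return `write_aln()`: invisibly `path`; `read_aln()`: a list of
#'   `Alignment` objects (endpoints, strand, diffs, trace points).
#' @export
write_aln <- function(alignments, path, meta = NULL) {
  tps <- lapply(alignments, `[[`, "tracepoints")
  if (any(vapply(tps, is.null, logical(1))))
    stop("all alignments must carry trace-point arrays")
  deltas <- unique(vapply(tps, `[[`, integer(1), "delta"))
  if (length(deltas) > 1L)
    stop("trace spacing differs across records: ",
         paste(deltas, collapse = ", "))
  delta <- if (length(deltas)) deltas else 100L
  n <- length(alignments)
  maxt <- if (n) max(vapply(tps, function(t) length(t$b), integer(1))) else 0L
  hdr <- c("1 aln 1 0",
           paste("!", "adaptalign",
                 as.character(utils::packageVersion("adaptalign"))),
           if (!is.null(meta)) paste("!", names(meta), meta),
           "~ d 1 INT",
           "~ A 7 INT INT CHAR INT INT INT INT",
           "~ D 1 INT",
           "~ T 1 INT_LIST",
           paste("# A", n), paste("# D", n), paste("# T", n),
           paste("@ T", maxt),
           paste("d", delta))
  body <- character(0)
  if (n) {
    body <- unlist(lapply(alignments, function(a) {
      b <- a$tracepoints$b
      tline <- if (length(b)) paste(length(b), b[1L],
                                    paste(diff(b), collapse = " "))
               else "0"
      c(paste("A", a$contig_g, a$contig_h,
              if (a$strand == "+") "+" else "-",
              a$ab, a$ae, a$bb, a$be),
        paste("D", a$diffs),
        paste("T", trimws(tline)))
    }))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_aln
#' @export
read_aln <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^1 aln", lines[1L]))
    stop("not an ALN document: ", path)
  code <- sub("^(.).*$", "\\1", lines)
  schema <- sub("^~ ", "", lines[code == "~"])
  declared <- substr(schema, 1L, 1L)
  counts <- lines[code == "#"]
  delta <- as.integer(sub("^d ", "", lines[code == "d"][1L]))
  arec <- lines[code == "A"]
  drec <- lines[code == "D" & !grepl("^D ?$", lines) ]
  trec <- lines[code == "T"]
  used <- unique(code[!(code %in% c("1", "!", "~", "#", "@"))])
  if (!all(used %in% declared))
    stop("undeclared line code(s): ",
         paste(setdiff(used, declared), collapse = ", "))
  n <- length(arec)
  ndecl <- as.integer(sub("^# A ", "", counts[grepl("^# A ", counts)]))
  if (length(ndecl) && ndecl != n)
    stop("header count does not match records")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    af <- strsplit(arec[i], " ", fixed = TRUE)[[1L]]
    dv <- as.integer(sub("^D ", "", drec[i]))
    tf <- as.integer(strsplit(sub("^T ", "", trec[i]), " ",
                              fixed = TRUE)[[1L]])
    nb <- tf[1L]
    b <- if (nb > 0L) cumsum(c(tf[2L], tf[seq2(3L, nb + 1L)])) else integer(0)
    tp <- structure(list(delta = delta, b = as.integer(b)),
                    class = "TracePointArray")
    out[[i]] <- new_alignment(as.integer(af[2L]), as.integer(af[3L]),
                              af[4L], as.integer(af[5L]),
                              as.integer(af[6L]), as.integer(af[7L]),
                              as.integer(af[8L]), dv, tracepoints = tp)
  }
  out
}

#' Persist and restore a GenomeDB
#'
#' The genome database is stored as an ONEcode-style ASCII document
#' (scaffolds, contigs, gap lengths, soft-mask intervals) plus a packed
#' 2-bit sequence sidecar file `<path>.seq`.
#'
#' @param gdb a `GenomeDB`.
#' @param path main document path (sidecar written next to it).
#' @return `write_gdb()`: invisibly `path`; `read_gdb()`: the `GenomeDB`.
#' @export
write_gdb <- function(gdb, path) {
  nsc <- nrow(gdb$scaffolds)
  nct <- nrow(gdb$contigs)
  hdr <- c("1 gdb 1 0",
           paste("!", "adaptalign",
                 as.character(utils::packageVersion("adaptalign"))),
           "~ S 2 STRING INT",
           "~ C 4 INT INT INT INT",
           "~ G 1 INT_LIST",
           "~ M 1 INT_LIST",
           paste("# S", nsc), paste("# C", nct))
  slines <- paste("S", gdb$scaffolds$name, gdb$scaffolds$length)
  clines <- paste("C", gdb$contigs$scaffold, gdb$contigs$ordinal,
                  gdb$contigs$offset, gdb$contigs$length)
  glines <- vapply(seq_len(nsc), function(si)
    trimws(paste("G", length(gdb$gaps[[si]]),
                 paste(gdb$gaps[[si]], collapse = " "))), character(1))
  mlines <- vapply(seq_len(nct), function(ci) {
    m <- gdb$mask[[ci]]
    trimws(paste("M", nrow(m), paste(t(m), collapse = " ")))
  }, character(1))
  writeLines(c(hdr, slines, clines, glines, mlines), path)
  con <- file(paste0(path, ".seq"), "wb")
  on.exit(close(con))
  for (ci in seq_len(nct)) writeBin(gdb$seq[[ci]], con)
  invisible(path)
}

#' @rdname write_gdb
#' @export
read_gdb <- function(path) {
  lines <- readLines(path)
  code <- substr(lines, 1L, 1L)
  sl <- strsplit(lines[code == "S"], " ", fixed = TRUE)
  scafs <- data.frame(name = vapply(sl, `[[`, character(1), 2L),
                      length = as.integer(vapply(sl, `[[`, character(1),
                                                 3L)),
                      stringsAsFactors = FALSE)
  cl <- lines[code == "C"]
  cm <- matrix(scan(text = sub("^C ", "", cl), quiet = TRUE), ncol = 4L,
               byrow = TRUE)
  contigs <- data.frame(scaffold = as.integer(cm[, 1L]),
                        ordinal = as.integer(cm[, 2L]),
                        offset = as.integer(cm[, 3L]),
                        length = as.integer(cm[, 4L]))
  gl <- lines[code == "G"]
  gaps <- lapply(gl, function(x) {
    v <- as.integer(strsplit(sub("^G ", "", x), " ")[[1L]])
    if (v[1L] == 0L) integer(0) else v[-1L]
  })
  ml <- lines[code == "M"]
  masks <- lapply(ml, function(x) {
    v <- as.integer(strsplit(sub("^M ", "", x), " ")[[1L]])
    if (v[1L] == 0L) matrix(integer(0), ncol = 2L)
    else matrix(v[-1L], ncol = 2L, byrow = TRUE)
  })
  con <- file(paste0(path, ".seq"), "rb")
  on.exit(close(con))
  seqs <- vector("list", nrow(contigs))
  for (ci in seq_len(nrow(contigs))) {
    nb <- as.integer(ceiling(contigs$length[ci] / 4))
    seqs[[ci]] <- readBin(con, "raw", nb)
  }
  structure(list(scaffolds = scafs, contigs = contigs, seq = seqs,
                 mask = masks, gaps = gaps),
            class = "GenomeDB")
}
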