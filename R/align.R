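# Minimal ungapped read placement with a mismatch bound.
#
# A read is assigned the unique position minimising its Hamming distance to
# the reference, provided that distance is at most `max_mismatch`
# (default 2); reads whose minimum is tied between two or more positions, or
# exceeds the bound, are left unplaced.  Candidate positions are enumerated
# by the pigeonhole principle: with at most 2 mismatches, at least one of
# three disjoint read segments must match the reference exactly, so exact
# multi-pattern matching of the segments recovers every admissible position.

#' Place reads on a reference by unique minimum-mismatch ungapped alignment
#'
#' @param reads Data frame with columns `id`, `seq` (and optionally `qual`),
#'   e.g. from [read_fastq()] after [qc_filter()].
#' @param reference Named [Biostrings::DNAStringSet] (or FASTA path).
#' @param max_mismatch Maximum Hamming distance for a placement (N bases in a
#'   read always count as mismatches).
#' @return Data frame with one row per read: `id`, `contig`, `start`
#'   (1-based) and `mismatches`; unplaced reads carry `NA` in all three.
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGGTTAACCGGATCGATCG"))
#' place_reads(data.frame(id = "r1", seq = "GGTTAACC"), ref)
place_reads <- function(reads, reference, max_mismatch = 2L) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (length(reference) == 0L || sum(Biostrings::width(reference)) == 0L)
    stop("reference is empty")
  if (is.null(names(reference)))
    names(reference) <- paste0("contig", seq_along(reference))
  n <- nrow(reads)
  res <- data.frame(id = reads$id, contig = NA_character_,
                    start = NA_integer_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)

  seqs <- toupper(reads$seq)
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  widths <- nchar(seqs)

  for (w in unique(widths)) {
    grp <- which(widths == w & n_count <= max_mismatch)
    if (!length(grp)) next
    clean <- grp[n_count[grp] == 0L]
    fuzzy <- setdiff(grp, clean)

    placed <- .place_group(seqs[clean], w, reference, max_mismatch)
    res$contig[clean] <- placed$contig
    res$start[clean] <- placed$start
    res$mismatches[clean] <- placed$mismatches

    # reads containing N cannot enter the exact-match dictionaries; scan them
    # individually (they are few after QC)
    for (i in fuzzy) {
      hit <- .place_single(seqs[i], reference, max_mismatch)
      res$contig[i] <- hit$contig
      res$start[i] <- hit$start
      res$mismatches[i] <- hit$mismatches
    }
  }
  res
}

# Place a group of same-width, N-free reads.
.place_group <- function(seqs, w, reference, max_mismatch) {
  m <- length(seqs)
  out <- list(contig = rep(NA_character_, m), start = rep(NA_integer_, m),
              mismatches = rep(NA_integer_, m))
  if (!m) return(out)
  dss <- Biostrings::DNAStringSet(seqs)

  # stage 1: full-width exact matches
  pd <- Biostrings::PDict(dss)
  ex_contig <- rep(NA_character_, m)
  ex_start <- rep(NA_integer_, m)
  ex_n <- integer(m)
  for (ci in seq_along(reference)) {
    hits <- Biostrings::startIndex(Biostrings::matchPDict(pd, reference[[ci]]))
    nh <- lengths(hits)
    one <- which(nh >= 1L)
    for (i in one) {
      ex_n[i] <- ex_n[i] + nh[i]
      if (is.na(ex_start[i])) {
        ex_start[i] <- hits[[i]][1]
        ex_contig[i] <- names(reference)[ci]
      }
    }
  }
  uniq <- ex_n == 1L
  out$contig[uniq] <- ex_contig[uniq]
  out$start[uniq] <- ex_start[uniq]
  out$mismatches[uniq] <- 0L
  if (max_mismatch == 0L) return(out)

  # stage 2: pigeonhole segments for reads without a unique exact match
  todo <- which(ex_n == 0L)
  if (!length(todo)) return(out)
  k <- w %/% 3L
  if (k < 4L) {  # segments too short to index; scan individually
    for (i in todo) {
      hit <- .place_single(seqs[i], reference, max_mismatch)
      out$contig[i] <- hit$contig; out$start[i] <- hit$start
      out$mismatches[i] <- hit$mismatches
    }
    return(out)
  }
  offsets <- c(0L, k, w - k)
  seg_hits <- vector("list", length(todo))  # per read: list of (contig, start)
  for (ci in seq_along(reference)) {
    Lc <- Biostrings::width(reference)[ci]
    for (j in seq_along(offsets)) {
      segs <- Biostrings::subseq(dss[todo], start = offsets[j] + 1L, width = k)
      pdj <- Biostrings::PDict(segs)
      hits <- Biostrings::startIndex(Biostrings::matchPDict(pdj, reference[[ci]]))
      for (t in seq_along(todo)) {
        hs <- hits[[t]]
        if (is.null(hs) || !length(hs)) next
        cand <- hs - offsets[j]
        cand <- cand[cand >= 1L & cand <= Lc - w + 1L]
        if (length(cand))
          seg_hits[[t]] <- rbind(seg_hits[[t]],
                                 cbind(ci = ci, start = cand))
      }
    }
  }
  for (t in seq_along(todo)) {
    ch <- seg_hits[[t]]
    if (is.null(ch)) next
    ch <- unique(ch)
    ned <- integer(nrow(ch))
    pat <- Biostrings::DNAString(seqs[todo[t]])
    for (ci in unique(ch[, "ci"])) {
      sel <- ch[, "ci"] == ci
      ned[sel] <- Biostrings::neditStartingAt(pat, reference[[ci]],
                                              starting.at = ch[sel, "start"],
                                              with.indels = FALSE)
    }
    best <- min(ned)
    if (best > max_mismatch || sum(ned == best) != 1L) next
    bi <- which.min(ned)
    out$contig[todo[t]] <- names(reference)[ch[bi, "ci"]]
    out$start[todo[t]] <- ch[bi, "start"]
    out$mismatches[todo[t]] <- best
  }
  out
}

# Exhaustive scan for a single read (used for N-containing or short reads).
.place_single <- function(seq, reference, max_mismatch) {
  best <- list(contig = NA_character_, start = NA_integer_,
               mismatches = NA_integer_)
  pat <- Biostrings::DNAString(seq)
  found <- data.frame(ci = integer(0), start = integer(0), ned = integer(0))
  for (ci in seq_along(reference)) {
    mm <- Biostrings::matchPattern(pat, reference[[ci]],
                                   max.mismatch = max_mismatch, fixed = TRUE)
    st <- BiocGenerics::start(mm)
    if (!length(st)) next
    ned <- Biostrings::neditStartingAt(pat, reference[[ci]], starting.at = st,
                                       with.indels = FALSE)
    found <- rbind(found, data.frame(ci = ci, start = st, ned = ned))
  }
  if (!nrow(found)) return(best)
  bm <- min(found$ned)
  if (bm > max_mismatch || sum(found$ned == bm) != 1L) return(best)
  i <- which.min(found$ned)
  list(contig = names(reference)[found$ci[i]], start = found$start[i],
       mismatches = bm)
}
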