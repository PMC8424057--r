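# Independent brute-force duplicate-marking oracle.
#
# Deliberately shares no code with the package implementation: its own
# CIGAR walker, its own key strings, a flat hash of all candidates with an
# arg-max sweep — no sorting, no batching, no region routing. Used to check
# mark_duplicates_routed() by exact flagged-set equality.

oracle_cigar_walk <- function(cigar) {
  lead <- 0L; trail <- 0L; span <- 0L
  n <- 0L; seen_aligned <- FALSE; pending_clip <- 0L
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      n <- n * 10L + as.integer(ch)
    } else {
      if (ch %in% c("S", "H")) {
        if (!seen_aligned) lead <- lead + n else pending_clip <- pending_clip + n
      } else {
        seen_aligned <- TRUE
        pending_clip <- 0L
        if (ch %in% c("M", "D", "N", "=", "X")) span <- span + n
      }
      n <- 0L
    }
  }
  trail <- pending_clip
  c(lead = lead, trail = trail, span = span)
}

oracle_end <- function(rec) {
  w <- oracle_cigar_walk(rec$cigar)
  if (bitwAnd(rec$flag, 16L) != 0L) {
    c(coord = rec$pos + w[["span"]] - 1L + w[["trail"]], strand = 1L)
  } else {
    c(coord = rec$pos - w[["lead"]], strand = 0L)
  }
}

oracle_score <- function(recs) {
  s <- 0L
  for (r in recs) {
    if (r$qual == "*") next
    for (q in utf8ToInt(r$qual) - 33L) if (q >= 15L) s <- s + q
  }
  s
}

oracle_lib <- function(rec, rg_lb) {
  hit <- grep("^RG:Z:", rec$tags, value = TRUE)
  if (length(hit) == 0L) return("unknown")
  id <- sub("^RG:Z:", "", hit[1])
  if (!is.null(rg_lb) && id %in% names(rg_lb) && !is.na(rg_lb[[id]]))
    rg_lb[[id]] else "unknown"
}

# Returns the sorted qnames of all reads that must carry FLAG 0x400.
oracle_mark_duplicates <- function(records, rg_lb = NULL, contig_order = NULL) {
  usable <- Filter(function(r)
    bitwAnd(r$flag, 0x4 + 0x100 + 0x800) == 0L && r$cigar != "*", records)
  if (is.null(contig_order)) {
    contig_order <- unique(vapply(usable, function(r) r$rname, character(1)))
  }
  by_qname <- split(usable, vapply(usable, function(r) r$qname, character(1)))

  pair_keys <- character(0); pair_scores <- integer(0); pair_qn <- character(0)
  pair_ends <- character(0)
  frag_keys <- character(0); frag_scores <- integer(0); frag_qn <- character(0)

  for (qn in names(by_qname)) {
    recs <- by_qname[[qn]]
    paired <- vapply(recs, function(r)
      bitwAnd(r$flag, 0x1) != 0L && bitwAnd(r$flag, 0x8) == 0L, logical(1))
    if (sum(paired) == 2L) {
      pr <- recs[paired]
      e1 <- oracle_end(pr[[1]]); r1 <- pr[[1]]$rname
      e2 <- oracle_end(pr[[2]]); r2 <- pr[[2]]$rname
      o1 <- c(match(r1, contig_order), e1[["coord"]], e1[["strand"]])
      o2 <- c(match(r2, contig_order), e2[["coord"]], e2[["strand"]])
      if (o1[1] > o2[1] || (o1[1] == o2[1] && (o1[2] > o2[2] ||
          (o1[2] == o2[2] && o1[3] > o2[3])))) {
        tmp <- e1; e1 <- e2; e2 <- tmp; tmpr <- r1; r1 <- r2; r2 <- tmpr
      }
      lib <- oracle_lib(pr[[1]], rg_lb)
      pair_keys <- c(pair_keys, paste(lib, r1, e1[["coord"]], e1[["strand"]],
                                      r2, e2[["coord"]], e2[["strand"]]))
      pair_scores <- c(pair_scores, oracle_score(pr))
      pair_qn <- c(pair_qn, qn)
      pair_ends <- c(pair_ends,
                     paste(lib, r1, e1[["coord"]], e1[["strand"]]),
                     paste(lib, r2, e2[["coord"]], e2[["strand"]]))
    }
    for (r in recs[!paired]) {
      e <- oracle_end(r)
      lib <- oracle_lib(r, rg_lb)
      frag_keys <- c(frag_keys, paste(lib, r$rname, e[["coord"]], e[["strand"]]))
      frag_scores <- c(frag_scores, oracle_score(list(r)))
      frag_qn <- c(frag_qn, qn)
    }
  }

  flagged <- character(0)
  for (k in unique(pair_keys)) {
    grp <- which(pair_keys == k)
    if (length(grp) < 2L) next
    best <- grp[pair_scores[grp] == max(pair_scores[grp])]
    keep <- best[order(pair_qn[best])[1]]
    flagged <- c(flagged, pair_qn[setdiff(grp, keep)])
  }
  for (i in seq_along(frag_keys)) {
    if (frag_keys[i] %in% pair_ends) flagged <- c(flagged, frag_qn[i])
  }
  rest <- which(!(frag_keys %in% pair_ends))
  for (k in unique(frag_keys[rest])) {
    grp <- rest[frag_keys[rest] == k]
    if (length(grp) < 2L) next
    best <- grp[frag_scores[grp] == max(frag_scores[grp])]
    keep <- best[order(frag_qn[best])[1]]
    flagged <- c(flagged, frag_qn[setdiff(grp, keep)])
  }
  sort(unique(flagged))
}
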