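# Per-region coordinate sorting and duplicate marking.
#
# Duplicate marking follows the Picard MarkDuplicates model: reads are
# grouped by library and by the unclipped 5' coordinates and strands of
# their fragment ends; within each group the highest-scoring candidate
# (sum of base qualities >= 15 over both mates) is kept and the rest are
# flagged 0x400. Fragments (unpaired or mate-unmapped reads) whose end
# coincides with any paired end are flagged unconditionally. All tie-breaks
# are content-based (ascending qname) so the outcome is independent of
# input order.

#' Coordinate-sort one region batch
#'
#' Orders records by non-decreasing POS; ties are broken by (qname, flag)
#' ascending so the output is a pure function of batch content.
#'
#' @param batch A sealed `read_batch`.
#' @return A new sealed `read_batch` in sorted order.
#' @export
sort_region <- function(batch) {
  if (batch_length(batch) == 0L) return(batch_seal(batch))
  fields <- strsplit(batch$sam, "\t", fixed = TRUE)
  flag <- as.integer(vapply(fields, `[`, character(1), 2L))
  qname <- vapply(fields, `[`, character(1), 1L)
  o <- order(batch$pos, qname, flag, method = "radix")
  read_batch(batch$region_id, batch$pos[o], batch$sam[o], batch$rname[o],
             sealed = TRUE)
}

#' Clip profile of a CIGAR string
#'
#' @param cigar A valid CIGAR (not "*").
#' @return List with `leading_clip` (S+H before the first aligned base),
#'   `trailing_clip`, and `ref_span` (bases consumed on the reference:
#'   M/D/N/=/X).
#' @examples
#' clip_profile("10S90M")   # leading 10, ref_span 90
#' clip_profile("50M10D40M5S")  # trailing 5, ref_span 100
#' @export
clip_profile <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L || sum(nchar(toks)) != nchar(cigar)) {
    stop("CIGAR parse error: '", cigar, "'", call. = FALSE)
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- substr(toks, nchar(toks), nchar(toks))
  clip_op <- op %in% c("S", "H")
  lead <- 0L
  for (i in seq_along(op)) { if (!clip_op[i]) break; lead <- lead + len[i] }
  trail <- 0L
  for (i in rev(seq_along(op))) { if (!clip_op[i]) break; trail <- trail + len[i] }
  if (all(clip_op)) trail <- 0L  # degenerate all-clip CIGAR
  list(leading_clip = lead, trailing_clip = trail,
       ref_span = sum(len[op %in% c("M", "D", "N", "=", "X")]))
}

#' Unclipped 5' coordinate of a mapped read
#'
#' The grouping coordinate of duplicate marking: the position the read's 5'
#' end would have had without soft/hard clipping. Forward strand:
#' `POS - leading_clip`; reverse strand: `POS + ref_span - 1 + trailing_clip`.
#'
#' @param rec A mapped, primary, non-supplementary `read_record` with a
#'   real CIGAR; otherwise `NULL` is returned and the read is excluded from
#'   duplicate keys (it passes through unmarked).
#' @return List with `rname`, `coord`, `strand` ("F"/"R"), or `NULL`.
#' @export
unclipped_5prime <- function(rec) {
  if (has_flag(rec$flag, FLAG_UNMAPPED) ||
      has_flag(rec$flag, FLAG_SECONDARY) ||
      has_flag(rec$flag, FLAG_SUPPLEMENTARY) ||
      rec$cigar == "*" || rec$rname == "*" || rec$pos == 0L) {
    return(NULL)
  }
  cp <- clip_profile(rec$cigar)
  if (has_flag(rec$flag, FLAG_REVERSE)) {
    list(rname = rec$rname, coord = rec$pos + cp$ref_span - 1L + cp$trailing_clip,
         strand = "R")
  } else {
    list(rname = rec$rname, coord = rec$pos - cp$leading_clip, strand = "F")
  }
}

#' Duplicate-selection score of a candidate
#'
#' Sum, over the supplied records, of Phred base qualities that are >= 15
#' (the de-facto Picard default). A `*` quality string contributes 0.
#'
#' @param records List of one (fragment) or two (pair) `read_record`.
#' @return Integer score.
#' @export
duplicate_score <- function(records) {
  total <- 0L
  for (rec in records) {
    if (rec$qual == "*") next
    q <- utf8ToInt(rec$qual) - 33L
    total <- total + sum(q[q >= 15L])
  }
  as.integer(total)
}

## ---- keys and candidates -------------------------------------------------

get_tag <- function(rec, tag) {
  prefix <- paste0(tag, ":")
  hit <- rec$tags[startsWith(rec$tags, prefix)]
  if (length(hit) == 0L) return(NA_character_)
  sub("^[A-Za-z][A-Za-z0-9]:[AifZHB]:", "", hit[1])
}

read_library <- function(rec, rg_lb) {
  rg <- get_tag(rec, "RG")
  if (is.na(rg) || is.null(rg_lb) || !(rg %in% names(rg_lb))) return("unknown")
  lb <- rg_lb[[rg]]
  if (is.na(lb)) "unknown" else lb
}

# Mate 5' end from the MC tag (mate CIGAR) when the mate record is not at
# hand; clip-unaware PNEXT fallback when MC is absent.
mate_unclipped_end <- function(rec) {
  mrname <- if (rec$rnext == "=") rec$rname else rec$rnext
  strand <- if (has_flag(rec$flag, FLAG_MATE_REVERSE)) "R" else "F"
  mc <- get_tag(rec, "MC")
  used_mc <- !is.na(mc) && mc != "*"
  if (used_mc) {
    cp <- clip_profile(mc)
    coord <- if (strand == "R") rec$pnext + cp$ref_span - 1L + cp$trailing_clip
             else rec$pnext - cp$leading_clip
  } else {
    coord <- rec$pnext
  }
  list(rname = mrname, coord = as.integer(coord), strand = strand,
       used_mc = used_mc)
}

end_key <- function(library, end) {
  paste(library, end$rname, end$coord, end$strand, sep = "|")
}

# end1 <= end2 by (contig order, coordinate, strand F < R)
end_lte <- function(e1, e2, contig_rank) {
  r1 <- contig_rank[[e1$rname]]; r2 <- contig_rank[[e2$rname]]
  if (r1 != r2) return(r1 < r2)
  if (e1$coord != e2$coord) return(e1$coord < e2$coord)
  e1$strand <= e2$strand
}

#' Build duplicate-marking candidates for a set of records
#'
#' Primary mapped paired records whose mates are also mapped are joined by
#' qname into pair candidates; unpaired or mate-unmapped primary records
#' become fragment candidates. Secondary (0x100), supplementary (0x800) and
#' unmapped (0x4) records are excluded entirely. When a paired record's mate
#' is not among `records`, the mate end is derived from the MC tag (PNEXT
#' clip-unaware fallback, counted in the `mc_missing` attribute).
#'
#' @param records List of `read_record` (one routing region, or a whole run).
#' @param rg_lb Named character vector, RG ID -> LB (from the header);
#'   records without a resolvable library fall into "unknown".
#' @param contig_order Character vector of contig names defining genome
#'   order for canonical end ordering; defaults to order of appearance.
#' @return List with `pairs` and `fragments`: each a list of candidates
#'   (`qname`, `key`, `score`, `library`, `end1`, `end2`, `orientation`).
#'   Attribute `mc_missing` counts MC-less mate lookups.
#' @export
build_pair_candidates <- function(records, rg_lb = NULL, contig_order = NULL) {
  keep <- vapply(records, function(r)
    !has_flag(r$flag, FLAG_UNMAPPED) && !has_flag(r$flag, FLAG_SECONDARY) &&
      !has_flag(r$flag, FLAG_SUPPLEMENTARY) && r$cigar != "*",
    logical(1))
  records <- records[keep]
  if (is.null(contig_order)) {
    contig_order <- unique(vapply(records, `[[`, character(1), "rname"))
  }
  contig_rank <- stats::setNames(as.list(seq_along(contig_order)), contig_order)

  is_pair_side <- vapply(records, function(r)
    has_flag(r$flag, FLAG_PAIRED) && !has_flag(r$flag, FLAG_MATE_UNMAPPED),
    logical(1))

  mc_missing <- 0L
  pairs <- list()
  fragments <- list()

  make_fragment <- function(rec) {
    end <- unclipped_5prime(rec)
    lib <- read_library(rec, rg_lb)
    list(qname = rec$qname, kind = "fragment", library = lib,
         key = paste("frag", end_key(lib, end), sep = "|"),
         score = duplicate_score(list(rec)), end1 = end, end2 = NULL,
         orientation = NA_character_)
  }

  make_pair <- function(recs, end2_override = NULL) {
    lib <- read_library(recs[[1]], rg_lb)
    e1 <- unclipped_5prime(recs[[1]])
    e2 <- if (is.null(end2_override)) unclipped_5prime(recs[[2]]) else end2_override
    if (!end_lte(e1, e2, contig_rank)) { tmp <- e1; e1 <- e2; e2 <- tmp }
    orient <- paste0(e1$strand, e2$strand)
    list(qname = recs[[1]]$qname, kind = "pair", library = lib,
         key = paste("pair", lib, e1$rname, e1$coord, e1$strand,
                     e2$rname, e2$coord, e2$strand, orient, sep = "|"),
         score = duplicate_score(recs), end1 = e1, end2 = e2,
         orientation = orient)
  }

  qnames <- vapply(records, `[[`, character(1), "qname")
  for (qn in unique(qnames[is_pair_side])) {
    idx <- which(qnames == qn & is_pair_side)
    if (length(idx) > 2L) {
      stop("data-integrity error: qname '", qn, "' has ", length(idx),
           " primary records", call. = FALSE)
    }
    if (length(idx) == 2L) {
      pairs[[length(pairs) + 1L]] <- make_pair(records[idx])
    } else {
      rec <- records[[idx]]
      mate <- mate_unclipped_end(rec)
      if (!mate$used_mc) mc_missing <- mc_missing + 1L
      pairs[[length(pairs) + 1L]] <-
        make_pair(list(rec), end2_override = mate[c("rname", "coord", "strand")])
    }
  }
  for (i in which(!is_pair_side)) {
    fragments[[length(fragments) + 1L]] <- make_fragment(records[[i]])
  }
  structure(list(pairs = pairs, fragments = fragments),
            mc_missing = mc_missing)
}

#' Decide which candidates are duplicates
#'
#' Within each pair key group the highest-scoring pair is kept and all other
#' pairs' reads are to be flagged 0x400. A fragment whose (library, end)
#' coincides with any pair end is flagged unconditionally; among the
#' remaining fragment groups the highest-scoring fragment is kept. Ties are
#' broken by ascending qname, so decisions depend only on content.
#'
#' @param pairs,fragments Candidate lists from [build_pair_candidates()].
#' @return data.frame with columns `qname`, `kind` — the candidates whose
#'   records must be flagged (zero rows when nothing is duplicated).
#' @export
mark_duplicates <- function(pairs, fragments) {
  flagged_qn <- character(0)
  flagged_kind <- character(0)

  pick_losers <- function(cands) {
    scores <- vapply(cands, `[[`, numeric(1), "score")
    qns <- vapply(cands, `[[`, character(1), "qname")
    best <- which(scores == max(scores))
    keep <- best[order(qns[best])[1]]  # lexicographically smallest max-score
    qns[-keep]
  }

  if (length(pairs) > 0L) {
    keys <- vapply(pairs, `[[`, character(1), "key")
    for (grp in split(seq_along(pairs), keys)) {
      if (length(grp) < 2L) next
      losers <- pick_losers(pairs[grp])
      flagged_qn <- c(flagged_qn, losers)
      flagged_kind <- c(flagged_kind, rep("pair", length(losers)))
    }
  }

  pair_end_keys <- unlist(lapply(pairs, function(p)
    c(end_key(p$library, p$end1), end_key(p$library, p$end2))))

  if (length(fragments) > 0L) {
    fkeys <- vapply(fragments, `[[`, character(1), "key")
    fend <- vapply(fragments, function(f) end_key(f$library, f$end1), character(1))
    beats_pair <- fend %in% pair_end_keys
    flagged_qn <- c(flagged_qn,
                    vapply(fragments[beats_pair], `[[`, character(1), "qname"))
    flagged_kind <- c(flagged_kind, rep("fragment", sum(beats_pair)))
    rest <- which(!beats_pair)
    for (grp in split(rest, fkeys[rest])) {
      if (length(grp) < 2L) next
      losers <- pick_losers(fragments[grp])
      flagged_qn <- c(flagged_qn, losers)
      flagged_kind <- c(flagged_kind, rep("fragment", length(losers)))
    }
  }
  data.frame(qname = flagged_qn, kind = flagged_kind, stringsAsFactors = FALSE)
}

#' Apply duplicate decisions to a region batch
#'
#' Sets FLAG bit 0x400 on every primary mapped record whose qname appears in
#' `decisions`; every other byte of every record is left unchanged and the
#' read count is conserved.
#'
#' @param batch A `read_batch`.
#' @param decisions Character vector of qnames to flag (or the data.frame
#'   from [mark_duplicates()]).
#' @param reconcile When `TRUE` (default), a decision qname absent from the
#'   batch raises a reconciliation error.
#' @return A new `read_batch` with updated FLAG fields.
#' @export
apply_marks <- function(batch, decisions, reconcile = TRUE) {
  if (is.data.frame(decisions)) decisions <- decisions$qname
  decisions <- unique(decisions)
  if (length(decisions) == 0L) return(batch)
  fields <- strsplit(batch$sam, "\t", fixed = TRUE)
  qn <- vapply(fields, `[`, character(1), 1L)
  if (reconcile && !all(decisions %in% qn)) {
    missing <- setdiff(decisions, qn)
    stop("reconciliation error: decision qname(s) absent from batch: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sam <- batch$sam
  for (i in which(qn %in% decisions)) {
    f <- fields[[i]]
    flag <- as.integer(f[2])
    if (has_flag(flag, FLAG_UNMAPPED) || has_flag(flag, FLAG_SECONDARY) ||
        has_flag(flag, FLAG_SUPPLEMENTARY)) next
    f[2] <- as.character(bitwOr(flag, FLAG_DUP))
    sam[i] <- paste(f, collapse = "\t")
  }
  read_batch(batch$region_id, batch$pos, sam, batch$rname,
             sealed = batch$sealed)
}

## ---- routing across regions ---------------------------------------------

# Region holding a candidate's smaller canonical end; unclipped coordinates
# may fall just outside [1, contig length] after clip adjustment, so the
# coordinate is clamped for the lookup only (keys keep the exact value).
routing_region <- function(cand, table) {
  ord <- table$contig_order
  len <- ord$length[match(cand$end1$rname, ord$rname)]
  if (is.na(len)) return(NA_integer_)
  assign_region(table, cand$end1$rname, min(max(cand$end1$coord, 1L), len))
}

#' Duplicate decisions for a whole run, region-routed
#'
#' Builds candidates from all records, routes each candidate to the region
#' containing its smaller canonical end, and marks each routing region
#' independently. Because every pair in one duplicate group shares both end
#' coordinates, each group is complete in exactly one routing region and the
#' union of per-region decisions equals the global decision set.
#'
#' @param records List of `read_record` (a whole run).
#' @param header A `sam_header` (for RG->LB and contig order).
#' @param table A `region_table`.
#' @return data.frame of flagged (`qname`, `kind`), with attribute
#'   `mc_missing`.
#' @export
mark_duplicates_routed <- function(records, header, table) {
  cands <- build_pair_candidates(records, rg_lb = header$rg_lb,
                                 contig_order = table$contig_order$rname)
  route_of <- function(cs) vapply(cs, routing_region, integer(1), table = table)
  pr <- route_of(cands$pairs)
  fr <- route_of(cands$fragments)
  out <- lapply(sort(unique(c(pr, fr))), function(rid) {
    mark_duplicates(cands$pairs[which(pr == rid)],
                    cands$fragments[which(fr == rid)])
  })
  decisions <- if (length(out) == 0L)
    data.frame(qname = character(0), kind = character(0)) else
    do.call(rbind, out)
  attr(decisions, "mc_missing") <- attr(cands, "mc_missing")
  decisions
}
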