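# Static load balancing: partition each contig into contiguous regions of
# roughly 40-50 Mb so downstream stages (sort, duplicate marking, calling)
# can run one region per worker.

#' GRCh37 primary-contig lengths
#'
#' Lengths of the 25 primary contigs of the GRCh37/hg19 human reference
#' (chr1-22, X, Y, MT), used as the built-in example genome for the default
#' region table.
#'
#' @return data.frame with columns `rname`, `length`.
#' @export
grch37_contigs <- function() {
  data.frame(
    rname = c(paste0("chr", 1:22), "chrX", "chrY", "chrMT"),
    length = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
               171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
               135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
               90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
               48129895L, 51304566L, 155270560L, 59373566L, 16569L),
    stringsAsFactors = FALSE
  )
}

#' Build the static region table for a genome
#'
#' Each contig is divided into `max(1, round(length / target_size))`
#' contiguous, near-equal spans; the first spans absorb the remainder bases.
#' With the default 47 Mb target on GRCh37 primary contigs this yields 65
#' regions averaging 40-50 Mb.
#'
#' @param contig_lengths data.frame with columns `rname`, `length` (order
#'   defines genome order), or a named integer vector.
#' @param target_size Target region size in base pairs.
#' @return A `region_table`: list with `regions` (data.frame `region_id`
#'   0-based, `rname`, `start`, `end`, 1-based inclusive) and `contig_order`
#'   (the input data.frame).
#' @export
build_regions <- function(contig_lengths, target_size = 47000000L) {
  if (!is.data.frame(contig_lengths)) {
    contig_lengths <- data.frame(rname = names(contig_lengths),
                                 length = as.integer(contig_lengths),
                                 stringsAsFactors = FALSE)
  }
  stopifnot(all(contig_lengths$length > 0), target_size > 0)
  if (anyDuplicated(contig_lengths$rname)) {
    stop("configuration error: duplicate contig name in contig table",
         call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(contig_lengths)), function(i) {
    len <- as.numeric(contig_lengths$length[i])
    n <- max(1L, as.integer(round(len / target_size)))
    base <- len %/% n
    extra <- len %% n  # first `extra` spans get one extra base
    counts <- rep(base, n) + as.numeric(seq_len(n) <= extra)
    ends <- cumsum(counts)
    data.frame(rname = contig_lengths$rname[i],
               start = as.integer(c(1, ends[-n] + 1)),
               end = as.integer(ends),
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, pieces)
  regions <- cbind(region_id = seq_len(nrow(regions)) - 1L, regions)
  structure(list(regions = regions, contig_order = contig_lengths),
            class = "region_table")
}

#' @export
print.region_table <- function(x, ...) {
  cat("<region_table> ", nrow(x$regions), " regions over ",
      nrow(x$contig_order), " contigs; mean span ",
      round(mean(x$regions$end - x$regions$start + 1) / 1e6, 2), " Mb\n", sep = "")
  invisible(x)
}

#' Assign a position to its region
#'
#' Binary search over region starts within the contig; region spans are
#' 1-based inclusive, so a position equal to a region's `end` belongs to
#' that region and `end + 1` to the next.
#'
#' @param table A `region_table`.
#' @param rname Contig name.
#' @param pos 1-based position; vectorized.
#' @return Integer region id(s).
#' @export
assign_region <- function(table, rname, pos) {
  regs <- table$regions
  ord <- table$contig_order
  vapply(seq_along(pos), function(i) {
    ci <- match(rname[i], ord$rname)
    if (is.na(ci)) stop("lookup error: unknown contig '", rname[i], "'",
                        call. = FALSE)
    if (is.na(pos[i]) || pos[i] < 1L || pos[i] > ord$length[ci]) {
      stop(sprintf("lookup error: position %s out of bounds for contig %s",
                   pos[i], rname[i]), call. = FALSE)
    }
    sub <- which(regs$rname == rname[i])
    starts <- regs$start[sub]
    j <- findInterval(pos[i], starts)  # binary search: last start <= pos
    regs$region_id[sub[j]]
  }, integer(1))
}

#' Per-region read counts over a set of batches
#'
#' @param batches List of `read_batch`.
#' @return Named integer vector, region id -> read count (regions with no
#'   reads are absent).
#' @export
region_histogram <- function(batches) {
  counts <- integer(0)
  for (b in batches) {
    if (batch_length(b) == 0L) next
    key <- as.character(b$region_id)
    counts[key] <- (if (key %in% names(counts)) counts[[key]] else 0L) +
      batch_length(b)
  }
  counts
}

#' Read contig lengths from a FASTA index
#'
#' @param path A `.fai` file (name, length, offset, linebases, linewidth).
#' @return data.frame with columns `rname`, `length`.
#' @export
read_fai <- function(path) {
  fai <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(rname = fai[[1]], length = as.integer(fai[[2]]),
             stringsAsFactors = FALSE)
}

#' Export a region table as BED
#'
#' BED is 0-based, half-open: a region `[start, end]` (1-based inclusive)
#' becomes the BED interval `start - 1, end`.
#'
#' @param table A `region_table`.
#' @param path Optional output file; when `NULL` the BED data.frame is
#'   returned instead.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
regions_to_bed <- function(table, path = NULL) {
  bed <- data.frame(chrom = table$regions$rname,
                    start = table$regions$start - 1L,
                    end = table$regions$end,
                    name = sprintf("region_%d", table$regions$region_id),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  bed
}
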