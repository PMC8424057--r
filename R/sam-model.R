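# Domain model for aligned reads: a lossless text representation of SAM
# alignment lines, the <POS:SAM(+RNAME)> key-value view used for sorting,
# and the columnar per-region batch container.

# SAM FLAG bits used throughout the package.
FLAG_PAIRED        <- 0x1L
FLAG_PROPER        <- 0x2L
FLAG_UNMAPPED      <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE       <- 0x10L
FLAG_MATE_REVERSE  <- 0x20L
FLAG_FIRST         <- 0x40L
FLAG_SECOND        <- 0x80L
FLAG_SECONDARY     <- 0x100L
FLAG_QCFAIL        <- 0x200L
FLAG_DUP           <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Parse one SAM alignment line
#'
#' Splits a tab-delimited SAMv1 alignment line into its 11 mandatory fields
#' plus any auxiliary tags. Tags are kept as opaque strings, verbatim and in
#' order, so that [format_sam_line()] reproduces the input byte for byte.
#'
#' @param line A single non-header SAM alignment line (no trailing newline).
#' @return A `read_record` object: a list with elements `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`,
#'   `qual` and `tags` (character vector, possibly empty).
#' @examples
#' rec <- parse_sam_line("r1\t0\tchr1\t100\t60\t5M\t*\t0\t0\tACGTA\tIIIII")
#' rec$pos
#' @export
parse_sam_line <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L) {
    stop(sprintf("SAM parse error: expected >= 11 tab-separated fields, got %d",
                 length(f)), call. = FALSE)
  }
  flag <- suppressWarnings(as.integer(f[2]))
  pos <- suppressWarnings(as.integer(f[4]))
  if (is.na(flag)) stop("SAM parse error: non-integer FLAG field: ", f[2], call. = FALSE)
  if (is.na(pos)) stop("SAM parse error: non-integer POS field: ", f[4], call. = FALSE)
  rec <- list(
    qname = f[1], flag = flag, rname = f[3], pos = pos,
    mapq = suppressWarnings(as.integer(f[5])), cigar = f[6],
    rnext = f[7], pnext = suppressWarnings(as.integer(f[8])),
    tlen = suppressWarnings(as.integer(f[9])), seq = f[10], qual = f[11],
    tags = if (length(f) > 11L) f[12:length(f)] else character(0)
  )
  if (rec$seq != "*" && rec$qual != "*" && nchar(rec$seq) != nchar(rec$qual)) {
    stop("SAM parse error: SEQ and QUAL lengths differ for read ", rec$qname,
         call. = FALSE)
  }
  class(rec) <- "read_record"
  rec
}

#' Serialize a read record back to a SAM line
#'
#' Inverse of [parse_sam_line()]: `format_sam_line(parse_sam_line(x))`
#' is byte-identical to `x` for any valid alignment line.
#'
#' @param rec A `read_record`.
#' @return A single tab-delimited character string.
#' @export
format_sam_line <- function(rec) {
  paste(c(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq, rec$cigar,
          rec$rnext, rec$pnext, rec$tlen, rec$seq, rec$qual, rec$tags),
        collapse = "\t")
}

#' @export
print.read_record <- function(x, ...) {
  cat("<read_record> ", x$qname, " flag=", x$flag, " ", x$rname, ":", x$pos,
      " ", x$cigar, "\n", sep = "")
  invisible(x)
}

#' Convert a read record to its key-value form
#'
#' The key-value view keeps the alignment position (the sort key) and the
#' contig name alongside the full serialized SAM line, mirroring a columnar
#' `<POS:SAM>`-plus-RNAME record. POS and RNAME stay duplicated inside the
#' SAM string so the record remains lossless.
#'
#' @param rec A `read_record`.
#' @return A `keyed_read`: list with `pos`, `sam`, `rname`.
#' @export
to_keyed <- function(rec) {
  structure(list(pos = rec$pos, sam = format_sam_line(rec), rname = rec$rname),
            class = "keyed_read")
}

#' Columnar batch of keyed reads for one region
#'
#' A `read_batch` holds three parallel columns (`pos` integer, `sam`
#' character, `rname` character) for the reads of one region. Batches are
#' append-only until sealed; a sealed batch is immutable and transformations
#' return new batches.
#'
#' @param region_id Integer region id (0-based, genome order); `NA` marks the
#'   unplaced pseudo-region.
#' @param pos,sam,rname Optional initial columns (equal length).
#' @param sealed Whether the new batch starts sealed.
#' @return A `read_batch` object.
#' @export
read_batch <- function(region_id = NA_integer_, pos = integer(0),
                       sam = character(0), rname = character(0),
                       sealed = FALSE) {
  stopifnot(length(pos) == length(sam), length(sam) == length(rname))
  structure(list(region_id = as.integer(region_id), pos = as.integer(pos),
                 sam = as.character(sam), rname = as.character(rname),
                 sealed = isTRUE(sealed)),
            class = "read_batch")
}

#' @rdname read_batch
#' @param batch A `read_batch`.
#' @param k A `keyed_read` to append.
#' @export
batch_append <- function(batch, k) {
  if (batch$sealed) stop("read_batch is sealed and immutable", call. = FALSE)
  batch$pos <- c(batch$pos, as.integer(k$pos))
  batch$sam <- c(batch$sam, k$sam)
  batch$rname <- c(batch$rname, k$rname)
  batch
}

#' @rdname read_batch
#' @export
batch_seal <- function(batch) {
  batch$sealed <- TRUE
  batch
}

#' @rdname read_batch
#' @export
batch_length <- function(batch) length(batch$pos)

#' @export
print.read_batch <- function(x, ...) {
  cat("<read_batch> region_id=", x$region_id, " n=", batch_length(x),
      if (x$sealed) " (sealed)" else "", "\n", sep = "")
  invisible(x)
}

## ---- SAM header handling -------------------------------------------------

#' Parse SAM header lines
#'
#' Header lines (`@HD`, `@SQ`, `@RG`, `@PG`, `@CO`) are preserved verbatim
#' and made queryable for contig lengths and the read-group to library
#' mapping used by duplicate marking.
#'
#' @param lines Character vector of header lines (each starting with "@").
#' @return A `sam_header`: list with `text` (verbatim lines), `contigs`
#'   (data.frame `rname`, `length` in header order) and `rg_lb` (named
#'   character vector, RG ID -> LB).
#' @export
parse_sam_header <- function(lines) {
  lines <- lines[startsWith(lines, "@")]
  sq <- lines[startsWith(lines, "@SQ")]
  field_of <- function(line, tag) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    hit <- f[startsWith(f, paste0(tag, ":"))]
    if (length(hit) == 0L) NA_character_ else sub(paste0("^", tag, ":"), "", hit[1])
  }
  contigs <- data.frame(
    rname = vapply(sq, field_of, character(1), tag = "SN", USE.NAMES = FALSE),
    length = as.integer(vapply(sq, field_of, character(1), tag = "LN",
                               USE.NAMES = FALSE)),
    stringsAsFactors = FALSE
  )
  rg <- lines[startsWith(lines, "@RG")]
  rg_lb <- stats::setNames(
    vapply(rg, field_of, character(1), tag = "LB", USE.NAMES = FALSE),
    vapply(rg, field_of, character(1), tag = "ID", USE.NAMES = FALSE)
  )
  structure(list(text = lines, contigs = contigs, rg_lb = rg_lb),
            class = "sam_header")
}

#' Build a minimal SAM header
#'
#' @param contigs data.frame with columns `rname`, `length`.
#' @param rg_id,rg_lb Optional read-group id and library name.
#' @param sort_order Value for the `SO` field of `@HD`.
#' @return A `sam_header`.
#' @export
make_sam_header <- function(contigs, rg_id = NULL, rg_lb = NULL,
                            sort_order = "coordinate") {
  lines <- c(sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
             sprintf("@SQ\tSN:%s\tLN:%d", contigs$rname, as.integer(contigs$length)))
  if (!is.null(rg_id)) {
    lines <- c(lines, sprintf("@RG\tID:%s\tLB:%s\tSM:sample1\tPL:ILLUMINA",
                              rg_id, if (is.null(rg_lb)) "unknown" else rg_lb))
  }
  parse_sam_header(lines)
}

#' Read a SAM file (or BAM via on-the-fly conversion)
#'
#' @param path Path to a SAM text file, or a BAM file (detected by `.bam`
#'   extension and converted through Rsamtools).
#' @return List with `header` (a `sam_header`) and `records` (list of
#'   `read_record`).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp), add = TRUE)
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    path <- tmp
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  records <- lapply(lines[!is_hdr & nzchar(lines)], parse_sam_line)
  list(header = parse_sam_header(lines[is_hdr]), records = records)
}

#' Write header plus records as SAM text
#'
#' @param header A `sam_header`.
#' @param records List of `read_record`, or a character vector of
#'   pre-serialized SAM lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(header, records, path) {
  body <- if (is.character(records)) records else
    vapply(records, format_sam_line, character(1))
  writeLines(c(header$text, body), path)
  invisible(path)
}
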