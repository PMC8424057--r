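# Paired FASTQ chunking: split two mate files into a configurable number of
# record-synchronized chunks so each chunk can be aligned independently.

fastq_connection <- function(path) gzfile(path, "rt")

#' Count records in a 4-line FASTQ file
#'
#' @param path FASTQ file, plain or gzip.
#' @return Integer record count.
#' @export
count_fastq_records <- function(path) {
  con <- fastq_connection(path)
  on.exit(close(con), add = TRUE)
  n_lines <- 0L
  first <- NULL
  repeat {
    chunk <- readLines(con, n = 65536L)
    if (length(chunk) == 0L) break
    if (is.null(first) && length(chunk) > 0L) first <- chunk[1]
    n_lines <- n_lines + length(chunk)
  }
  if (n_lines %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, n_lines), call. = FALSE)
  }
  if (n_lines > 0L && !startsWith(first, "@")) {
    stop(sprintf("malformed FASTQ '%s': first record header does not start with '@'",
                 path), call. = FALSE)
  }
  n_lines %/% 4L
}

#' Plan balanced chunk boundaries
#'
#' Splits `total_records` into at most `n_chunks` contiguous index ranges
#' whose sizes differ by at most one; the remainder goes to the lowest-index
#' chunks. When more chunks than records are requested, the plan is capped
#' at one record per chunk with a warning.
#'
#' @param total_records Non-negative record count.
#' @param n_chunks Requested number of chunks (>= 1).
#' @return A `chunk_plan`: list with `total_records`, `n_chunks` and a
#'   data.frame `boundaries` (`start` 0-based record index, `count`).
#' @examples
#' chunk_boundaries(10, 3)$boundaries$count  # 4 3 3
#' @export
chunk_boundaries <- function(total_records, n_chunks) {
  stopifnot(total_records >= 0, n_chunks >= 1)
  total_records <- as.integer(total_records)
  n_chunks <- as.integer(n_chunks)
  if (total_records > 0L && n_chunks > total_records) {
    warning(sprintf("requested %d chunks for %d records; capping at %d nonempty chunks",
                    n_chunks, total_records, total_records))
    n_chunks <- total_records
  }
  if (total_records == 0L) {
    counts <- integer(0)
  } else {
    base <- total_records %/% n_chunks
    extra <- total_records %% n_chunks
    counts <- rep(base, n_chunks) + as.integer(seq_len(n_chunks) <= extra)
  }
  boundaries <- if (length(counts) == 0L) {
    data.frame(start = integer(0), count = integer(0))
  } else {
    data.frame(start = cumsum(c(0L, counts[-length(counts)])), count = counts)
  }
  structure(list(total_records = total_records,
                 n_chunks = length(counts),
                 boundaries = boundaries),
            class = "chunk_plan")
}

read_fastq_records <- function(path) {
  con <- fastq_connection(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)), call. = FALSE)
  }
  lines
}

#' Stream one synchronized chunk of a read pair
#'
#' Yields the records of chunk `chunk_index` from both mate files, byte
#' identical to the source and index-synchronized (record j of R1 pairs with
#' record j of R2).
#'
#' @param r1_path,r2_path Mate FASTQ files; `r2_path` may be `NULL` for
#'   single-end input.
#' @param plan A `chunk_plan` for the shared record count.
#' @param chunk_index 1-based chunk index.
#' @return List with `r1` and `r2` character vectors of FASTQ lines
#'   (4 per record); `r2` is `NULL` for single-end input.
#' @export
stream_chunk <- function(r1_path, r2_path, plan, chunk_index) {
  if (chunk_index < 1L || chunk_index > plan$n_chunks) {
    stop(sprintf("chunk_index %d out of range [1, %d]", chunk_index, plan$n_chunks),
         call. = FALSE)
  }
  l1 <- read_fastq_records(r1_path)
  if (length(l1) %/% 4L != plan$total_records) {
    stop("R1 record count does not match the chunk plan", call. = FALSE)
  }
  l2 <- NULL
  if (!is.null(r2_path)) {
    l2 <- read_fastq_records(r2_path)
    if (length(l2) != length(l1)) {
      stop(sprintf("R1/R2 pairing error: %d vs %d records",
                   length(l1) %/% 4L, length(l2) %/% 4L), call. = FALSE)
    }
  }
  b <- plan$boundaries[chunk_index, ]
  idx <- if (b$count == 0L) integer(0) else
    (b$start * 4L + 1L):((b$start + b$count) * 4L)
  list(r1 = l1[idx], r2 = if (is.null(l2)) NULL else l2[idx])
}

#' Write all chunks of a (paired) FASTQ input to disk
#'
#' @inheritParams stream_chunk
#' @param n_chunks Number of chunks to create.
#' @param outdir Output directory (created if needed).
#' @return Data frame with per-chunk paths and record counts.
#' @export
write_fastq_chunks <- function(r1_path, r2_path, n_chunks, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n1 <- count_fastq_records(r1_path)
  if (!is.null(r2_path)) {
    n2 <- count_fastq_records(r2_path)
    if (n1 != n2) stop(sprintf("R1/R2 pairing error: %d vs %d records", n1, n2),
                       call. = FALSE)
  }
  plan <- chunk_boundaries(n1, n_chunks)
  out <- lapply(seq_len(plan$n_chunks), function(i) {
    ch <- stream_chunk(r1_path, r2_path, plan, i)
    p1 <- file.path(outdir, sprintf("chunk_%03d_R1.fastq", i))
    writeLines(ch$r1, p1)
    p2 <- NA_character_
    if (!is.null(ch$r2)) {
      p2 <- file.path(outdir, sprintf("chunk_%03d_R2.fastq", i))
      writeLines(ch$r2, p2)
    }
    data.frame(chunk = i, r1 = p1, r2 = p2,
               records = plan$boundaries$count[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
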