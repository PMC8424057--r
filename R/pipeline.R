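# Pipeline driver: binds assignment, per-region sorting, routed duplicate
# marking, shard emission, per-region calling and VCF merging. Regions are
# the unit of parallelism; within-region work is sequential, so final
# artifacts are invariant to the worker count.

#' Pipeline configuration
#'
#' @param output_dir Run directory for shards, VCFs and reports.
#' @param region_target_size Target region size in base pairs.
#' @param n_chunks FASTQ chunk count (chunking stage only).
#' @param max_parallel_workers Maximum concurrent region workers.
#' @param caller_template A [caller_template()] (or `NULL` when only
#'   pre-processing is run).
#' @param reference_fasta Reference FASTA path handed to the caller.
#' @param pad Region padding in bases for caller input (0 keeps hard
#'   boundaries; merge restores partition semantics when > 0).
#' @param seed Integer seed for any randomized stage.
#' @param log_level "quiet" or "info".
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            region_target_size = 47000000L,
                            n_chunks = 1L,
                            max_parallel_workers = 1L,
                            caller_template = NULL,
                            reference_fasta = NULL,
                            pad = 0L,
                            seed = 1L,
                            log_level = "info") {
  stopifnot(max_parallel_workers >= 1L, pad >= 0L, region_target_size > 0)
  structure(list(output_dir = output_dir,
                 region_target_size = as.integer(region_target_size),
                 n_chunks = as.integer(n_chunks),
                 max_parallel_workers = as.integer(max_parallel_workers),
                 caller_template = caller_template,
                 reference_fasta = reference_fasta,
                 pad = as.integer(pad), seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(sprintf("[vcshard] %s", sprintf(...)))
  }
}

#' Pre-process alignments into sorted, duplicate-marked region shards
#'
#' For each region: assign reads by POS, coordinate-sort, mark duplicates
#' (candidates routed to the region of their smaller canonical end, then
#' reconciled back to storage regions by qname), and write an indexed BAM
#' shard. Unmapped/unplaced records go to an `unplaced` pseudo-shard and
#' never enter sorting keys or duplicate marking.
#'
#' @param input Path to a SAM (or BAM) file of aligned reads.
#' @param config A `pipeline_config`.
#' @param table Optional pre-built `region_table`; by default one is built
#'   from the input header's `@SQ` lines at `region_target_size`.
#' @return List with `manifest` (per-region shards incl. duplicate counts),
#'   `decisions` (flagged qname table), `table`, `header` and `report`
#'   (named list of conservation checks, all of which must pass).
#' @export
preprocess <- function(input, config, table = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_sam(input)
  if (is.null(table)) {
    if (nrow(dat$header$contigs) == 0L) {
      stop("configuration error: input has no @SQ lines and no region table was supplied",
           call. = FALSE)
    }
    table <- build_regions(dat$header$contigs, config$region_target_size)
  }
  records <- dat$records
  placed <- vapply(records, function(r)
    r$rname != "*" && r$pos > 0L && !has_flag(r$flag, FLAG_UNMAPPED), logical(1))
  known <- vapply(records, function(r)
    r$rname %in% table$contig_order$rname, logical(1))
  if (any(placed & !known)) {
    warning(sum(placed & !known),
            " record(s) on contigs absent from the region table routed to the unplaced pseudo-region")
  }
  placed <- placed & known
  pipe_log(config, "preprocess: %d records (%d placed, %d unplaced)",
           length(records), sum(placed), sum(!placed))

  rid <- rep(NA_integer_, length(records))
  if (any(placed)) {
    rid[placed] <- assign_region(
      table,
      vapply(records[placed], `[[`, character(1), "rname"),
      vapply(records[placed], `[[`, integer(1), "pos"))
  }

  decisions <- mark_duplicates_routed(records[placed], dat$header, table)
  qn_all <- vapply(records, `[[`, character(1), "qname")
  if (!all(decisions$qname %in% qn_all[placed])) {
    stop("reconciliation error: duplicate decision for qname absent from placed records",
         call. = FALSE)
  }

  shard_dir <- file.path(config$output_dir, "shards")
  sorted_header <- parse_sam_header(
    c(sub("SO:[^\t]*", "SO:coordinate", dat$header$text[startsWith(dat$header$text, "@HD")]),
      dat$header$text[!startsWith(dat$header$text, "@HD")]))

  process_region <- function(i) {
    region <- table$regions[i, ]
    sel <- which(!is.na(rid) & rid == region$region_id)
    b <- read_batch(region$region_id,
                    pos = vapply(records[sel], `[[`, integer(1), "pos"),
                    sam = vapply(records[sel], format_sam_line, character(1)),
                    rname = vapply(records[sel], `[[`, character(1), "rname"),
                    sealed = TRUE)
    b <- sort_region(b)
    local_dups <- intersect(decisions$qname, qn_all[sel])
    b <- apply_marks(b, local_dups, reconcile = FALSE)
    entry <- write_region_shard(b, sorted_header, region, shard_dir)
    entry$dup_records <- sum(vapply(strsplit(b$sam, "\t", fixed = TRUE),
                                    function(f) has_flag(as.integer(f[2]), FLAG_DUP),
                                    logical(1)))
    entry
  }
  idx <- seq_len(nrow(table$regions))
  rows <- if (config$max_parallel_workers > 1L) {
    parallel::mclapply(idx, process_region,
                       mc.cores = config$max_parallel_workers)
  } else {
    lapply(idx, process_region)
  }
  bad <- vapply(rows, function(r) inherits(r, "try-error") || !is.data.frame(r),
                logical(1))
  if (any(bad)) stop("stage failure in preprocess for region(s) ",
                     paste(idx[bad], collapse = ", "), call. = FALSE)
  manifest <- do.call(rbind, rows)

  if (any(!placed)) {
    ub <- read_batch(NA_integer_,
                     pos = vapply(records[!placed], `[[`, integer(1), "pos"),
                     sam = vapply(records[!placed], format_sam_line, character(1)),
                     rname = vapply(records[!placed], `[[`, character(1), "rname"),
                     sealed = TRUE)
    ue <- write_region_shard(ub, sorted_header, NULL, shard_dir)
    ue$dup_records <- 0L
    manifest <- rbind(manifest, ue)
  }

  placed_total <- sum(placed)
  shard_total <- sum(manifest$read_count[!is.na(manifest$region_id)])
  report <- list(
    total_records = length(records),
    placed_records = placed_total,
    shard_records = shard_total,
    conservation_ok = shard_total == placed_total,
    duplicate_candidates_flagged = nrow(decisions),
    duplicate_records_flagged = sum(manifest$dup_records),
    mc_missing = attr(decisions, "mc_missing")
  )
  if (!report$conservation_ok) {
    stop("read-count conservation check failed: ", shard_total, " vs ",
         placed_total, call. = FALSE)
  }
  pipe_log(config, "preprocess: %d regions, %d duplicate candidates flagged",
           nrow(table$regions), nrow(decisions))
  list(manifest = manifest, decisions = decisions, table = table,
       header = dat$header, report = report)
}

#' Run the full pipeline: preprocess, call per region, merge VCFs
#'
#' @param input Aligned SAM/BAM input.
#' @param config A `pipeline_config` with a caller template and reference.
#' @return List with `merged_vcf`, `manifest`, `table` and `report`; the
#'   machine-readable run report is also written to
#'   `output_dir/run_report.json`.
#' @export
full_pipeline <- function(input, config) {
  if (is.null(config$caller_template)) {
    stop("configuration error: full_pipeline needs a caller template",
         call. = FALSE)
  }
  pre <- preprocess(input, config)
  call_dir <- file.path(config$output_dir, "calls")
  table <- pre$table
  manifest <- pre$manifest
  if (config$pad > 0L) {
    # pad the caller's view of each region; merge restores the partition
    padded <- table
    lens <- padded$contig_order$length[
      match(padded$regions$rname, padded$contig_order$rname)]
    padded$regions$start <- pmax(1L, padded$regions$start - config$pad)
    padded$regions$end <- pmin(lens, padded$regions$end + config$pad)
    call_table <- padded
  } else {
    call_table <- table
  }
  manifest <- run_region_callers(manifest, config$caller_template, call_table,
                                 config$reference_fasta, call_dir,
                                 config$max_parallel_workers)
  if (!isTRUE(attr(manifest, "ok"))) {
    stop("stage failure in call: one or more regions failed", call. = FALSE)
  }
  done <- manifest[!is.na(manifest$region_id) & manifest$status == "done", ]
  done <- done[order(done$region_id), ]
  merged <- file.path(config$output_dir, "merged.vcf")
  span_regions <- if (config$pad > 0L)
    table$regions[match(done$region_id, table$regions$region_id),
                  c("rname", "start", "end")]
  else NULL
  out <- merge_vcfs(done$vcf_path, table, merged, regions = span_regions)
  report <- c(pre$report,
              list(regions_called = nrow(done),
                   merged_vcf_records = attr(out, "n_records")))
  jsonlite::write_json(report, file.path(config$output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipe_log(config, "pipeline done: %d merged VCF records",
           attr(out, "n_records"))
  list(merged_vcf = merged, manifest = manifest, table = table,
       report = report)
}
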