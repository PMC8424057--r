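# Scatter-gather stage: write per-region BAM shards, run a pluggable
# variant caller per region (command template with placeholders), and merge
# the per-region VCFs into one.

#' Caller command template
#'
#' Any caller that supports region-restricted calling can be plugged in via
#' a shell command pattern with the placeholders `{bam}`, `{ref}`,
#' `{region_bed}`, `{vcf}` (each exactly once) and optionally `{threads}`.
#'
#' @param name Template name.
#' @param command_pattern Shell command with placeholders.
#' @param threads_per_instance Threads handed to each caller instance.
#' @return A `caller_template`.
#' @export
caller_template <- function(name, command_pattern, threads_per_instance = 1L) {
  for (ph in c("{bam}", "{ref}", "{region_bed}", "{vcf}")) {
    n <- lengths(regmatches(command_pattern,
                            gregexpr(ph, command_pattern, fixed = TRUE)))
    if (n != 1L) {
      stop("caller template '", name, "': placeholder ", ph,
           " must appear exactly once (found ", n, ")", call. = FALSE)
    }
  }
  structure(list(name = name, command_pattern = command_pattern,
                 threads_per_instance = as.integer(threads_per_instance)),
            class = "caller_template")
}

#' @rdname caller_template
#' @export
deepvariant_template <- function(threads_per_instance = 6L) {
  caller_template(
    "deepvariant",
    paste("run_deepvariant --model_type=WGS --ref={ref} --reads={bam}",
          "--regions={region_bed} --output_vcf={vcf}",
          "--num_shards={threads}"),
    threads_per_instance
  )
}

#' @rdname caller_template
#' @export
octopus_template <- function(threads_per_instance = 4L) {
  caller_template(
    "octopus",
    "octopus -R {ref} -I {bam} -t {region_bed} -o {vcf} --threads {threads}",
    threads_per_instance
  )
}

render_caller_command <- function(template, bam, ref, region_bed, vcf) {
  cmd <- template$command_pattern
  subs <- c("{bam}" = bam, "{ref}" = ref, "{region_bed}" = region_bed,
            "{vcf}" = vcf, "{threads}" = as.character(template$threads_per_instance))
  for (ph in names(subs)) cmd <- gsub(ph, subs[[ph]], cmd, fixed = TRUE)
  cmd
}

## ---- shard emission ------------------------------------------------------

#' Write one region's sorted batch as an indexed BAM shard
#'
#' The shard carries the full header (all @SQ lines of the reference, not
#' only the region's contig) so any downstream caller accepts it.
#'
#' @param sorted_batch A sorted, sealed `read_batch`.
#' @param header A `sam_header`.
#' @param region One row of a region table (`region_id`, `rname`, `start`,
#'   `end`), or `NULL` for the unplaced pseudo-shard.
#' @param outdir Output directory.
#' @return One-row data.frame manifest entry (`region_id`, `shard_path`,
#'   `read_count`, `vcf_path`, `status`).
#' @export
write_region_shard <- function(sorted_batch, header, region, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rid <- if (is.null(region)) NA_integer_ else as.integer(region$region_id)
  stem <- if (is.na(rid)) "region_unplaced" else sprintf("region_%03d", rid)
  sam_tmp <- tempfile(fileext = ".sam")
  on.exit(unlink(sam_tmp), add = TRUE)
  write_sam(header, sorted_batch$sam, sam_tmp)
  dest <- file.path(outdir, stem)
  bam <- tryCatch(
    Rsamtools::asBam(sam_tmp, dest, overwrite = TRUE, indexDestination = TRUE),
    error = function(e) stop("I/O error writing shard for region ",
                             ifelse(is.na(rid), "unplaced", rid), ": ",
                             conditionMessage(e), call. = FALSE))
  data.frame(region_id = rid, shard_path = bam,
             read_count = batch_length(sorted_batch),
             vcf_path = NA_character_, status = "pending",
             stringsAsFactors = FALSE)
}

#' Split an existing coordinate-sorted BAM into region shards
#'
#' Each record is placed by its own POS into exactly one region shard;
#' unmapped/unplaced records are dropped from the shards (they carry no
#' region). The input must be indexed.
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @param table A `region_table`.
#' @param outdir Output directory for shards.
#' @return A manifest data.frame with one row per region.
#' @export
split_existing_bam <- function(bam_path, table, outdir) {
  idx <- paste0(bam_path, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam_path)
  if (!file.exists(idx) && !file.exists(idx2)) {
    stop("input BAM is not indexed; run samtools index (or Rsamtools::indexBam) first",
         call. = FALSE)
  }
  dat <- read_sam(bam_path)
  placed <- vapply(dat$records, function(r)
    r$rname != "*" && r$pos > 0L && !has_flag(r$flag, FLAG_UNMAPPED), logical(1))
  recs <- dat$records[placed]
  rid <- if (length(recs) > 0L)
    assign_region(table,
                  vapply(recs, `[[`, character(1), "rname"),
                  vapply(recs, `[[`, integer(1), "pos"))
  else integer(0)
  manifest <- lapply(seq_len(nrow(table$regions)), function(i) {
    region <- table$regions[i, ]
    sel <- which(rid == region$region_id)
    b <- read_batch(region$region_id,
                    pos = vapply(recs[sel], `[[`, integer(1), "pos"),
                    sam = vapply(recs[sel], format_sam_line, character(1)),
                    rname = vapply(recs[sel], `[[`, character(1), "rname"),
                    sealed = TRUE)
    write_region_shard(sort_region(b), dat$header, region, outdir)
  })
  do.call(rbind, manifest)
}

## ---- caller orchestration ------------------------------------------------

#' Run one caller instance per region shard
#'
#' Renders the command template for every pending/failed manifest entry and
#' executes at most `max_parallel` instances concurrently. A failing region
#' is recorded (`status = "failed"`, exit code kept) and the run continues
#' for other regions.
#'
#' @param manifest Manifest data.frame from shard emission.
#' @param template A `caller_template`.
#' @param table A `region_table` (for region BED rendering).
#' @param ref Reference FASTA path handed to the caller.
#' @param outdir Directory for region BEDs and VCFs.
#' @param max_parallel Maximum concurrent caller instances.
#' @return Updated manifest; attribute `ok` is `FALSE` if any region failed.
#' @export
run_region_callers <- function(manifest, template, table, ref, outdir,
                               max_parallel = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  exe <- strsplit(trimws(template$command_pattern), "[[:space:]]+")[[1]][1]
  if (!nzchar(Sys.which(exe)) && !file.exists(exe)) {
    stop("configuration error: caller executable '", exe, "' not found",
         call. = FALSE)
  }
  todo <- which(manifest$status %in% c("pending", "failed") &
                  !is.na(manifest$region_id))
  run_one <- function(i) {
    region <- table$regions[table$regions$region_id == manifest$region_id[i], ]
    bed <- file.path(outdir, sprintf("region_%03d.bed", manifest$region_id[i]))
    utils::write.table(
      data.frame(region$rname, region$start - 1L, region$end),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    vcf <- file.path(outdir, sprintf("region_%03d.vcf", manifest$region_id[i]))
    cmd <- render_caller_command(template, manifest$shard_path[i], ref, bed, vcf)
    status <- system2("sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = FALSE)
    list(i = i, vcf = vcf, exit = status)
  }
  results <- if (max_parallel > 1L) {
    parallel::mclapply(todo, run_one, mc.cores = max_parallel)
  } else {
    lapply(todo, run_one)
  }
  for (res in results) {
    if (res$exit == 0L && file.exists(res$vcf)) {
      manifest$status[res$i] <- "done"
      manifest$vcf_path[res$i] <- res$vcf
    } else {
      manifest$status[res$i] <- "failed"
      manifest$vcf_path[res$i] <- NA_character_
      attr(manifest, paste0("exit_", manifest$region_id[res$i])) <- res$exit
    }
  }
  attr(manifest, "ok") <- all(manifest$status[!is.na(manifest$region_id)] == "done")
  manifest
}

## ---- VCF merge -----------------------------------------------------------

read_vcf_lines <- function(path) {
  lines <- readLines(path)
  list(header = lines[startsWith(lines, "#")],
       records = lines[!startsWith(lines, "#") & nzchar(lines)])
}

#' Merge per-region VCFs into one
#'
#' The merged file takes its header from the first input (contig lines are
#' verified consistent across inputs; per-region headers are dropped) and
#' orders records by (contig order of the region table, POS, REF, ALT).
#' With zero-padding regions the output record count is the sum of the
#' inputs; with padded regions, records outside their region's span are
#' dropped before concatenation and exact (contig, POS, REF, ALT)
#' duplicates are removed, restoring partition semantics.
#'
#' @param vcf_paths VCF paths ordered by region.
#' @param table A `region_table`.
#' @param out Output VCF path.
#' @param regions Optional data.frame (rows parallel to `vcf_paths`) with
#'   `rname`, `start`, `end`: when given, each input is span-filtered to its
#'   region (the pad-restoring rule).
#' @param gvcf When `TRUE`, inputs are treated as gVCF: concatenated without
#'   span filtering or dedup (reference-block semantics differ).
#' @return `out`, invisibly; attribute `n_records` carries the record count.
#' @export
merge_vcfs <- function(vcf_paths, table, out, regions = NULL, gvcf = FALSE) {
  stopifnot(length(vcf_paths) >= 1L)
  parsed <- lapply(vcf_paths, read_vcf_lines)
  contig_def <- function(hdr) {
    ln <- hdr[startsWith(hdr, "##contig=")]
    stats::setNames(ln, sub('.*ID=([^,>]+).*', '\\1', ln))
  }
  base_def <- contig_def(parsed[[1]]$header)
  for (p in parsed[-1]) {
    d <- contig_def(p$header)
    common <- intersect(names(base_def), names(d))
    bad <- common[base_def[common] != d[common]]
    if (length(bad) > 0L) {
      stop("merge error: conflicting contig definition for ", bad[1],
           call. = FALSE)
    }
  }
  records <- character(0)
  for (i in seq_along(parsed)) {
    recs <- parsed[[i]]$records
    if (!gvcf && !is.null(regions) && length(recs) > 0L) {
      f <- strsplit(recs, "\t", fixed = TRUE)
      pos <- as.integer(vapply(f, `[`, character(1), 2L))
      chrom <- vapply(f, `[`, character(1), 1L)
      keep <- chrom == regions$rname[i] &
        pos >= regions$start[i] & pos <= regions$end[i]
      recs <- recs[keep]
    }
    records <- c(records, recs)
  }
  if (length(records) > 0L) {
    f <- strsplit(records, "\t", fixed = TRUE)
    chrom <- vapply(f, `[`, character(1), 1L)
    pos <- as.integer(vapply(f, `[`, character(1), 2L))
    ref <- vapply(f, `[`, character(1), 4L)
    alt <- vapply(f, `[`, character(1), 5L)
    if (!gvcf) {
      o <- order(match(chrom, table$contig_order$rname), pos, ref, alt,
                 method = "radix")
      records <- records[o]
      key <- paste(chrom[o], pos[o], ref[o], alt[o], sep = "\r")
      if (!is.null(regions)) records <- records[!duplicated(key)]
    }
  }
  writeLines(c(parsed[[1]]$header, records), out)
  invisible(structure(out, n_records = length(records)))
}
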