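# Stub variant caller used by orchestration tests: a POSIX sh script that
# emits a deterministic 2-record VCF per region BED (positions start,
# start+1 of the region). `fail_chrom` makes the stub exit non-zero for
# regions on one contig, to test failure isolation.

write_stub_caller <- function(dir, fail_chrom = NULL, contigs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "stub_caller.sh")
  contig_lines <- if (is.null(contigs)) "" else
    paste(sprintf("printf '##contig=<ID=%s,length=%d>\\n'", contigs$rname,
                  contigs$length), collapse = "\n  ")
  fail_check <- if (is.null(fail_chrom)) "" else
    sprintf("grep -q '^%s\t' \"$bed\" && exit 1\n", fail_chrom)
  writeLines(c(
    "#!/bin/sh",
    "bam=\"$1\"; ref=\"$2\"; bed=\"$3\"; vcf=\"$4\"",
    fail_check,
    "{",
    "  printf '##fileformat=VCFv4.2\\n'",
    paste0("  ", contig_lines),
    "  printf '#CHROM\\tPOS\\tID\\tREF\\tALT\\tQUAL\\tFILTER\\tINFO\\n'",
    "  awk -F'\\t' '{print $1\"\\t\"($2+1)\"\\t.\\tA\\tC\\t30\\tPASS\\t.\";",
    "                print $1\"\\t\"($2+2)\"\\t.\\tA\\tG\\t30\\tPASS\\t.\"}' \"$bed\"",
    "} > \"$vcf\""
  ), path)
  Sys.chmod(path, "0755")
  path
}

stub_template <- function(stub_path) {
  caller_template("stub",
                  paste(stub_path, "{bam} {ref} {region_bed} {vcf}"),
                  threads_per_instance = 1L)
}
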