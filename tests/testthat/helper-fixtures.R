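# Hand-built records and small simulated datasets shared across tests.

make_rec <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 60L, cigar = "100M", rnext = "*", pnext = 0L,
                     tlen = 0L, seq = NULL, qual = NULL, tags = character(0),
                     read_len = 100L) {
  if (is.null(seq)) seq <- paste(rep("A", read_len), collapse = "")
  if (is.null(qual)) qual <- paste(rep("I", read_len), collapse = "")  # Q40
  parse_sam_line(paste(c(qname, flag, rname, pos, mapq, cigar, rnext, pnext,
                         tlen, seq, qual, tags), collapse = "\t"))
}

# A minimal proper pair: both mates mapped, FR orientation.
make_pair_recs <- function(qname, rname = "chr1", pos1 = 1000L, pos2 = 1200L,
                           read_len = 10L, qual1 = NULL, qual2 = NULL,
                           cigar1 = NULL, cigar2 = NULL,
                           tags = c("RG:Z:rg1")) {
  if (is.null(cigar1)) cigar1 <- sprintf("%dM", read_len)
  if (is.null(cigar2)) cigar2 <- sprintf("%dM", read_len)
  tlen <- pos2 + read_len - pos1
  r1 <- make_rec(qname, flag = 0x1 + 0x2 + 0x20 + 0x40, rname = rname,
                 pos = pos1, cigar = cigar1, rnext = "=", pnext = pos2,
                 tlen = tlen, qual = qual1, read_len = read_len,
                 tags = c(sprintf("MC:Z:%s", cigar2), tags))
  r2 <- make_rec(qname, flag = 0x1 + 0x2 + 0x10 + 0x80, rname = rname,
                 pos = pos2, cigar = cigar2, rnext = "=", pnext = pos1,
                 tlen = -tlen, qual = qual2, read_len = read_len,
                 tags = c(sprintf("MC:Z:%s", cigar1), tags))
  list(r1, r2)
}

tiny_reference <- function(seed = 42L) {
  make_reference(seed, c(c1 = 60000L, c2 = 40000L))
}

tiny_table <- function(ref = tiny_reference()) {
  build_regions(ref$contigs, target_size = 25000L)
}

qual_of <- function(values) intToUtf8(values + 33L)
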