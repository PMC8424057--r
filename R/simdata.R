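# Synthetic data: seeded reference sequences, paired aligned reads with
# soft-clipped ends and injected PCR-duplicate groups, plus the ground-truth
# table that makes duplicate-recovery tests exact. Alignment is bypassed:
# reads are emitted directly as valid SAM with consistent FLAG/POS/CIGAR/MC.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. uniform over A/C/G/T from a seeded generator, so
#' the same seed always yields byte-identical FASTA output.
#'
#' @param seed Integer seed.
#' @param contigs data.frame with `rname`, `length`, or a named integer
#'   vector of contig lengths.
#' @return A `sim_reference`: list with `sequences` (named character) and
#'   `contigs` (data.frame).
#' @export
make_reference <- function(seed, contigs) {
  if (!is.data.frame(contigs)) {
    contigs <- data.frame(rname = names(contigs), length = as.integer(contigs),
                          stringsAsFactors = FALSE)
  }
  sequences <- with_seed(seed, {
    vapply(contigs$length, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
  })
  names(sequences) <- contigs$rname
  structure(list(sequences = sequences, contigs = contigs),
            class = "sim_reference")
}

#' Write a simulated reference as FASTA
#'
#' @param reference A `sim_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

qual_string <- function(n, values = c(10L, 20L, 30L, 35L, 40L),
                        probs = c(0.05, 0.15, 0.40, 0.25, 0.15)) {
  intToUtf8(sample(values, n, replace = TRUE, prob = probs) + 33L)
}

#' Simulate a paired-end read set with injected duplicate groups
#'
#' Fragments are placed uniformly on the reference; a `dup_rate` fraction of
#' them seed PCR-duplicate groups whose members copy the seed's coordinates
#' and strands but redraw base qualities (so selection scores differ almost
#' surely). With probability `clip_prob` a read receives a 5'-end soft clip
#' with POS adjusted so its unclipped 5' coordinate is unchanged — clipped
#' and clip-free copies of a fragment therefore still share duplicate keys.
#'
#' @param reference A `sim_reference`.
#' @param n_pairs Number of original (non-duplicate) fragments.
#' @param read_len Read length in bases.
#' @param insert_mean,insert_sd Insert-size distribution (normal, rounded,
#'   truncated to `[read_len, contig length]` by rejection; an insert that
#'   fails 1000 redraws raises an error).
#' @param dup_rate Fraction of fragments spawning duplicate groups, in
#'   `[0, 1)`.
#' @param dup_geom_p,dup_max_size Truncated-geometric group-size model:
#'   1 + min(Geom(p), max - 1) extra members per seeded group.
#' @param clip_prob Per-read probability of a 5' soft clip (1..`max_clip`
#'   bases).
#' @param max_clip Maximum soft-clip length.
#' @param seed Integer seed; fixes every random choice.
#' @param rg_id,library Read-group id and library name written to the
#'   header and RG tags.
#' @return A `sim_read_set`: list with `records` (list of `read_record`,
#'   mates adjacent), `truth` (data.frame: `qname`, `rname`, `true_pos_r1`,
#'   `true_pos_r2`, `strand_r1`, `strand_r2`, `dup_group_id`,
#'   `is_seed_of_group` — the seed flags the member duplicate marking is
#'   expected to keep, i.e. the highest-scoring pair of its group),
#'   `header` (a `sam_header`) and `reference`.
#' @export
simulate_read_set <- function(reference, n_pairs = 500L, read_len = 100L,
                              insert_mean = 300, insert_sd = 30,
                              dup_rate = 0.1, dup_geom_p = 0.5,
                              dup_max_size = 6L, clip_prob = 0.1,
                              max_clip = 10L, seed = 1L,
                              rg_id = "rg1", library = "lib1") {
  stopifnot(n_pairs >= 1L, read_len >= 1L, dup_rate >= 0, dup_rate < 1)
  contigs <- reference$contigs
  if (any(contigs$length < read_len)) {
    stop("every contig must be at least one read long", call. = FALSE)
  }
  with_seed(seed, {
    ## fragment placement
    ci <- sample(nrow(contigs), n_pairs, replace = TRUE,
                 prob = contigs$length)
    insert <- integer(n_pairs)
    start <- integer(n_pairs)
    for (i in seq_len(n_pairs)) {
      len <- contigs$length[ci[i]]
      ok <- FALSE
      for (try in seq_len(1000L)) {
        ins <- as.integer(round(stats::rnorm(1, insert_mean, insert_sd)))
        if (ins >= read_len && ins <= len) { ok <- TRUE; break }
      }
      if (!ok) stop("insert size incompatible with contig length after 1000 draws",
                    call. = FALSE)
      insert[i] <- ins
      start[i] <- sample.int(len - ins + 1L, 1L)
    }
    r1_forward <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)

    frag <- data.frame(
      qname = sprintf("sim_%06d", seq_len(n_pairs)),
      ci = ci, start = start, insert = insert, r1_forward = r1_forward,
      dup_group = NA_integer_, is_seed = FALSE, stringsAsFactors = FALSE
    )

    ## duplicate-group injection
    n_groups <- as.integer(round(dup_rate * n_pairs))
    if (n_groups > 0L) {
      seeds <- sort(sample.int(n_pairs, n_groups))
      frag$dup_group[seeds] <- seq_len(n_groups)
      frag$is_seed[seeds] <- TRUE
      extras <- pmin(stats::rgeom(n_groups, dup_geom_p) + 1L, dup_max_size - 1L)
      for (g in seq_len(n_groups)) {
        s <- frag[seeds[g], ]
        for (j in seq_len(extras[g])) {
          member <- s
          member$qname <- sprintf("%s_d%d", s$qname, j)
          member$is_seed <- FALSE
          frag <- rbind(frag, member)
        }
      }
    }

    ## per-read emission
    n_frag <- nrow(frag)
    records <- vector("list", 2L * n_frag)
    truth <- frag[, c("qname", "dup_group", "is_seed")]
    truth$rname <- contigs$rname[frag$ci]
    truth$true_pos_r1 <- NA_integer_; truth$true_pos_r2 <- NA_integer_
    truth$strand_r1 <- NA_character_; truth$strand_r2 <- NA_character_

    for (i in seq_len(n_frag)) {
      rn <- contigs$rname[frag$ci[i]]
      seq_full <- reference$sequences[[rn]]
      fstart <- frag$start[i]
      fend <- fstart + frag$insert[i] - 1L
      fwd_pos <- fstart                       # leftmost read, forward strand
      rev_pos <- fend - read_len + 1L         # rightmost read, reverse strand
      # mate 1 takes the forward slot iff r1_forward
      for (mate in 1:2) {
        is_r1 <- mate == 1L
        forward <- xor(!frag$r1_forward[i], is_r1)
        pos0 <- if (forward) fwd_pos else rev_pos
        five_prime <- if (forward) pos0 else pos0 + read_len - 1L
        clip <- if (stats::runif(1) < clip_prob)
          sample.int(max_clip, 1L) else 0L
        if (clip >= read_len) clip <- read_len - 1L
        if (forward) {
          pos <- pos0 + clip
          cigar <- if (clip > 0L)
            sprintf("%dS%dM", clip, read_len - clip) else sprintf("%dM", read_len)
        } else {
          pos <- pos0
          cigar <- if (clip > 0L)
            sprintf("%dM%dS", read_len - clip, clip) else sprintf("%dM", read_len)
        }
        flag <- FLAG_PAIRED + FLAG_PROPER +
          (if (is_r1) FLAG_FIRST else FLAG_SECOND) +
          (if (!forward) FLAG_REVERSE else 0L) +
          (if (forward) FLAG_MATE_REVERSE else 0L)
        mate_pos0 <- if (forward) rev_pos else fwd_pos
        rec <- list(
          qname = frag$qname[i], flag = as.integer(flag), rname = rn,
          pos = as.integer(pos), mapq = 60L, cigar = cigar, rnext = "=",
          pnext = NA_integer_, tlen = if (forward) frag$insert[i]
                                       else -frag$insert[i],
          seq = substr(seq_full, pos0, pos0 + read_len - 1L),
          qual = qual_string(read_len),
          tags = c(NA_character_, sprintf("RG:Z:%s", rg_id))
        )
        class(rec) <- "read_record"
        records[[2L * (i - 1L) + mate]] <- rec
        if (is_r1) {
          truth$true_pos_r1[i] <- five_prime
          truth$strand_r1[i] <- if (forward) "F" else "R"
        } else {
          truth$true_pos_r2[i] <- five_prime
          truth$strand_r2[i] <- if (forward) "F" else "R"
        }
      }
      # backfill mate-dependent fields (PNEXT and the MC tag)
      a <- records[[2L * (i - 1L) + 1L]]
      b <- records[[2L * (i - 1L) + 2L]]
      a$pnext <- b$pos; b$pnext <- a$pos
      a$tags[1] <- sprintf("MC:Z:%s", b$cigar)
      b$tags[1] <- sprintf("MC:Z:%s", a$cigar)
      records[[2L * (i - 1L) + 1L]] <- a
      records[[2L * (i - 1L) + 2L]] <- b
    }

    # the truth "seed" is the member expected to be kept: within each group,
    # the pair with the highest selection score (tie: smallest qname) —
    # groups share coordinates/strands, so selection is decided by score
    if (any(!is.na(frag$dup_group))) {
      for (g in unique(frag$dup_group[!is.na(frag$dup_group)])) {
        members <- which(!is.na(frag$dup_group) & frag$dup_group == g)
        scores <- vapply(members, function(i)
          duplicate_score(records[(2L * (i - 1L) + 1L):(2L * i)]), integer(1))
        best <- members[scores == max(scores)]
        keep <- best[order(frag$qname[best])[1]]
        truth$is_seed[members] <- FALSE
        truth$is_seed[keep] <- TRUE
      }
    }

    truth <- truth[, c("qname", "rname", "true_pos_r1", "true_pos_r2",
                       "strand_r1", "strand_r2", "dup_group", "is_seed")]
    names(truth)[7:8] <- c("dup_group_id", "is_seed_of_group")
    structure(list(records = records, truth = truth,
                   header = make_sam_header(contigs, rg_id = rg_id,
                                            rg_lb = library,
                                            sort_order = "unsorted"),
                   reference = reference,
                   params = list(n_pairs = n_pairs, read_len = read_len,
                                 dup_rate = dup_rate, clip_prob = clip_prob,
                                 seed = seed)),
              class = "sim_read_set")
  })
}

#' Expected duplicate count of a truth table
#'
#' Every duplicate group keeps one representative, so the expected number of
#' flagged read pairs is the sum of (group size - 1) over groups.
#'
#' @param truth Truth data.frame from [simulate_read_set()].
#' @return Integer count of non-seed group members.
#' @export
truth_duplicate_count <- function(truth) {
  sum(!is.na(truth$dup_group_id) & !truth$is_seed_of_group)
}

#' Emit a read set as SAM
#'
#' @param read_set A `sim_read_set`.
#' @param path Optional output path; when `NULL` the SAM lines are returned.
#' @return Character vector of SAM lines, or `path` invisibly.
#' @export
emit_sam <- function(read_set, path = NULL) {
  lines <- c(read_set$header$text,
             vapply(read_set$records, format_sam_line, character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Emit a read set as paired FASTQ
#'
#' Mates on the reverse strand are reverse-complemented (and their quality
#' strings reversed) so the FASTQ carries reads as sequenced.
#'
#' @param read_set A `sim_read_set`.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisible list of the two paths.
#' @export
emit_fastq <- function(read_set, r1_path, r2_path) {
  recs <- read_set$records
  is_r1 <- vapply(recs, function(r) has_flag(r$flag, FLAG_FIRST), logical(1))
  fq <- function(rec) {
    rev <- has_flag(rec$flag, FLAG_REVERSE)
    seq <- if (rev) revcomp(rec$seq) else rec$seq
    qual <- if (rev) paste(rev(strsplit(rec$qual, "")[[1]]), collapse = "")
            else rec$qual
    c(paste0("@", rec$qname), seq, "+", qual)
  }
  writeLines(unlist(lapply(recs[is_r1], fq)), r1_path)
  writeLines(unlist(lapply(recs[!is_r1], fq)), r2_path)
  invisible(list(r1 = r1_path, r2 = r2_path))
}

#' Write the ground-truth table as TSV
#'
#' @param read_set A `sim_read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(read_set, path) {
  utils::write.table(read_set$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
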