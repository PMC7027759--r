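#' Detect runs of homozygosity from ordered genotype calls
#'
#' Scans a subject's ordered biallelic calls for runs of homozygosity
#' (ROH): stretches of consecutive non-missing calls containing at most
#' \code{max_het} heterozygous calls, at least \code{min_snps} variants, and
#' no gap between consecutive retained variants larger than
#' \code{max_gap_bp}. Missing calls are removed before scanning, so they
#' neither break nor extend a run. Candidate runs start and end on
#' homozygous calls; where runs sharing variants both qualify, a greedy
#' left-to-right scan keeps the longest run at each start, so reported
#' segments never overlap.
#'
#' The detector is a conventional genotype-window ROH caller. The study
#' decision rule applied downstream (>3 Mb segments covering >3% of the
#' genome, roughly second-cousin relatedness) is independent of the
#' detector and is implemented in [consanguinity_flag()].
#'
#' @param calls Data.frame with columns \code{chrom}, \code{pos} (1-based,
#'   sorted within chromosome), \code{is_het} (logical) and optionally
#'   \code{is_missing} (logical, default all FALSE).
#' @param min_snps Minimum variants per reported segment (default 50).
#' @param max_het Maximum heterozygous calls tolerated inside a segment
#'   (default 1).
#' @param max_gap_bp Maximum distance between consecutive retained variants
#'   within a segment (default 1e6).
#' @return Data.frame of segments: \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive first/last variant positions), \code{length_bp},
#'   \code{n_snps}, \code{n_het}.
#' @export
detect_roh <- function(calls, min_snps = 50L, max_het = 1L, max_gap_bp = 1e6) {
  need <- c("chrom", "pos", "is_het")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns chrom, pos, is_het")
  }
  if (is.null(calls$is_missing)) calls$is_missing <- FALSE
  calls <- calls[!calls$is_missing, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer(), stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)

  segs <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    if (is.unsorted(cc$pos)) stop("variant positions unsorted on chromosome ", ch)
    # split into blocks at oversized gaps
    brk <- c(0L, which(diff(cc$pos) > max_gap_bp), nrow(cc))
    for (b in seq_len(length(brk) - 1L)) {
      blk <- cc[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
      segs[[length(segs) + 1L]] <- .roh_block(blk, min_snps, max_het, ch)
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  rownames(out) <- NULL
  out
}

# ROH candidates within one gap-free block of one chromosome.
# Works on the run-length encoding of is_het: a candidate segment is a span
# of consecutive homozygous runs joined across intervening heterozygous runs
# whose total length is <= max_het.
.roh_block <- function(blk, min_snps, max_het, ch) {
  n <- nrow(blk)
  if (n == 0L) return(NULL)
  r <- rle(as.logical(blk$is_het))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hom <- which(!r$values)
  if (length(hom) == 0L) return(NULL)
  # cumulative het-call count by rle run, for het cost between hom runs
  het_len <- ifelse(r$values, r$lengths, 0L)
  cs <- cumsum(het_len)

  best_end <- rep(NA_integer_, length(hom))  # rle index of furthest feasible hom run
  best_cost <- rep(0L, length(hom))
  for (j in 0:max_het) {                     # join across up to max_het het runs
    t2 <- hom + 2L * j
    ok <- t2 <= length(r$lengths)
    if (!any(ok)) break
    cost <- rep(0L, length(hom))
    cost[ok] <- cs[t2[ok]] - cs[hom[ok]]     # hets strictly inside the span
    feas <- ok & cost <= max_het
    best_end[feas] <- t2[feas]
    best_cost[feas] <- cost[feas]
  }
  i1 <- starts[hom]
  i2 <- ends[best_end]
  n_snps <- i2 - i1 + 1L
  keep <- which(!is.na(i2) & n_snps >= min_snps)
  if (length(keep) == 0L) return(NULL)

  # greedy left-to-right non-overlapping selection
  sel <- integer()
  last_end <- -Inf
  for (k in keep) {
    if (i1[k] > last_end) {
      sel <- c(sel, k)
      last_end <- i2[k]
    }
  }
  data.frame(chrom = ch,
             start = blk$pos[i1[sel]],
             end = blk$pos[i2[sel]],
             length_bp = blk$pos[i2[sel]] - blk$pos[i1[sel]] + 1L,
             n_snps = n_snps[sel],
             n_het = best_cost[sel],
             stringsAsFactors = FALSE)
}

#' Per-subject homozygosity profile
#'
#' Summarizes a subject's ROH segments as the fraction of the genome covered
#' by qualifying segments (those longer than \code{min_seg_bp}).
#'
#' @param subject_id Subject identifier.
#' @param segments Segment data.frame from [detect_roh()].
#' @param genome_size_bp Total genome size in bp (supplied, not inferred, so
#'   toy genomes remain testable).
#' @param min_seg_bp Segment length floor for the qualifying sum
#'   (default 3e6; strict \code{>}).
#' @return An object of class \code{homozygosity_profile} with fields
#'   \code{subject_id}, \code{segments}, \code{genome_size_bp},
#'   \code{fraction_in_roh}.
#' @export
homozygosity_profile <- function(subject_id, segments, genome_size_bp,
                                 min_seg_bp = 3e6) {
  if (!is.finite(genome_size_bp) || genome_size_bp <= 0) {
    stop("genome_size_bp must be positive")
  }
  qual <- segments$length_bp > min_seg_bp
  structure(list(subject_id = subject_id,
                 segments = segments,
                 genome_size_bp = genome_size_bp,
                 min_seg_bp = min_seg_bp,
                 fraction_in_roh = sum(segments$length_bp[qual]) / genome_size_bp),
            class = "homozygosity_profile")
}

#' Consanguinity flag from a homozygosity profile
#'
#' Applies the study decision rule: a subject is flagged when segments
#' longer than \code{min_seg_bp} (default 3 Mb) cover more than
#' \code{min_fraction} (default 3\%) of the genome. Both comparisons are
#' strict, following the printed wording; the 3\%/3 Mb level roughly
#' corresponds to second-cousin parental relatedness. Known first or
#' second-cousin parentage recorded in a pedigree is combined with this
#' computed flag by logical OR (argument \code{known_consanguineous}),
#' mirroring the combined definition used in the study.
#'
#' @param profile A [homozygosity_profile()].
#' @param min_seg_bp Qualifying segment length floor in bp (default 3e6).
#' @param min_fraction Genome fraction that must be exceeded (default 0.03).
#' @param known_consanguineous Optional logical: pedigree-known first or
#'   second cousin parents.
#' @return Logical flag.
#' @export
consanguinity_flag <- function(profile, min_seg_bp = 3e6, min_fraction = 0.03,
                               known_consanguineous = FALSE) {
  stopifnot(inherits(profile, "homozygosity_profile"))
  if (profile$genome_size_bp <= 0) stop("genome size must be positive")
  qual <- profile$segments$length_bp > min_seg_bp
  frac <- sum(profile$segments$length_bp[qual]) / profile$genome_size_bp
  isTRUE(known_consanguineous) || frac > min_fraction
}

#' Write ROH segments as BED
#'
#' Converts the 1-based inclusive segment coordinates to BED's 0-based
#' half-open convention (start-1, end) and writes one line per segment with
#' the subject id in the name column.
#'
#' @param segments Segment data.frame from [detect_roh()], optionally with a
#'   \code{subject_id} column.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  name <- if ("subject_id" %in% names(segments)) segments$subject_id else "."
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end,
                    name = name,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
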