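#' Per-marker segregation classes
#'
#' Classifies every marker of one chromosome by its parental allele counts
#' among the four spores: `S22` (2:2), `S31`/`S13` (3:1 toward parent 1 /
#' parent 2), `S40`/`S04` (4:0), or `INCOMPLETE` when any spore call is
#' missing. The class is a pure function of the four calls.
#'
#' @param t a [tetrad_genotypes()] object.
#' @param chrom chromosome id.
#' @return A data.frame with columns `pos` and `class`.
#' @export
segregation_profile <- function(t, chrom) {
  idx <- .chrom_marker_index(t$map, chrom)
  if (length(idx) == 0L) stop("chromosome not in map: ", chrom)
  m <- t$calls[, idx, drop = FALSE]
  n_na <- colSums(is.na(m))
  n1 <- colSums(m == 1L, na.rm = TRUE)
  cls <- rep("INCOMPLETE", length(idx))
  ok <- n_na == 0L
  cls[ok & n1 == 2L] <- "S22"
  cls[ok & n1 == 3L] <- "S31"
  cls[ok & n1 == 1L] <- "S13"
  cls[ok & n1 == 4L] <- "S40"
  cls[ok & n1 == 0L] <- "S04"
  data.frame(pos = t$map$markers$pos[idx], class = cls,
             stringsAsFactors = FALSE)
}

# empty tract table (schema in one place)
.empty_tracts <- function() {
  data.frame(chrom = character(), chromatids = character(),
             direction = character(), first = numeric(), last = numeric(),
             min_start = numeric(), min_end = numeric(),
             mid_start = numeric(), mid_end = numeric(),
             max_start = numeric(), max_end = numeric(),
             n_markers = integer(), stringsAsFactors = FALSE)
}

.empty_breakpoints <- function() {
  data.frame(chrom = character(), spore_a = integer(), spore_b = integer(),
             start = numeric(), end = numeric(), stringsAsFactors = FALSE)
}

.empty_complex <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             n_changed = integer(), note = character(),
             stringsAsFactors = FALSE)
}

#' Call gene-conversion tracts on one chromosome
#'
#' A tract is a maximal run of same-direction non-2:2 segregation involving a
#' fixed set of converted chromatids (one chromatid for 3:1, two for 4:0).
#' Markers with missing calls bridge a run but never start or end one, so
#' missing data cannot fabricate discontinuities. A run is split wherever the
#' converted chromatid set or the conversion direction changes; tandem tracts
#' separated by 2:2 markers are reported separately (their merging is the job
#' of event grouping).
#'
#' Three span conventions are reported per tract: the minimal span (first to
#' last converted marker), the maximal span (out to the nearest flanking
#' non-converted markers) and the midpoint span (midpoints of the two
#' flanking intervals). Length statistics downstream use the midpoint span.
#'
#' @param t a [tetrad_genotypes()] object.
#' @param chrom chromosome id.
#' @param min_markers minimum number of converted markers supporting a tract
#'   (default 1: single-marker conversions are real events at typical marker
#'   resolution).
#' @return A data.frame of tracts; `chromatids` is a comma-separated spore
#'   index set, `direction` the parent the tract converts toward.
#' @export
call_tracts <- function(t, chrom, min_markers = 1L) {
  prof <- segregation_profile(t, chrom)
  idx <- .chrom_marker_index(t$map, chrom)
  pos <- prof$pos
  cls <- prof$class
  n <- length(pos)
  chrom_len <- t$map$chromosomes$length[t$map$chromosomes$chrom == chrom]

  non22 <- cls %in% c("S31", "S13", "S40", "S04")
  out <- .empty_tracts()
  if (!any(non22)) return(out)

  cand <- non22 | cls == "INCOMPLETE"
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  calls <- t$calls[, idx, drop = FALSE]
  complete22 <- cls == "S22"

  rows <- list()
  for (b in which(r$values)) {
    i0 <- starts[b]; i1 <- ends[b]
    # trim INCOMPLETE edges: runs must start and end on converted markers
    while (i0 <= i1 && !non22[i0]) i0 <- i0 + 1L
    while (i1 >= i0 && !non22[i1]) i1 <- i1 - 1L
    if (i0 > i1) next
    run <- i0:i1
    run <- run[non22[run]]

    # anchor phase at the nearest fully-typed 2:2 marker outside the run
    left22 <- which(complete22[seq_len(i0 - 1L)])
    right_rel <- which(complete22[seq.int(i1 + 1L, length.out = n - i1)])
    anchor <- if (length(left22)) max(left22)
              else if (length(right_rel)) i1 + right_rel[1L]
              else NA_integer_
    if (is.na(anchor)) next  # whole chromosome non-2:2: nothing callable
    phase <- calls[, anchor]

    dir_m <- ifelse(cls[run] %in% c("S31", "S40"), "P1", "P2")
    conv_key <- vapply(run, function(j) {
      conv <- which(!is.na(calls[, j]) & calls[, j] != phase)
      paste(conv, collapse = ",")
    }, character(1))
    key <- paste(dir_m, conv_key)
    seg <- rle(key)
    seg_end <- cumsum(seg$lengths)
    seg_start <- seg_end - seg$lengths + 1L
    for (s in seq_along(seg$lengths)) {
      mks <- run[seg_start[s]:seg_end[s]]
      if (length(mks) < min_markers) next
      ck <- conv_key[seg_start[s]]
      if (ck == "") next  # call equals anchor phase: unphaseable oddity
      first <- pos[mks[1L]]
      last <- pos[mks[length(mks)]]
      # nearest markers outside the tract (any class) bound the max span
      lmk <- if (mks[1L] > 1L) pos[mks[1L] - 1L] else 1
      rmk <- if (mks[length(mks)] < n) pos[mks[length(mks)] + 1L]
             else chrom_len
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, chromatids = ck,
        direction = dir_m[seg_start[s]],
        first = first, last = last,
        min_start = first, min_end = last,
        mid_start = (lmk + first) / 2, mid_end = (last + rmk) / 2,
        max_start = lmk, max_end = rmk,
        n_markers = length(mks), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else out
}

#' Call crossover breakpoints on one chromosome
#'
#' Crossovers are persistent reciprocal phase switches between two spores.
#' Phase blocks are extracted over the fully typed 2:2 markers only, which
#' masks conversion tracts by construction (their markers are non-2:2), so a
#' conversion tract is never miscalled as a pair of crossovers. A change in
#' the 2:2 configuration in which exactly two spores swap parental origin
#' yields one breakpoint whose interval runs from the last marker of the old
#' phase to the first marker of the new phase. Any other configuration change
#' (e.g. four spores changing at once) is reported as a complex region, never
#' silently dropped.
#'
#' @param t a [tetrad_genotypes()] object.
#' @param chrom chromosome id.
#' @param min_phase_markers minimum number of consecutive 2:2 markers a new
#'   phase must hold to be believed; shorter internal blocks flanked by one
#'   identical phase on both sides are treated as unsupported and removed
#'   (default 1: every switch is believed).
#' @return A list with data.frames `breakpoints` (`spore_a` < `spore_b` are
#'   the exchanging chromatids) and `complex`.
#' @export
call_crossovers <- function(t, chrom, min_phase_markers = 1L) {
  prof <- segregation_profile(t, chrom)
  idx <- .chrom_marker_index(t$map, chrom)
  keep <- prof$class == "S22"
  bps <- .empty_breakpoints()
  cpx <- .empty_complex()
  if (sum(keep) < 2L)
    return(list(breakpoints = bps, complex = cpx))
  pos <- prof$pos[keep]
  m <- t$calls[, idx[keep], drop = FALSE]

  tuple <- paste(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
  if (min_phase_markers > 1L) {
    # drop unsupported internal blocks sandwiched by one identical phase
    r <- rle(tuple)
    nb <- length(r$lengths)
    dropb <- rep(FALSE, nb)
    for (b in seq_len(nb)) {
      if (b > 1L && b < nb && r$lengths[b] < min_phase_markers &&
          r$values[b - 1L] == r$values[b + 1L])
        dropb[b] <- TRUE
    }
    if (any(dropb)) {
      keep2 <- rep(!dropb, r$lengths)
      pos <- pos[keep2]
      m <- m[, keep2, drop = FALSE]
      tuple <- tuple[keep2]
    }
  }

  chg <- which(tuple[-length(tuple)] != tuple[-1L])
  for (j in chg) {
    dspore <- which(m[, j] != m[, j + 1L])
    if (length(dspore) == 2L) {
      bps <- rbind(bps, data.frame(
        chrom = chrom, spore_a = dspore[1L], spore_b = dspore[2L],
        start = pos[j], end = pos[j + 1L], stringsAsFactors = FALSE))
    } else {
      cpx <- rbind(cpx, data.frame(
        chrom = chrom, start = pos[j], end = pos[j + 1L],
        n_changed = length(dspore),
        note = "non-reciprocal 2:2 phase change", stringsAsFactors = FALSE))
    }
  }
  list(breakpoints = bps, complex = cpx)
}

#' Infer sister-chromatid pairing per chromosome
#'
#' For each chromosome, the two spores sharing the parental allele at the
#' fully typed 2:2 marker nearest the centromere are sisters (centromeres
#' segregate with the chromatid, so centromere-linked parental origin
#' identifies the two chromatids copied from the same homolog). If the map
#' carries no centromere for a chromosome, or no fully typed 2:2 marker
#' exists, sisterhood is undefined there (`NA`), which disables the E5B2/E5B3
#' distinction downstream.
#'
#' @param t a [tetrad_genotypes()] object.
#' @return An integer matrix, 4 spores x chromosomes: pair label 1 or 2
#'   (spore 1's pair is labelled 1), or `NA` when undefined.
#' @export
infer_sisterhood <- function(t) {
  chroms <- t$map$chromosomes
  out <- matrix(NA_integer_, nrow = 4L, ncol = nrow(chroms),
                dimnames = list(t$spores, chroms$chrom))
  for (ci in seq_len(nrow(chroms))) {
    cen <- chroms$centromere[ci]
    if (is.na(cen)) next
    prof <- segregation_profile(t, chroms$chrom[ci])
    ok <- prof$class == "S22"
    if (!any(ok)) next
    pick <- which(ok)[which.min(abs(prof$pos[ok] - cen))]
    idx <- .chrom_marker_index(t$map, chroms$chrom[ci])
    calls <- t$calls[, idx[pick]]
    out[, ci] <- ifelse(calls == calls[1L], 1L, 2L)
  }
  out
}
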