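# chromatid sets are comma-separated spore indices; masks are 4-bit integers
.chromatid_mask <- function(s) {
  vapply(strsplit(s, ",", fixed = TRUE), function(x)
    sum(bitwShiftL(1L, as.integer(x) - 1L)), integer(1))
}

.mask_to_string <- function(mask) {
  vapply(mask, function(m)
    paste(which(bitwAnd(m, bitwShiftL(1L, 0:3)) > 0L), collapse = ","),
    character(1))
}

.mask_size <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:3)) > 0L),
         integer(1))
}

#' Number of chromatids involved in an event
#'
#' The size of the union of the member chromatid sets: each breakpoint
#' contributes its two exchanging chromatids, each tract its one (3:1) or two
#' (4:0) converted chromatids.
#'
#' @param tracts member tracts (data.frame as from [call_tracts()]).
#' @param breakpoints member breakpoints (as from [call_crossovers()]).
#' @return Integer in 1..4.
#' @export
count_chromatids <- function(tracts, breakpoints) {
  mask <- 0L
  if (nrow(tracts))
    mask <- bitwOr(mask, Reduce(bitwOr, .chromatid_mask(tracts$chromatids)))
  if (nrow(breakpoints))
    mask <- bitwOr(mask, Reduce(bitwOr, bitwOr(
      bitwShiftL(1L, breakpoints$spore_a - 1L),
      bitwShiftL(1L, breakpoints$spore_b - 1L))))
  .mask_size(mask)
}

# nearest-edge gap between [s1,e1] and [s2,e2]; <= 0 means touch/overlap
.edge_gap <- function(s1, e1, s2, e2) pmax(s1 - e2, s2 - e1)

#' Classify one grouped recombination event
#'
#' Assigns the E1-E7 label from the member breakpoints and tracts:
#' \itemize{
#' \item E1 simple noncrossover: one 3:1 tract, one chromatid, no breakpoint;
#' \item E2 simple crossover: one breakpoint, any conversion tracts contiguous
#'   with the breakpoint interval, two chromatids;
#' \item E3 crossover with discontinuous conversion: one breakpoint plus at
#'   least one tract on the crossover chromatids separated from it by 2:2
#'   markers;
#' \item E4 discontinuous noncrossover: two or more tandem tracts on one
#'   chromatid separated by 2:2 segregation;
#' \item E5 two-chromatid multi-unit events, subtyped by [classify_e5()];
#' \item E6 / E7 events involving three / four chromatids.
#' }
#' A configuration outside the table is labelled `"unclassified"` rather than
#' silently binned.
#'
#' @param tracts member tract rows.
#' @param breakpoints member breakpoint rows.
#' @param sisterhood integer vector of length 4 giving the sister-pair label
#'   of each spore for this chromosome (see [infer_sisterhood()]), or `NULL`.
#' @param e5a_require_opposite_direction require opposite conversion
#'   directions for the overlapping-tract form of E5A (default `TRUE`; the
#'   expected signature of unbiased double-Holliday-junction resolution).
#' @return The class label (character scalar).
#' @export
classify_event <- function(tracts, breakpoints, sisterhood = NULL,
                           e5a_require_opposite_direction = TRUE) {
  n_chr <- count_chromatids(tracts, breakpoints)
  n_bp <- nrow(breakpoints)
  n_tr <- nrow(tracts)
  if (n_chr == 1L) {
    if (n_bp == 0L && n_tr == 1L) return("E1")
    if (n_bp == 0L && n_tr >= 2L) return("E4")
    return("unclassified")
  }
  if (n_chr == 3L) return("E6")
  if (n_chr == 4L) return("E7")
  # two chromatids
  if (n_bp == 1L) {
    if (n_tr == 0L) return("E2")
    gap <- .edge_gap(tracts$mid_start, tracts$mid_end,
                     breakpoints$start, breakpoints$end)
    return(if (all(gap <= 0)) "E2" else "E3")
  }
  if (n_bp >= 2L || n_tr >= 1L)
    return(classify_e5(tracts, breakpoints, sisterhood,
                       e5a_require_opposite_direction))
  "unclassified"
}

#' Subtype a two-chromatid multi-unit (E5) event
#'
#' \itemize{
#' \item E5A: the signature of unbiased double-Holliday-junction resolution.
#'   Two observational forms are recognised: (i) exactly two reciprocal
#'   breakpoints between the same pair of non-sister chromatids (the
#'   "apparent double crossover" appearance, produced when the converted
#'   region between the two junctions carries informative markers and is
#'   therefore seen as a phase swap), and (ii) exactly two noncrossover
#'   tracts on non-sister chromatids with overlapping footprints and, by
#'   default, opposite conversion directions (the appearance when the overlap
#'   carries no informative marker).
#' \item E5B1: two non-sister noncrossover tracts, non-overlapping.
#' \item E5B2: noncrossovers confined to a pair of sister chromatids
#'   (including a single 4:0 tract).
#' \item E5B3: every other two-chromatid configuration (triple crossovers,
#'   crossover-noncrossover mixtures, ...), and any event whose chromosome
#'   has undefined sisterhood.
#' }
#'
#' @inheritParams classify_event
#' @return One of `"E5A"`, `"E5B1"`, `"E5B2"`, `"E5B3"`.
#' @export
classify_e5 <- function(tracts, breakpoints, sisterhood = NULL,
                        e5a_require_opposite_direction = TRUE) {
  n_bp <- nrow(breakpoints)
  sis_of <- function(i, j) {
    if (is.null(sisterhood)) return(NA)
    si <- sisterhood[i]; sj <- sisterhood[j]
    if (is.na(si) || is.na(sj)) return(NA)
    si == sj
  }
  if (n_bp == 2L) {
    pair1 <- sort(c(breakpoints$spore_a[1L], breakpoints$spore_b[1L]))
    pair2 <- sort(c(breakpoints$spore_a[2L], breakpoints$spore_b[2L]))
    if (identical(pair1, pair2)) {
      sis <- sis_of(pair1[1L], pair1[2L])
      if (is.na(sis)) return("E5B3")
      if (!sis) return("E5A")
    }
    return("E5B3")
  }
  if (n_bp == 0L && nrow(tracts)) {
    single <- !grepl(",", tracts$chromatids, fixed = TRUE)
    if (nrow(tracts) == 2L && all(single) &&
        tracts$chromatids[1L] != tracts$chromatids[2L]) {
      i <- as.integer(tracts$chromatids[1L])
      j <- as.integer(tracts$chromatids[2L])
      sis <- sis_of(i, j)
      if (is.na(sis)) return("E5B3")
      if (sis) return("E5B2")
      overlap <- tracts$mid_start[1L] < tracts$mid_end[2L] &&
        tracts$mid_start[2L] < tracts$mid_end[1L]
      opposite <- tracts$direction[1L] != tracts$direction[2L]
      if (overlap && (opposite || !e5a_require_opposite_direction))
        return("E5A")
      if (!overlap) return("E5B1")
      return("E5B3")
    }
    # all conversion confined to one sister pair (e.g. a 4:0 tract)
    spores <- sort(unique(unlist(strsplit(tracts$chromatids, ",",
                                          fixed = TRUE))))
    spores <- as.integer(spores)
    if (length(spores) == 2L) {
      sis <- sis_of(spores[1L], spores[2L])
      if (is.na(sis)) return("E5B3")
      if (sis) return("E5B2")
    }
  }
  "E5B3"
}

#' Group tracts and breakpoints into recombination events
#'
#' Members on the same chromosome whose footprints lie within `cutoff_bp` of
#' each other (nearest-edge distance; overlap counts as distance 0) are
#' merged into one event by transitive closure: the events are the connected
#' components of the proximity graph. Tract footprints use the midpoint-span
#' convention; breakpoint footprints are their marker-bounded uncertainty
#' intervals. Each event is then classified (see [classify_event()]).
#'
#' @param tracts tract table from [call_tracts()] (any number of
#'   chromosomes).
#' @param breakpoints breakpoint table from [call_crossovers()].
#' @param cutoff_bp grouping distance in bp (default 5000; inclusive:
#'   a gap of exactly `cutoff_bp` merges). Must be >= 0.
#' @param sisterhood sisterhood matrix from [infer_sisterhood()] (spores x
#'   chromosomes), or `NULL` to disable sister-dependent subtypes.
#' @param e5a_require_opposite_direction passed to [classify_event()].
#' @return An object of class `recomb_events`: a list with the classified
#'   `events` table, the member `tracts` and `breakpoints` tables (each
#'   gaining an `event_id` column), `cutoff_bp` and `sisterhood`.
#' @export
group_events <- function(tracts, breakpoints, cutoff_bp = 5000,
                         sisterhood = NULL,
                         e5a_require_opposite_direction = TRUE) {
  if (length(cutoff_bp) != 1L || is.na(cutoff_bp) || cutoff_bp < 0)
    stop("cutoff_bp must be a single non-negative number")
  if (is.null(tracts) || nrow(tracts) == 0L) tracts <- .empty_tracts()
  if (is.null(breakpoints) || nrow(breakpoints) == 0L)
    breakpoints <- .empty_breakpoints()

  mem <- rbind(
    if (nrow(tracts)) data.frame(
      type = "tract", row = seq_len(nrow(tracts)), chrom = tracts$chrom,
      start = tracts$mid_start, end = tracts$mid_end,
      mask = .chromatid_mask(tracts$chromatids), stringsAsFactors = FALSE),
    if (nrow(breakpoints)) data.frame(
      type = "breakpoint", row = seq_len(nrow(breakpoints)),
      chrom = breakpoints$chrom,
      start = breakpoints$start, end = breakpoints$end,
      mask = bitwOr(bitwShiftL(1L, breakpoints$spore_a - 1L),
                    bitwShiftL(1L, breakpoints$spore_b - 1L)),
      stringsAsFactors = FALSE)
  )
  tracts$event_id <- integer(nrow(tracts))
  breakpoints$event_id <- integer(nrow(breakpoints))
  ev_rows <- list()
  eid <- 0L
  if (!is.null(mem) && nrow(mem)) {
    for (ch in unique(mem$chrom)) {
      sub <- mem[mem$chrom == ch, , drop = FALSE]
      o <- order(sub$start, sub$end)
      sub <- sub[o, , drop = FALSE]
      run_end <- -Inf
      comp <- integer(nrow(sub))
      for (i in seq_len(nrow(sub))) {
        if (sub$start[i] - run_end > cutoff_bp) eid <- eid + 1L
        comp[i] <- eid
        run_end <- max(run_end, sub$end[i])
      }
      sis <- if (!is.null(sisterhood) && ch %in% colnames(sisterhood))
        sisterhood[, ch] else NULL
      for (e in unique(comp)) {
        rows <- sub[comp == e, , drop = FALSE]
        tr <- tracts[rows$row[rows$type == "tract"], , drop = FALSE]
        bp <- breakpoints[rows$row[rows$type == "breakpoint"], , drop = FALSE]
        tracts$event_id[rows$row[rows$type == "tract"]] <- e
        breakpoints$event_id[rows$row[rows$type == "breakpoint"]] <- e
        mask <- Reduce(bitwOr, rows$mask)
        cls <- classify_event(tr, bp, sis, e5a_require_opposite_direction)
        flag <- if (cls %in% c("E5A", "E5B1", "E5B2", "E5B3") &&
                    (is.null(sis) || anyNA(sis)))
          "sisterhood_undefined" else ""
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          event_id = e, chrom = ch,
          start = min(rows$start), end = max(rows$end),
          n_breakpoints = nrow(bp), n_tracts = nrow(tr),
          chromatids = .mask_to_string(mask), n_chromatids = .mask_size(mask),
          mask = mask, class = cls, is_co = nrow(bp) > 0L, flag = flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = integer(), chrom = character(), start = numeric(),
               end = numeric(), n_breakpoints = integer(),
               n_tracts = integer(), chromatids = character(),
               n_chromatids = integer(), mask = integer(),
               class = character(), is_co = logical(), flag = character(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  structure(list(events = events, tracts = tracts,
                 breakpoints = breakpoints, cutoff_bp = cutoff_bp,
                 sisterhood = sisterhood),
            class = "recomb_events")
}

#' Call, group and classify all recombination events of one tetrad
#'
#' Runs the full per-tetrad pipeline: segregation profiling, tract and
#' crossover calling on every chromosome, sisterhood inference, proximity
#' grouping and E1-E7 classification.
#'
#' @param t a [tetrad_genotypes()] object.
#' @param cutoff_bp event-grouping distance (default 5000 bp).
#' @param min_tract_markers passed to [call_tracts()].
#' @param min_phase_markers passed to [call_crossovers()].
#' @param e5a_require_opposite_direction passed to [classify_event()].
#' @return A `recomb_events` object; additionally carries the tetrad id and
#'   any complex (unphaseable) regions.
#' @examples
#' p <- sim_params(genome = test_genome(), n_markers = 2000,
#'                 co_mean = 6, nco_mean = 4)
#' sim <- simulate_meiosis(p, seed = 1)
#' ev <- call_recombination(sim$tetrad)
#' table(ev$events$class)
#' @export
call_recombination <- function(t, cutoff_bp = 5000, min_tract_markers = 1L,
                               min_phase_markers = 1L,
                               e5a_require_opposite_direction = TRUE) {
  stopifnot(inherits(t, "tetrad_genotypes"))
  chroms <- t$map$chromosomes$chrom
  tr <- list(); bp <- list(); cx <- list()
  for (ch in chroms) {
    tr[[ch]] <- call_tracts(t, ch, min_markers = min_tract_markers)
    co <- call_crossovers(t, ch, min_phase_markers = min_phase_markers)
    bp[[ch]] <- co$breakpoints
    cx[[ch]] <- co$complex
  }
  sis <- infer_sisterhood(t)
  out <- group_events(do.call(rbind, tr), do.call(rbind, bp),
                      cutoff_bp = cutoff_bp, sisterhood = sis,
                      e5a_require_opposite_direction =
                        e5a_require_opposite_direction)
  out$tetrad <- t$tetrad
  out$complex <- do.call(rbind, cx)
  rownames(out$tracts) <- NULL
  rownames(out$breakpoints) <- NULL
  out
}

#' @export
print.recomb_events <- function(x, ...) {
  cat("recomb_events",
      if (!is.null(x$tetrad)) paste0("(tetrad '", x$tetrad, "')"), "\n")
  cat("  ", nrow(x$events), " events from ", nrow(x$tracts), " tracts and ",
      nrow(x$breakpoints), " breakpoints (cutoff ", x$cutoff_bp, " bp)\n",
      sep = "")
  if (nrow(x$events)) print(table(class = x$events$class))
  invisible(x)
}

#' @export
plot.recomb_events <- function(x, chrom = NULL, ...) {
  ev <- x$events
  if (!nrow(ev)) {
    warning("no events to plot")
    return(invisible(x))
  }
  if (is.null(chrom)) chrom <- ev$chrom[1L]
  ev <- ev[ev$chrom == chrom, , drop = FALSE]
  cls <- c("E1", "E2", "E3", "E4", "E5A", "E5B1", "E5B2", "E5B3", "E6", "E7",
           "unclassified")
  col <- stats::setNames(grDevices::hcl.colors(length(cls), "Dark 3"), cls)
  graphics::plot(NA, xlim = range(c(ev$start, ev$end)), ylim = c(0.5, 4.5),
                 xlab = paste0("position on ", chrom, " (bp)"),
                 ylab = "chromatid", yaxt = "n", ...)
  graphics::axis(2, at = 1:4)
  for (i in seq_len(nrow(ev))) {
    spores <- as.integer(strsplit(ev$chromatids[i], ",")[[1L]])
    graphics::segments(ev$start[i], spores, ev$end[i], spores,
                       lwd = 3, col = col[ev$class[i]])
  }
  graphics::legend("topright", legend = names(col), col = col, lwd = 3,
                   cex = 0.6, bty = "n")
  invisible(x)
}

#' Length components of a discontinuous event
#'
#' For an event with tandem conversion tracts (E3/E4-style), returns the
#' whole-event length (footprint span), the individual tract lengths
#' (midpoint-span convention) and the 2:2 gap lengths between consecutive
#' tracts on the same chromatid set.
#'
#' @param x a `recomb_events` object.
#' @param event_id the event to decompose.
#' @return A list with `event_length`, `tract_lengths`, `gap_lengths`.
#' @export
discontinuity_components <- function(x, event_id) {
  ev <- x$events[x$events$event_id == event_id, , drop = FALSE]
  if (nrow(ev) != 1L) stop("unknown event_id: ", event_id)
  tr <- x$tracts[x$tracts$event_id == event_id, , drop = FALSE]
  gaps <- numeric(0)
  if (nrow(tr) > 1L) {
    for (cc in unique(tr$chromatids)) {
      sub <- tr[tr$chromatids == cc, , drop = FALSE]
      if (nrow(sub) < 2L) next
      sub <- sub[order(sub$mid_start), , drop = FALSE]
      gaps <- c(gaps, sub$mid_start[-1L] - sub$mid_end[-nrow(sub)])
    }
  }
  list(event_length = ev$end - ev$start,
       tract_lengths = tr$mid_end - tr$mid_start,
       gap_lengths = gaps)
}

#' Discontinuity components for all multi-tract events
#'
#' @param x a `recomb_events` object.
#' @return A data.frame with one row per event having >= 2 tracts on one
#'   chromatid set: `event_id`, `class`, `event_length`, `n_tracts`,
#'   `median_tract`, `median_gap`.
#' @export
discontinuity_table <- function(x) {
  ids <- x$events$event_id[x$events$n_tracts >= 2L]
  rows <- lapply(ids, function(id) {
    d <- discontinuity_components(x, id)
    if (length(d$gap_lengths) == 0L) return(NULL)
    data.frame(event_id = id,
               class = x$events$class[x$events$event_id == id],
               event_length = d$event_length,
               n_tracts = length(d$tract_lengths),
               median_tract = stats::median(d$tract_lengths),
               median_gap = stats::median(d$gap_lengths),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(), class = character(),
               event_length = numeric(), n_tracts = integer(),
               median_tract = numeric(), median_gap = numeric(),
               stringsAsFactors = FALSE)
}

# vectorised adjacency walk used by both the user-facing distance table and
# the randomization inner loop; returns list of 4 numeric distance vectors
.adjacent_distances <- function(chrom, start, end, is_co, mask) {
  cats <- list(`NCO-NCO same` = numeric(0), `NCO-NCO different` = numeric(0),
               `CO-NCO same` = numeric(0), `CO-NCO different` = numeric(0))
  if (length(chrom) < 2L) return(cats)
  o <- order(chrom, start, end)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  is_co <- is_co[o]; mask <- mask[o]
  n <- length(chrom)
  i <- seq_len(n - 1L); j <- i + 1L
  same_chrom <- chrom[i] == chrom[j]
  keep <- same_chrom & !(is_co[i] & is_co[j])
  if (!any(keep)) return(cats)
  i <- i[keep]; j <- j[keep]
  d <- pmax(0, start[j] - end[i])
  both_nco <- !is_co[i] & !is_co[j]
  same <- bitwAnd(mask[i], mask[j]) > 0L
  cats[["NCO-NCO same"]] <- d[both_nco & same]
  cats[["NCO-NCO different"]] <- d[both_nco & !same]
  cats[["CO-NCO same"]] <- d[!both_nco & same]
  cats[["CO-NCO different"]] <- d[!both_nco & !same]
  cats
}

#' Distances between adjacent events, by category
#'
#' Walks each chromosome in genome order and measures the nearest-edge
#' distance between consecutive events, assigning each adjacent pair to one
#' of four categories: noncrossover pairs on the same or on different
#' chromatids, and crossover-noncrossover pairs on the same or on different
#' chromatids ("same chromatid" means the chromatid sets intersect).
#' Crossover-crossover adjacencies are not categorised.
#'
#' @param x a `recomb_events` object, a list of them (a cohort; distances are
#'   pooled), or a plain events data.frame with columns `chrom`, `start`,
#'   `end`, `is_co`, `mask`.
#' @return A data.frame with columns `category` and `distance`.
#' @export
inter_event_distances <- function(x) {
  evs <- if (inherits(x, "recomb_events")) list(x$events)
         else if (is.data.frame(x)) list(x)
         else lapply(x, function(e)
           if (inherits(e, "recomb_events")) e$events else e)
  pooled <- list(`NCO-NCO same` = numeric(0),
                 `NCO-NCO different` = numeric(0),
                 `CO-NCO same` = numeric(0), `CO-NCO different` = numeric(0))
  for (ev in evs) {
    if (!nrow(ev)) next
    cats <- .adjacent_distances(ev$chrom, ev$start, ev$end, ev$is_co,
                                ev$mask)
    for (k in names(pooled)) pooled[[k]] <- c(pooled[[k]], cats[[k]])
  }
  data.frame(
    category = rep(names(pooled), lengths(pooled)),
    distance = unlist(pooled, use.names = FALSE),
    stringsAsFactors = FALSE)
}
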