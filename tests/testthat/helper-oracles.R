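# Independent oracles, coded directly from the event-taxonomy definitions
# and kept deliberately naive (brute force, no shared code with the package
# internals).

# transitive-closure grouping via explicit pairwise gap graph
oracle_group_ids <- function(chrom, start, end, cutoff) {
  n <- length(chrom)
  if (n == 0L) return(integer(0))
  gap <- pmax(outer(start, end, "-"), t(outer(start, end, "-")))
  ok <- gap <= cutoff & outer(chrom, chrom, "==") & upper.tri(gap)
  edges <- which(ok, arr.ind = TRUE)
  edges <- if (nrow(edges)) cbind(edges[, 2L], edges[, 1L]) else NULL
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = integer(), to = integer())
        else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(seq_len(n))])
}

# rule-table classifier: members described as a list of
# list(type = "bp"/"tract", chromatids = int vector, start, end, direction)
oracle_classify <- function(members, sisters = c(1L, 1L, 2L, 2L),
                            require_opposite = TRUE) {
  chromatids <- sort(unique(unlist(lapply(members, `[[`, "chromatids"))))
  k <- length(chromatids)
  bps <- Filter(function(m) m$type == "bp", members)
  trs <- Filter(function(m) m$type == "tract", members)
  nb <- length(bps); nt <- length(trs)
  is_sis <- function(i, j) sisters[i] == sisters[j]

  if (k == 1L) {
    if (nb == 0L && nt == 1L) return("E1")
    if (nb == 0L && nt >= 2L) return("E4")
    return("unclassified")
  }
  if (k == 3L) return("E6")
  if (k == 4L) return("E7")
  # two chromatids
  if (nb == 1L) {
    if (nt == 0L) return("E2")
    sep <- vapply(trs, function(t)
      max(t$start - bps[[1]]$end, bps[[1]]$start - t$end) > 0, logical(1))
    return(if (any(sep)) "E3" else "E2")
  }
  # E5 bucket
  if (nb == 2L) {
    p1 <- sort(bps[[1]]$chromatids); p2 <- sort(bps[[2]]$chromatids)
    if (identical(p1, p2) && !is_sis(p1[1], p1[2])) return("E5A")
    return("E5B3")
  }
  if (nb == 0L) {
    if (nt == 2L && length(trs[[1]]$chromatids) == 1L &&
        length(trs[[2]]$chromatids) == 1L &&
        trs[[1]]$chromatids != trs[[2]]$chromatids) {
      i <- trs[[1]]$chromatids; j <- trs[[2]]$chromatids
      if (is_sis(i, j)) return("E5B2")
      ov <- trs[[1]]$start < trs[[2]]$end && trs[[2]]$start < trs[[1]]$end
      opp <- trs[[1]]$direction != trs[[2]]$direction
      if (ov && (opp || !require_opposite)) return("E5A")
      if (!ov) return("E5B1")
      return("E5B3")
    }
    if (k == 2L && is_sis(chromatids[1], chromatids[2])) return("E5B2")
  }
  "E5B3"
}

# members list -> the package's tract / breakpoint tables
members_to_tables <- function(members, chrom = "chr1") {
  tr <- Filter(function(m) m$type == "tract", members)
  bp <- Filter(function(m) m$type == "bp", members)
  tracts <- if (length(tr)) do.call(rbind, lapply(tr, function(m)
    fix_tract(chrom = chrom,
              chromatids = paste(m$chromatids, collapse = ","),
              direction = m$direction, mid_start = m$start,
              mid_end = m$end))) else NULL
  bps <- if (length(bp)) do.call(rbind, lapply(bp, function(m)
    fix_breakpoint(chrom = chrom, spore_a = min(m$chromatids),
                   spore_b = max(m$chromatids), start = m$start,
                   end = m$end))) else NULL
  list(tracts = if (is.null(tracts)) meiorec:::.empty_tracts() else tracts,
       breakpoints = if (is.null(bps)) meiorec:::.empty_breakpoints()
                     else bps)
}

# brute-force adjacency categoriser: all pairs, keep genome-order neighbours
oracle_distances <- function(ev) {
  out <- data.frame(category = character(), distance = numeric(),
                    stringsAsFactors = FALSE)
  for (ch in unique(ev$chrom)) {
    sub <- ev[ev$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      j <- i + 1L
      if (sub$is_co[i] && sub$is_co[j]) next
      d <- max(0, sub$start[j] - sub$end[i])
      set_i <- strsplit(sub$chromatids[i], ",")[[1]]
      set_j <- strsplit(sub$chromatids[j], ",")[[1]]
      same <- length(intersect(set_i, set_j)) > 0
      kind <- if (!sub$is_co[i] && !sub$is_co[j]) "NCO-NCO" else "CO-NCO"
      cat <- paste(kind, if (same) "same" else "different")
      out <- rbind(out, data.frame(category = cat, distance = d,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
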