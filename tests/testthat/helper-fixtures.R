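# small hand-built maps and tetrads used across the unit tests

fix_map <- function(pos = c(1000, 2000, 3000), chrom = "chr1",
                    len = max(pos) + 1000, cen = round(len / 2)) {
  marker_map(
    data.frame(chrom = chrom, length = len, centromere = cen,
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom, pos = pos,
               allele_p1 = rep("A", length(pos)),
               allele_p2 = rep("G", length(pos)),
               stringsAsFactors = FALSE))
}

# calls given as character rows per spore, e.g. "1122" = P1,P1,P2,P2 ...
# columns are markers; "." = missing
fix_tet <- function(map, spore_strings, tetrad = "t1") {
  stopifnot(length(spore_strings) == 4L)
  m <- do.call(rbind, lapply(spore_strings, function(s) {
    v <- strsplit(s, "")[[1]]
    suppressWarnings(ifelse(v == ".", NA_integer_, as.integer(v)))
  }))
  tetrad_genotypes(tetrad, paste0("s", 1:4), m, map)
}

# minimal tract row with the span convention filled in directly
fix_tract <- function(chrom = "chr1", chromatids = "1", direction = "P1",
                      mid_start, mid_end, first = mid_start,
                      last = mid_end, n_markers = 2L) {
  data.frame(chrom = chrom, chromatids = chromatids, direction = direction,
             first = first, last = last, min_start = first, min_end = last,
             mid_start = mid_start, mid_end = mid_end,
             max_start = mid_start, max_end = mid_end,
             n_markers = n_markers, stringsAsFactors = FALSE)
}

fix_breakpoint <- function(chrom = "chr1", spore_a = 1L, spore_b = 3L,
                           start, end) {
  data.frame(chrom = chrom, spore_a = spore_a, spore_b = spore_b,
             start = start, end = end, stringsAsFactors = FALSE)
}

# sisterhood vector: spores 1,2 sisters and 3,4 sisters
fix_sisters <- c(1L, 1L, 2L, 2L)

fast_params <- function(mode = "wt", ...) {
  sim_params(mode = mode, genome = test_genome(), n_markers = 4000, ...)
}
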