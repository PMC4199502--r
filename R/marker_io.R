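#' Construct a marker map
#'
#' A marker map holds the genotypable biallelic SNP positions of a hybrid
#' cross, together with the chromosome sizes and centromere positions used
#' downstream for sister-chromatid inference. Marker positions are 1-based;
#' interval output (BED) is converted to 0-based half-open coordinates at the
#' I/O boundary only.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`, `centromere`.
#'   Centromere positions are required metadata: without them sister-chromatid
#'   inference (and hence the E5B2 subclass) is disabled.
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp),
#'   `allele_p1`, `allele_p2`. Positions must be unique within a chromosome;
#'   markers whose two parental alleles are identical are uninformative and
#'   are dropped with a warning.
#' @return An object of class `marker_map`: a list with elements
#'   `chromosomes` and `markers` (markers sorted by chromosome, position).
#' @export
marker_map <- function(chromosomes, markers) {
  need_chr <- c("chrom", "length")
  if (!all(need_chr %in% names(chromosomes)))
    stop("chromosomes table needs columns: ", paste(need_chr, collapse = ", "))
  if (is.null(chromosomes$centromere)) {
    warning("marker map has no centromere positions; ",
            "sisterhood inference and E5B2 subclassification are disabled")
    chromosomes$centromere <- NA_real_
  }
  need_mk <- c("chrom", "pos", "allele_p1", "allele_p2")
  if (!all(need_mk %in% names(markers)))
    stop("markers table needs columns: ", paste(need_mk, collapse = ", "))
  if (nrow(markers) == 0L) stop("no markers")
  markers$chrom <- as.character(markers$chrom)
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (!all(markers$chrom %in% chromosomes$chrom))
    stop("markers reference chromosomes absent from the chromosome table")

  same <- markers$allele_p1 == markers$allele_p2
  if (any(same)) {
    warning(sum(same), " marker(s) with identical parental alleles dropped")
    markers <- markers[!same, , drop = FALSE]
  }
  if (nrow(markers) == 0L) stop("no markers")

  ord_chrom <- match(markers$chrom, chromosomes$chrom)
  o <- order(ord_chrom, markers$pos)
  if (is.unsorted(o)) warning("markers were not sorted by position; sorting")
  markers <- markers[o, , drop = FALSE]
  dup <- duplicated(paste(markers$chrom, markers$pos))
  if (any(dup)) stop("duplicate marker position(s): ",
                     paste(utils::head(paste(markers$chrom[dup],
                                             markers$pos[dup]), 3),
                           collapse = ", "))
  bad <- markers$pos < 1 |
    markers$pos > chromosomes$length[match(markers$chrom, chromosomes$chrom)]
  if (any(bad)) stop("marker position(s) outside chromosome bounds")
  cen_ok <- is.na(chromosomes$centromere) |
    (chromosomes$centromere >= 1 & chromosomes$centromere <= chromosomes$length)
  if (!all(cen_ok)) stop("centromere position outside chromosome bounds")

  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat("marker_map:", nrow(x$markers), "markers on",
      nrow(x$chromosomes), "chromosomes\n")
  cat("  genome size:", sum(x$chromosomes$length), "bp;",
      "mean marker spacing:",
      round(sum(x$chromosomes$length) / nrow(x$markers)), "bp\n")
  invisible(x)
}

# column index range of each chromosome's markers in map order
.chrom_marker_index <- function(map, chrom) {
  which(map$markers$chrom == chrom)
}

#' Read a marker map from a TSV file
#'
#' The file format is a tab-separated table with columns `chrom`, `pos`,
#' `allele_p1`, `allele_p2`, preceded by chromosome header lines of the form
#' `#chromosome <chrom> <length> <centromere>` (centromere may be `NA`).
#'
#' @param path path to the marker map TSV.
#' @return A validated [marker_map()].
#' @seealso [write_marker_map()]
#' @export
load_marker_map <- function(path) {
  if (!file.exists(path)) stop("marker map file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#chromosome\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) <= 1L) stop("no markers in ", path)
  if (length(hdr) == 0L) stop("no '#chromosome' header lines in ", path)
  hparts <- do.call(rbind, strsplit(hdr, "\t", fixed = TRUE))
  chromosomes <- data.frame(
    chrom = hparts[, 2L],
    length = as.numeric(hparts[, 3L]),
    centromere = suppressWarnings(as.numeric(hparts[, 4L])),
    stringsAsFactors = FALSE
  )
  markers <- utils::read.delim(text = paste(body, collapse = "\n"),
                               stringsAsFactors = FALSE)
  marker_map(chromosomes, markers)
}

#' Write a marker map to TSV
#'
#' @param map a [marker_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chromosome\t%s\t%s\t%s", map$chromosomes$chrom,
                     format(map$chromosomes$length, scientific = FALSE,
                            trim = TRUE),
                     map$chromosomes$centromere), con)
  utils::write.table(map$markers, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a tetrad genotype object
#'
#' Holds the parental-origin calls of the four spores of one meiosis over a
#' marker map. Calls are coded `1` (parent 1), `2` (parent 2) or `NA`
#' (missing). Missing calls are retained in the matrix so that tract-boundary
#' logic can bridge them rather than fabricating discontinuities.
#'
#' @param tetrad tetrad identifier.
#' @param spores character vector of 4 spore identifiers.
#' @param calls integer matrix, 4 rows (spores) x one column per map marker.
#' @param map the [marker_map()] the calls are keyed to.
#' @return An object of class `tetrad_genotypes`.
#' @export
tetrad_genotypes <- function(tetrad, spores, calls, map) {
  if (length(spores) != 4L) stop("tetrad requires 4 spores")
  if (!is.matrix(calls) || nrow(calls) != 4L)
    stop("calls must be a 4-row matrix")
  if (ncol(calls) != nrow(map$markers))
    stop("call matrix has ", ncol(calls), " columns but map has ",
         nrow(map$markers), " markers")
  if (!all(calls %in% c(1L, 2L) | is.na(calls)))
    stop("calls must be 1 (P1), 2 (P2) or NA (missing)")
  storage.mode(calls) <- "integer"
  rownames(calls) <- spores
  structure(list(tetrad = as.character(tetrad), spores = as.character(spores),
                 calls = calls, map = map),
            class = "tetrad_genotypes")
}

#' @export
print.tetrad_genotypes <- function(x, ...) {
  nm <- ncol(x$calls)
  cat("tetrad_genotypes '", x$tetrad, "': 4 spores x ", nm, " markers (",
      sum(is.na(x$calls)), " missing calls)\n", sep = "")
  invisible(x)
}

#' Read tetrad genotype tables
#'
#' Reads a long-format TSV with columns `tetrad`, `spore`, `chrom`, `pos`,
#' `call` where `call` is one of `P1`, `P2`, `MISSING`. Any (spore, marker)
#' pair absent from the file becomes a missing call. Positions not present in
#' the marker map are rejected; a tetrad with a spore count other than four
#' is an error (the analysis is defined on four-spore-viable tetrads).
#'
#' @param path path to the genotype TSV.
#' @param map the [marker_map()] the calls are keyed to.
#' @return A named list of [tetrad_genotypes()] objects, one per tetrad id.
#' @export
load_tetrad_genotypes <- function(path, map) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tetrad", "spore", "chrom", "pos", "call")
  if (!all(need %in% names(d)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  bad_call <- !(d$call %in% c("P1", "P2", "MISSING"))
  if (any(bad_call))
    stop("invalid call value(s): ",
         paste(unique(d$call[bad_call]), collapse = ", "))
  key_map <- paste(map$markers$chrom, map$markers$pos)
  key_d <- paste(d$chrom, d$pos)
  idx <- match(key_d, key_map)
  if (anyNA(idx))
    stop("genotype table contains position(s) absent from the marker map: ",
         paste(utils::head(unique(key_d[is.na(idx)]), 3), collapse = ", "))
  out <- list()
  for (tid in unique(d$tetrad)) {
    dt <- d[d$tetrad == tid, , drop = FALSE]
    spores <- sort(unique(dt$spore))
    if (length(spores) != 4L)
      stop("tetrad requires 4 spores (tetrad '", tid, "' has ",
           length(spores), ")")
    calls <- matrix(NA_integer_, nrow = 4L, ncol = nrow(map$markers))
    si <- match(dt$spore, spores)
    mi <- idx[d$tetrad == tid]
    v <- ifelse(dt$call == "P1", 1L, ifelse(dt$call == "P2", 2L, NA_integer_))
    calls[cbind(si, mi)] <- v
    out[[as.character(tid)]] <- tetrad_genotypes(tid, spores, calls, map)
  }
  out
}

#' Write tetrad genotype tables
#'
#' Inverse of [load_tetrad_genotypes()]: missing calls are written explicitly
#' as `MISSING` so that a write/load round trip is an identity.
#'
#' @param tetrads a [tetrad_genotypes()] object or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tetrad_genotypes <- function(tetrads, path) {
  if (inherits(tetrads, "tetrad_genotypes")) tetrads <- list(tetrads)
  rows <- lapply(tetrads, function(t) {
    mk <- t$map$markers
    v <- as.vector(t(t$calls))
    data.frame(
      tetrad = t$tetrad,
      spore = rep(t$spores, each = nrow(mk)),
      chrom = rep(mk$chrom, times = 4L),
      pos = rep(mk$pos, times = 4L),
      call = ifelse(is.na(v), "MISSING", c("P1", "P2")[v]),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read four per-spore VCFs as one tetrad
#'
#' Optional VCF ingestion: each spore's haploid genotype calls are mapped to
#' parental origin by matching the called allele against the two parental
#' alleles of the marker map. Sites absent from a spore's VCF, uncalled
#' genotypes, and alleles matching neither parent become missing calls.
#' Requires the `vcfR` package.
#'
#' @param paths character vector of 4 VCF paths (one per spore).
#' @param map the [marker_map()].
#' @param tetrad tetrad identifier.
#' @param spores spore identifiers; default derived from file names.
#' @return A [tetrad_genotypes()] object.
#' @export
load_spore_vcfs <- function(paths, map, tetrad = "tetrad1",
                            spores = sub("\\.vcf$", "", basename(paths))) {
  if (length(paths) != 4L) stop("tetrad requires 4 spores (got ",
                                length(paths), " VCFs)")
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("load_spore_vcfs() requires the 'vcfR' package")
  key_map <- paste(map$markers$chrom, map$markers$pos)
  calls <- matrix(NA_integer_, nrow = 4L, ncol = nrow(map$markers))
  for (i in seq_len(4L)) {
    v <- vcfR::read.vcfR(paths[i], verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(v)[, 1L]
    mi <- match(paste(fix[, "CHROM"], fix[, "POS"]), key_map)
    keep <- !is.na(mi) & !is.na(gt)
    a_idx <- suppressWarnings(as.integer(substr(gt[keep], 1L, 1L)))
    allele <- ifelse(a_idx == 0L, fix[keep, "REF"], fix[keep, "ALT"])
    m <- mi[keep]
    p1 <- map$markers$allele_p1[m]
    p2 <- map$markers$allele_p2[m]
    calls[i, m] <- ifelse(allele == p1, 1L, ifelse(allele == p2, 2L,
                                                   NA_integer_))
  }
  tetrad_genotypes(tetrad, spores, calls, map)
}

#' Write a classified event table
#'
#' Writes a BED-style TSV: the first three columns are the event footprint in
#' 0-based half-open coordinates, followed by the event id, class label,
#' chromatid set and member counts, plus the exact (possibly half-integer)
#' footprint boundaries so that a write/read round trip reproduces spans
#' exactly. Column order is fixed.
#'
#' @param events a `recomb_events` object (see [call_recombination()]) or its
#'   `$events` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  ev <- if (inherits(events, "recomb_events")) events$events else events
  out <- data.frame(
    chrom = ev$chrom,
    start = floor(ev$start) - 1L,
    end = ceiling(ev$end),
    event = ev$event_id,
    class = ev$class,
    chromatids = ev$chromatids,
    n_breakpoints = ev$n_breakpoints,
    n_tracts = ev$n_tracts,
    footprint_start = ev$start,
    footprint_end = ev$end,
    stringsAsFactors = FALSE
  )
  if (nrow(out)) out <- out[order(match(out$chrom, unique(out$chrom)),
                                  out$start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an event table written by [write_event_table()]
#'
#' @param path path to the event TSV.
#' @return A data.frame with the exact footprint spans restored in `start`,
#'   `end` (1-based, as held internally).
#' @export
read_event_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(d)
  d$start <- d$footprint_start
  d$end <- d$footprint_end
  d
}
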