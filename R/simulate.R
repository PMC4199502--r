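#' Gamma deviates parameterised by their median
#'
#' Tract lengths are drawn from a gamma distribution specified by its median
#' (the paper-style summary statistic) and shape; the scale is solved from
#' `median = qgamma(0.5, shape) * scale`. A non-positive median gives
#' all-zero draws.
#'
#' @param n number of deviates.
#' @param median target median (bp).
#' @param shape gamma shape (default 2: positively skewed, strictly positive
#'   lengths resembling observed tract-length histograms).
#' @return Numeric vector of length `n`.
#' @export
rgamma_median <- function(n, median, shape = 2) {
  if (median <= 0) return(rep(0, n))
  scale <- median / stats::qgamma(0.5, shape = shape)
  stats::rgamma(n, shape = shape, scale = scale)
}

#' Simulation parameters for synthetic meioses
#'
#' Bundles the generative settings of the synthetic tetrad generator. The
#' defaults describe a wild-type-like meiosis of a yeast hybrid: ~60,000
#' genotypable markers genome-wide, Poisson crossover and noncrossover
#' counts, and gamma tract lengths with a 1.8 kb median for simple
#' noncrossovers. The mutant modes add their characteristic aberrations:
#' \describe{
#' \item{`mms4`}{tandem multi-invasion: a large fraction of events becomes a
#'   chain of 2-11 sequential tracts on one chromatid (truncated-geometric
#'   tract count, gamma inter-tract gaps), yielding long discontinuous events
#'   with wild-type-sized member tracts; the noncrossover DSB mean rises.}
#' \item{`sgs1`}{a fraction of crossover-destined intermediates resolves
#'   without cutting bias (overlapping opposite-direction conversion pair on
#'   non-sister chromatids, the E5A signature) or engages a third chromatid;
#'   an extra subpopulation of short (0-500 bp) noncrossovers appears.}
#' \item{`msh2`}{heteroduplex is repaired as short patches: a
#'   normal-length noncrossover footprint is subdivided into converted
#'   patches (median 0.5 kb) separated by restored 2:2 gaps (median 0.3 kb),
#'   so the whole-event span keeps the simple-noncrossover distribution
#'   while internal tracts shrink.}
#' }
#'
#' @param mode one of `"wt"`, `"mms4"`, `"sgs1"`, `"msh2"`.
#' @param genome chromosome table (`chrom`, `length`, `centromere`).
#' @param n_markers total marker count (near-uniform spacing with jitter).
#' @param spacing_jitter relative jitter of marker spacing (default 0.25).
#' @param co_mean Poisson mean of crossover-destined DSBs per meiosis.
#' @param nco_mean Poisson mean of noncrossover DSBs per meiosis (default
#'   39; 52 in `mms4` mode, where each DSB may spawn several tracts).
#' @param nco_tract_median,nco_tract_shape gamma parameters of simple
#'   noncrossover tract lengths (median 1800 bp).
#' @param gc_co_median gamma median of crossover-associated conversion
#'   tracts (2000 bp).
#' @param p_disc probability an NCO is a tandem multi-tract chain.
#' @param disc_n_p,disc_n_max truncated-geometric parameters of the chain
#'   tract count: `n = min(2 + rgeom(disc_n_p), disc_n_max)`.
#' @param disc_gap_median gamma median of inter-tract gaps in a chain.
#' @param p_patchy probability an NCO is repaired as short patches
#'   (msh2 mode).
#' @param patch_median,patch_gap_median gamma medians of converted patches
#'   and restored gaps inside a patchy tract (500 / 300 bp).
#' @param unbiased_fraction fraction of crossover-destined intermediates
#'   resolved without bias (emitting the overlapping opposite-direction
#'   noncrossover pair).
#' @param unbiased_core_median gamma median of the inter-junction (shared)
#'   segment of an unbiased pair.
#' @param unbiased_flank_median gamma median of each tract's private
#'   extension beyond the shared segment.
#' @param p_multichromatid fraction of crossovers engaging a third chromatid
#'   via an extra nearby conversion (sgs1 mode).
#' @param short_nco_fraction fraction of noncrossovers drawn from the short
#'   0-500 bp subpopulation (sgs1 mode).
#' @param p_intersister fraction of noncrossover DSBs repaired off the
#'   sister chromatid: genotype-invisible, emitted only as ground truth.
#' @param missing_rate per-call missing-data rate.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mode = c("wt", "mms4", "sgs1", "msh2"),
                       genome = yeast_genome(),
                       n_markers = 60000,
                       spacing_jitter = 0.25,
                       co_mean = 90,
                       nco_mean = NULL,
                       nco_tract_median = 1800,
                       nco_tract_shape = 2,
                       gc_co_median = 2000,
                       p_disc = NULL,
                       disc_n_p = 0.5,
                       disc_n_max = NULL,
                       disc_gap_median = 1000,
                       p_patchy = NULL,
                       patch_median = 500,
                       patch_gap_median = 300,
                       unbiased_fraction = NULL,
                       unbiased_core_median = 2000,
                       unbiased_flank_median = 300,
                       p_multichromatid = NULL,
                       short_nco_fraction = NULL,
                       p_intersister = 0,
                       missing_rate = 0.005) {
  mode <- match.arg(mode)
  dflt <- function(x, wt, mms4 = wt, sgs1 = wt, msh2 = wt)
    if (!is.null(x)) x else switch(mode, wt = wt, mms4 = mms4,
                                   sgs1 = sgs1, msh2 = msh2)
  p <- list(
    mode = mode, genome = genome, n_markers = n_markers,
    spacing_jitter = spacing_jitter, co_mean = co_mean,
    nco_mean = dflt(nco_mean, 39, mms4 = 52),
    nco_tract_median = nco_tract_median,
    nco_tract_shape = nco_tract_shape,
    gc_co_median = gc_co_median,
    p_disc = dflt(p_disc, 0.05, mms4 = 0.5),
    disc_n_p = disc_n_p,
    disc_n_max = dflt(disc_n_max, 3, mms4 = 11),
    disc_gap_median = disc_gap_median,
    p_patchy = dflt(p_patchy, 0, msh2 = 0.1),
    patch_median = patch_median, patch_gap_median = patch_gap_median,
    unbiased_fraction = dflt(unbiased_fraction, 0, sgs1 = 0.15),
    unbiased_core_median = unbiased_core_median,
    unbiased_flank_median = unbiased_flank_median,
    p_multichromatid = dflt(p_multichromatid, 0, sgs1 = 0.1),
    short_nco_fraction = dflt(short_nco_fraction, 0, sgs1 = 0.15),
    p_intersister = p_intersister,
    missing_rate = missing_rate)
  stopifnot(p$co_mean >= 0, p$nco_mean >= 0, p$missing_rate >= 0,
            p$missing_rate <= 1, p$p_disc >= 0, p$p_disc <= 1,
            p$unbiased_fraction >= 0, p$unbiased_fraction <= 1,
            p$nco_tract_median > 0)
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params (mode ", x$mode, "): ", nrow(x$genome),
      " chromosomes, ~", x$n_markers, " markers, CO mean ", x$co_mean,
      ", NCO mean ", x$nco_mean, "\n", sep = "")
  invisible(x)
}

#' Simulate a hybrid marker map
#'
#' Marker counts are apportioned to chromosomes by length; within a
#' chromosome markers sit on a near-uniform grid with +/- `spacing_jitter`
#' relative jitter. Parental alleles are random distinct nucleotides.
#'
#' @param genome chromosome table (`chrom`, `length`, `centromere`).
#' @param n_markers total marker count.
#' @param spacing_jitter relative spacing jitter.
#' @param seed optional integer seed.
#' @return A [marker_map()].
#' @export
simulate_marker_map <- function(genome, n_markers = 60000,
                                spacing_jitter = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- sum(genome$length)
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    k <- max(2L, round(n_markers * genome$length[i] / total))
    s <- genome$length[i] / (k + 1)
    pos <- round((1:k) * s + stats::runif(k, -spacing_jitter * s,
                                          spacing_jitter * s))
    pos <- sort(unique(pmin(pmax(pos, 1), genome$length[i])))
    data.frame(chrom = genome$chrom[i], pos = pos, stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, rows)
  nt <- c("A", "C", "G", "T")
  a1 <- sample.int(4L, nrow(mk), replace = TRUE)
  a2 <- ((a1 - 1L + sample.int(3L, nrow(mk), replace = TRUE)) %% 4L) + 1L
  mk$allele_p1 <- nt[a1]
  mk$allele_p2 <- nt[a2]
  marker_map(genome, mk)
}

# truncated-geometric chain length on 2..n_max
.rchain_n <- function(n, p, n_max) pmin(2L + stats::rgeom(n, p), n_max)

#' Simulate one meiosis
#'
#' Starts from perfect 2:2 segregation (spores 1,2 carry parent 1, spores
#' 3,4 parent 2, fixing sisterhood at generation time), places
#' crossover-destined and noncrossover-destined DSBs uniformly per bp across
#' the genome, and applies the outcome templates of the configured mode:
#' reciprocal arm exchange plus an adjacent conversion tract for crossovers;
#' a single 3:1 tract for noncrossovers; overlapping opposite-direction
#' tract pairs on non-sister chromatids for unbiased resolution; tandem
#' tract chains, short-patch repair, multichromatid engagement and
#' sister-chromatid (invisible) repair for the mutant modes. Genotypes exist
#' only at the marker grid; a conversion spanning no marker is emitted in
#' the truth table flagged undetectable. Missing calls are injected last.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed.
#' @param map optional pre-built [marker_map()]; when `NULL` a map is drawn
#'   from `params` (cohorts should share one map via [simulate_cohort()]).
#' @param tetrad tetrad id for the output object.
#' @return A list with `tetrad` (a [tetrad_genotypes()]) and `truth`, a
#'   data.frame with one row per breakpoint or intended tract: `dsb`
#'   (DSB index), `outcome`, `kind` (`breakpoint`/`tract`), `chrom`,
#'   `chromatids`, `start`, `end`, `n_markers`, `detectable`.
#' @export
simulate_meiosis <- function(params, seed = NULL, map = NULL,
                             tetrad = "tetrad1") {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map))
    map <- simulate_marker_map(params$genome, params$n_markers,
                               params$spacing_jitter)
  genome <- map$chromosomes
  nchrom <- nrow(genome)
  M <- nrow(map$markers)
  calls <- matrix(rep(c(1L, 1L, 2L, 2L), M), nrow = 4L)
  pos_by_chrom <- split(map$markers$pos, map$markers$chrom)[genome$chrom]
  col0 <- cumsum(c(0L, lengths(pos_by_chrom)))  # column offsets per chrom

  swaps <- list()   # CO arm exchanges: (chrom_i, pos, a, b)
  # conversions: (chrom_i, start, end, chromatid, kind, x, truth_row)
  # kind 0 = fixed chromatid; 1 = retarget to the observable exchange pair
  # at x; 2 = retarget away from the observable pair at x
  flips <- list()
  truth <- list()
  dsb <- 0L
  n_mk <- function(ci, s, e) {
    p <- pos_by_chrom[[ci]]
    sum(p >= s & p <= e)
  }
  add_truth <- function(outcome, kind, ci, chromatids, s, e,
                        detectable = NULL) {
    if (kind == "tract") {
      s <- max(1, s); e <- min(genome$length[ci], e)
      nm <- n_mk(ci, s, e)
      if (is.null(detectable)) detectable <- nm >= 1L
    } else {
      nm <- NA_integer_
      p <- pos_by_chrom[[ci]]
      if (is.null(detectable)) detectable <- any(p < s) && any(p > s)
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      dsb = dsb, outcome = outcome, kind = kind, chrom = genome$chrom[ci],
      chromatids = paste(chromatids, collapse = ","), start = s, end = e,
      n_markers = nm, detectable = detectable, stringsAsFactors = FALSE)
  }
  draw_site <- function() {
    ci <- sample.int(nchrom, 1L, prob = genome$length)
    c(ci, stats::runif(1, 1, genome$length[ci]))
  }

  n_co <- stats::rpois(1L, params$co_mean)
  n_nco <- stats::rpois(1L, params$nco_mean)

  for (i in seq_len(n_co)) {
    dsb <- dsb + 1L
    st <- draw_site(); ci <- st[1L]; x <- st[2L]
    u <- stats::runif(1)
    if (u < params$unbiased_fraction) {
      # unbiased junction cutting: opposite-direction conversion pair
      a <- sample(1:2, 1L); b <- sample(3:4, 1L)
      L <- rgamma_median(1, params$unbiased_core_median)
      e1 <- rgamma_median(1, params$unbiased_flank_median)
      e2 <- rgamma_median(1, params$unbiased_flank_median)
      add_truth("CO_unbiased", "tract", ci, a, x - e1, x + L)
      flips[[length(flips) + 1L]] <- c(ci, x - e1, x + L, a, 0, NA,
                                       length(truth))
      add_truth("CO_unbiased", "tract", ci, b, x, x + L + e2)
      flips[[length(flips) + 1L]] <- c(ci, x, x + L + e2, b, 0, NA,
                                       length(truth))
    } else {
      a <- sample(1:2, 1L); b <- sample(3:4, 1L)
      swaps[[length(swaps) + 1L]] <- c(ci, x, a, b)
      add_truth(if (u < params$unbiased_fraction + params$p_multichromatid)
                  "CO_multichromatid" else "CO", "breakpoint", ci,
                c(a, b), x, x)
      Lg <- rgamma_median(1, params$gc_co_median)
      if (Lg > 0) {
        cg <- if (stats::runif(1) < 0.5) a else b
        add_truth("GC_CO", "tract", ci, cg, x - Lg, x)
        flips[[length(flips) + 1L]] <- c(ci, x - Lg, x, cg, 1, x,
                                         length(truth))
      }
      if (u < params$unbiased_fraction + params$p_multichromatid) {
        cc <- sample(setdiff(1:4, c(a, b)), 1L)
        off <- stats::runif(1, 200, 3000)
        Lm <- rgamma_median(1, params$nco_tract_median,
                            params$nco_tract_shape)
        add_truth("CO_multichromatid", "tract", ci, cc, x + off,
                  x + off + Lm)
        flips[[length(flips) + 1L]] <- c(ci, x + off, x + off + Lm, cc, 2,
                                         x, length(truth))
      }
    }
  }

  for (i in seq_len(n_nco)) {
    dsb <- dsb + 1L
    st <- draw_site(); ci <- st[1L]; x <- st[2L]
    cc <- sample.int(4L, 1L)
    if (stats::runif(1) < params$p_intersister) {
      L <- rgamma_median(1, params$nco_tract_median, params$nco_tract_shape)
      add_truth("NCO_intersister", "tract", ci, cc, x, x + L,
                detectable = FALSE)
      next
    }
    if (stats::runif(1) < params$p_disc) {
      n <- .rchain_n(1L, params$disc_n_p, params$disc_n_max)
      at <- x
      for (k in seq_len(n)) {
        L <- rgamma_median(1, params$nco_tract_median,
                           params$nco_tract_shape)
        add_truth("NCO_disc", "tract", ci, cc, at, at + L)
        flips[[length(flips) + 1L]] <- c(ci, at, at + L, cc, 0, NA,
                                         length(truth))
        at <- at + L + rgamma_median(1, params$disc_gap_median)
      }
    } else if (stats::runif(1) < params$p_patchy) {
      L <- rgamma_median(1, params$nco_tract_median, params$nco_tract_shape)
      at <- x
      repeat {
        pl <- rgamma_median(1, params$patch_median)
        if (at + pl >= x + L) {
          add_truth("NCO_patch", "tract", ci, cc, at, x + L)
          flips[[length(flips) + 1L]] <- c(ci, at, x + L, cc, 0, NA,
                                           length(truth))
          break
        }
        g <- rgamma_median(1, params$patch_gap_median)
        if (at + pl + g >= x + L) pl <- x + L - at  # end chain on a patch
        add_truth("NCO_patch", "tract", ci, cc, at, at + pl)
        flips[[length(flips) + 1L]] <- c(ci, at, at + pl, cc, 0, NA,
                                         length(truth))
        if (at + pl >= x + L) break
        at <- at + pl + g
      }
    } else {
      L <- if (stats::runif(1) < params$short_nco_fraction)
        stats::runif(1, 0, 500)
      else rgamma_median(1, params$nco_tract_median, params$nco_tract_shape)
      add_truth("NCO", "tract", ci, cc, x, x + L)
      flips[[length(flips) + 1L]] <- c(ci, x, x + L, cc, 0, NA,
                                       length(truth))
    }
  }

  # apply arm exchanges in position order, then conversions as call flips;
  # the exchanged segment is the arm distal to the centromere, so
  # centromere-linked parental origin (sisterhood) is preserved
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(dsb = integer(), outcome = character(), kind = character(),
               chrom = character(), chromatids = character(),
               start = numeric(), end = numeric(), n_markers = integer(),
               detectable = logical(), stringsAsFactors = FALSE)
  if (length(swaps)) {
    sw <- do.call(rbind, swaps)
    cen <- genome$centromere[sw[, 1L]]
    left_arm <- !is.na(cen) & sw[, 2L] < cen
    # strand tracing composes junctions distal-to-proximal: the exchange
    # farthest from the centromere is applied first on each arm
    ord <- c(which(!left_arm)[order(sw[!left_arm, 1L],
                                    -sw[!left_arm, 2L])],
             which(left_arm)[order(sw[left_arm, 1L],
                                   sw[left_arm, 2L])])
    for (r in ord) {
      ci <- sw[r, 1L]
      x <- sw[r, 2L]
      distal <- if (left_arm[r]) pos_by_chrom[[ci]] < x
                else pos_by_chrom[[ci]] > x
      cols <- col0[ci] + which(distal)
      if (!length(cols)) next
      a <- sw[r, 3L]; b <- sw[r, 4L]
      tmp <- calls[a, cols]
      calls[a, cols] <- calls[b, cols]
      calls[b, cols] <- tmp
    }
  }
  # conversion tracts ride the exchanged strands: a crossover-associated
  # tract surfaces on a spore of the *observable* exchange pair at its
  # junction (which can differ from the drawn chromatid pair when other
  # junctions lie distal on the same molecules), and the sgs1-mode extra
  # tract engages a chromatid outside that pair
  observable_pair <- function(ci, x) {
    p <- pos_by_chrom[[ci]]
    li <- which(p < x); ri <- which(p > x)
    if (!length(li) || !length(ri)) return(NULL)
    l <- col0[ci] + max(li); rr <- col0[ci] + min(ri)
    d <- which(calls[, l] != calls[, rr])
    if (length(d) == 2L) d else NULL
  }
  for (k in seq_along(flips)) {
    f <- flips[[k]]
    if (is.na(f[5L]) || f[5L] == 0) next
    pair <- observable_pair(f[1L], f[6L])
    if (is.null(pair)) next
    cc <- if (f[5L] == 1) pair[sample.int(2L, 1L)]
          else sample(setdiff(1:4, pair), 1L)
    flips[[k]][4L] <- cc
    truth$chromatids[f[7L]] <- as.character(cc)
  }
  for (f in flips) {
    ci <- f[1L]
    cols <- col0[ci] + which(pos_by_chrom[[ci]] >= f[2L] &
                               pos_by_chrom[[ci]] <= f[3L])
    if (!length(cols)) next
    cc <- f[4L]
    calls[cc, cols] <- 3L - calls[cc, cols]
  }
  # a breakpoint is observable only if a reciprocal two-spore difference
  # remains between its nearest flanking clean 2:2 markers once every
  # exchange and conversion is in place (close same-pair double crossovers
  # cancel; a conversion can consume a chromosome-end flank)
  is_bp <- truth$kind == "breakpoint"
  if (any(is_bp)) {
    s22_cache <- list()
    for (r in which(is_bp)) {
      ci <- match(truth$chrom[r], genome$chrom)
      key <- as.character(ci)
      if (is.null(s22_cache[[key]])) {
        cols <- col0[ci] + seq_along(pos_by_chrom[[ci]])
        s22_cache[[key]] <- colSums(calls[, cols, drop = FALSE] == 1L) == 2L
      }
      s22 <- s22_cache[[key]]
      p <- pos_by_chrom[[ci]]
      x <- truth$start[r]
      li <- which(s22 & p < x)
      ri <- which(s22 & p > x)
      truth$detectable[r] <- if (!length(li) || !length(ri)) FALSE else {
        l <- col0[ci] + max(li)
        rr <- col0[ci] + min(ri)
        sum(calls[, l] != calls[, rr]) == 2L
      }
    }
  }
  if (params$missing_rate > 0) {
    nmiss <- stats::rbinom(1L, length(calls), params$missing_rate)
    if (nmiss > 0)
      calls[sample.int(length(calls), nmiss)] <- NA_integer_
  }

  truth$tetrad <- rep(tetrad, nrow(truth))
  list(tetrad = tetrad_genotypes(tetrad, paste0("spore", 1:4), calls, map),
       truth = truth)
}

#' Simulate a cohort of tetrads
#'
#' Draws one shared marker map and `n_tetrads` meioses from it. With `dir`
#' set, writes `markers.tsv`, `genotypes.tsv` and `truth.tsv` in the
#' package's I/O formats; output is byte-identical for identical seeds.
#'
#' @param params a [sim_params()] object.
#' @param n_tetrads number of meioses (>= 1).
#' @param seed integer seed.
#' @param dir optional output directory (created if needed).
#' @return Invisibly, a list with `map`, `tetrads` (list of
#'   [tetrad_genotypes()]), `truth` (combined truth table) and, when `dir`
#'   is set, the written `paths`.
#' @export
simulate_cohort <- function(params, n_tetrads, seed = 1, dir = NULL) {
  stopifnot(n_tetrads >= 1)
  set.seed(seed)
  map <- simulate_marker_map(params$genome, params$n_markers,
                             params$spacing_jitter)
  tets <- vector("list", n_tetrads)
  truths <- vector("list", n_tetrads)
  for (i in seq_len(n_tetrads)) {
    sim <- simulate_meiosis(params, map = map,
                            tetrad = sprintf("tetrad%03d", i))
    tets[[i]] <- sim$tetrad
    truths[[i]] <- sim$truth
  }
  names(tets) <- vapply(tets, function(t) t$tetrad, character(1))
  out <- list(map = map, tetrads = tets, truth = do.call(rbind, truths))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("markers.tsv", "genotypes.tsv", "truth.tsv"))
    write_marker_map(map, paths[1L])
    write_tetrad_genotypes(tets, paths[2L])
    utils::write.table(out$truth, paths[3L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  invisible(out)
}
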