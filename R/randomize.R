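.DIST_CATEGORIES <- c("NCO-NCO same", "NCO-NCO different",
                      "CO-NCO same", "CO-NCO different")

# per-category medians; n = 0 categories stay NA (undefined), never 0
.cat_medians <- function(cats) {
  vapply(.DIST_CATEGORIES, function(k)
    if (length(cats[[k]])) stats::median(cats[[k]]) else NA_real_,
    numeric(1))
}

#' Random-placement null for noncrossover positions
#'
#' Implements the positional null model for noncrossover (NCO) spacing: in
#' each replicate the observed number of NCO events per tetrad is replaced by
#' NCOs placed uniformly per bp across the genome (chromosome chosen
#' proportional to its length) on a uniformly chosen chromatid, while the
#' crossover-containing events stay exactly where they were observed. Each
#' simulated NCO keeps one of the observed NCO footprint lengths (the
#' observed length multiset is permuted without replacement). Adjacent-event
#' distances are then recomputed per replicate and compared with the observed
#' distances per category.
#'
#' Two significance summaries are available: a two-sided Wilcoxon rank-sum
#' test of the observed distances against the pooled simulated distances
#' (`test = "wilcoxon"`), and an empirical permutation p-value for the
#' observed median's rank among the replicate medians
#' (`test = "permutation"`). The permutation form is exactly calibrated even
#' though spacings within one genome are mutually dependent; the Wilcoxon
#' form mirrors the package's tract-length comparisons.
#'
#' @param x a `recomb_events` object or a list of them (a cohort; observed
#'   and simulated distances are pooled over tetrads).
#' @param map the [marker_map()] or a chromosome table (`chrom`, `length`)
#'   defining the genome the NCOs are scattered over.
#' @param n_reps number of replicates (default 1000).
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @param test `"wilcoxon"` or `"permutation"`.
#' @param point_nco place zero-length NCOs instead of resampling observed
#'   footprint lengths.
#' @param per_chromosome preserve each tetrad's per-chromosome NCO counts
#'   instead of redistributing genome-wide.
#' @return An object of class `nco_randomization` with elements `observed`
#'   (category, n, median), `replicate_medians` (n_reps x 4 matrix),
#'   `p_values`, `simulated` (pooled distances per category), `test`,
#'   `n_reps`, `seed`. With zero observed NCO events the result is empty and
#'   no test is run.
#' @export
randomize_nco_positions <- function(x, map, n_reps = 1000, seed = 1,
                                    test = c("wilcoxon", "permutation"),
                                    point_nco = FALSE,
                                    per_chromosome = FALSE) {
  test <- match.arg(test)
  stopifnot(n_reps >= 1)
  chroms <- if (inherits(map, "marker_map")) map$chromosomes else map
  evs <- if (inherits(x, "recomb_events")) list(x$events)
         else if (is.data.frame(x)) list(x)
         else lapply(x, function(e)
           if (inherits(e, "recomb_events")) e$events else e)

  # per-tetrad fixed CO part and observed NCO geometry, integer chrom codes
  chrom_code <- stats::setNames(seq_len(nrow(chroms)), chroms$chrom)
  len <- chroms$length
  prep <- lapply(evs, function(ev) {
    ci <- unname(chrom_code[ev$chrom])
    list(co = list(chrom = ci[ev$is_co], start = ev$start[ev$is_co],
                   end = ev$end[ev$is_co], mask = ev$mask[ev$is_co]),
         nco_len = if (point_nco) rep(0, sum(!ev$is_co))
                   else (ev$end - ev$start)[!ev$is_co],
         nco_chrom = ci[!ev$is_co])
  })
  n_nco_total <- sum(vapply(prep, function(p) length(p$nco_len), numeric(1)))

  obs_cats <- lapply(stats::setNames(nm = .DIST_CATEGORIES),
                     function(k) numeric(0))
  for (ev in evs) {
    cats <- .adjacent_distances(unname(chrom_code[ev$chrom]), ev$start,
                                ev$end, ev$is_co, ev$mask)
    for (k in .DIST_CATEGORIES) obs_cats[[k]] <- c(obs_cats[[k]], cats[[k]])
  }
  observed <- data.frame(category = .DIST_CATEGORIES,
                         n = lengths(obs_cats)[.DIST_CATEGORIES],
                         median = .cat_medians(obs_cats),
                         stringsAsFactors = FALSE)
  out <- structure(list(observed = observed,
                        replicate_medians = NULL, simulated = NULL,
                        p_values = NULL, test = test, n_reps = n_reps,
                        seed = seed), class = "nco_randomization")
  if (n_nco_total == 0L) return(out)

  set.seed(seed)
  rep_med <- matrix(NA_real_, nrow = n_reps, ncol = 4L,
                    dimnames = list(NULL, .DIST_CATEGORIES))
  sim_pool <- lapply(stats::setNames(nm = .DIST_CATEGORIES),
                     function(k) numeric(0))
  for (r in seq_len(n_reps)) {
    cats_r <- lapply(stats::setNames(nm = .DIST_CATEGORIES),
                     function(k) numeric(0))
    for (p in prep) {
      n <- length(p$nco_len)
      if (n == 0L && length(p$co$chrom) < 2L) next
      L <- if (n) sample(p$nco_len) else numeric(0)
      ci <- if (n == 0L) integer(0)
            else if (per_chromosome) p$nco_chrom
            else sample.int(length(len), n, replace = TRUE, prob = len)
      s <- if (n) stats::runif(n, 0, pmax(0, len[ci] - L)) else numeric(0)
      mask <- if (n) bitwShiftL(1L, sample.int(4L, n, replace = TRUE) - 1L)
              else integer(0)
      cats <- .adjacent_distances(
        c(p$co$chrom, ci), c(p$co$start, s), c(p$co$end, s + L),
        c(rep(TRUE, length(p$co$chrom)), rep(FALSE, n)),
        c(p$co$mask, mask))
      for (k in .DIST_CATEGORIES) cats_r[[k]] <- c(cats_r[[k]], cats[[k]])
    }
    rep_med[r, ] <- .cat_medians(cats_r)
    for (k in .DIST_CATEGORIES) sim_pool[[k]] <- c(sim_pool[[k]],
                                                   cats_r[[k]])
  }

  pv <- rep(NA_real_, 4L)
  names(pv) <- .DIST_CATEGORIES
  for (k in .DIST_CATEGORIES) {
    obs <- obs_cats[[k]]
    if (length(obs) == 0L) next
    if (test == "wilcoxon") {
      if (length(sim_pool[[k]]) == 0L) next
      pv[k] <- suppressWarnings(
        stats::wilcox.test(obs, sim_pool[[k]])$p.value)
    } else {
      sm <- rep_med[, k]
      sm <- sm[!is.na(sm)]
      if (length(sm) == 0L) next
      om <- stats::median(obs)
      p_lo <- (1 + sum(sm <= om)) / (length(sm) + 1)
      p_hi <- (1 + sum(sm >= om)) / (length(sm) + 1)
      pv[k] <- min(1, 2 * min(p_lo, p_hi))
    }
  }
  out$replicate_medians <- rep_med
  out$simulated <- sim_pool
  out$p_values <- data.frame(category = .DIST_CATEGORIES, p = unname(pv),
                             stringsAsFactors = FALSE)
  out
}

#' @export
print.nco_randomization <- function(x, ...) {
  cat("NCO position randomization (", x$n_reps, " reps, seed ", x$seed,
      ", ", x$test, " test)\n", sep = "")
  if (is.null(x$p_values)) {
    cat("  no NCO events observed; no test run\n")
    return(invisible(x))
  }
  d <- x$observed
  d$sim_median <- apply(x$replicate_medians, 2, stats::median, na.rm = TRUE)
  d$p <- x$p_values$p
  print(d, row.names = FALSE)
  invisible(x)
}

#' @export
plot.nco_randomization <- function(x, category = "NCO-NCO same", ...) {
  if (is.null(x$replicate_medians)) {
    warning("empty randomization result")
    return(invisible(x))
  }
  sm <- x$replicate_medians[, category]
  om <- x$observed$median[x$observed$category == category]
  graphics::hist(sm, breaks = 30, main = category,
                 xlab = "replicate median distance (bp)",
                 xlim = range(c(sm, om), na.rm = TRUE), ...)
  graphics::abline(v = om, col = "red", lwd = 2)
  invisible(x)
}

#' Exhaustive 1:2:1 chromatid enumeration for double crossovers
#'
#' Enumerates the 16 equally likely chromatid choices of two independent
#' crossovers (each picks one chromatid per homolog) and counts how many
#' distinct chromatids the pair involves. Without chromatid interference the
#' counts are exactly 4:8:4, i.e. a 1:2:1 ratio of two-, three- and
#' four-chromatid apparent double crossovers.
#'
#' @return Integer vector `c("2" = 4, "3" = 8, "4" = 4)` computed by
#'   enumeration.
#' @export
chromatid_ratio_enumeration <- function() {
  g <- expand.grid(a1 = 1:2, b1 = 3:4, a2 = 1:2, b2 = 3:4)
  k <- apply(g, 1L, function(r) length(unique(r)))
  table(factor(k, levels = 2:4))
}

#' Monte-Carlo 1:2:1 chromatid-interference null
#'
#' Simulates `n_events` apparent double crossovers as two independent
#' crossovers, each choosing one chromatid per homolog uniformly, and bins
#' each event by the number of distinct chromatids involved (2, 3 or 4).
#'
#' @param n_events number of double-crossover events to simulate (>= 1).
#' @param seed integer seed.
#' @return A list with `counts`, `proportions`, `se` (binomial standard
#'   errors), `ci_low`/`ci_high` (normal-approximation 95% intervals),
#'   `expected = c(0.25, 0.5, 0.25)` and `n_events`.
#' @export
chromatid_ratio_null <- function(n_events, seed = NULL) {
  stopifnot(n_events >= 1)
  if (!is.null(seed)) set.seed(seed)
  a1 <- sample.int(2L, n_events, replace = TRUE)
  b1 <- sample.int(2L, n_events, replace = TRUE) + 2L
  a2 <- sample.int(2L, n_events, replace = TRUE)
  b2 <- sample.int(2L, n_events, replace = TRUE) + 2L
  k <- 2L + (a1 != a2) + (b1 != b2)
  counts <- table(factor(k, levels = 2:4))
  p <- as.numeric(counts) / n_events
  se <- sqrt(p * (1 - p) / n_events)
  list(counts = counts, proportions = stats::setNames(p, 2:4),
       se = stats::setNames(se, 2:4),
       ci_low = stats::setNames(pmax(0, p - 1.96 * se), 2:4),
       ci_high = stats::setNames(pmin(1, p + 1.96 * se), 2:4),
       expected = c(`2` = 0.25, `3` = 0.5, `4` = 0.25),
       n_events = n_events)
}

#' Chi-square goodness of fit of an observed chromatid triple against 1:2:1
#'
#' @param observed integer vector of length 3: counts of apparent double
#'   crossovers on 2, 3 and 4 chromatids.
#' @return An `htest` object from [stats::chisq.test()] with expected
#'   proportions (0.25, 0.5, 0.25).
#' @export
chromatid_ratio_test <- function(observed) {
  stopifnot(length(observed) == 3L)
  suppressWarnings(stats::chisq.test(observed, p = c(0.25, 0.5, 0.25)))
}

#' Configuration null for two close noncrossovers
#'
#' Generative null for a pair of independent DSBs less than `max_sep` bp
#' apart, each repaired as a noncrossover on a uniformly chosen chromatid
#' with a tract length drawn from the configured gamma distribution. Pairs
#' landing on the same chromatid (4 of the 16 chromatid pairings) would be
#' seen as a single or discontinuous tract rather than a double
#' noncrossover and are discarded. The remaining pairs are classified as
#' (A) overlapping tracts on non-sister chromatids, (B) non-overlapping
#' tracts on non-sister chromatids, or (C) tracts on sister chromatids
#' (sisters are chromatids 1,2 and 3,4).
#'
#' @param n_pairs number of DSB pairs to draw.
#' @param seed integer seed.
#' @param max_sep maximal DSB separation (default 5000 bp).
#' @param tract_median,tract_shape gamma tract-length parameters (median
#'   parameterisation; a zero median gives point tracts, which can never
#'   overlap).
#' @return A list with `counts` and `proportions` over A/B/C, binomial `se`,
#'   `n_pairs` (drawn) and `n_used` (distinct-chromatid pairs).
#' @export
double_nco_configuration_null <- function(n_pairs, seed = NULL,
                                          max_sep = 5000,
                                          tract_median = 1800,
                                          tract_shape = 2) {
  stopifnot(n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  c1 <- sample.int(4L, n_pairs, replace = TRUE)
  c2 <- sample.int(4L, n_pairs, replace = TRUE)
  sep <- stats::runif(n_pairs, 0, max_sep)
  L1 <- rgamma_median(n_pairs, tract_median, tract_shape)
  L2 <- rgamma_median(n_pairs, tract_median, tract_shape)
  keep <- c1 != c2
  sister <- ((c1 <= 2L) == (c2 <= 2L))[keep]
  # tracts centred on their DSBs at 0 and sep
  overlap <- ((sep - L2 / 2) < (L1 / 2) & (-L1 / 2) < (sep + L2 / 2))[keep]
  conf <- ifelse(sister, "C", ifelse(overlap, "A", "B"))
  counts <- table(factor(conf, levels = c("A", "B", "C")))
  n_used <- sum(keep)
  p <- as.numeric(counts) / n_used
  list(counts = counts,
       proportions = stats::setNames(p, c("A", "B", "C")),
       se = stats::setNames(sqrt(p * (1 - p) / n_used), c("A", "B", "C")),
       n_pairs = n_pairs, n_used = n_used)
}
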