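#' Standard error of a proportion
#'
#' `sqrt(p * (1 - p) / n)`, the standard error attached to event-class
#' proportions in the summaries.
#'
#' @param p proportion in \[0, 1\].
#' @param n sample size (>= 1).
#' @return The standard error.
#' @export
se_proportion <- function(p, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  sqrt(p * (1 - p) / n)
}

.EVENT_CLASSES <- c("E1", "E2", "E3", "E4", "E5A", "E5B1", "E5B2", "E5B3",
                    "E6", "E7", "unclassified")

#' Per-tetrad event statistics
#'
#' Counts and length medians for one tetrad's classified events: counts per
#' class (E5 subtypes kept separate and also pooled), crossover and
#' noncrossover event counts, the majority (E1+E2+E3) / minority
#' (E4+E5+E6+E7) split with the standard error of the minority proportion,
#' and tract-length medians (simple-noncrossover span, crossover-associated
#' conversion tracts, and the discontinuous event/tract/gap components).
#' Medians of empty sets are reported as `NA`, never 0.
#'
#' @param x a `recomb_events` object.
#' @return A one-row data.frame.
#' @export
summarize_events <- function(x) {
  ev <- x$events
  cnt <- table(factor(ev$class, levels = .EVENT_CLASSES))
  e5 <- sum(cnt[c("E5A", "E5B1", "E5B2", "E5B3")])
  total <- nrow(ev)
  majority <- sum(cnt[c("E1", "E2", "E3")])
  minority <- sum(cnt[c("E4", "E5A", "E5B1", "E5B2", "E5B3", "E6", "E7")])
  n_co <- sum(ev$is_co)
  n_nco <- sum(!ev$is_co)

  e1_ids <- ev$event_id[ev$class == "E1"]
  simple_nco <- x$tracts[x$tracts$event_id %in% e1_ids, , drop = FALSE]
  gc_ids <- ev$event_id[ev$class %in% c("E2", "E3")]
  gc_co <- x$tracts[x$tracts$event_id %in% gc_ids, , drop = FALSE]
  disc <- discontinuity_table(x)

  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  out <- data.frame(
    tetrad = if (!is.null(x$tetrad)) x$tetrad else NA_character_,
    total = total, majority = majority, minority = minority,
    minority_prop = if (total) minority / total else NA_real_,
    minority_se = if (total) se_proportion(minority / total, total)
                  else NA_real_,
    n_co_events = n_co, n_nco_events = n_nco,
    median_simple_nco = med(simple_nco$mid_end - simple_nco$mid_start),
    median_gc_co = med(gc_co$mid_end - gc_co$mid_start),
    median_disc_event = med(disc$event_length),
    median_disc_tract = med(disc$median_tract),
    median_disc_gap = med(disc$median_gap),
    stringsAsFactors = FALSE)
  for (k in .EVENT_CLASSES) out[[k]] <- as.integer(cnt[k])
  out$E5 <- as.integer(e5)
  out
}

#' @export
summary.recomb_events <- function(object, ...) summarize_events(object)

#' Cohort-level summary over tetrads
#'
#' @param xs a list of `recomb_events` objects.
#' @return A list with `per_tetrad` (one row per tetrad, see
#'   [summarize_events()]) and `pooled` (means of counts, pooled minority
#'   proportion with its standard error, and pooled length medians).
#' @export
cohort_summary <- function(xs) {
  per <- do.call(rbind, lapply(xs, summarize_events))
  total <- sum(per$total)
  minority <- sum(per$minority)
  lens <- list(simple_nco = numeric(0), gc_co = numeric(0),
               disc_event = numeric(0), disc_tract = numeric(0),
               disc_gap = numeric(0))
  for (x in xs) {
    ev <- x$events
    e1 <- x$tracts[x$tracts$event_id %in%
                     ev$event_id[ev$class == "E1"], , drop = FALSE]
    gc <- x$tracts[x$tracts$event_id %in%
                     ev$event_id[ev$class %in% c("E2", "E3")], ,
                   drop = FALSE]
    d <- discontinuity_table(x)
    lens$simple_nco <- c(lens$simple_nco, e1$mid_end - e1$mid_start)
    lens$gc_co <- c(lens$gc_co, gc$mid_end - gc$mid_start)
    lens$disc_event <- c(lens$disc_event, d$event_length)
    lens$disc_tract <- c(lens$disc_tract, d$median_tract)
    lens$disc_gap <- c(lens$disc_gap, d$median_gap)
  }
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  pooled <- data.frame(
    n_tetrads = length(xs),
    mean_total = mean(per$total),
    mean_co = mean(per$n_co_events),
    mean_nco = mean(per$n_nco_events),
    minority_prop = if (total) minority / total else NA_real_,
    minority_se = if (total) se_proportion(minority / total, total)
                  else NA_real_,
    mean_e5a = mean(per$E5A),
    median_simple_nco = med(lens$simple_nco),
    median_gc_co = med(lens$gc_co),
    median_disc_event = med(lens$disc_event),
    median_disc_tract = med(lens$disc_tract),
    median_disc_gap = med(lens$disc_gap))
  list(per_tetrad = per, pooled = pooled, lengths = lens)
}

#' Two-sided z-test of two proportions
#'
#' Pooled-variance z statistic without continuity correction; the squared
#' statistic equals the uncorrected chi-square of the 2x2 table.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return A list with `statistic` (z) and `p_value` (two-sided).
#' @export
z_test_proportions <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Two-group comparison with the study's test battery
#'
#' Dispatches to the test matching the data type: Welch's t-test of means
#' for event counts, the two-sided Wilcoxon rank-sum test or
#' Kolmogorov-Smirnov test for tract-length distributions, and the z-test of
#' proportions for class proportions. All p-values are two-sided and
#' uncorrected for multiple comparisons.
#'
#' @param a,b the two samples. For `test = "z"` each must be `c(successes,
#'   trials)`; otherwise numeric vectors of observations (>= 2 each).
#' @param test one of `"t"`, `"wilcoxon"`, `"ks"`, `"z"`.
#' @return A data.frame with `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(a, b, test = c("t", "wilcoxon", "ks", "z")) {
  test <- match.arg(test)
  if (test == "z") {
    if (length(a) != 2L || length(b) != 2L)
      stop("z test expects c(successes, trials) for each group")
    r <- z_test_proportions(a[1L], a[2L], b[1L], b[2L])
    return(data.frame(test = "z", statistic = r$statistic,
                      p_value = r$p_value, stringsAsFactors = FALSE))
  }
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 observations per group")
  r <- switch(test,
    t = stats::t.test(a, b, var.equal = FALSE),
    wilcoxon = suppressWarnings(stats::wilcox.test(a, b)),
    ks = suppressWarnings(stats::ks.test(a, b)))
  data.frame(test = test, statistic = unname(r$statistic),
             p_value = r$p.value, stringsAsFactors = FALSE)
}
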