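test_that("grouping merges within the cutoff, transitively", {
  # two NCO tracts, 4.9 kb gap -> one event; 5.1 kb gap -> two
  t1 <- fix_tract(mid_start = 10000, mid_end = 11000)
  t2 <- fix_tract(mid_start = 15900, mid_end = 16900, chromatids = "2")
  ev <- group_events(rbind(t1, t2), NULL)
  expect_equal(nrow(ev$events), 1L)
  t2b <- fix_tract(mid_start = 16100, mid_end = 17100, chromatids = "2")
  ev <- group_events(rbind(t1, t2b), NULL)
  expect_equal(nrow(ev$events), 2L)

  # chain A-B 4 kb, B-C 4 kb, A-C > 5 kb: one event of three members
  a <- fix_tract(mid_start = 0, mid_end = 1000)
  b <- fix_tract(mid_start = 5000, mid_end = 6000, chromatids = "2")
  c3 <- fix_tract(mid_start = 10000, mid_end = 11000, chromatids = "3")
  ev <- group_events(rbind(a, b, c3), NULL)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$n_tracts, 3L)

  # cutoff 0: only overlapping/abutting members merge
  ev <- group_events(rbind(a, b, c3), NULL, cutoff_bp = 0)
  expect_equal(nrow(ev$events), 3L)
  abut <- fix_tract(mid_start = 1000, mid_end = 2000, chromatids = "2")
  ev <- group_events(rbind(a, abut), NULL, cutoff_bp = 0)
  expect_equal(nrow(ev$events), 1L)

  expect_error(group_events(a, NULL, cutoff_bp = -1), "non-negative")
})

test_that("an exact 5 kb gap merges (inclusive boundary)", {
  t1 <- fix_tract(mid_start = 10000, mid_end = 11000)
  t2 <- fix_tract(mid_start = 16000, mid_end = 17000, chromatids = "2")
  expect_equal(nrow(group_events(rbind(t1, t2), NULL)$events), 1L)
})

test_that("grouping equals the pairwise transitive-closure oracle", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:60, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    start <- runif(n, 0, 2e5)
    end <- start + runif(n, 0, 4000)
    cutoff <- sample(c(0, 1000, 5000), 1)
    tr <- do.call(rbind, lapply(seq_len(n), function(i)
      fix_tract(chrom = chrom[i], mid_start = start[i], mid_end = end[i],
                chromatids = as.character(sample(1:4, 1)))))
    ev <- group_events(tr, NULL, cutoff_bp = cutoff)
    got <- ev$tracts$event_id
    want <- oracle_group_ids(chrom, start, end, cutoff)
    # same partition (labels may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1L))
  }
})

test_that("event count is non-increasing in the cutoff, maximal at 0", {
  set.seed(7)
  n <- 80
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- runif(1, 0, 3e5)
    fix_tract(mid_start = s, mid_end = s + runif(1, 100, 3000),
              chromatids = as.character(sample(1:4, 1)))
  }))
  cutoffs <- c(0, 500, 1000, 2000, 5000, 10000)
  counts <- vapply(cutoffs, function(co)
    nrow(group_events(tr, NULL, cutoff_bp = co)$events), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], max(counts))
})

test_that("chromatid counting unions member chromatid sets", {
  tr <- fix_tract(mid_start = 0, mid_end = 1000)
  expect_equal(count_chromatids(tr, meiorec:::.empty_breakpoints()), 1L)
  # one crossover (chromatids 1,3) + conversion on chromatid 2 -> 3
  bp <- fix_breakpoint(start = 0, end = 1000)
  tr2 <- fix_tract(mid_start = 2000, mid_end = 3000, chromatids = "2")
  expect_equal(count_chromatids(tr2, bp), 3L)
  # two crossovers covering all four spores -> 4
  bp2 <- rbind(fix_breakpoint(spore_a = 1, spore_b = 3, start = 0,
                              end = 1000),
               fix_breakpoint(spore_a = 2, spore_b = 4, start = 2000,
                              end = 3000))
  expect_equal(count_chromatids(meiorec:::.empty_tracts(), bp2), 4L)
  # a 4:0 tract occupies two chromatids
  expect_equal(count_chromatids(fix_tract(mid_start = 0, mid_end = 1,
                                          chromatids = "3,4"),
                                meiorec:::.empty_breakpoints()), 2L)
})

test_that("the decision table labels canonical configurations", {
  emptyb <- meiorec:::.empty_breakpoints()
  # isolated 3:1 tract -> E1
  expect_equal(classify_event(fix_tract(mid_start = 0, mid_end = 1800),
                              emptyb, fix_sisters), "E1")
  # tandem tracts on one chromatid -> E4
  e4 <- rbind(fix_tract(mid_start = 0, mid_end = 1800),
              fix_tract(mid_start = 2600, mid_end = 4400))
  expect_equal(classify_event(e4, emptyb, fix_sisters), "E4")
  # crossover with contiguous conversion -> E2
  bp <- fix_breakpoint(spore_a = 1, spore_b = 3, start = 1000, end = 4000)
  gc <- fix_tract(mid_start = 1200, mid_end = 2900, chromatids = "3")
  expect_equal(classify_event(gc, bp, fix_sisters), "E2")
  expect_equal(classify_event(meiorec:::.empty_tracts(), bp, fix_sisters),
               "E2")
  # crossover with 2:2-separated conversions on a crossover chromatid -> E3
  gc2 <- rbind(gc, fix_tract(mid_start = 6000, mid_end = 7000,
                             chromatids = "3"))
  expect_equal(classify_event(gc2, bp, fix_sisters), "E3")
  # crossover + conversion on a third chromatid -> E6
  gc3 <- fix_tract(mid_start = 6000, mid_end = 7000, chromatids = "2")
  expect_equal(classify_event(gc3, bp, fix_sisters), "E6")
  # two crossovers over all four -> E7
  bp2 <- rbind(bp, fix_breakpoint(spore_a = 2, spore_b = 4, start = 5000,
                                  end = 6000))
  expect_equal(classify_event(meiorec:::.empty_tracts(), bp2, fix_sisters),
               "E7")
})

test_that("E5 subtypes follow overlap, direction and sisterhood", {
  emptyb <- meiorec:::.empty_breakpoints()
  # overlapping opposite-direction tracts on non-sisters -> E5A
  a <- fix_tract(mid_start = 10000, mid_end = 12000, chromatids = "1",
                 direction = "P2")
  b <- fix_tract(mid_start = 11000, mid_end = 13000, chromatids = "3",
                 direction = "P1")
  expect_equal(classify_event(rbind(a, b), emptyb, fix_sisters), "E5A")
  # same two tracts, non-overlapping -> E5B1
  b2 <- fix_tract(mid_start = 12500, mid_end = 13500, chromatids = "3",
                  direction = "P1")
  expect_equal(classify_event(rbind(a, b2), emptyb, fix_sisters), "E5B1")
  # two NCOs on sister chromatids -> E5B2
  b3 <- fix_tract(mid_start = 11000, mid_end = 13000, chromatids = "2",
                  direction = "P1")
  expect_equal(classify_event(rbind(a, b3), emptyb, fix_sisters), "E5B2")
  # overlapping same-direction non-sisters: not the unbiased signature
  b4 <- fix_tract(mid_start = 11000, mid_end = 13000, chromatids = "3",
                  direction = "P2")
  expect_equal(classify_event(rbind(a, b4), emptyb, fix_sisters), "E5B3")
  expect_equal(classify_event(rbind(a, b4), emptyb, fix_sisters,
                              e5a_require_opposite_direction = FALSE),
               "E5A")
  # apparent double crossover between one non-sister pair -> E5A
  dco <- rbind(fix_breakpoint(spore_a = 1, spore_b = 3, start = 10000,
                              end = 11000),
               fix_breakpoint(spore_a = 1, spore_b = 3, start = 13000,
                              end = 14000))
  expect_equal(classify_event(meiorec:::.empty_tracts(), dco, fix_sisters),
               "E5A")
  # triple crossovers on two chromatids -> E5B3
  tco <- rbind(dco, fix_breakpoint(spore_a = 1, spore_b = 3, start = 15000,
                                   end = 16000))
  expect_equal(classify_event(meiorec:::.empty_tracts(), tco, fix_sisters),
               "E5B3")
  # a lone 4:0 tract sits on a sister pair -> E5B2
  expect_equal(classify_event(fix_tract(mid_start = 0, mid_end = 1000,
                                        chromatids = "3,4"),
                              emptyb, fix_sisters), "E5B2")
  # undefined sisterhood -> E5B3
  expect_equal(classify_event(rbind(a, b), emptyb, NULL), "E5B3")
  expect_equal(classify_event(rbind(a, b), emptyb,
                              c(NA_integer_, NA, NA, NA)), "E5B3")
})

test_that("classification matches the rule-table oracle exhaustively", {
  # all configurations of up to 3 members over 4 chromatids in a 20 kb
  # window (positions from fixed slots covering disjoint, abutting and
  # overlapping geometries)
  slots <- list(c(0, 2000), c(1000, 3000), c(2500, 4500), c(8000, 10000),
                c(15000, 17000))
  dirs <- c("P1", "P2")
  mk_tract <- function(sl, ch, d)
    list(type = "tract", chromatids = ch, start = slots[[sl]][1],
         end = slots[[sl]][2], direction = d)
  mk_bp <- function(sl, a, b)
    list(type = "bp", chromatids = c(a, b), start = slots[[sl]][1],
         end = slots[[sl]][2])
  units <- list()
  for (sl in seq_along(slots)) {
    for (ch in 1:4) for (d in dirs)
      units[[length(units) + 1L]] <- mk_tract(sl, ch, d)
    for (a in 1:2) for (b in 3:4)
      units[[length(units) + 1L]] <- mk_bp(sl, a, b)
  }
  n_checked <- 0L
  check <- function(members) {
    tb <- members_to_tables(members)
    got <- classify_event(tb$tracts, tb$breakpoints, fix_sisters)
    want <- oracle_classify(members, fix_sisters)
    n_checked <<- n_checked + 1L
    if (!identical(got, want))
      fail(sprintf("mismatch: got %s want %s", got, want))
  }
  nu <- length(units)
  for (i in seq_len(nu)) check(units[i])
  for (i in seq_len(nu)) for (j in seq_len(nu))
    if (i <= j) check(units[c(i, j)])
  # triples on a reduced slot set to keep the sweep quick (the acceptance
  # suite runs the full window)
  red <- which(vapply(units, function(u) u$start <= 4500, logical(1)))
  for (i in red) for (j in red) for (k in red)
    if (i <= j && j <= k) check(units[c(i, j, k)])
  expect_gt(n_checked, 1000)
  succeed()
})

test_that("discontinuity components decompose tandem events", {
  tr <- rbind(fix_tract(mid_start = 10000, mid_end = 11800),
              fix_tract(mid_start = 12600, mid_end = 14400))
  ev <- group_events(tr, NULL)
  d <- discontinuity_components(ev, ev$events$event_id[1])
  expect_equal(d$event_length, 4400)
  expect_equal(d$tract_lengths, c(1800, 1800))
  expect_equal(d$gap_lengths, 800)

  one <- group_events(fix_tract(mid_start = 0, mid_end = 1500), NULL)
  d1 <- discontinuity_components(one, one$events$event_id[1])
  expect_equal(d1$event_length, 1500)
  expect_length(d1$gap_lengths, 0)
})

test_that("adjacent-event distances fall in exactly one category", {
  mk_ev <- function(chrom, start, end, is_co, chromatids) data.frame(
    chrom = chrom, start = start, end = end, is_co = is_co,
    chromatids = chromatids, mask = meiorec:::.chromatid_mask(chromatids),
    stringsAsFactors = FALSE)
  # single NCO: all categories empty
  d <- inter_event_distances(mk_ev("chr1", 0, 1000, FALSE, "1"))
  expect_equal(nrow(d), 0L)
  # two same-chromatid NCO footprints 9 kb apart
  ev <- rbind(mk_ev("chr1", 10000, 11000, FALSE, "1"),
              mk_ev("chr1", 20000, 21000, FALSE, "1"))
  d <- inter_event_distances(ev)
  expect_equal(d$category, "NCO-NCO same")
  expect_equal(d$distance, 9000)
  # randomized layouts match the brute-force oracle
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(2:40, 1)
    ch <- sample(c("chr1", "chr2"), n, replace = TRUE)
    s <- runif(n, 0, 1e5)
    ev <- mk_ev(ch, s, s + runif(n, 100, 2000),
                runif(n) < 0.4,
                vapply(seq_len(n), function(i)
                  paste(sort(sample(1:4, sample(1:2, 1))), collapse = ","),
                  character(1)))
    got <- inter_event_distances(ev)
    want <- oracle_distances(ev)
    got <- got[order(got$category, got$distance), ]
    want <- want[order(want$category, want$distance), ]
    expect_equal(got$category, want$category)
    expect_equal(got$distance, want$distance)
  }
})

test_that("labels are invariant under spore and chromosome relabeling", {
  p <- fast_params(co_mean = 8, nco_mean = 8, missing_rate = 0)
  sim <- simulate_meiosis(p, seed = 77)
  ev1 <- call_recombination(sim$tetrad)
  # permute spores
  perm <- c(3L, 1L, 4L, 2L)
  tet2 <- tetrad_genotypes(sim$tetrad$tetrad, sim$tetrad$spores,
                           sim$tetrad$calls[perm, ], sim$tetrad$map)
  ev2 <- call_recombination(tet2)
  expect_equal(table(ev1$events$class), table(ev2$events$class))
  # permute chromosome order in the map
  map <- sim$tetrad$map
  map2 <- suppressWarnings(marker_map(map$chromosomes[2:1, ], map$markers))
  o <- order(match(map$markers$chrom, map2$chromosomes$chrom),
             map$markers$pos)
  tet3 <- tetrad_genotypes(sim$tetrad$tetrad, sim$tetrad$spores,
                           sim$tetrad$calls[, o], map2)
  ev3 <- call_recombination(tet3)
  expect_equal(table(ev1$events$class), table(ev3$events$class))
})
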