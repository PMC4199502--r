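test_that("segregation classes are a pure function of the four calls", {
  map <- fix_map(pos = c(1000, 2000, 3000, 4000, 5000, 6000))
  expect_error(fix_tet(fix_map(pos = 1000), c("3", "1", "1", "2")),
               "calls must be")
  # each string is one spore; columns are markers
  tet <- fix_tet(map, c("112211",
                        "112121",
                        "21.221",
                        "221122"))
  prof <- segregation_profile(tet, "chr1")
  expect_equal(prof$class,
               c("S22", "S31", "INCOMPLETE", "S22", "S13", "S31"))
  expect_equal(prof$pos, map$markers$pos)
})

test_that("4:0 and 0:4 segregation are recognised", {
  map <- fix_map(pos = c(1000, 2000))
  tet <- fix_tet(map, c("12", "12", "12", "12"))
  expect_equal(segregation_profile(tet, "chr1")$class, c("S40", "S04"))
})

test_that("tract runs respect direction, bridging and 2:2 interruption", {
  map <- fix_map(pos = seq(1000, 8000, by = 1000))
  # one simple 3:1 run on spore 3 (markers 3..4)
  tet <- fix_tet(map, c("11111111",
                        "11111111",
                        "22112222",
                        "22222222"))
  tr <- call_tracts(tet, "chr1")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$chromatids, "3")
  expect_equal(tr$direction, "P1")
  expect_equal(tr$min_start, 3000)
  expect_equal(tr$min_end, 4000)
  expect_equal(tr$mid_start, 2500)
  expect_equal(tr$mid_end, 4500)
  expect_equal(tr$max_start, 2000)
  expect_equal(tr$max_end, 5000)

  # a missing call bridges the run instead of splitting it
  tet <- fix_tet(map, c("11111111",
                        "11111111",
                        "221.1222",
                        "22222222"))
  tr <- call_tracts(tet, "chr1")
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$min_start, tr$min_end), c(3000, 5000))

  # an intervening 2:2 marker splits the run: discontinuity is preserved
  tet <- fix_tet(map, c("11111111",
                        "11111111",
                        "22121222",
                        "22222222"))
  tr <- call_tracts(tet, "chr1")
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$min_start, c(3000, 5000))

  # a change of converted chromatid splits the run
  tet <- fix_tet(map, c("11111111",
                        "11111111",
                        "22112222",
                        "22221122"))
  tr <- call_tracts(tet, "chr1")
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$chromatids, c("3", "4"))

  # min_markers filter
  expect_equal(nrow(call_tracts(tet, "chr1", min_markers = 3L)), 0L)
})

test_that("4:0 tracts occupy the two converted chromatids", {
  map <- fix_map(pos = seq(1000, 5000, by = 1000))
  tet <- fix_tet(map, c("11111",
                        "11111",
                        "21112",
                        "21112"))
  tr <- call_tracts(tet, "chr1")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$chromatids, "3,4")
  expect_equal(tr$direction, "P1")
})

test_that("span conventions are ordered and marker-bounded", {
  p <- fast_params(co_mean = 8, nco_mean = 8, missing_rate = 0.01)
  sim <- simulate_meiosis(p, seed = 11)
  for (ch in test_genome()$chrom) {
    tr <- call_tracts(sim$tetrad, ch)
    if (!nrow(tr)) next
    expect_true(all(tr$max_start <= tr$mid_start))
    expect_true(all(tr$mid_start <= tr$min_start))
    expect_true(all(tr$min_end <= tr$mid_end))
    expect_true(all(tr$mid_end <= tr$max_end))
    # boundary uncertainty spans at least the neighbouring marker interval
    expect_true(all(tr$max_end - tr$min_end >= 0))
    expect_true(all(tr$min_start - tr$max_start >= 0))
  }
})

test_that("crossovers are reciprocal persistent phase switches", {
  map <- fix_map(pos = seq(1000, 8000, by = 1000))
  tet <- fix_tet(map, c("11112222",
                        "11111111",
                        "22221111",
                        "22222222"))
  co <- call_crossovers(tet, "chr1")
  expect_equal(nrow(co$breakpoints), 1L)
  expect_equal(co$breakpoints$spore_a, 1L)
  expect_equal(co$breakpoints$spore_b, 3L)
  expect_equal(co$breakpoints$start, 4000)
  expect_equal(co$breakpoints$end, 5000)
  expect_equal(nrow(co$complex), 0L)

  # uniform parental chromosome: no breakpoints
  tet <- fix_tet(map, c("11111111", "11111111", "22222222", "22222222"))
  expect_equal(nrow(call_crossovers(tet, "chr1")$breakpoints), 0L)

  # a conversion tract alone is masked, never called as two crossovers
  tet <- fix_tet(map, c("11111111",
                        "11111111",
                        "22112222",
                        "22222222"))
  expect_equal(nrow(call_crossovers(tet, "chr1")$breakpoints), 0L)

  # four spores changing at once cannot be phased: complex region
  tet <- fix_tet(map, c("11112222",
                        "11112222",
                        "22221111",
                        "22221111"))
  co <- call_crossovers(tet, "chr1")
  expect_equal(nrow(co$breakpoints), 0L)
  expect_equal(co$complex$n_changed, 4L)
})

test_that("crossover calling is idempotent under tract masking", {
  p <- fast_params(co_mean = 8, nco_mean = 8)
  sim <- simulate_meiosis(p, seed = 3)
  for (ch in test_genome()$chrom) {
    bp1 <- call_crossovers(sim$tetrad, ch)$breakpoints
    bp2 <- call_crossovers(sim$tetrad, ch)$breakpoints
    expect_identical(bp1, bp2)
  }
})

test_that("simulated crossovers are recovered in their marker intervals", {
  p <- fast_params(co_mean = 6, nco_mean = 0, missing_rate = 0)
  hits <- 0L; total <- 0L; spurious <- 0L
  for (s in 1:20) {
    sim <- simulate_meiosis(p, seed = 100 + s)
    tru <- sim$truth[sim$truth$kind == "breakpoint" & sim$truth$detectable, ]
    bps <- do.call(rbind, lapply(test_genome()$chrom, function(ch)
      call_crossovers(sim$tetrad, ch)$breakpoints))
    for (r in seq_len(nrow(tru))) {
      total <- total + 1L
      ok <- any(bps$chrom == tru$chrom[r] & bps$start <= tru$start[r] &
                  bps$end >= tru$start[r])
      hits <- hits + ok
    }
  }
  expect_equal(hits, total)

  # and no spurious calls on event-free meioses
  p0 <- fast_params(co_mean = 0, nco_mean = 0, missing_rate = 0)
  for (s in 1:5) {
    sim <- simulate_meiosis(p0, seed = 200 + s)
    for (ch in test_genome()$chrom) {
      spurious <- spurious +
        nrow(call_crossovers(sim$tetrad, ch)$breakpoints) +
        nrow(call_tracts(sim$tetrad, ch))
    }
  }
  expect_equal(spurious, 0L)
})

test_that("sisterhood is inferred from centromere-linked 2:2 markers", {
  map <- fix_map(pos = c(1000, 2000, 3000), cen = 2100)
  tet <- fix_tet(map, c("111", "111", "222", "222"))
  sis <- infer_sisterhood(tet)
  expect_equal(unname(sis[, "chr1"]), c(1L, 1L, 2L, 2L))

  # centromere-nearest marker not 2:2 -> nearest flanking 2:2 used
  tet <- fix_tet(map, c("111", "111", "212", "222"))
  sis <- infer_sisterhood(tet)
  expect_equal(unname(sis[, "chr1"]), c(1L, 1L, 2L, 2L))

  # no centromere in the map -> undefined
  map_nc <- fix_map(pos = c(1000, 2000, 3000))
  map_nc$chromosomes$centromere <- NA_real_
  tet <- fix_tet(map_nc, c("111", "111", "222", "222"))
  expect_true(all(is.na(infer_sisterhood(tet))))
})

test_that("inferred sisterhood matches generator truth almost always", {
  p <- fast_params(co_mean = 6, nco_mean = 5)
  ok <- 0L; total <- 0L
  for (s in 1:25) {
    sim <- simulate_meiosis(p, seed = 300 + s)
    sis <- infer_sisterhood(sim$tetrad)
    for (ch in colnames(sis)) {
      if (anyNA(sis[, ch])) next
      total <- total + 1L
      ok <- ok + identical(unname(sis[, ch]), c(1L, 1L, 2L, 2L))
    }
  }
  expect_gte(ok / total, 0.99)
})
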