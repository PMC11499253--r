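test_that("bout_table validates and sorts intervals", {
  b <- bt(c("male", "male"), c("mount", "mount"), c(50, 0), c(80, 20))
  expect_equal(b$start, c(0, 50))
  expect_error(bt("male", "mount", 10, 10), "start < stop")
  expect_error(bt("dog", "mount", 0, 10), "actor")
  expect_error(bt(c("male", "male"), c("mount", "mount"), c(0, 5),
                  c(10, 15)), "overlap")
})

test_that("merge_bouts fuses sub-threshold gaps and is idempotent", {
  # 4-s gap at 10 Hz merges under a 5-s threshold
  b <- bt(c("male", "male"), c("mount", "mount"), c(0, 60), c(20, 80))
  m <- merge_bouts(b, 5)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$stop), c(0, 80))
  # gap 0 leaves the table unchanged
  m0 <- merge_bouts(b, 0)
  expect_equal(m0$start, b$start)
  expect_equal(m0$stop, b$stop)
  # idempotent
  m2 <- merge_bouts(m, 5)
  expect_equal(m2$start, m$start)
  expect_equal(m2$stop, m$stop)
  expect_error(merge_bouts(b, -1), ">= 0")
})

test_that("merged coverage contains the original coverage (random tables)", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    gaps <- sample(1:60, n, replace = TRUE)
    durs <- sample(5:25, n, replace = TRUE)
    stops <- cumsum(gaps + durs)
    starts <- stops - durs
    b <- bt(rep("male", length(starts)), rep("mount", length(starts)),
            starts, stops)
    m <- merge_bouts(b, sample(1:8, 1))
    occ_in <- lineattractor:::occupancy(b, 1200)
    occ_out <- lineattractor:::occupancy(m, 1200)
    expect_true(all(occ_out[occ_in]))
    expect_lte(nrow(m), nrow(b))
  }
})

test_that("behavior_probability reports per-bin occupancy in [0, 1]", {
  # one accept bout covering an entire 20-s bin
  b <- bt("female", "lordose", 200, 400)
  p <- behavior_probability(b, n_frames = 600, bin = 20)
  expect_equal(unname(p[2, "accept"]), 1)
  expect_true(all(p >= 0 & p <= 1))
  # multi-label: groups are scored independently, sums can exceed 1
  b2 <- bt(c("female", "female"), c("lordose", "approach"), c(0, 0),
           c(200, 200))
  p2 <- behavior_probability(b2, n_frames = 200, bin = 20)
  expect_equal(sum(p2[1, ]), 2)
  # empty table gives all-zero probabilities
  p0 <- behavior_probability(bt(character(), character(), integer(),
                                integer()), n_frames = 600, bin = 20)
  expect_true(all(p0 == 0))
  # occurrence mode is binary
  p3 <- behavior_probability(b, 600, 20, mode = "occurrence")
  expect_true(all(p3 %in% c(0, 1)))
})

test_that("bout_ibi_stats computes durations and IBIs in seconds", {
  b <- bt(c("male", "male"), c("mount", "intromission"), c(0, 20),
          c(10, 30))
  st <- bout_ibi_stats(b)
  expect_equal(st$ibis, 1.0)
  expect_equal(st$durations, c(1, 1))
  # fewer than 2 copulation bouts: no IBIs
  st1 <- bout_ibi_stats(bt("male", "mount", 0, 10))
  expect_length(st1$ibis, 0)
  # order invariance: statistics only depend on the interval set
  b2 <- bt(c("male", "male", "male"), c("mount", "intromission", "mount"),
           c(100, 0, 300), c(150, 50, 340))
  b3 <- bt(c("male", "male", "male"), c("intromission", "mount", "mount"),
           c(0, 300, 100), c(50, 340, 150))
  expect_equal(bout_ibi_stats(b2)$ibis, bout_ibi_stats(b3)$ibis)
})

test_that("initiation_split fractions and male/female ratio", {
  # all-lordose session is fully responsive
  f <- bt("female", "lordose", 0, 100)
  m <- bt("male", "mount", 0, 100)
  s <- initiation_split(f, m)
  expect_equal(s$responsive_fraction, 1)
  # constructed 83.9% responsive / 16.1% self-initiated split
  f2 <- bt(c("female", "female"), c("lordose", "approach"), c(0, 1000),
           c(839, 1161))
  s2 <- initiation_split(f2, m)
  expect_equal(s2$responsive_fraction, 0.839, tolerance = 1e-9)
  expect_equal(s2$self_initiated_fraction, 0.161, tolerance = 1e-9)
  expect_equal(s2$responsive_fraction + s2$self_initiated_fraction, 1,
               tolerance = 1e-9)
  # 11.3:1 male/female self-initiated time ratio
  f3 <- bt("female", "approach", 0, 100)
  m3 <- bt("male", "sniff", 0, 1130)
  expect_equal(initiation_split(f3, m3)$male_female_ratio, 11.3)
  # zero female mating time is flagged undefined
  s0 <- initiation_split(bt(character(), character(), integer(),
                            integer()), m)
  expect_false(s0$defined)
})

test_that("engagement_fractions recovers constructed bout/IBI splits", {
  n_frames <- 1000
  male <- bt(c("male", "male"), c("mount", "mount"), c(0, 500),
             c(100, 600))
  # female social covers 62% of each bout, 23% of the IBI
  fem <- bt(c("female", "female", "female"),
            c("lordose", "wiggle", "approach"),
            c(0, 500, 100 + 0), c(62, 562, 100 + 92))
  e <- engagement_fractions(fem, male, n_frames)
  expect_equal(e$bouts$social, c(0.62, 0.62), tolerance = 1e-9)
  expect_equal(e$ibis$social, 0.23, tolerance = 1e-9)
  # full coverage gives fraction 1
  fem2 <- bt("female", "lordose", 0, 100)
  e2 <- engagement_fractions(fem2, bt("male", "mount", 0, 100), 200)
  expect_equal(e2$bouts$social, 1)
  # complementary fractions sum to 1
  expect_equal(e$bouts$social + e$bouts$disengaged + e$bouts$others,
               c(1, 1), tolerance = 1e-9)
})

test_that("bout CSV round-trips and rejects malformed rows", {
  path <- tempfile(fileext = ".csv")
  b <- bt(c("male", "male", "female"), c("mount", "sniff", "lordose"),
          c(0, 30, 5), c(10, 50, 9))
  write_bouts(b, path)
  b2 <- read_bouts(path)
  expect_equal(b2$start, b$start)
  expect_equal(b2$behavior, b$behavior)
  # malformed row is named
  df <- utils::read.csv(path)
  df$stop_frame[2] <- df$start_frame[2]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_bouts(path), "row")
  # overlapping rows are rejected with row numbers
  df2 <- data.frame(actor = "male", behavior = "mount",
                    start_frame = c(0, 5), stop_frame = c(10, 15))
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_bouts(path), "overlap")
})
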