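test_that("block averaging reproduces the analytic oracle on 1:10", {
  bs <- block_stats(1:10, n_blocks = 5)
  # block means 1.5, 3.5, 5.5, 7.5, 9.5 -> sd = sqrt(10), se = sqrt(2)
  expect_equal(bs$mean, 5.5)
  expect_equal(bs$se, sqrt(2))
  expect_equal(bs$sd, stats::sd(1:10))
  expect_equal(bs$block_size, 2L)
})

test_that("block SE matches a direct hand computation on random series", {
  set.seed(7)
  for (k in 1:10) {
    n_blocks <- sample(2:6, 1)
    bsz <- sample(3:9, 1)
    x <- stats::rnorm(n_blocks * bsz, mean = 10, sd = 3)
    got <- block_stats(x, n_blocks = n_blocks)
    bm <- colMeans(matrix(x, nrow = bsz))
    expect_equal(got$mean, mean(x))
    expect_equal(got$se, stats::sd(bm) / sqrt(n_blocks))
  }
})

test_that("a constant series has zero block SE and zero SD", {
  bs <- block_stats(rep(4, 20), n_blocks = 5)
  expect_equal(bs$mean, 4)
  expect_equal(bs$se, 0)
  expect_equal(bs$sd, 0)
})

test_that("ragged series are an error unless truncation is requested", {
  expect_error(block_stats(1:11, n_blocks = 5), "equal blocks")
  bs <- block_stats(1:11, n_blocks = 5, allow_ragged = TRUE)
  expect_equal(bs$mean, mean(1:10))
  expect_equal(bs$block_size, 2L)
  expect_error(block_stats(1:3, n_blocks = 5), "shorter")
  expect_error(block_stats(1:10, n_blocks = 1), "at least 2")
})

test_that("lifetime and partner counts recover a planted schedule", {
  # residue 1: contacts in 6 of 10 frames, always PIP2 lipid 1
  # residue 2: contacts in all frames, alternating PIP2 lipids 3 and 4
  pl <- rbind(
    data.frame(frame = c(1, 2, 3, 6, 7, 10), residue = 1, lipid = 1),
    data.frame(frame = 1:10, residue = 2, lipid = rep(c(3, 4), 5))
  )
  sys <- make_toy_system(n_frames = 10, planted = pl, seed = 11)
  ct <- find_contacts(sys$frames, sys$topology)

  r1 <- lifetime_and_partners(ct, residue = 1, topology = sys$topology)
  expect_equal(r1$lifetime_percent, 60)
  expect_equal(r1$n_partners, 1L)

  r2 <- lifetime_and_partners(ct, residue = 2)
  expect_equal(r2$lifetime_percent, 100)
  expect_equal(r2$n_partners, 2L)

  # residue 3 never binds
  r3 <- lifetime_and_partners(ct, residue = 3)
  expect_equal(r3$lifetime_percent, 0)
  expect_equal(r3$n_partners, 0L)

  expect_error(
    lifetime_and_partners(ct, residue = 99, topology = sys$topology),
    "not found"
  )
})

test_that("window clipping renumbers frames and preserves statistics", {
  pl <- data.frame(frame = c(1, 5, 6, 10), residue = 1, lipid = 1)
  sys <- make_toy_system(n_frames = 10, planted = pl, seed = 12)
  ct <- find_contacts(sys$frames, sys$topology)

  # frames at t = (0:9)*0.24 ns; [0.96, 2.4) keeps frames 5..10
  win <- clip_window(ct, 0.96, 2.4)
  expect_equal(attr(win, "n_frames"), 6L)
  expect_equal(sort(unique(win$frame)), c(1L, 2L, 6L))
  r <- lifetime_and_partners(win, residue = 1)
  expect_equal(r$lifetime_percent, 100 * 3 / 6)
  expect_error(clip_window(ct, 100, 200), "empty")
})

test_that("the residue table ranks by mean contacts and applies min_mean", {
  # residue 1: 3 pairs every frame (mean 3); residue 2: 2 pairs every frame;
  # residue 3: 1 pair in half the frames (mean 0.5, filtered out)
  fr <- 1:10
  pl <- rbind(
    data.frame(frame = rep(fr, each = 3), residue = 1, lipid = rep(c(1, 2, 3), 10)),
    data.frame(frame = rep(fr, each = 2), residue = 2, lipid = rep(c(1, 4), 10)),
    data.frame(frame = seq(1, 10, by = 2), residue = 3, lipid = 2)
  )
  sys <- make_toy_system(n_frames = 10, planted = pl, seed = 13)
  ct <- find_contacts(sys$frames, sys$topology)
  tab <- residue_table(ct, species = "PIP2", n_blocks = 5)

  expect_equal(tab$residue_number, c(1L, 2L))
  expect_equal(tab$rank, 1:2)
  expect_equal(tab$mean_contacts, c(3, 2))
  # constant series -> zero block SE
  expect_equal(tab$se_contacts, c(0, 0))
  expect_equal(tab$lifetime_percent, c(100, 100))
  expect_equal(tab$n_partners, c(3L, 2L))

  # lowering min_mean admits residue 3 with mean 0.5 and lifetime 50%
  tab0 <- residue_table(ct, species = "PIP2", min_mean = 0, n_blocks = 5)
  expect_equal(tab0$residue_number, c(1L, 2L, 3L))
  expect_equal(tab0$mean_contacts[3], 0.5)
  expect_equal(tab0$lifetime_percent[3], 50)
})

test_that("rank ties break by residue number and domains split at the boundary", {
  pl <- rbind(
    data.frame(frame = 1:10, residue = 2, lipid = 1),
    data.frame(frame = 1:10, residue = 1, lipid = 2)
  )
  sys <- make_toy_system(n_frames = 10, planted = pl, seed = 14)
  ct <- find_contacts(sys$frames, sys$topology)
  tab <- residue_table(ct, n_blocks = 5, n_term_end = 1)
  expect_equal(tab$residue_number, c(1L, 2L))
  expect_equal(tab$domain, c("N", "C"))
})

test_that("simultaneous partner mode counts per-frame maxima", {
  # residue 1 touches lipids 1 and 2 in frame 1, lipid 3 in frame 2:
  # cumulative 3, simultaneous 2
  pl <- data.frame(frame = c(1, 1, 2), residue = 1, lipid = c(1, 2, 3))
  sys <- make_toy_system(n_frames = 2, planted = pl, seed = 15)
  ct <- find_contacts(sys$frames, sys$topology)
  cum <- residue_table(ct, min_mean = 0, n_blocks = 2)
  sim <- residue_table(ct, min_mean = 0, n_blocks = 2, partner_mode = "simultaneous")
  expect_equal(cum$n_partners, 3L)
  expect_equal(sim$n_partners, 2L)
})

test_that("residue table attaches site ratios for PIP2 rows", {
  pl <- data.frame(
    frame = 1, residue = 1, lipid = c(1, 1), atom_name = c("P4", "P5")
  )
  sys <- make_toy_system(n_frames = 1, planted = pl, seed = 16)
  ct <- find_contacts(sys$frames, sys$topology)
  sm <- build_site_map(sys$topology)
  tab <- residue_table(ct, min_mean = 0, n_blocks = 2, site_map = sm,
                       allow_ragged = TRUE, n_frames = 2)
  expect_equal(tab$P4p, 50) # lipid 1 is the 4-protonated species
  expect_equal(tab$P5np, 50)
})

test_that("distinct-lipid summaries separate window and per-frame counts", {
  # 4 frames; lipid 1 in frames 1-4, lipid 2 in frame 1, lipid 3 in frame 2
  pl <- data.frame(
    frame = c(1, 2, 3, 4, 1, 2),
    residue = c(1, 1, 1, 1, 2, 3),
    lipid = c(1, 1, 1, 1, 2, 3)
  )
  sys <- make_toy_system(n_frames = 4, planted = pl, seed = 17)
  ct <- find_contacts(sys$frames, sys$topology)
  d <- distinct_lipid_summary(ct, species = "PIP2")
  expect_equal(d$distinct_over_window, 3L)
  expect_equal(d$mean_per_frame, (2 + 2 + 1 + 1) / 4)

  # no POPA contacts at all
  d0 <- distinct_lipid_summary(ct, species = "POPA")
  expect_equal(d0$distinct_over_window, 0L)
  expect_equal(d0$mean_per_frame, 0)
})
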