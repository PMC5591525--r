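# Interval arithmetic: Jaccard, method intersection, replicate filtering,
# merging, splitting.

test_that("jaccard similarity matches per-base arithmetic on known cases", {
  a <- mk_peaks("X", 0, 100)
  expect_equal(jaccard_similarity(a, a), 1.0)
  b <- mk_peaks("X", 200, 300)
  expect_equal(jaccard_similarity(a, b), 0.0)
  c_ <- mk_peaks("X", 50, 150)
  expect_equal(jaccard_similarity(a, c_), 50 / 150)
  expect_error(jaccard_similarity(mk_peaks("X", integer(0), integer(0)),
                                  mk_peaks("Y", integer(0), integer(0))),
               "empty")
})

test_that("jaccard is symmetric and agrees with the boolean-vector oracle", {
  set.seed(101)
  for (i in 1:25) {
    da <- random_intervals(sample(3:20, 1), 10000L)
    db <- random_intervals(sample(3:20, 1), 10000L)
    ja <- jaccard_similarity(gr_from_0based(da), gr_from_0based(db))
    expect_equal(ja, ob_jaccard(da$start, da$end, db$start, db$end, 10000L))
    expect_equal(ja, jaccard_similarity(gr_from_0based(db),
                                        gr_from_0based(da)))
  }
})

test_that("method intersection keeps primary coordinates of overlapping peaks", {
  prim <- mk_peaks("RBP1", c(0, 100), c(50, 150), counts = c(7L, 9L))
  other <- mk_peaks("RBP1", 40, 60, method = "m2")
  out <- intersect_methods(prim, other)
  expect_equal(length(out), 1L)
  expect_equal(start(out$peaks), 1L)       # kept its own coordinates
  expect_equal(end(out$peaks), 50L)
  expect_equal(out$peaks$read_count, 7L)

  expect_equal(length(intersect_methods(prim, mk_peaks("RBP1", 500, 600))), 0L)
  same <- intersect_methods(prim, prim)
  expect_equal(granges(same$peaks), granges(prim$peaks))
  expect_error(intersect_methods(prim, mk_peaks("RBP2", 0, 50)), "mismatch")
})

test_that("replicate filter applies the more-than-3-reads semi-overlap rule", {
  r1 <- mk_peaks("R", c(0, 200), c(50, 260), counts = c(10L, 10L),
                 replicate = "r1")
  r2 <- mk_peaks("R", c(0, 200), c(50, 260), counts = c(10L, 10L),
                 replicate = "r2")
  expect_equal(length(filter_replicas(list(r1, r2))), 2L)

  # present in one replicate only -> dropped
  r2b <- mk_peaks("R", 0, 50, counts = 10L, replicate = "r2")
  kept <- filter_replicas(list(r1, r2b))
  expect_equal(length(kept), 1L)
  expect_equal(start(kept$peaks) - 1L, 0L)

  # overlapping partner with only 3 reads does not qualify
  r2c <- mk_peaks("R", c(0, 200), c(50, 260), counts = c(10L, 3L),
                  replicate = "r2")
  kept <- filter_replicas(list(r1, r2c))
  expect_equal(length(kept), 1L)

  # single replicate falls back to the count filter alone
  solo <- mk_peaks("R", c(0, 100), c(50, 160), counts = c(3L, 4L))
  kept <- filter_replicas(list(solo))
  expect_equal(length(kept), 1L)
  expect_equal(kept$peaks$read_count, 4L)

  expect_error(filter_replicas(list()), "non-empty")
  expect_error(filter_replicas(list(r1, mk_peaks("S", 0, 10))), "rbp_id")
})

test_that("replicate filter is invariant to replica order", {
  set.seed(77)
  reps <- lapply(1:3, function(k) {
    d <- random_intervals(15, 5000L)
    mk_peaks("R", d$start, d$end, counts = sample(1:12, 15, TRUE),
             replicate = paste0("r", k))
  })
  a <- filter_replicas(reps)
  b <- filter_replicas(rev(reps))
  expect_equal(granges(a$peaks), granges(b$peaks))
  expect_equal(a$peaks$read_count, b$peaks$read_count)
})

test_that("merged sites coalesce overlapping peaks and track contributors", {
  one <- merge_sites(list(mk_peaks("A", 10, 60)))
  expect_equal(length(one), 1L)
  expect_equal(as.character(one$source_rbps[[1]]), "A")

  two <- merge_sites(list(mk_peaks("A", 0, 60), mk_peaks("B", 40, 90)))
  expect_equal(length(two), 1L)
  expect_equal(start(two) - 1L, 0L)
  expect_equal(end(two), 90L)
  expect_setequal(as.character(two$source_rbps[[1]]), c("A", "B"))

  apart <- merge_sites(list(mk_peaks("A", 0, 60), mk_peaks("B", 70, 90)))
  expect_equal(length(apart), 2L)
})

test_that("merged sites are disjoint, non-bookended, and cover the input union", {
  set.seed(202)
  for (i in 1:25) {
    sets <- lapply(1:4, function(k) {
      d <- random_intervals(sample(5:25, 1), 10000L)
      mk_peaks(paste0("R", k), d$start, d$end)
    })
    sites <- merge_sites(sets)
    s0 <- start(sites) - 1L
    e0 <- end(sites)
    # pairwise disjoint and not bookended (sorted output)
    if (length(sites) > 1L) expect_true(all(s0[-1L] > e0[-length(e0)]))
    # per-base union equals oracle runs
    all_iv <- do.call(rbind, lapply(sets, function(ps)
      data.frame(start = start(ps$peaks) - 1L, end = end(ps$peaks))))
    runs <- ob_runs(ob_cover(all_iv$start, all_iv$end, 10000L))
    expect_equal(s0, runs$start)
    expect_equal(e0, runs$end)
    # every site credits at least one source RBP
    expect_true(all(lengths(sites$source_rbps) >= 1L))
  }
})

test_that("long sites split into end-anchored overlapping bins", {
  mk_site <- function(s0, e0) {
    g <- gr_from_0based(data.frame(start = s0, end = e0))
    g$site_id <- "site_00001"
    g$source_rbps <- IRanges::CharacterList(list("A"))
    g$annotation <- NA_character_
    g$parent_id <- NA_character_
    g
  }
  # boundary length passes through untouched
  same <- split_long_sites(mk_site(0, 100))
  expect_equal(width(same), 100L)
  expect_true(is.na(same$parent_id))

  b250 <- split_long_sites(mk_site(0, 250))
  expect_equal(start(b250) - 1L, c(0, 50, 100, 150))
  expect_equal(end(b250), c(100, 150, 200, 250))

  b230 <- split_long_sites(mk_site(0, 230))
  expect_equal(start(b230) - 1L, c(0, 50, 100, 130))
  expect_equal(end(b230), c(100, 150, 200, 230))
  expect_equal(unique(b230$parent_id), "site_00001")

  expect_error(split_long_sites(mk_site(0, 250), bin_len = 50, step = 50),
               "bin_len > step")
})

test_that("split bins cover every parent base with exact widths and overlap", {
  set.seed(303)
  for (i in 1:20) {
    d <- random_intervals(10, 10000L, max_w = 600L)
    sites <- merge_sites(list(mk_peaks("A", d$start, d$end)))
    bins <- split_long_sites(sites, bin_len = 100L, step = 50L)
    expect_true(all(width(bins) <= 100L))
    long <- which(width(sites) > 100L)
    for (k in long) {
      kids <- bins[!is.na(bins$parent_id) &
                     bins$parent_id == sites$site_id[k]]
      expect_true(all(width(kids) == 100L))
      cov <- ob_cover(start(kids) - 1L, end(kids), 10000L)
      parent_cov <- ob_cover(start(sites)[k] - 1L, end(sites)[k], 10000L)
      expect_true(all(cov[parent_cov]))        # full parent coverage
      expect_true(all(cov == (cov & parent_cov) | !cov)) # bins inside parent
      s <- sort(start(kids))
      if (length(kids) > 1L)
        expect_true(all(diff(s) <= 50L))       # >= 50 bp mutual overlap
    }
  }
})
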