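mk_targets <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("target_intervals", class(tibble::tibble())))
}

test_that("distance is zero inside targets and gap-counted outside", {
  tg <- mk_targets(tibble::tibble(contig = "c1", start = 101L, end = 200L))
  expect_equal(distance_to_target(
    tibble::tibble(contig = "c1", position = 150L), tg), 0)
  expect_equal(distance_to_target(
    tibble::tibble(contig = "c1", position = 205L), tg), 5)
  tg2 <- mk_targets(tibble::tibble(contig = "c1", start = c(50L, 101L),
                                   end = c(60L, 200L)))
  expect_equal(distance_to_target(
    tibble::tibble(contig = "c1", position = 96L), tg2), 5)
  # contig with no targets is uncapturable
  expect_equal(distance_to_target(
    tibble::tibble(contig = "cZ", position = 10L), tg), Inf)
})

test_that("distance agrees with a per-base brute-force scan on random fixtures", {
  set.seed(61)
  for (i in 1:300) {
    k <- sample(0:4, 1)
    starts <- sort(sample(1:9000, k))
    ends <- pmin(starts + sample(10:400, max(k, 1))[seq_len(k)], 10000L)
    # drop overlapping intervals to respect the merged-input precondition
    if (k > 1) {
      keep <- c(TRUE, starts[-1] > utils::head(ends, -1))
      starts <- starts[keep]
      ends <- ends[keep]
    }
    tg <- mk_targets(tibble::tibble(contig = "c1", start = starts, end = ends))
    pos <- sample(1:10000, 5)
    got <- distance_to_target(tibble::tibble(contig = "c1", position = pos), tg)
    want <- vapply(pos, oracle_distance, 0, starts = starts, ends = ends)
    expect_equal(got, want)
  }
})

test_that("enlarging every interval never increases any distance", {
  set.seed(62)
  for (i in 1:20) {
    starts <- sort(sample(seq(1, 9000, by = 600), 5))
    ends <- starts + 100L
    pos <- sample(1:10000, 10)
    base <- distance_to_target(tibble::tibble(contig = "c1", position = pos),
                               mk_targets(tibble::tibble(contig = "c1",
                                                         start = starts,
                                                         end = ends)))
    for (p in c(10L, 50L, 200L)) {
      grown <- distance_to_target(
        tibble::tibble(contig = "c1", position = pos),
        mk_targets(tibble::tibble(contig = "c1",
                                  start = pmax(starts - p, 1L),
                                  end = ends + p)))
      expect_true(all(grown <= base))
    }
  }
})

test_that("padding partitions sites into three classes", {
  tg <- mk_targets(tibble::tibble(contig = "c1", start = 101L, end = 200L))
  sites <- tibble::tibble(contig = "c1", position = c(150L, 240L, 600L))
  ann <- classify_off_target(sites, tg, padding = 100)
  expect_equal(ann$category, c("on_target", "within_padding", "beyond_padding"))
  expect_equal(ann$within_padding, c(TRUE, TRUE, FALSE))
  # padding zero empties the within-padding class for positive distances
  ann0 <- classify_off_target(sites, tg, padding = 0)
  expect_false(any(ann0$category == "within_padding"))
  # growing padding never shrinks the within-padding class
  for (p in c(0, 40, 100, 500)) {
    a1 <- classify_off_target(sites, tg, padding = p)
    a2 <- classify_off_target(sites, tg, padding = p + 50)
    expect_true(all(a2$within_padding[a1$within_padding]))
  }
})

test_that("beyond-padding counts match a brute-force recount on random fixtures", {
  set.seed(63)
  for (i in 1:25) {
    starts <- sort(sample(seq(1, 9000, by = 700), 4))
    ends <- starts + sample(50:200, 4)
    tg <- mk_targets(tibble::tibble(contig = "c1", start = starts, end = ends))
    sites <- tibble::tibble(contig = "c1", position = sample(1:10000, 30))
    ann <- classify_off_target(sites, tg, padding = 100)
    brute <- sum(vapply(sites$position, oracle_distance, 0,
                        starts = starts, ends = ends) > 100)
    expect_equal(sum(ann$category == "beyond_padding"), brute)
    expect_equal(nrow(offtarget_report(ann)), brute)
  }
})

test_that("coverage bins report medians, maxima and low-coverage flags", {
  tg <- mk_targets(tibble::tibble(contig = "c1", start = 1000L, end = 2000L))
  sites <- tibble::tibble(
    contig = c(rep("c1", 5), "c2"),  # last site's contig has no targets
    position = c(1500L, 1990L, 2040L, 2150L, 2150L, 9000L),
    aggregate_depth = c(900, 700, 400, 120, 90, 30)
  )
  ann <- classify_off_target(sites, tg)
  cov <- coverage_by_distance(ann, bin_edges = c(0, 1, 101, 201, Inf),
                              low_coverage_threshold = 150)
  on_bin <- cov[cov$bin == "[0,1)", ]
  expect_equal(on_bin$n_sites, 2L)
  expect_equal(on_bin$median_depth, 800)
  expect_false(on_bin$low_coverage)
  far_bin <- cov[cov$bin == "[101,201)", ]
  expect_equal(far_bin$n_sites, 2L)
  expect_true(far_bin$low_coverage)   # max 120 < 150
  expect_equal(cov$n_sites[cov$bin == "[201,Inf)"], 0L)
  expect_true(is.na(cov$median_depth[cov$bin == "[201,Inf)"]))
  expect_equal(cov$n_sites[cov$bin == "uncaptured"], 1L)
  expect_equal(cov$median_depth[cov$bin == "uncaptured"], 30)
})

test_that("a single site beyond padding with sub-threshold depth flags its bin", {
  tg <- mk_targets(tibble::tibble(contig = "c1", start = 1000L, end = 2000L))
  sites <- tibble::tibble(contig = "c1", position = 2150L,
                          aggregate_depth = 120)
  cov <- coverage_by_distance(classify_off_target(sites, tg),
                              low_coverage_threshold = 150)
  expect_true(any(cov$low_coverage, na.rm = TRUE))
})

test_that("bin medians match a sort-based recomputation on random fixtures", {
  set.seed(64)
  tg <- mk_targets(tibble::tibble(contig = "c1", start = 5000L, end = 5100L))
  for (i in 1:20) {
    sites <- tibble::tibble(
      contig = "c1", position = sample(1:10000, 40),
      aggregate_depth = sample(10:2000, 40)
    )
    ann <- classify_off_target(sites, tg)
    edges <- c(0, 1, 101, 501, Inf)
    cov <- coverage_by_distance(ann, bin_edges = edges)
    d <- ann$distance
    for (b in seq_len(length(edges) - 1)) {
      sel <- d >= edges[b] & d < edges[b + 1]
      lab <- paste0("[", edges[b], ",", edges[b + 1], ")")
      if (any(sel)) {
        expect_equal(cov$median_depth[cov$bin == lab],
                     oracle_median(ann$aggregate_depth[sel]))
      }
    }
  }
})
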