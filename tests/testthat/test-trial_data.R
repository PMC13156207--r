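test_that("ingestion recodes labels, infers K, and reconstructs columns", {
  raw <- data.frame(participant = rep(1:2, each = 4),
                    stimulus = rep(c("left", "right"), 4),
                    response = c("left", "right", "right", "left",
                                 "left", "left", "right", "right"),
                    rt = seq(0.5, 1.9, by = 0.2),
                    confidence = c(1, 4, 2, 3, 1, 2, 4, 3))
  tr <- ingest_trials(raw, n_ratings = 4, rating = "confidence")
  expect_equal(attr(tr, "n_ratings"), 4)
  expect_setequal(unique(tr$stimulus), c(-1L, 1L))
  expect_setequal(unique(tr$response), c(-1L, 1L))
  expect_equal(tr$correct, as.integer(tr$stimulus == tr$response))
  # 'left' sorts before 'right' -> -1/+1 by sorted order
  expect_equal(tr$stimulus[1], -1L)

  # response reconstructed from correct: R = S * (2*correct - 1)
  raw2 <- data.frame(stimulus = c(-1, 1, -1, 1), correct = c(1, 0, 0, 1),
                     rt = c(0.5, 0.7, 0.9, 1.1), rating = c(1, 2, 2, 1))
  tr2 <- ingest_trials(raw2)
  expect_equal(tr2$response, c(-1L, -1L, 1L, 1L))
  expect_equal(attr(tr2, "n_ratings"), 2)

  # already-signed values are kept (involutive recoding)
  tr3 <- ingest_trials(as.data.frame(tr2))
  expect_equal(tr3$response, tr2$response)
  expect_equal(tr3$stimulus, tr2$stimulus)
})

test_that("unused rating categories are tracked per response sign", {
  raw <- data.frame(stimulus = rep(c(-1, 1), 10), correct = rep(1, 20),
                    rt = runif(20, 0.5, 2),
                    rating = rep(c(1, 2, 3, 1, 2), 4))
  tr <- ingest_trials(raw, n_ratings = 4)
  used <- attr(tr, "rating_info")$used
  expect_false(4 %in% used$`-1`)
  expect_false(4 %in% used$`1`)
})

test_that("ingestion fails loudly on bad input", {
  base <- data.frame(stimulus = c(-1, 1), response = c(-1, 1),
                     rt = c(0.5, 0.8), rating = c(1, 2))
  expect_error(ingest_trials(base[-3]), "rt")
  expect_error(ingest_trials(transform(base, rt = c(-0.2, 0.8))),
               "non-positive")
  expect_error(ingest_trials(base, n_ratings = 4, rating = "confidence"),
               "confidence")
  expect_error(ingest_trials(transform(base, rating = c(0, 2)),
                             n_ratings = 3), "rating")
  # conflicting correct column: fail, do not silently prefer either
  expect_error(ingest_trials(transform(base, correct = c(0, 1))),
               "conflict")
})

test_that("ingest(write(T)) round trips", {
  tr <- ingest_trials(make_trials(10), n_ratings = 3)
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tr), f, row.names = FALSE)
  tr2 <- ingest_trials(f, n_ratings = 3)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("split_by_subject partitions and preserves rows", {
  tr <- make_trials(5, subjects = 2)
  sp <- split_by_subject(tr)
  expect_length(sp, 2)
  expect_equal(sum(vapply(sp, nrow, integer(1))), nrow(tr))

  expect_length(split_by_subject(tr[0, ]), 0)

  tr3 <- data.frame(subject = c(3, 1, 1), stimulus = 1, condition = 1,
                    response = 1, rt = 1, rating = 1, correct = 1)
  sp3 <- split_by_subject(tr3)
  expect_equal(sort(vapply(sp3, nrow, integer(1))), c(1L, 2L),
               ignore_attr = TRUE)

  expect_warning(sp1 <- split_by_subject(tr3[-1]), "single group")
  expect_length(sp1, 1)
})

test_that("RT outlier helper applies the stated cutoffs per subject", {
  tr <- make_trials(50, subjects = 2)
  tr$rt[1] <- 0.1    # below lower cutoff
  tr$rt[2] <- 50     # far above mean + k*sd
  expect_message(out <- filter_rt_outliers(tr, lower = 0.3, k_sd = 2),
                 "removed")
  expect_false(any(out$rt < 0.3))
  expect_lt(nrow(out), nrow(tr))
})
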