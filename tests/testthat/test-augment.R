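test_that("recombined trials are segment-wise copies of same-class donors", {
  x <- random_epochs(n = 10, C = 3, T = 200, K = 2, seed = 2)
  cfg <- augmentation_config(n_segments = 8, segment_len = 25, factor = 2,
                             seed = 1)
  aug <- segment_recombine(x, cfg)
  expect_equal(n_trials(aug), 30)
  expect_identical(aug$data[1:10, , ], x$data)       # originals kept verbatim

  prov <- attr(aug, "provenance")
  expect_equal(nrow(prov), 20 * 8)
  id2row <- match(prov$donor_id, x$trial_ids)
  for (r in seq_len(nrow(prov))) {
    ai <- 10L + match(prov$trial_id[r], unique(prov$trial_id))
    seg <- ((prov$segment[r] - 1L) * 25L + 1L):(prov$segment[r] * 25L)
    # channel coherence: the whole channel group comes from one donor
    expect_identical(aug$data[ai, , seg], x$data[id2row[r], , seg])
    # label conservation at the donor level
    expect_identical(aug$labels[ai], x$labels[id2row[r]])
  }
})

test_that("label histogram of augmented-only trials is factor x original", {
  set.seed(3)
  x <- eeg_epochs(array(rnorm(9 * 2 * 100), c(9, 2, 100)),
                  c(0, 0, 0, 0, 1, 1, 1, 2, 2), 250)
  aug <- segment_recombine(x, augmentation_config(4, 25, factor = 3, seed = 0))
  new_labels <- aug$labels[-(1:9)]
  expect_equal(as.vector(table(new_labels)), 3 * c(4, 3, 2))
})

test_that("a single-donor class reproduces its one trial exactly", {
  set.seed(4)
  x <- eeg_epochs(array(rnorm(3 * 2 * 100), c(3, 2, 100)),
                  c(0, 1, 1), 250)
  aug <- segment_recombine(x, augmentation_config(4, 25, factor = 5, seed = 2))
  new0 <- which(aug$labels == 0)[-1]          # augmented class-0 trials
  for (i in new0)
    expect_identical(aug$data[i, , ], x$data[1, , ])
})

test_that("two donors x two segments: every output is one of the 4 recombinations", {
  set.seed(5)
  x <- eeg_epochs(array(rnorm(2 * 2 * 50), c(2, 2, 50)), c(0, 0), 250)
  seg1 <- 1:25; seg2 <- 26:50
  # brute-force enumeration of all 2^2 possible recombinations
  combos <- list()
  for (d1 in 1:2) for (d2 in 1:2) {
    tr <- x$data[d1, , , drop = FALSE][1, , ]
    tr[, seg2] <- x$data[d2, , seg2]
    combos[[length(combos) + 1L]] <- tr
  }
  seen <- logical(4)
  for (seed in 0:24) {
    aug <- segment_recombine(x, augmentation_config(2, 25, factor = 1,
                                                    seed = seed))
    for (i in 3:n_trials(aug)) {
      match_found <- FALSE
      for (ci in 1:4)
        if (isTRUE(all.equal(aug$data[i, , ], combos[[ci]]))) {
          seen[ci] <- TRUE; match_found <- TRUE
        }
      expect_true(match_found)
    }
  }
  expect_true(all(seen))                       # sweep reaches all 4 combos
})

test_that("configuration errors are caught", {
  x <- random_epochs(n = 4, T = 200, K = 2)
  expect_error(segment_recombine(x, augmentation_config(8, 30)),
               "trial length")
  expect_error(augmentation_config(factor = -1), "non-negative")
  expect_error(augmentation_config(factor = 1.5), "non-negative")
  # factor 0 returns the input with empty provenance
  aug0 <- segment_recombine(x, augmentation_config(8, 25, factor = 0))
  expect_equal(n_trials(aug0), 4)
  expect_equal(nrow(attr(aug0, "provenance")), 0)
})
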