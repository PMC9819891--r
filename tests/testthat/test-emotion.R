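# Valence-arousal annotation, quadrants, and transition-table estimation.

test_that("the default anchor set is complete and spans all quadrants", {
  a <- default_emotion_anchors()
  expect_identical(nrow(a), 20L)
  expect_identical(anyDuplicated(a$name), 0L)
  expect_true(all(a$valence >= 1 & a$valence <= 9))
  expect_true(all(a$arousal >= 1 & a$arousal <= 9))
  quads <- quadrant(a$valence, a$arousal)
  expect_setequal(unique(quads), c("HVHA", "HVLA", "LVHA", "LVLA"))
})

test_that("annotation picks the nearest anchor with lexicographic ties", {
  a <- default_emotion_anchors()
  # a rating exactly at an anchor returns that anchor
  expect_identical(annotate_emotion(a$valence, a$arousal), a$name)
  # anchors re-annotated onto themselves are fixed points (idempotence)
  expect_identical(annotate_emotion(a$valence, a$arousal, a), a$name)
  toy <- data.frame(name = c("beta", "alpha"), valence = c(4, 6), arousal = c(5, 5))
  expect_identical(annotate_emotion(5, 5, toy), "alpha")  # tie -> lexicographic
  expect_error(annotate_emotion(0.5, 5), "\\[1, 9\\]")
})

test_that("annotation matches the exhaustive-distance oracle", {
  a <- default_emotion_anchors()
  v <- with_test_seed(801, runif(1000, 1, 9))
  r <- with_test_seed(802, runif(1000, 1, 9))
  got <- annotate_emotion(v, r, a)
  ord <- a[order(a$name), ]
  oracle <- character(1000)
  for (i in 1:1000) {
    d <- sqrt((ord$valence - v[i])^2 + (ord$arousal - r[i])^2)
    oracle[i] <- ord$name[which.min(d)]
  }
  expect_identical(got, oracle)
})

test_that("quadrants split on the midpoint with boundary to High", {
  expect_identical(quadrant(7, 7), "HVHA")
  expect_identical(quadrant(5, 5), "HVHA")
  expect_identical(quadrant(3, 8), "LVHA")
  expect_identical(quadrant(8, 3), "HVLA")
  expect_identical(quadrant(c(2, 6), c(2, 2)), c("LVLA", "HVLA"))
})

test_that("transition tables normalize per conditioning key", {
  one <- data.frame(before = "fear", music_type = "joy", after = "surprise")
  t1 <- transition_probabilities(one)
  expect_identical(t1$probability, 1)
  expect_identical(t1$count, 1L)
  mat <- random_transition_matrix(c("fear", "joy", "sadness"),
                                  c("joy", "sadness"), seed = 81)
  rec <- simulate_transitions(transition_sim_spec(mat, n_records = 400, seed = 82))
  tt <- transition_probabilities(rec)
  key <- paste(tt$before, tt$music_type)
  sums <- tapply(tt$probability, key, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tt$count == as.integer(tt$count) & tt$count >= 0))
  expect_error(transition_probabilities(one[0, ]), "empty")
})

test_that("the transition estimator is consistent as n grows", {
  # two conditioning keys: at n = 5000 each key sees ~2500 records, so the
  # per-cell Monte-Carlo error (~2.5 binomial SEs) stays within 0.03
  mat <- random_transition_matrix(c("fear", "joy"), "joy",
                                  after = c("anger", "fear", "joy", "relaxation"),
                                  seed = 83)
  err_at <- function(n) {
    rec <- simulate_transitions(transition_sim_spec(mat, n_records = n, seed = 84))
    tt <- transition_probabilities(rec)
    m <- merge(mat, as.data.frame(tt), all.x = TRUE,
               by = c("before", "music_type", "after"))
    m$probability.y[is.na(m$probability.y)] <- 0
    max(abs(m$probability.x - m$probability.y))
  }
  e500 <- err_at(500); e5000 <- err_at(5000)
  expect_lt(e5000, e500)
  expect_lte(e5000, 0.03)
})

test_that("quadrant granularity maps labels through the anchors", {
  rec <- data.frame(before = c("fear", "sadness"), music_type = "joy",
                    after = c("joy", "intimacy"))
  tt <- transition_probabilities(rec, granularity = "quadrant")
  expect_setequal(tt$before, c("LVHA", "LVLA"))
  expect_setequal(tt$after, c("HVHA", "HVLA"))
  bad <- data.frame(before = "boredom", music_type = "joy", after = "joy")
  expect_error(transition_probabilities(bad, granularity = "quadrant"),
               "boredom")
})

test_that("parallel-coordinate export filters and round-trips", {
  mat <- random_transition_matrix(c("fear", "joy"), c("joy", "sadness"), seed = 85)
  rec <- simulate_transitions(transition_sim_spec(mat, 300, seed = 86))
  tt <- transition_probabilities(rec)
  full <- export_parallel_coordinates(tt)
  expect_identical(nrow(full), nrow(tt))
  sub <- export_parallel_coordinates(tt, after_filter = "joy")
  expect_true(all(sub$after == "joy"))
  expect_error(export_parallel_coordinates(tt, after_filter = "zeal"), "zeal")
  f <- tempfile(fileext = ".csv")
  export_parallel_coordinates(tt, file = f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$probability, full$probability, tolerance = 1e-12)
  expect_identical(back$before, full$before)
  grDevices::pdf(NULL); plot(tt); grDevices::dev.off()
})
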