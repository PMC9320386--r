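test_that("build_confusion tallies reference vs predicted counts", {
  cm <- build_confusion(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(diag(cm$counts), c(a = 2L, b = 1L))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0L)

  cm2 <- build_confusion(c("a", "a"), c("b", "b"), c("a", "b"))
  expect_equal(cm2$counts["a", "b"], 2L)
  expect_equal(accuracy(cm2), 0)

  expect_error(build_confusion(c("a", "z"), c("a", "a"), c("a", "b")), "z")
  expect_error(build_confusion("a", c("a", "b"), c("a", "b")), "length")
})

test_that("confusion counts conserve and one-vs-rest identities hold", {
  withr::with_seed(17, {
    classes <- c("neg", "trace", "+", "++")
    for (i in 1:100) {
      n <- sample(5:50, 1)
      ref <- sample(classes, n, replace = TRUE)
      prd <- sample(classes, n, replace = TRUE)
      cm <- build_confusion(ref, prd, classes)
      expect_equal(sum(cm$counts), n)
      expect_equal(unname(rowSums(cm$counts)),
                   unname(table(factor(ref, classes))[classes]),
                   ignore_attr = TRUE)
      cs <- confusion_summary(cm)
      expect_true(all(cs$TP + cs$FP + cs$TN + cs$FN == n))
      # per-class TP + FN = reference count of that class
      expect_equal(cs$TP + cs$FN,
                   as.integer(table(factor(ref, classes))[cs$class]),
                   ignore_attr = TRUE)
    }
  })
})

test_that("accuracy is the trace fraction and is label-permutation invariant", {
  cm <- build_confusion(c("a", "a", "b", "b"), c("a", "a", "b", "a"),
                        c("a", "b"))
  expect_equal(accuracy(cm), 75)
  # binary TP=1 TN=1 FP=1 FN=1 -> 50
  cm50 <- build_confusion(c("p", "p", "n", "n"), c("p", "n", "p", "n"),
                          c("p", "n"))
  expect_equal(accuracy(cm50), 50)
  withr::with_seed(23, {
    classes <- c("a", "b", "c")
    ref <- sample(classes, 30, replace = TRUE)
    prd <- sample(classes, 30, replace = TRUE)
    base <- accuracy(build_confusion(ref, prd, classes))
    perm <- c(a = "c", b = "a", c = "b")
    expect_equal(accuracy(build_confusion(perm[ref], perm[prd], classes)),
                 base)
  })
})

test_that("snap_to_reference is nearest-exemplar with deterministic tie-break", {
  st <- reference_store()
  st <- update(st, "Hemoglobin", c(100, 0, 0), "+")
  st <- update(st, "Hemoglobin", c(200, 0, 0), "++")
  expect_identical(snap_to_reference(st, "Hemoglobin", c(110, 0, 0)), "+")
  # equidistant -> earliest-inserted exemplar wins
  expect_identical(snap_to_reference(st, "Hemoglobin", c(150, 0, 0)), "+")
  # exact exemplar color -> its own label
  expect_identical(snap_to_reference(st, "Hemoglobin", c(200, 0, 0)), "++")
  expect_error(snap_to_reference(st, "Glucose", c(1, 2, 3)), "no exemplars")
})

test_that("the optimized channel is up-weighted in the snap distance", {
  # Glucose is calibrated on B. Query (0,0,0) against exemplars (0,0,10)
  # and (9,9,0): unweighted distances are 100 vs 162, but with B x2 they
  # become 200 vs 162, flipping the nearest exemplar.
  weighted <- reference_store()
  weighted <- update(weighted, "Glucose", c(0, 0, 10), "low")
  weighted <- update(weighted, "Glucose", c(9, 9, 0), "high")
  expect_identical(snap_to_reference(weighted, "Glucose", c(0, 0, 0)), "high")

  flat <- reference_store(channel_weight = 1)
  flat <- update(flat, "Glucose", c(0, 0, 10), "low")
  flat <- update(flat, "Glucose", c(9, 9, 0), "high")
  expect_identical(snap_to_reference(flat, "Glucose", c(0, 0, 0)), "low")
})

test_that("duplicating every exemplar leaves snap predictions unchanged", {
  withr::with_seed(29, {
    st <- reference_store()
    for (i in 1:6) {
      st <- update(st, "pH", runif(3, 0, 255), sample(c("acidic", "normal"), 1))
    }
    st2 <- st
    ex <- st$exemplars$pH
    for (i in seq_len(nrow(ex))) {
      st2 <- update(st2, "pH", c(ex$r[i], ex$g[i], ex$b[i]), ex$label[i])
    }
    for (k in 1:20) {
      q <- runif(3, 0, 255)
      expect_identical(snap_to_reference(st2, "pH", q),
                       snap_to_reference(st, "pH", q))
    }
  })
})

test_that("online update scores per-class warm predictions and accumulates exemplars", {
  st <- reference_store()
  # cold start: exemplar stored, nothing scored
  st <- update(st, "Ketones", c(140, 140, 100), "negative")
  expect_equal(nrow(st$exemplars$Ketones), 1L)
  expect_true(is.na(running_accuracy(st)))
  expect_false(st$log$scored[1])

  # replaying exact previous colors keeps running accuracy at 100
  cols <- list(c(140, 140, 100), c(90, 80, 60))
  labs <- c("negative", "+")
  st <- update(st, "Ketones", cols[[2]], labs[2])   # cold start for "+"
  for (rep in 1:5) for (i in 1:2) {
    st <- update(st, "Ketones", cols[[i]], labs[i])
  }
  expect_equal(running_accuracy(st), 100)
  expect_equal(nrow(st$exemplars$Ketones), 12L)  # grows by one per update
  cm <- store_confusion(st, "Ketones")
  expect_equal(accuracy(cm), 100)
  expect_equal(sum(cm$counts), sum(st$log$scored))
})

test_that("store JSON round trip preserves exemplar order and log", {
  withr::with_seed(37, {
    st <- reference_store()
    for (i in 1:10) {
      st <- update(st, sample(c("pH", "Glucose"), 1), runif(3, 0, 255),
                   sample(c("negative", "+"), 1))
    }
    path <- tempfile(fileext = ".json")
    save_store(st, path)
    st2 <- load_store(path)
    expect_equal(st2$exemplars, st$exemplars)
    expect_equal(st2$log, st$log)
    expect_equal(st2$channel_weight, st$channel_weight)
    q <- c(10, 200, 30)
    expect_identical(snap_to_reference(st2, "pH", q),
                     snap_to_reference(st, "pH", q))
  })
})
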