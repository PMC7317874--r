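test_that("AICc formula matches direct evaluation", {
  expect_equal(aicc(0.01, 8, 1), 8 * log(0.00125) + 2 + 2 / 3, tolerance = 1e-12)
  expect_equal(aicc(0.01, 8, 1), -50.8102, tolerance = 1e-4)
  expect_equal(aicc(0.01, 8, 4), -32.1436, tolerance = 1e-4)
  # equal RSS: the one-parameter model always scores lower
  expect_lt(aicc(0.037, 8, 1), aicc(0.037, 8, 4))
  # small-sample correction undefined at n <= k + 1
  expect_true(is.na(aicc(0.01, 5, 4)))
})

test_that("model preference follows the lower AICc with TID fallbacks", {
  mk <- function(rss, n, unfittable = FALSE)
    list(rss = rss, n_used = n, unfittable = unfittable)
  # MM wins on clearly lower AICc
  sel <- select_model(mk(1e-6, 8), mk(1e-2, 8))
  expect_identical(sel$label, "MM")
  expect_lt(sel$aicc_mm, sel$aicc_tid)
  # exact tie in AICc is impossible with k=4 vs k=1 at equal rss, so force a
  # tie through rss = 0 in both (both -Inf): parsimony keeps TID
  expect_identical(select_model(mk(0, 8), mk(0, 8))$label, "TID")
  # MM AICc undefined at n_used = 5 -> TID
  expect_identical(select_model(mk(1e-8, 5), mk(1e-2, 5))$label, "TID")
  # both unfittable -> unfittable
  expect_identical(select_model(mk(NA, 0, TRUE), mk(NA, 0, TRUE))$label,
                   "unfittable")
  # mismatched retained sets invalidate the comparison
  expect_error(select_model(mk(1e-4, 7), mk(1e-4, 8)), "different retained")
})

test_that("%MM is the MM fraction of fittable voxels", {
  expect_equal(percent_mm(rep("MM", 5)), 100)
  expect_equal(percent_mm(c(rep("MM", 3), rep("TID", 7))), 30)
  expect_equal(percent_mm(c(rep("MM", 3), rep("TID", 7),
                            rep("unfittable", 10))), 30)
  expect_true(is.na(percent_mm(rep("unfittable", 4))))
  # invariant to voxel ordering
  set.seed(8)
  prefs <- sample(c("MM", "TID", "unfittable"), 50, replace = TRUE)
  expect_equal(percent_mm(prefs), percent_mm(sample(prefs)))
})

test_that("preference is invariant to monotone rescaling of both AICc values", {
  mk <- function(rss, n) list(rss = rss, n_used = n, unfittable = FALSE)
  set.seed(14)
  for (i in 1:20) {
    mm <- mk(10^runif(1, -8, -1), 8); tid <- mk(10^runif(1, -8, -1), 8)
    sel <- select_model(mm, tid)
    # a*x + b with a > 0 preserves the ordering used for the label
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_identical(sel$label,
                     if (a * sel$aicc_mm + b < a * sel$aicc_tid + b) "MM"
                     else "TID")
  }
})

test_that("confusion statistics use MM as the positive class", {
  perfect <- confusion_stats(c("MM", "TID"), c("MM", "TID"))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  truth <- c(rep("MM", 100), rep("TID", 100))
  pred <- c(rep("MM", 60), rep("TID", 40), rep("TID", 95), rep("MM", 5))
  cs <- confusion_stats(truth, pred)
  expect_equal(cs$sensitivity, 0.60)
  expect_equal(cs$specificity, 0.95)
  expect_equal(cs$accuracy, 0.775)
  all_tid <- confusion_stats(truth, rep("TID", 200))
  expect_equal(all_tid$sensitivity, 0)
  expect_equal(all_tid$specificity, 1)
  expect_equal(all_tid$accuracy, 0.5)
  # absent class leaves the corresponding rate undefined, not zero
  expect_true(is.na(confusion_stats(rep("MM", 4), rep("MM", 4))$specificity))
})

test_that("maps are assembled with the exclusion rules in order", {
  # three fitted voxels: MM accepted, MM-extreme, TID
  fits <- data.frame(
    i = 1:3, j = 1, k = 1, voxel = 1:3, n_used = 8,
    tid_Dprime = c(0.5, 0.6, 1.8), tid_rss = 1e-3, tid_r2 = 0.9,
    tid_extreme = FALSE, tid_converged = TRUE,
    mm_R = c(10, 24.9, 8), mm_Di = c(1, 1.5, 1), mm_De = c(0.6, 0.7, 0.9),
    mm_fi = c(0.4, 0.5, 0.3), mm_rss = 1e-5, mm_r2 = 0.99,
    mm_extreme = c(FALSE, TRUE, FALSE), mm_converged = TRUE,
    aicc_mm = c(-60, -60, -10), aicc_tid = c(-50, -50, -40),
    preference = c("MM", "MM", "TID"))
  maps <- build_maps(fits, c(3, 1, 1))
  # extreme MM voxel absent from parameter maps but still coded MM
  expect_true(is.na(maps$R[2, 1, 1]))
  expect_equal(maps$preference[2, 1, 1], 2)
  expect_equal(maps$R[1, 1, 1], 10)
  # TID voxel carries no MM parameters, only D'
  expect_true(is.na(maps$R[3, 1, 1]))
  expect_equal(maps$Dprime[3, 1, 1], 1.8)
  expect_true(is.na(maps$Dprime[1, 1, 1]))
  # ...and %MM still counts the extreme MM voxel
  expect_equal(percent_mm(fits$preference), 100 * 2 / 3)
  summ <- subregion_summary(fits)
  expect_equal(summ$n_excluded_extreme, 1L)
  expect_equal(summ$median_R, 10)
  # empty ROI gives empty maps
  empty <- build_maps(fits[0, ], c(2, 2, 1))
  expect_true(all(is.na(empty$preference)))
})
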