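test_that("parcel extraction averages voxels and matches a loop oracle", {
  # identical voxels reproduce their series; constants average exactly
  s <- sin(seq_len(20))
  vox <- cbind(s, s, s, rep(1, 20), rep(3, 20))
  out <- extract_parcel_timeseries(vox, labels = c(1, 1, 1, 2, 2),
                                   tr_seconds = 2)
  expect_equal(unname(out$data[, "1"]), s)
  expect_equal(unname(out$data[, "2"]), rep(2, 20))

  set.seed(31)
  vox <- matrix(rnorm(20 * 12), 20, 12)
  labels <- sample(c(7, 3, 5), 12, replace = TRUE)
  got <- extract_parcel_timeseries(vox, labels)
  expect_equal(unname(got$data), unname(loop_parcel_means(vox, labels)))
  expect_equal(colnames(got$data), c("3", "5", "7"))  # ascending parcel id

  expect_error(extract_parcel_timeseries(vox, labels, parcel_ids = c(3, 5, 7, 9)),
               "empty parcel.*9")
})

test_that("small-parcel filtering uses a strict lower bound", {
  expect_equal(filter_small_parcels(c(a = 7, b = 8, c = 9), 8), c("b", "c"))
  sizes <- c(x = 1, y = 5, z = 12, w = 3)
  expect_equal(filter_small_parcels(sizes, 1), names(sizes))
  set.seed(4)
  sizes <- setNames(sample(1:20, 30, replace = TRUE), paste0("p", 1:30))
  got <- filter_small_parcels(sizes, 8)
  want <- names(sizes)[vapply(names(sizes), function(n) sizes[[n]] >= 8,
                              logical(1))]
  expect_equal(got, want)
  expect_error(filter_small_parcels(sizes, 0), ">= 1")
})

test_that("FIR design places lagged indicators at floor(onset/TR)", {
  ev <- event_table(onset = 10, duration = 2, trial_type = "a")
  d <- build_fir_design(ev, n_timepoints = 12, tr_seconds = 2,
                        lag_samples = 3)
  expect_equal(dim(d), c(12, 3))
  # onset sample 5 (0-based): lag columns light rows 6, 7, 8 (1-based)
  expect_equal(which(d[, 1] == 1), 6L)
  expect_equal(which(d[, 2] == 1), 7L)
  expect_equal(which(d[, 3] == 1), 8L)

  # truncation at the run end
  d2 <- build_fir_design(ev, n_timepoints = 7, tr_seconds = 2,
                         lag_samples = 3)
  expect_equal(sum(d2), 2)  # third lag falls off the end
  expect_error(build_fir_design(ev, n_timepoints = 5, tr_seconds = 2,
                                lag_samples = 3), "beyond the end")
})

test_that("FIR design width is K event types x L lags", {
  # go/no-go emulation: 5 event types x 10 lags = 50 columns
  gonogo <- fcdecomp:::make_task_events("gonogo", 588)
  d <- build_fir_design(gonogo, n_timepoints = 294, tr_seconds = 2,
                        lag_samples = 10)
  expect_equal(ncol(d), 50)
  # anhedonia emulation: 7 event types x 10 lags = 70 columns
  anh <- fcdecomp:::make_task_events("anhedonia", 690)
  d <- build_fir_design(anh, n_timepoints = 345, tr_seconds = 2,
                        lag_samples = 10)
  expect_equal(ncol(d), 70)
  expect_error(build_fir_design(gonogo, 294, 2, 10,
                                trial_types = c("instruction")),
               "not in declared list")
})

test_that("task regression returns OLS residuals with collinearity drops", {
  set.seed(77)
  ts <- roi_timeseries(matrix(rnorm(200), 50, 4), tr_seconds = 2)

  # all-zero design leaves the data untouched
  out <- regress_out_task(ts, matrix(0, 50, 3))
  expect_equal(out$data, ts$data)
  expect_equal(length(attr(out, "dropped_columns")), 3)

  # an ROI equal to a design column is annihilated
  design <- matrix(rnorm(150), 50, 3)
  ts2 <- roi_timeseries(cbind(ts$data[, 1:3], design[, 2]), tr_seconds = 2)
  out2 <- regress_out_task(ts2, design)
  expect_lt(max(abs(out2$data[, 4])), 1e-10)

  # rank-deficient design: residuals equal the pseudoinverse solution on
  # the retained columns
  X <- cbind(matrix(rnorm(200), 50, 4), 0)
  X <- cbind(X, X[, 1] + X[, 2])  # 6 columns, rank 4
  colnames(X) <- paste0("c", 1:6)
  Y <- matrix(rnorm(200), 50, 4)
  out3 <- regress_out_task(roi_timeseries(Y, tr_seconds = 2), X)
  expect_setequal(attr(out3, "dropped_columns"), c("c5", "c6"))
  Xk <- X[, 1:4]
  res_oracle <- Y - Xk %*% solve(t(Xk) %*% Xk, t(Xk) %*% Y)
  expect_equal(unname(out3$data), unname(res_oracle), tolerance = 1e-10)

  expect_error(regress_out_task(ts, matrix(rnorm(40 * 4), 40, 4)),
               "rows")
})

test_that("demeaning centers every ROI exactly", {
  set.seed(8)
  ts <- roi_timeseries(matrix(rnorm(120) + 5, 30, 4))
  out <- demean_timeseries(ts)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # already-centered data is unchanged
  expect_equal(demean_timeseries(out)$data, out$data)
  # constant column maps to zeros (validated via a 3-ROI minimum matrix)
  ts2 <- roi_timeseries(cbind(rep(4, 10), rnorm(10), rnorm(10)))
  expect_equal(unname(demean_timeseries(ts2)$data[, 1]), rep(0, 10))
})

test_that("run concatenation follows task order and checks compatibility", {
  mk <- function(n, task, R = 4) {
    roi_timeseries(matrix(rnorm(n * R), n, R), "s1", "baseline", task, 2)
  }
  set.seed(5)
  runs <- list(mk(345, "anhedonia"), mk(294, "rest"), mk(294, "gonogo"))
  out <- concatenate_runs(runs)
  # 294 + 294 + 345 samples at TR 2 s: 933 samples ~ 31.1 min
  expect_equal(nrow(out$data), 933)
  expect_equal(out$task, "pooled")
  expect_equal(out$data[1:294, ], runs[[2]]$data)   # rest first
  expect_equal(out$data[295:588, ], runs[[3]]$data) # then go/no-go

  expect_equal(concatenate_runs(runs[1])$data, runs[[1]]$data)

  bad <- roi_timeseries(matrix(rnorm(50 * 5), 50, 5), "s1", "baseline",
                        "rest", 2)
  expect_error(concatenate_runs(list(runs[[1]], bad)), "ROI set")
  other <- mk(50, "rest")
  other$subject_id <- "s2"
  expect_error(concatenate_runs(list(runs[[1]], other)), "different")
})

test_that("regression and demeaning commute when design columns are centered", {
  set.seed(12)
  for (i in 1:5) {
    Y <- roi_timeseries(matrix(rnorm(60 * 4), 60, 4))
    X <- scale(matrix(rnorm(60 * 3), 60, 3), center = TRUE, scale = FALSE)
    a <- demean_timeseries(regress_out_task(Y, X))
    b <- regress_out_task(demean_timeseries(Y), X)
    expect_equal(a$data, b$data, tolerance = 1e-10)
  }
})
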