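test_that("bandpass_filter attenuates DC and preserves passband latency", {
  es <- toy_epochset(array(5, c(2, 1000, 2)), t0 = -200)
  out <- bandpass_filter(es, 0.1, 40)
  expect_lt(max(abs(out$values)), 0.05)
  # symmetric in-band pulse: peak latency unchanged (zero-phase)
  x <- exp(-(seq_len(1000) - 480)^2 / (2 * 15^2))
  es2 <- toy_epochset(array(rep(x, each = 1), c(1, 1000, 1)), t0 = -200)
  out2 <- bandpass_filter(es2, 0.1, 40)
  expect_equal(which.max(out2$values[1, , 1]), which.max(x))
  expect_error(bandpass_filter(es, 1, 600), "Nyquist")
})

test_that("rereference subtracts the reference mean and drops references", {
  # hand-computed 3-channel case: ref r = c(1, 2), channels a, b
  v <- array(0, c(3, 4, 1))
  v[1, , 1] <- c(1, 2, 3, 4)    # a
  v[2, , 1] <- c(0, 1, 0, 1)    # b
  v[3, , 1] <- c(2, 2, 2, 2)    # r
  es <- toy_epochset(v, channels = c("a", "b", "r"))
  out <- rereference(es, "r")
  expect_identical(out$channels, c("a", "b"))
  expect_equal(out$values[1, , 1], c(-1, 0, 1, 2))
  expect_equal(out$values[2, , 1], c(-2, -1, -2, -1))
  # references identically zero: values unchanged
  v[3, , 1] <- 0
  out0 <- rereference(toy_epochset(v, channels = c("a", "b", "r")), "r")
  expect_equal(out0$values[1, , 1], v[1, , 1])
  # all channels equal: all-zero output
  vv <- array(3, c(3, 4, 1))
  oz <- rereference(toy_epochset(vv, channels = c("a", "b", "r")), "r")
  expect_equal(max(abs(oz$values)), 0)
  expect_error(rereference(es, "missing"), "reference")
})

test_that("filtering and re-referencing commute", {
  set.seed(5)
  es <- toy_epochset(array(rnorm(3 * 800 * 2, sd = 10), c(3, 800, 2)),
                     channels = c("a", "b", "r"), t0 = -200)
  a <- rereference(bandpass_filter(es, 1, 40), "r")
  b <- bandpass_filter(rereference(es, "r"), 1, 40)
  expect_equal(a$values, b$values, tolerance = 1e-8)
})

test_that("artifact criteria fire per rule and rejection is idempotent", {
  set.seed(3)
  mkes <- function(v) toy_epochset(v, channels = c("e1", "HEOG", "VEOG"),
                                   t0 = -200)
  v <- array(rnorm(3 * 1000 * 6, sd = 3), c(3, 1000, 6))
  v[1, 500, 2] <- 200                          # absolute-voltage violation
  v[1, 400:450, 3] <- v[1, 400:450, 3] + 120   # 120 uV step: ptp > 150? no
  v[1, 460:520, 3] <- v[1, 460:520, 3] - 60    # combined swing > 150 in window
  v[2, 300:500, 4] <- 60                       # HEOG swing > 40
  v[3, 650:750, 5] <- 80   # VEOG swing at 449..549 ms: outside -200..200 win
  v[3, 90:140, 6] <- 80    # VEOG swing at -111..-61 ms: inside the window
  es <- mkes(v)
  rej <- reject_artifacts(es, artifact_criteria(), eog = c("HEOG", "VEOG"))
  fired <- split(rej$report$criterion, rej$report$epoch)
  expect_true("eeg_abs" %in% fired[["2"]])
  expect_true("eeg_ptp" %in% fired[["3"]])
  expect_true("heog_ptp" %in% fired[["4"]])
  expect_true("veog_ptp" %in% fired[["6"]])
  expect_false(rej$kept[2] || rej$kept[3] || rej$kept[4] || rej$kept[6])
  expect_true(rej$kept[5])   # out-of-window VEOG excursion is not a veto
  # all-zero epochs: no rejections
  rz <- reject_artifacts(mkes(array(0, c(3, 1000, 4))))
  expect_true(all(rz$kept))
  expect_identical(nrow(rz$report), 0L)
  # idempotence: re-applying to survivors removes nothing
  rej2 <- reject_artifacts(rej$epochs, artifact_criteria(),
                           eog = c("HEOG", "VEOG"))
  expect_true(all(rej2$kept))
})

test_that("compute_erp averages and subtract_erp centers exactly", {
  x <- array(rnorm(2 * 50 * 8), c(2, 50, 8))
  es <- toy_epochset(x, condition = rep(c("Go", "NoGo"), each = 4))
  erp <- compute_erp(es, "Go")
  expect_equal(erp$values, apply(x[, , 1:4], c(1, 2), mean),
               ignore_attr = TRUE)
  expect_identical(erp$n_epochs, 4L)
  # identical epochs: ERP equals any epoch
  xi <- array(rep(rnorm(2 * 50), 3), c(2, 50, 3))
  esi <- toy_epochset(xi, condition = rep("Go", 3))
  expect_equal(compute_erp(esi, "Go")$values, xi[, , 1], ignore_attr = TRUE)
  # epochs x and -x: zero ERP
  xm <- array(c(rnorm(2 * 50)), c(2, 50, 1))
  es2 <- toy_epochset(array(c(xm, -xm), c(2, 50, 2)))
  expect_equal(max(abs(compute_erp(es2, "Go")$values)), 0)
  # subtraction: per-condition mean exactly zero; other conditions untouched
  sub <- subtract_erp(es, erp)
  expect_equal(max(abs(compute_erp(sub, "Go")$values)), 0, tolerance = 1e-13)
  expect_identical(sub$values[, , 5:8], es$values[, , 5:8])
  # zero ERP is identity
  zerp <- erp; zerp$values[] <- 0
  expect_identical(subtract_erp(es, zerp)$values, es$values)
  # remove_evoked then compute_erp is zero for every condition
  out <- remove_evoked(es)$epochs
  for (cc in c("Go", "NoGo")) {
    expect_equal(max(abs(compute_erp(out, cc)$values)), 0, tolerance = 1e-13)
  }
  expect_error(compute_erp(es, "None"), "no epochs")
  bad <- erp; bad$values <- bad$values[, 1:10]
  expect_error(subtract_erp(es, bad), "shape")
})

test_that("purely evoked data is degenerate after subtraction, not PSI = 1", {
  xi <- array(rep(10 * sin(2 * pi * 6 * (0:999) / 1000), each = 2),
              c(2, 1000, 3))
  es <- toy_epochset(xi, t0 = -200, condition = rep("Go", 3))
  ind <- remove_evoked(es)$epochs
  ph <- instantaneous_phase(ind, "theta", window = c(200, 700))
  expect_true(all(ph$degenerate))
  expect_error(psi_matrix(ph, "Go"), "degenerate")
})

test_that("extract_window uses half-open sample conventions", {
  es <- toy_epochset(array(rnorm(1 * 1000 * 2), c(1, 1000, 2)), t0 = -200)
  w <- extract_window(es, c(200, 700))
  expect_identical(dim(w$values)[2], 500L)
  expect_equal(w$times[1], 200)
  expect_equal(w$times[500], 699)
  full <- extract_window(es, c(-200, 800))
  expect_identical(full$values, es$values)
  es250 <- toy_epochset(array(rnorm(1 * 250 * 1), c(1, 250, 1)),
                        srate = 250, t0 = -500)
  expect_identical(dim(extract_window(es250, c(-500, 0))$values)[2], 125L)
  expect_error(extract_window(es, c(900, 1000)), "window")
})
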