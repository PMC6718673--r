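# Background subtraction, dF* quantification, classification, calibration.

make_rec <- function(cell_values, bg_values, dt = 0.5) {
  n_t <- nrow(cell_values)
  t <- (seq_len(n_t) - 1) * dt
  long <- function(mat, prefix, type) {
    tibble::tibble(
      time_s = rep(t, ncol(mat)),
      roi_id = rep(sprintf("%s_%d", prefix, seq_len(ncol(mat))), each = n_t),
      roi_type = type,
      value = as.numeric(mat))
  }
  ca_recording(
    dplyr::bind_rows(long(cell_values, "cell", "cell"),
                     long(bg_values, "bg", "background")),
    tibble::tibble(agent = "GABA", onset_s = 60, duration_s = 2),
    sampling_interval = dt)
}

recording_matrix_for_test <- function(rec) {
  tr <- rec$traces[rec$traces$roi_type == "cell", ]
  ids <- unique(tr$roi_id)
  matrix(tr$value[order(match(tr$roi_id, ids))], ncol = length(ids))
}

process_like <- function(rec) {
  rec <- subtract_background(rec)
  tr <- rec$traces$value[rec$traces$roi_type == "cell"]
  compute_response(denoise(tr), 60, sampling_interval = 0.5)$dF_star
}

compute_shifted <- function(rec, onset) {
  rec <- subtract_background(rec)
  tr <- rec$traces$value[rec$traces$roi_type == "cell"]
  # denoise only the window-relevant stretch identically: use raw series to
  # isolate the windowing logic from boundary effects of the transform
  compute_response(tr, onset, sampling_interval = 0.5)$dF_star
}

test_that("background subtraction removes the across-background mean pointwise", {
  n_t <- 241L
  # constant example: cell 5, backgrounds 1/2/3 -> 3
  rec <- make_rec(matrix(5, n_t, 1),
                  cbind(rep(1, n_t), rep(2, n_t), rep(3, n_t)))
  out <- subtract_background(rec)
  expect_equal(unique(out$traces$value[out$traces$roi_type == "cell"]), 3)
  # backgrounds retained unchanged
  expect_equal(out$traces$value[out$traces$roi_id == "bg_2"], rep(2, n_t))

  # zero backgrounds leave cells untouched
  cells <- matrix(rnorm(n_t * 2), n_t, 2)
  rec0 <- make_rec(cells, matrix(0, n_t, 1))
  expect_equal(subtract_background(rec0)$traces$value[1:n_t], cells[, 1])

  # random traces match an elementwise loop oracle
  set.seed(11)
  cells <- matrix(rnorm(n_t * 3), n_t, 3)
  bgs <- matrix(rnorm(n_t * 3), n_t, 3)
  out <- subtract_background(make_rec(cells, bgs))
  expected <- cells
  for (i in seq_len(n_t)) {
    expected[i, ] <- cells[i, ] - mean(bgs[i, ])
  }
  got <- recording_matrix_for_test(out)
  expect_equal(got, expected, ignore_attr = TRUE)
})


test_that("dF* is (f - f0)/f0 with the stated windows", {
  # constant positive series -> 0
  expect_equal(compute_response(rep(2, 300), 60, sampling_interval = 0.5)$dF_star, 0)
  # f0 = 1, max in post-window = 3 -> 2
  tr <- rep(1, 300)
  tr[((60 / 0.5) + 3):((60 / 0.5) + 10)] <- 3
  r <- compute_response(tr, 60, sampling_interval = 0.5)
  expect_equal(r$f, 3)
  expect_equal(r$f0, 1)
  expect_equal(r$dF_star, 2)
  # windows out of range and nonpositive baseline error
  expect_error(compute_response(rep(1, 300), 10, sampling_interval = 0.5),
               class = "twindff_error_scheduling")
  expect_error(compute_response(rep(0, 300), 60, sampling_interval = 0.5),
               class = "twindff_error_calibration")
})

test_that("window endpoints: max over (onset, onset+20], min over [onset-50, onset]", {
  dt <- 0.5
  tr <- rep(1, 400)
  onset_i <- 121L  # t = 60
  tr[onset_i] <- 0.5          # at onset: belongs to the pre-window only
  tr[onset_i + 40L] <- 4      # t = 80 = onset + 20: inside post-window
  r <- compute_response(tr, 60, sampling_interval = dt)
  expect_equal(r$f0, 0.5)
  expect_equal(r$f, 4)
  tr2 <- rep(1, 400)
  tr2[onset_i + 41L] <- 4     # t = 80.5: just outside the post-window
  expect_equal(compute_response(tr2, 60, sampling_interval = dt)$f, 1)
})

test_that("dF* is invariant to rescaling all traces and to time shifts", {
  set.seed(12)
  n_t <- 481L
  cells <- matrix(abs(rnorm(n_t, 5)), n_t, 1)
  bgs <- matrix(abs(rnorm(n_t * 2, 1)), n_t, 2)
  base_rec <- make_rec(cells, bgs)
  r1 <- process_like(base_rec)
  # scale invariance: multiply everything by c > 0
  scaled <- make_rec(cells * 3.7, bgs * 3.7)
  r2 <- process_like(scaled)
  expect_equal(r2, r1, tolerance = 1e-10)
  # shift invariance: move onset and series by the same number of frames
  shift <- 40L
  cells_s <- rbind(matrix(cells[1, ], shift, 1), cells)[seq_len(n_t), ,
                                                        drop = FALSE]
  bgs_s <- rbind(matrix(bgs[1, ], shift, 2), bgs)[seq_len(n_t), ,
                                                  drop = FALSE]
  rec_s <- make_rec(cells_s, bgs_s)
  r3 <- compute_shifted(rec_s, 60 + shift * 0.5)
  r0 <- compute_shifted(base_rec, 60)
  expect_equal(r3, r0, tolerance = 1e-10)
})



test_that("neuron classification thresholds the KCl/ionomycin ratio", {
  expect_false(classify_neuron(0, 1.5, min_ratio = 0.1))
  expect_true(classify_neuron(0.75, 1.5, min_ratio = 0.1))
  expect_error(classify_neuron(0.5, 0), class = "twindff_error_calibration")
  # exact recovery on a noiseless simulated recording
  cfg <- noiseless_cfg()
  cfg$neuron_fraction <- 0.8
  rec <- simulate_recording(cfg, flat_schedule(), n_cells = 10, seed = 3)
  resp <- process_recording(rec)
  called <- unique(resp$roi_id[resp$is_neuron])
  truth <- sprintf("cell_%03d", attr(rec, "neuron_idx"))
  expect_setequal(called, truth)
  expect_equal(length(truth), round(0.8 * 10))
})

test_that("two-stage calibration behaves algebraically", {
  # equal raw responses -> every final ratio 1
  out <- calibrate_cell(c(GABA = 0.4, GluGlyNoMg = 0.4, KCl = 0.4,
                          ionomycin = 0.4))
  expect_equal(out$final[out$agent %in% c("GABA", "GluGlyNoMg")], c(1, 1))
  # zero agonist -> zero final
  out0 <- calibrate_cell(c(GABA = 0, KCl = 1, ionomycin = 2))
  expect_equal(out0$final[out0$agent == "GABA"], 0)
  # ionomycin cancels from the final ratio
  set.seed(13)
  for (i in 1:25) {
    raw <- c(GABA = runif(1, 0, 2), GluGlyNoMg = runif(1, 0, 2),
             KCl = runif(1, 0.1, 2), ionomycin = runif(1, 0.1, 5))
    out <- calibrate_cell(raw)
    expect_equal(out$final[out$agent == "GABA"],
                 unname(raw["GABA"] / raw["KCl"]), tolerance = 1e-12)
    # intermediate stage is recorded faithfully
    expect_equal(out$iono_calibrated,
                 unname(raw / raw["ionomycin"]), tolerance = 1e-12)
  }
  expect_error(calibrate_cell(c(GABA = 1, KCl = 1)),
               class = "twindff_error_incomplete_protocol")
  expect_error(calibrate_cell(c(GABA = 1, KCl = 0, ionomycin = 1)),
               class = "twindff_error_calibration")
})
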