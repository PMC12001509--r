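test_that("upper-quartile intensity follows the linear-interpolation convention", {
  expect_identical(upper_quartile_intensity(c(7, 7, 7, 7)), 7)
  # position 0.75 * (5 - 1) = 3 (0-based) -> 4th order statistic
  expect_identical(upper_quartile_intensity(c(1, 2, 3, 4, 5)), 4)
  expect_identical(upper_quartile_intensity(c(5, 3, 1, 4, 2)), 4)
  expect_identical(upper_quartile_intensity(c(1, 2)), 1.75)
  expect_error(upper_quartile_intensity(numeric(0)), "non-empty")
})

test_that("percentile matches an independent sorted-interpolation oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(1:1000, 1)
    x <- runif(n, 0, 65535)
    if (i %% 3 == 0) x <- round(x)  # exercise ties
    ours <- upper_quartile_intensity(x)
    oracle <- unname(quantile(x, 0.75, type = 7))
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

make_records <- function(image_ids, upq) {
  n <- length(upq)
  data.frame(image_id = rep(image_ids, length.out = n),
             condition = NA_character_, label = seq_len(n),
             area_px = 100L, perimeter_px = 60, circularity = 0.2,
             upq_intensity = upq, upq_normalized = NA_real_)
}

test_that("pooling groups fragments by manifest condition with counts", {
  man <- data.frame(file = c("a1", "a2", "a3", "b1"),
                    condition = c("CTRL", "CTRL", "CTRL", "TRT"))
  rec <- make_records(rep(c("a1", "a2", "a3"), each = 10), runif(30, 100, 200))
  expect_warning(tb <- pool_measurements(rec, man, "CTRL"), "no fragment records")
  expect_identical(unname(tb$n_per_condition["CTRL"]), 30L)
  expect_identical(unname(tb$n_per_condition["TRT"]), 0L)
  expect_identical(unname(tb$n_per_image["a2"]), 10L)
  # unknown image id is an error naming the id
  bad <- make_records("zz9", c(1, 2))
  expect_error(pool_measurements(bad, man, "CTRL"), "zz9")
  # order-independence
  rec2 <- rec[sample(nrow(rec)), ]
  tb2 <- suppressWarnings(pool_measurements(rec2, man, "CTRL"))
  o1 <- tb$records[order(tb$records$label), ]
  o2 <- tb2$records[order(tb2$records$label), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("control-median normalization has unit control median and invariances", {
  man <- data.frame(file = c("c", "t"), condition = c("CTRL", "TRT"))
  rec <- rbind(make_records("c", c(2, 4, 6)), make_records("t", c(4, 8, 12)))
  tb <- normalize_to_control(pool_measurements(rec, man, "CTRL"))
  ctrl <- tb$records$upq_normalized[tb$records$condition == "CTRL"]
  expect_equal(sort(ctrl), c(0.5, 1, 1.5))
  expect_identical(median(ctrl), 1)
  # treated raw median 2x control -> normalized treated median 2
  trt <- tb$records$upq_normalized[tb$records$condition == "TRT"]
  expect_identical(median(trt), 2)
  # global intensity scaling leaves normalized values unchanged
  rec_s <- rec; rec_s$upq_intensity <- rec_s$upq_intensity * 3.7
  tb_s <- normalize_to_control(pool_measurements(rec_s, man, "CTRL"))
  expect_equal(tb_s$records$upq_normalized, tb$records$upq_normalized)
  # idempotence: renormalizing a normalized table is the identity
  tb_id <- tb
  tb_id$records$upq_intensity <- tb$records$upq_normalized
  tb_id2 <- normalize_to_control(tb_id)
  expect_equal(tb_id2$records$upq_normalized, tb$records$upq_normalized)
  # zero control median is an error
  rec0 <- rbind(make_records("c", c(0, 0, 0)), make_records("t", c(1, 2)))
  expect_error(normalize_to_control(pool_measurements(rec0, man, "CTRL")),
               "zero or undefined")
})

test_that("condition summaries use the shared percentile convention", {
  man <- data.frame(file = c("c", "t"), condition = c("CTRL", "TRT"))
  rec <- rbind(make_records("c", c(1, 2, 3, 4, 5)), make_records("t", rep(7, 4)))
  tb <- normalize_to_control(pool_measurements(rec, man, "CTRL"))
  sm <- summarize_conditions(tb, value = "upq_intensity")
  ctrl <- sm[sm$condition == "CTRL", ]
  expect_equal(ctrl$median, 3)
  expect_equal(ctrl$q25, 2)
  expect_equal(ctrl$q75, 4)
  expect_identical(ctrl$n, 5L)
  trt <- sm[sm$condition == "TRT", ]
  expect_true(trt$median == 7 && trt$q25 == 7 && trt$q75 == 7)
  # normalized control median is reported as exactly 1
  smn <- summarize_conditions(tb)
  expect_identical(smn$median[smn$condition == "CTRL"], 1)
})

test_that("fragment scoring attaches UpQ values per label", {
  sig <- image_channel(matrix(as.integer(c(10, 20, 30, 40, 0, 0,
                                           100, 200, 300, 400, 500, 0)),
                              3, 4), "signal")
  lab <- matrix(0L, 3, 4)
  lab[sig$pixels %in% c(10, 20, 30, 40)] <- 1L
  lab[sig$pixels >= 100] <- 2L
  lm <- perimembrane:::new_label_map(lab, 2L)
  st <- measure_shapes(lm)
  rec <- quantify_fragments(sig, lm, st, "imgX")
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$upq_intensity[1],
               unname(quantile(c(10, 20, 30, 40), 0.75, type = 7)))
  expect_equal(rec$upq_intensity[2],
               unname(quantile(c(100, 200, 300, 400, 500), 0.75, type = 7)))
  expect_identical(rec$image_id, c("imgX", "imgX"))
})

test_that("synthetic enrichment is recovered by the measurement chain", {
  # medium-size check (the acceptance suite runs the full-scale version):
  # one control + one treated condition, pooled over several images
  cfg <- run_config(seed = 5)
  sp <- scene_spec(seed = 5)
  recs <- list(); man <- list()
  for (cond in c("CTRL", "TRT")) {
    mult <- if (cond == "CTRL") 1 else 1.35
    for (i in 1:3) {
      s <- generate_scene(local({
        x <- sp; x$seed <- substream_seed(5, cond, i); x
      }), mult)
      id <- paste0(cond, i)
      r <- process_image(s$channels, cfg, id)$records
      recs[[id]] <- r
      man[[id]] <- data.frame(file = id, condition = cond)
    }
  }
  tb <- normalize_to_control(pool_measurements(do.call(rbind, recs),
                                               do.call(rbind, man), "CTRL"))
  sm <- summarize_conditions(tb)
  trt_med <- sm$median[sm$condition == "TRT"]
  expect_gt(sm$n[sm$condition == "TRT"], 50)
  expect_lt(abs(trt_med - 1.35) / 1.35, 0.1)
})
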