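test_that("combined blocks satisfy all stream invariants", {
  cfg <- task_config()
  for (seed in c(7, 21, 99)) {
    b <- make_combined_block(1400, cfg, seed = seed)
    expect_length(b$kind, 60)
    expect_identical(b$kind, rep(c("letter", "number"), 30))
    expect_true(all(b$symbol[b$kind == "letter"] %in%
                      c("A", "C", "E", "L", "N", "P", "R", "T", "U")))
    expect_true(all(b$symbol[b$kind == "number"] %in%
                      c("1", "2", "3", "4", "6", "7", "8", "9")))
    expect_identical(sum(b$is_repeat_target, na.rm = TRUE), 10L)
    par <- table(b$parity)
    expect_lte(abs(par[["even"]] - par[["odd"]]), 1)
    expect_true(validate_block(b))
    # no symbol three times in a row among letters
    lets <- b$symbol[b$kind == "letter"]
    runs <- rle(lets)$lengths
    expect_lte(max(runs), 2)
  }
})

test_that("repeat-target placement respects configured counts and bounds", {
  b0 <- make_combined_block(1500, task_config(repeat_target_count = 0),
                            seed = 1)
  lets <- b0$symbol[b0$kind == "letter"]
  expect_false(any(lets[-1] == lets[-length(lets)]))

  b29 <- make_single_task_block(
    "fam_letter", task_config(repeat_target_count_single = 29), seed = 9)
  expect_true(all(b29$is_repeat_target[-1]))
  expect_true(validate_block(b29))

  expect_error(task_config(repeat_target_count = 30), "repeat_target_count")
  expect_error(make_combined_block(750, task_config()), "multiple")
  expect_error(make_combined_block(1600, task_config()), "within")
})

test_that("block generation is deterministic given a seed", {
  b1 <- make_combined_block(800, seed = 3)
  b2 <- make_combined_block(800, seed = 3)
  expect_identical(b1$symbol, b2$symbol)
  expect_identical(b1$is_repeat_target, b2$is_repeat_target)
  b3 <- make_combined_block(800, seed = 4)
  expect_false(identical(b1$symbol, b3$symbol))
})

test_that("single-task blocks have the right composition", {
  bn <- make_single_task_block("fam_number", seed = 2)
  expect_length(bn$kind, 30)
  expect_true(all(bn$kind == "number"))
  expect_identical(as.vector(table(bn$parity)[c("even", "odd")]),
                   c(15L, 15L))

  bl <- make_single_task_block("fam_letter", seed = 2)
  expect_true(all(bl$kind == "letter"))
  expect_identical(sum(bl$is_repeat_target), 5L)
  expect_error(make_single_task_block("fam_combined"), "kind")
})

test_that("scoring implements the weighted composite and pass rule", {
  cfg <- task_config()
  b <- make_combined_block(1000, cfg, seed = 11)

  # all letters right (targets answered, non-targets withheld), numbers wrong
  tgt <- which(b$kind == "letter" & b$is_repeat_target)
  wrong_num <- which(b$kind == "number")
  resp <- response_events(
    item_index = c(b$index[tgt], b$index[wrong_num]),
    action = c(rep("space", length(tgt)),
               ifelse(b$parity[wrong_num] == "even", "odd_key",
                      "even_key")),
    latency_ms = rep(500, length(tgt) + length(wrong_num))
  )
  s <- score_block(b, resp, cfg)
  expect_equal(s$letter_accuracy, 1)
  expect_equal(s$number_accuracy, 0)
  expect_equal(s$composite, 0.65)
  expect_false(s$passed)

  # everything right
  s2 <- score_block(b, perfect_responses(b), cfg)
  expect_equal(s2$composite, 1)
  expect_true(s2$passed)

  # 26/30 letters, 30/30 numbers: composite just above criterion
  miss <- which(b$kind == "letter" & !b$is_repeat_target)[1:4]
  pr <- perfect_responses(b)
  resp3 <- response_events(
    item_index = c(pr$item_index, b$index[miss]),
    action = c(pr$action, rep("space", 4)),
    latency_ms = c(pr$latency_ms, rep(400, 4))
  )
  s3 <- score_block(b, resp3, cfg)
  expect_equal(s3$letter_accuracy, 26 / 30)
  expect_equal(s3$composite, 0.65 * 26 / 30 + 0.35, tolerance = 1e-12)
  expect_true(s3$passed)
  # composite at exactly the criterion passes (inclusive boundary)
  expect_true(score_block(b, resp3,
                          task_config(pass_criterion = s3$composite))$passed)
})

test_that("creditability window, channels and first-press rule are enforced", {
  cfg <- task_config()
  b <- make_combined_block(600, cfg, seed = 5)
  tgt <- b$index[which(b$kind == "letter" & b$is_repeat_target)[1]]
  num <- b$index[which(b$kind == "number")[1]]
  num_correct <- if (b$parity[num + 1] == "even") "even_key" else "odd_key"
  num_wrong <- if (num_correct == "even_key") "odd_key" else "even_key"

  # late press not credited
  s <- score_block(b, response_events(tgt, "space", 600), cfg)
  expect_equal(s$letter_accuracy, 20 / 30) # target missed, non-targets right

  # cross-channel press ignored: space on a number leaves it unanswered
  s2 <- score_block(b, response_events(num, "space", 100), cfg)
  expect_equal(s2$number_accuracy, 0)

  # first creditable press wins over a later conflicting one
  s3 <- score_block(b, response_events(c(num, num),
                                       c(num_correct, num_wrong),
                                       c(100, 200)), cfg)
  expect_equal(s3$number_accuracy, 1 / 30)
  s4 <- score_block(b, response_events(c(num, num),
                                       c(num_wrong, num_correct),
                                       c(100, 200)), cfg)
  expect_equal(s4$number_accuracy, 0)

  # out-of-range index rejected
  expect_error(score_block(b, response_events(60, "space", 10), cfg),
               "out of range")
})

test_that("scoring is invariant to response order and matches the item-counting oracle", {
  cfg <- task_config()
  set.seed(42)
  p <- observer_profile(theta_ms = 700, slope_ms = 100, lapse = 0.05)
  for (rep in 1:10) {
    b <- make_combined_block(sample(seq(300, 1400, 100), 1), cfg)
    resp <- respond(p, b)
    s <- score_block(b, resp, cfg)
    o <- oracle_score(b, resp, cfg)
    expect_equal(s$letter_accuracy, o$letter_accuracy)
    expect_equal(s$number_accuracy, o$number_accuracy)
    expect_equal(s$composite, o$composite)
    expect_identical(s$passed, o$passed)
    if (nrow(resp) > 1) {
      perm <- sample(nrow(resp))
      s_perm <- score_block(b, resp[perm, ], cfg)
      expect_equal(s_perm$composite, s$composite)
    }
  }
})

test_that("composite is monotone in each channel accuracy", {
  cfg <- task_config()
  accs <- seq(0, 1, by = 0.25)
  comp <- function(la, na) cfg$w_letter * la + cfg$w_number * na
  for (la in accs) {
    expect_true(all(diff(sapply(accs, function(na) comp(la, na))) >= 0))
    expect_true(all(diff(sapply(accs, function(x) comp(x, la))) >= 0))
  }
})

test_that("absent responses score letters by omission and numbers zero", {
  b <- make_combined_block(1000, seed = 8)
  s <- score_block(b, response_events())
  n_nontarget <- sum(b$kind == "letter" & !b$is_repeat_target)
  expect_equal(s$letter_accuracy, n_nontarget / 30)
  expect_equal(s$number_accuracy, 0)
})
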