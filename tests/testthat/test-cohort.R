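# Gestational-age arithmetic, analysis-set construction and cohort summaries.

test_that("weeks + days notation parses and renders both ways", {
  expect_equal(parse_gestation("17 + 4"), 123L)
  expect_equal(parse_gestation("37 + 0"), 259L)
  expect_equal(parse_gestation("17+4"), 123L)
  expect_error(parse_gestation("16 + 9"), class = "voc_format_error")
  expect_error(parse_gestation("abc"), class = "voc_format_error")
  expect_equal(format_gestation(123), "17 + 4")
  expect_equal(format_gestation(259), "37 + 0")
  days <- c(70, 123, 200, 223, 259, 280)
  expect_equal(parse_gestation(format_gestation(days)), as.integer(days))
})

test_that("delivery categories partition gestational age at the stated bounds", {
  expect_equal(as.character(categorize_delivery(259)), "term")
  expect_equal(as.character(categorize_delivery(223)), "very_preterm")
  expect_equal(as.character(categorize_delivery(167)), "midtrimester_miscarriage")
  boundary <- c(167, 168, 195, 196, 223, 224, 258, 259)
  expect_equal(as.character(categorize_delivery(boundary)),
               c("midtrimester_miscarriage", "extreme_preterm",
                 "extreme_preterm", "very_preterm", "very_preterm",
                 "late_preterm", "late_preterm", "term"))
  # every day maps to exactly one category
  all_days <- 100:320
  expect_false(anyNA(categorize_delivery(all_days)))
  expect_equal(is_preterm(all_days),
               as.character(categorize_delivery(all_days)) != "term")
})

test_that("analysis swab selection honours mode and tie policy", {
  sw <- data.frame(patient_id = "p", sample_id = c("a", "b", "c"),
                   gestation_days = parse_gestation(c("15 + 0", "20 + 0", "26 + 0")),
                   bv_status = "negative", stringsAsFactors = FALSE)
  delivery <- parse_gestation("34 + 0")
  expect_equal(select_analysis_swab(sw, "first")$sample_id, "a")
  expect_equal(select_analysis_swab(sw, "closest_to_delivery", delivery)$sample_id, "c")
  tie <- sw[c(1, 1), ]; tie$sample_id <- c("x", "y")
  expect_equal(select_analysis_swab(tie, "first")$sample_id, "x")
  expect_error(select_analysis_swab(sw[0, ], "first"),
               class = "voc_degenerate_error")
  expect_error(select_analysis_swab(sw, "closest_to_delivery", NA),
               class = "voc_argument_error")
})

test_that("analysis sets apply the preterm exclusion rules", {
  ec <- example_cohort()
  pre <- build_analysis_set(ec$patients, ec$swabs, "preterm", "first")
  expect_equal(nrow(pre), 196L)   # 216 - 11 iatrogenic - 9 unknown
  expect_equal(sum(pre$label), 39L)
  iat <- ec$patients$patient_id[ec$patients$outcome == "iatrogenic"]
  expect_false(any(iat %in% pre$patient_id))
  bv <- build_analysis_set(ec$patients, ec$swabs, "bv", "first")
  expect_equal(nrow(bv), 216L)
  expect_true(all(iat %in% bv$patient_id))
  expect_equal(sum(bv$label), 26L)
  # closest-to-delivery restricts to known deliveries and picks the latest swab
  cl <- build_analysis_set(ec$patients, ec$swabs, "preterm", "closest_to_delivery")
  sw2 <- ec$swabs$sample_id[ec$swabs$gestation_days == 154]
  expect_true(all(cl$sample_id %in% sw2))
  # degenerate: nobody has delivery data
  unk <- ec$patients; unk$outcome <- "unknown"; unk$delivery_days <- NA_integer_
  expect_error(build_analysis_set(unk, ec$swabs, "preterm", "first"),
               class = "voc_degenerate_error")
})

test_that("cohort summary reproduces its own counts with half-up percentages", {
  ec <- example_cohort()
  s <- summarize_cohort(ec$patients, ec$swabs)
  expect_equal(s$bv_positive$count, 26L); expect_equal(s$bv_positive$n, 216L)
  expect_equal(s$bv_positive$pct, 12.0)
  expect_equal(s$preterm$count, 39L); expect_equal(s$preterm$n, 196L)
  expect_equal(s$preterm$pct, 19.9)
  expect_equal(s$preterm_given_bv$count, 13L)
  expect_equal(s$preterm_given_bv$n, 22L)
  expect_equal(s$preterm_given_bv$pct, 59.1)
  expect_equal(s$delivery_before_32w$count, 18L)
  expect_equal(s$delivery_before_32w$pct, 9.2)
  expect_equal(s$preterm_given_bv_negative$n, 174L)
  # every percentage recomputes from its own count and denominator
  for (f in s[setdiff(names(s), "delivery_categories")]) {
    expect_equal(f$pct, vocptb:::round_half_up(100 * f$count / f$n, 1))
  }
  expect_equal(as.integer(s$delivery_categories),
               c(2L, 6L, 10L, 21L, 157L))

  # all-negative cohort: zeros, no errors
  neg <- ec
  neg$swabs$bv_status <- "negative"
  neg$patients$delivery_days[neg$patients$outcome == "spontaneous"] <- 270L
  s0 <- summarize_cohort(neg$patients, neg$swabs)
  expect_equal(s0$preterm$pct, 0)
  expect_equal(s0$preterm_given_bv$pct, NA_real_)  # zero denominator flagged
  # single-patient cohort flags degenerate denominators
  one <- summarize_cohort(ec$patients[1, ], ec$swabs[1:2, ])
  expect_true(one$bv_positive$degenerate)
  expect_equal(one$bv_positive$pct, 100)
})

test_that("group comparisons fire the documented branches", {
  # identical near-normal groups: parametric branch, p = 1
  g <- c(1.1, 2.0, 2.9, 4.2, 5.1, 5.8)
  cmp <- compare_groups(c(g, g), rep(c("a", "b"), each = 6))
  expect_equal(cmp$test, "t")
  expect_equal(cmp$p, 1)
  # hand-computed chi-square without continuity correction
  x <- c(rep("yes", 20), rep("no", 10), rep("yes", 10), rep("no", 20))
  grp <- rep(c("a", "b"), each = 30)
  cc <- compare_groups(x, grp, type = "categorical")
  expect_equal(cc$test, "chi_square")
  expect_equal(unname(cc$statistic), 20 / 3, tolerance = 1e-9)
  # strongly skewed data routes to the rank-sum branch
  set.seed(23)
  v <- c(rexp(50), rexp(50))
  cm <- compare_groups(v, rep(c("a", "b"), each = 50))
  expect_equal(cm$test, "mann_whitney")
  expect_gt(cm$p, 0.001)
  # degenerate zero-variance comparison
  cz <- compare_groups(rep(5, 8), rep(c("a", "b"), 4))
  expect_equal(cz$test, "degenerate"); expect_equal(cz$p, 1)
  expect_error(compare_groups(1:4, rep("a", 4)), class = "voc_argument_error")
})

test_that("median and IQR use linear interpolation and render as weeks + days", {
  mi <- median_iqr(c(118, 123, 150))
  expect_equal(unname(mi["median"]), 123)
  expect_equal(format_gestation(mi["median"]), "17 + 4")
  expect_equal(unname(median_iqr(7)), c(7, 7, 7))
  # type-7 definition computed by hand: h = (n-1)p + 1
  mi4 <- median_iqr(c(1, 2, 3, 4))
  expect_equal(unname(mi4), c(2.5, 1.75, 3.25))
  expect_error(median_iqr(numeric(0)), class = "voc_argument_error")
})
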