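test_that("the uniform-design level matrix has the canonical layout", {
  lv <- uniform_design_levels()
  expect_equal(dim(lv), c(8, 6))
  expect_equal(unname(lv[1, ]), c("EC5", "EC10", "EC20", "EC30", "EC40", "EC50"))
  expect_true(all(lv[7, ] == "EC50"))
  expect_true(all(lv[8, ] == "EC5"))
  for (i in 1:6)
    expect_length(unique(lv[i, ]), 6)    # Latin property of the design rows
})

test_that("mixture ratios follow the EC-proportional formula", {
  ec <- standards_ec_table()
  r1 <- mixture_ratios(uniform_design_levels()[1, ], ec)
  # denominator 8.11 + 19.86 + 18.53 + 31.91 + 60.79 + 69.02 = 208.22
  expect_equal(unname(r1[1]), 8.11 / 208.22, tolerance = 1e-12)
  expect_equal(sum(r1), 1)

  r8 <- mixture_ratios(uniform_design_levels()[8, ], ec)
  expect_equal(unname(r8), ec$EC5 / sum(ec$EC5))

  for (i in 1:8)
    expect_equal(sum(mixture_ratios(uniform_design_levels()[i, ], ec)), 1,
                 tolerance = 1e-12)
  expect_error(mixture_ratios(rep("EC15", 6), ec), "unknown")
})

test_that("the resolved design conserves mass down the dilution series", {
  d <- mixture_design(total = 500)
  expect_equal(nrow(d), 8 * 7)
  conc <- as.matrix(d[, -(1:3)])
  expect_equal(unname(rowSums(conc)), d$total, tolerance = 1e-9)
  expect_equal(sort(unique(d$total), decreasing = TRUE),
               500 / 2^(0:6), tolerance = 1e-12)
})

test_that("dilution series are geometric", {
  expect_equal(dilution_series(500, 2, 7),
               c(500, 250, 125, 62.5, 31.25, 15.625, 7.8125))
  expect_equal(dilution_series(10, 3, 1), 10)
  s <- dilution_series(400, 2, 7)
  expect_equal(s[-length(s)] / s[-1], rep(2, 6))
  expect_error(dilution_series(10, 1, 5), "factor")
})

test_that("pairwise designs enumerate all unordered pairs", {
  expect_equal(nrow(pairwise_design(paste0("S", 1:12))), 66)
  expect_equal(nrow(pairwise_design(c("a", "b"))), 1)
  expect_equal(nrow(pairwise_design(letters[1:5])), 10)
  for (n in 2:20)
    expect_equal(nrow(pairwise_design(paste0("x", seq_len(n)))),
                 nrow(unique(t(combn(n, 2)))))
  d <- pairwise_design(c("s1", "s2", "s3"))
  expect_false(any(d$a == d$b))
  expect_false(anyDuplicated(d$pair_id) > 0)
  expect_error(pairwise_design(c("a", "a")), "duplicate")
})

test_that("blending averages base profiles pair by pair", {
  ft <- feature_table(rbind(A = c(2, 0), B = c(0, 2)))
  d <- pairwise_design(c("A", "B"))
  bl <- blend_profiles(ft, d)
  expect_equal(unname(bl$abundance[1, ]), c(1, 1))

  # blending a sample with itself reproduces the profile
  self <- structure(data.frame(pair_id = "AA", a = "A", b = "A"),
                    class = c("pairwise_design", "data.frame"))
  expect_equal(unname(blend_profiles(ft, self)$abundance[1, ]),
               unname(ft$abundance["A", ]))

  expect_error(blend_profiles(ft, pairwise_design(c("A", "Z"))), "missing")
})

test_that("blended-table dispersion matches the generating log-normal", {
  # pair means of iid LN(0, s) have CV ~ sqrt(exp(s^2) - 1)/sqrt(2)
  set.seed(12)
  s <- 0.4
  base <- feature_table(matrix(rlnorm(12 * 73, 0, s), 12, 73))
  bl <- blend_profiles(base, pairwise_design(base$sample_ids))
  cv <- apply(bl$abundance, 2, function(x) sd(x) / mean(x))
  expect_equal(mean(cv), sqrt(exp(s^2) - 1) / sqrt(2), tolerance = 0.2)
})

test_that("the inhibition-rate transform is the exact assay ratio", {
  expect_equal(inhibition_rate(0.1, 0.1, 1.1), 0)
  expect_equal(inhibition_rate(1.1, 0.1, 1.1), 1)
  expect_equal(inhibition_rate(0.6, 0.1, 1.1), 0.5)
  expect_error(inhibition_rate(0.5, 0.2, 0.2), "differ")
  expect_warning(out <- inhibition_rate(1.4, 0.1, 1.1, clip = TRUE),
                 "clipped")
  expect_equal(out, 1)
  expect_equal(viability_complement(0.3), 0.7)
})
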