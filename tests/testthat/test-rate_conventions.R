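test_that("published single-cell rates are reproduced", {
  expect_equal(as_pct(observed_rate(2239, 6189)), 36.18)
  expect_equal(as_pct(observed_rate(427, 1175)), 36.34)
  expect_equal(observed_rate(0, 100), 0)
  expect_equal(as_pct(ms_rate(1361, 16430)), 8.28)
  expect_equal(as_pct(ms_rate(526, 4118)), 12.77)
  expect_equal(ms_rate(100, 100), 1)
  expect_equal(as_pct(mquit_rate(1361, 3292, 16430)), 88.25)
  expect_equal(mquit_rate(7, 10, 10), observed_rate(7, 10))
  expect_equal(mquit_rate(3, 5, 10), 0.8) # 3 quit + 5 missing over 10
  expect_equal(as_pct(followup_rate(6563, 16430)), 39.95)
  expect_equal(as_pct(followup_rate(3606, 16430)), 21.95)
  expect_equal(followup_rate(0, 10), 0)
})

test_that("zero denominators raise undefined-rate errors, never silent zero", {
  expect_error(observed_rate(0, 0), class = "cessbounds_undefined_rate")
  expect_error(ms_rate(0, 0), class = "cessbounds_undefined_rate")
  expect_error(mquit_rate(0, 0, 0), class = "cessbounds_undefined_rate")
  expect_error(followup_rate(0, 0), class = "cessbounds_undefined_rate")
})

test_that("convention ordering and width identities hold over random counts", {
  set.seed(2024)
  tab <- random_counts(1000L)
  tab <- tab[tab$n_answered >= 1, ]
  cr <- convention_rates(tab$n_quit, tab$n_answered, tab$n_assigned)
  expect_true(all(cr$m_s <= cr$observed + 1e-12))
  expect_true(all(cr$observed <= cr$m_quit + 1e-12))
  # equality exactly when ascertainment is complete
  full <- cr$n_answered == cr$n_assigned
  expect_equal(cr$m_s[full], cr$observed[full])
  expect_equal(cr$observed[full], cr$m_quit[full])
  expect_true(all(cr$m_s[!full] < cr$m_quit[!full]))
  # M=S is the observed rate shrunk by ascertainment
  expect_equal(cr$m_s, cr$observed * cr$n_answered / cr$n_assigned)
  # interval width equals the missingness fraction
  expect_equal(cr$m_quit - cr$m_s,
               (cr$n_assigned - cr$n_answered) / cr$n_assigned)
})

test_that("convention table reproduces every pooled published percentage", {
  ct <- convention_table(fixture_table2())
  cell <- function(w, win, col) ct[[col]][ct$wave_months == w & ct$window == win]
  expect_equal(as_pct(cell(6, "7-day", "observed")), 42.13)
  expect_equal(as_pct(cell(12, "30-day", "m_s")), 7.37)
  expect_equal(as_pct(cell(1, "7-day", "observed")), 36.18)
  expect_equal(as_pct(cell(1, "7-day", "followup")), 39.95)
  # the full grid, against directly recomputed unrounded values
  expect_equal(ct$observed, ct$n_quit / ct$n_answered, tolerance = 5e-5)
  expect_equal(ct$m_s, ct$n_quit / ct$n_assigned, tolerance = 5e-5)
})

test_that("missing cells get an explicit gap marker, not zero", {
  ct <- convention_table(fixture_table2(), waves = c(1L, 2L))
  gap <- ct[ct$wave_months == 2, ]
  expect_true(all(gap$missing_cell))
  expect_true(all(is.na(gap$observed)))
  one <- convention_table(fixture_table2()[1, ])
  expect_equal(nrow(one[!one$missing_cell, ]), 1)
})

test_that("condition table reproduces published per-arm percentages", {
  cd <- condition_table(fixture_table3())
  pick <- function(cond, w, col) cd[[col]][cd$condition == cond & cd$wave_months == w]
  expect_equal(as_pct(pick("1", 1, "observed")), 27.51)
  expect_equal(as_pct(pick("4", 12, "m_s")), 9.40)
  expect_equal(as_pct(pick("2", 6, "observed")), 44.23)
})

test_that("identical counts in all arms give identical rates in all arms", {
  wc <- wave_counts(condition = as.character(1:4), wave_months = 1L,
                    window = "7-day", n_assigned = 100L, n_responded = 60L,
                    n_answered = 50L, n_quit = 20L)
  cd <- condition_table(wc)
  expect_equal(length(unique(cd$observed)), 1L)
  expect_equal(length(unique(cd$m_s)), 1L)
})

test_that("the missing-denominator flag switches between answered and responded", {
  ct_a <- convention_table(fixture_table2(), missing_from = "answered")
  ct_r <- convention_table(fixture_table2(), missing_from = "responded")
  m12a <- ct_a$m_quit[ct_a$wave_months == 12 & ct_a$window == "7-day"]
  m12r <- ct_r$m_quit[ct_r$wave_months == 12 & ct_r$window == "7-day"]
  expect_equal(as_pct(m12a), 88.25)  # answered-item denominator: the 88% figure
  expect_equal(as_pct(m12r), 86.34)  # completed-follow-up denominator: ~86%
})
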