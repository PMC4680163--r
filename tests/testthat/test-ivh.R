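test_that("maximal states reach the printed scale maxima", {
  classic <- graeb_schema("classic")
  mgs <- graeb_schema("mgs32")
  expect_identical(graeb_score(ventricular_preset("maximal", classic),
                               classic), 12L)
  expect_identical(modified_graeb_score(ventricular_preset("maximal", mgs),
                                        mgs), 32L)
  expect_identical(schema_max(classic), 12L)
  expect_identical(schema_max(mgs), 32L)
  # enabling the per-ventricle expansion point raises the maximum above 32
  mgs_exp <- graeb_schema("mgs32", expansion_bonus = 1)
  expect_identical(schema_max(mgs_exp), 36L)
})

test_that("classic scoring follows the asymmetric lateral and small-ventricle rules", {
  classic <- graeb_schema("classic")
  st <- ventricular_preset("empty", classic)
  expect_identical(graeb_score(st, classic), 0L)
  # trace in one lateral only
  st$trace[st$compartment == "lateral_left"] <- TRUE
  expect_identical(graeb_score(ventricular_state(st), classic), 1L)
  # half-filled lateral scores 2, fuller (not expanded) 3
  st2 <- ventricular_preset("empty", classic)
  st2$fill[st2$compartment == "lateral_left"] <- 0.4
  expect_identical(graeb_score(ventricular_state(st2), classic), 2L)
  st2$fill[st2$compartment == "lateral_left"] <- 1
  expect_identical(graeb_score(ventricular_state(st2), classic), 3L)
  st2$expanded[st2$compartment == "lateral_left"] <- TRUE
  expect_identical(graeb_score(ventricular_state(st2), classic), 4L)
  # third ventricle: present = 1, filled and expanded = 2
  st3 <- ventricular_preset("empty", classic)
  st3$fill[st3$compartment == "third"] <- 0.6
  expect_identical(graeb_score(ventricular_state(st3), classic), 1L)
  st3$fill[st3$compartment == "third"] <- 1
  st3$expanded[st3$compartment == "third"] <- TRUE
  expect_identical(graeb_score(ventricular_state(st3), classic), 2L)
})

test_that("modified scoring uses filling quartiles", {
  mgs <- graeb_schema("mgs32")
  st <- ventricular_preset("empty", mgs)
  expect_identical(modified_graeb_score(st, mgs), 0L)
  st$fill[1] <- 0.30
  expect_identical(modified_graeb_score(ventricular_state(st), mgs), 2L)
  for (fill_score in list(c(0.2, 1L), c(0.5, 2L), c(0.6, 3L), c(0.76, 4L))) {
    st$fill[1] <- fill_score[[1]]
    expect_identical(modified_graeb_score(ventricular_state(st), mgs),
                     as.integer(fill_score[[2]]))
  }
})

test_that("a classic-schema score accepts fine-compartment states by aggregation", {
  mgs <- graeb_schema("mgs32")
  classic <- graeb_schema("classic")
  st <- ventricular_preset("maximal", mgs)
  expect_identical(graeb_score(st, classic), 12L)
  # missing compartments are reported by name
  partial <- st[st$ventricle == "third", ]
  expect_error(graeb_score(ventricular_state(partial), classic),
               "missing compartments: lateral_left, lateral_right, fourth")
})

test_that("both scores are monotone in fills and expansion flags", {
  mgs <- graeb_schema("mgs32")
  classic <- graeb_schema("classic")
  for (s in 1:30) {
    st <- generate_ventricular_state(s)
    g0 <- graeb_score(st, classic)
    m0 <- modified_graeb_score(st, mgs)
    up <- st
    up$fill <- pmin(1, up$fill + withr::with_seed(s, stats::runif(nrow(up), 0, 0.3)))
    up$trace <- up$trace & up$fill < 0.02
    expect_gte(graeb_score(ventricular_state(up), classic), g0)
    expect_gte(modified_graeb_score(ventricular_state(up), mgs), m0)
    exp_up <- up
    exp_up$expanded <- exp_up$fill > 0 | exp_up$trace
    expect_gte(graeb_score(ventricular_state(exp_up), classic),
               graeb_score(ventricular_state(up), classic))
  }
})

test_that("Graeb and modified Graeb rank cases concordantly", {
  scores <- vapply(1:500, function(s) {
    st <- generate_ventricular_state(s)
    c(graeb_score(st), modified_graeb_score(st))
  }, numeric(2))
  keep <- stats::sd(scores[1, ]) > 0 && stats::sd(scores[2, ]) > 0
  expect_true(keep)
  expect_gt(spearman_rs(scores[1, ], scores[2, ])$rs, 0.8)
})

test_that("custom schema files load and validate", {
  toy <- tempfile(fileext = ".yaml")
  writeLines(c(
    "name: toy",
    "expansion_bonus: 0",
    "compartments:",
    "  - name: only",
    "    ventricle: only",
    "    trace_score: 1",
    "    fill_scores:",
    "      - {max: 0.25, score: 1}",
    "      - {max: 0.50, score: 2}",
    "      - {max: 0.75, score: 3}",
    "      - {max: 1.00, score: 4}"
  ), toy)
  schema <- graeb_schema(toy)
  expect_identical(schema_max(schema), 4L)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "name: bad",
    "compartments:",
    "  - name: only",
    "    ventricle: only",
    "    fill_scores:",
    "      - {max: 0.75, score: 1}",
    "      - {max: 0.50, score: 2}"
  ), bad)
  expect_error(graeb_schema(bad), "strictly increasing")
})
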