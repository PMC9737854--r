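model <- plus_default_model()

test_that("the default hierarchy has the published structure", {
  expect_length(model$normalizers, 6)
  expect_setequal(names(model$normalizers),
                  c("pss10", "swls", "nmq", "mbi_ee", "mbi_dp", "mbi_pa"))
  expect_length(model$module_burnout$rules, 8)
  expect_length(model$module_mental$rules, 4)
  # final tier has the same structure as the three-input burnout module
  expect_length(model$final$rules, 8)
  strip_names <- function(sys) {
    list(out = lapply(sys$output$sets, function(s) c(s$l, s$k1, s$k2, s$r)),
         cons = vapply(sys$rules, `[[`, character(1), "consequent"),
         ant = lapply(sys$rules, function(r) unname(r$antecedent)))
  }
  expect_equal(strip_names(model$final), strip_names(model$module_burnout))
})

test_that("every model partition is a Ruspini partition on a dense grid", {
  grids <- c(lapply(model$normalizers, function(sys) sys$inputs[[1]]),
             list(module_input_variable("i"),
                  tier1_output_variable(extended = FALSE),
                  module_output_variable(extended = FALSE)))
  for (v in grids) {
    xs <- seq(v$domain[1], v$domain[2], length.out = 10001)
    sums <- rowSums(vapply(v$sets, trapezoid_membership,
                           numeric(length(xs)), x = xs))
    expect_lt(max(abs(sums - 1)), 1e-12)
  }
})

test_that("tier-1 normalization hits the exact boundaries and midpoints", {
  expect_identical(plus_normalize("pss10", 0, model), 1)
  expect_identical(plus_normalize("pss10", 40, model), 0)
  expect_equal(plus_normalize("swls", 35, model), 1)
  expect_equal(plus_normalize("swls", 5, model), 0)
  expect_equal(plus_normalize("pss10", 20, model), 0.5)
  expect_equal(plus_normalize("pss10", 7, model), 0.75, tolerance = 1e-12)
  expect_error(plus_normalize("pss10", 41, model), "legal|lie in")
  expect_error(plus_normalize("swls", 3, model), "lie in")
})

test_that("tier-1 normalization matches an independent numeric pipeline", {
  sets_out <- list(c(-0.5, 0, 0, 0.5), c(0, 0.5, 0.5, 1), c(0.5, 1, 1, 1.5))
  cases <- list(
    list(scale = "pss10", reversed = TRUE,
         sets = list(c(0, 0, 0, 14), c(0, 14, 26, 40), c(26, 40, 40, 40)),
         xs = c(0, 3, 7, 20, 31, 40)),
    list(scale = "swls", reversed = FALSE,
         sets = list(c(5, 5, 5, 15), c(5, 15, 24, 35), c(24, 35, 35, 35)),
         xs = c(5, 10, 19.5, 30, 35)),
    list(scale = "mbi_pa", reversed = FALSE,
         sets = list(c(0, 0, 0, 31), c(0, 31, 39, 49), c(39, 49, 49, 49)),
         xs = c(0, 20, 35, 44, 48)))
  for (cs in cases) {
    cons <- if (cs$reversed) c(3, 2, 1) else c(1, 2, 3)
    for (x in cs$xs) {
      expect_equal(plus_normalize(cs$scale, x, model),
                   oracle_normalize(x, cs$sets, sets_out, cons, -0.5, 1.5),
                   tolerance = 1e-6,
                   label = sprintf("normalize(%s, %g)", cs$scale, x))
    }
  }
})

test_that("aggregation modules reproduce the closed-form anchor points", {
  expect_equal(plus_module2(0, 0, model$module_mental), 0)
  expect_equal(plus_module2(1, 0, model$module_mental), 0.5)
  expect_equal(plus_module2(0.5, 0.5, model$module_mental), 0.5)
  expect_equal(plus_module3(1, 1, 1, model$module_burnout), 1)
  expect_equal(plus_module3(0, 0, 0, model$module_burnout), 0)
  expect_equal(plus_module3(1, 1, 0, model$module_burnout), 2 / 3)
  expect_equal(plus_module3(0.5, 0.5, 0.5, model$module_burnout), 0.5)
})

test_that("three-input modules are mirror-symmetric under complementation", {
  set.seed(99)
  for (i in 1:500) {
    a <- runif(1); b <- runif(1); cc <- runif(1)
    expect_equal(plus_module3(1 - a, 1 - b, 1 - cc, model$module_burnout),
                 1 - plus_module3(a, b, cc, model$module_burnout),
                 tolerance = 1e-9)
  }
})

test_that("a full evaluation propagates midpoints, boundaries and traces", {
  mid <- plus_evaluate(default_scores(), model)
  expect_s3_class(mid, "plus_result")
  expect_equal(unname(mid$normalized), rep(0.5, 6))
  expect_equal(mid$plus_score, 0.5)

  worst <- plus_evaluate(c(pss10 = 40, swls = 5, nmq = 40, mbi_ee = 54,
                           mbi_dp = 30, mbi_pa = 0), model)
  expect_equal(worst$plus_score, 0)
  expect_equal(unname(worst$normalized), rep(0, 6))

  # best raw profile: personal accomplishment tops out below 1 because the
  # published partition uses support bound 49 on the 0-48 instrument
  best <- plus_evaluate(c(pss10 = 0, swls = 35, nmq = 0, mbi_ee = 0,
                          mbi_dp = 0, mbi_pa = 48), model)
  expect_lt(best$normalized[["mbi_pa"]], 1)
  expect_gt(best$plus_score, 0.9)
  expect_lt(best$plus_score, 1)

  tr <- plus_evaluate(default_scores(), model, trace = TRUE)
  expect_named(tr$trace, c("tier1", "mental", "burnout", "final"))
  expect_equal(tr$trace$final$value, tr$plus_score)

  expect_error(plus_evaluate(c(pss10 = 20), model), "missing score")
  expect_error(plus_evaluate(replace(default_scores(), "mbi_dp", 31), model),
               "mbi_dp")
})

test_that("the physical module is an exact passthrough of normalized NMQ", {
  set.seed(5)
  for (i in 1:25) {
    sc <- default_scores()
    sc["nmq"] <- sample(0:40, 1)
    r <- plus_evaluate(sc, model)
    expect_identical(r$module_physical, r$normalized[["nmq"]])
    expect_identical(r$module_physical, plus_normalize("nmq", sc[["nmq"]], model))
  }
})

test_that("the PLUS score is monotone along every single score axis", {
  ranges <- plus_scales()
  for (i in seq_len(nrow(ranges))) {
    sc <- default_scores()
    dir <- if (ranges$higher_better[i]) 1 else -1
    xs <- seq(ranges$min[i], ranges$max[i], length.out = 21)
    if (dir < 0) xs <- rev(xs)           # sweep worst -> best
    vals <- vapply(xs, function(x) {
      sc[ranges$scale[i]] <- x
      plus_evaluate(sc, model)$plus_score
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-9),
                label = paste("monotone in", ranges$scale[i]))
  }
})

test_that("model definitions round-trip through config files unchanged", {
  json <- withr::local_tempfile(fileext = ".json")
  write_model_config(model, json)
  reloaded <- read_model_config(json)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(model, yml)
  reloaded_y <- read_model_config(yml)

  set.seed(123)
  ranges <- plus_scales()
  for (i in 1:100) {
    sc <- setNames(vapply(seq_len(6), function(j)
      round(runif(1, ranges$min[j], ranges$max[j])), numeric(1)),
      ranges$scale)
    a <- plus_evaluate(sc, model)$plus_score
    expect_identical(plus_evaluate(sc, reloaded)$plus_score, a)
    expect_identical(plus_evaluate(sc, reloaded_y)$plus_score, a)
  }
  expect_true(validate_model(reloaded))
  expect_error(read_model_config(withr::local_tempfile(fileext = ".json")),
               "not found")
})
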