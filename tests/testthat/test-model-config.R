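test_that("Michaelis constants derive from elementary rates", {
  expect_equal(derive_km_matrix(matrix(0.19), matrix(0.1), matrix(0.08))[1, 1],
               0.947, tolerance = 5e-4)
  expect_equal(derive_km_matrix(matrix(0.2), matrix(0.1), matrix(0.1))[1, 1], 1.0)
  expect_equal(derive_km_matrix(matrix(1.0), matrix(0), matrix(0))[1, 1], 0.0)
  # elementwise over a full matrix
  kon <- matrix(c(0.2, 0.19, 1e-5, 1e-5), 2, 2, byrow = TRUE)
  km <- derive_km_matrix(kon, matrix(0.1, 2, 2),
                         matrix(c(0.1, 0.08, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(km, (matrix(0.1, 2, 2) + matrix(c(0.1, 0.08, 0, 0), 2, 2, byrow = TRUE)) / kon)
  # a nonpositive association rate is rejected, naming the offending entry
  kon[2, 1] <- 0
  expect_error(derive_km_matrix(kon, matrix(0.1, 2, 2), matrix(0, 2, 2)),
               "kon\\[2,1\\]")
})

test_that("presets reproduce every printed Michaelis constant", {
  m1 <- build_preset("1")
  expect_equal(m1$km[1, 1], 1.0)
  expect_equal(m1$km[1, 2], 0.947, tolerance = 5e-4)
  expect_equal(m1$km[2, 1], 1e4)  # placeholder pairs: eta / epsilon
  expect_equal(m1$km[2, 2], 1e4)
  expect_equal(build_preset("2.1")$km[1, 3], 1.0)
  expect_equal(build_preset("3.1")$km[3, 4], 1.0)
  expect_equal(build_preset("3.1")$km[4, 4], 1.0)
  expect_equal(build_preset("3.2")$km[3, 4], 0.1)
  expect_equal(build_preset("3.2")$km[4, 4], 0.1)
  expect_equal(build_preset("3.0.1")$km[3, 4], 1.4)
  expect_equal(build_preset("3.0.2")$km[3, 4], 0.14)
  expect_equal(build_preset("3.0.2")$km[4, 4], 0.14)
})

test_that("presets are structurally valid and carry the stated parameters", {
  for (id in preset_ids()) {
    spec <- build_preset(id)
    findings <- validate_spec(spec)
    expect_identical(nrow(findings), 0L, label = paste("findings for preset", id))
  }
  m1 <- build_preset("1")
  expect_identical(m1$n, 2L)
  expect_equal(m1$decay, c(0.005, 0.005))
  expect_equal(m1$capacity, 20)
  expect_equal(m1$initials, c(1, 1))
  # the host cycle has no parasite and no rule producing a third species
  expect_true(all(m1$rules$product %in% 1:2))

  m22 <- build_preset("2.2")
  expect_equal(m22$mu, 0)
  expect_equal(m22$alpha, c(0, 0, 0.005))

  m31 <- build_preset("3.1")
  expect_equal(m31$mu, 0.01)
  expect_equal(m31$alpha, c(0, 0, 0.001, 0))
  expect_equal(m31$beta, 1.5)
  expect_equal(m31$species$capacity_weight, c(1, 1, 5, 10))
  # trigger rule: hyperparasites produced from the polymerase-parasite complex
  trig <- m31$rules[m31$rules$product == 4, ]
  expect_identical(nrow(trig), 1L)
  expect_equal(unlist(trig[, c("enzyme", "template")]), c(enzyme = 1L, template = 3L))
  expect_equal(trig$yield, 1.5)

  # residual-catalysis variants add the two futile-complex production routes
  m301 <- build_preset("3.0.1")
  extra <- m301$rules[m301$rules$enzyme %in% 3:4, ]
  expect_identical(nrow(extra), 2L)
  expect_true(all(extra$product == 4))
})

test_that("preset pairs differ only in their declared parameters", {
  flat <- function(spec) spec[setdiff(names(spec), c("name", "rules"))]
  a <- build_preset("2.1"); b <- build_preset("2.2")
  same <- setdiff(names(flat(a)), c("mu", "alpha"))
  expect_equal(flat(a)[same], flat(b)[same])
  expect_false(isTRUE(all.equal(a$mu, b$mu)))
  expect_false(isTRUE(all.equal(a$alpha, b$alpha)))
  # the numeric rule yields legitimately differ through mu
  expect_identical(a$rules[, c("enzyme", "template", "product", "yield_kind")],
                   b$rules[, c("enzyme", "template", "product", "yield_kind")])

  a <- build_preset("3.1"); b <- build_preset("3.2")
  same <- setdiff(names(flat(a)), c("kon", "km"))
  expect_equal(flat(a)[same], flat(b)[same])
  d <- which(a$kon != b$kon, arr.ind = TRUE)
  expect_setequal(paste(d[, 1], d[, 2]), c("3 4", "4 4"))
})

test_that("validation reports findings instead of throwing", {
  spec <- build_preset("1")
  spec$kon[1, 1] <- 0
  f <- validate_spec(spec)
  expect_true(any(f$severity == "error" & f$field == "kon"))

  spec <- build_preset("2.1")
  spec$mu <- 1.5
  f <- validate_spec(spec)
  expect_true(any(f$severity == "error" & f$field == "mu"))

  spec <- build_preset("1")
  spec$initials[2] <- -1
  expect_true(any(validate_spec(spec)$field == "initials"))

  spec <- build_preset("1")
  spec$dt <- 2000
  expect_true(any(validate_spec(spec)$field == "dt"))

  spec <- build_preset("1")
  spec$km[1, 1] <- 7  # stale derived field
  expect_true(any(validate_spec(spec)$field == "km"))
})

test_that("unknown preset ids are rejected with the list of valid ids", {
  expect_error(build_preset("9.9"), "3\\.0\\.2")
  expect_error(build_preset("model1"), "valid ids")
})

test_that("a spec round-trips through the configuration file format", {
  for (id in c("1", "2.2", "3.0.1")) {
    spec <- build_preset(id)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model_config(spec, path)
    back <- read_model_config(path)
    expect_equal(back[names(spec)], spec[names(spec)], tolerance = 1e-12,
                 label = paste("round-trip of preset", id))
  }
})

test_that("parameter overrides address scalars, vectors and matrix entries", {
  spec <- build_preset("3.1")
  spec2 <- set_spec_value(spec, "kon[3,4]", 1.0)
  expect_equal(spec2$kon[3, 4], 1.0)
  expect_equal(spec2$km[3, 4], 0.1)  # derived field refreshed

  spec2 <- set_spec_value(spec, "mu", 0)
  expect_equal(spec2$mu, 0)
  # mu-routing yields follow the new mutation rate
  expect_equal(spec2$rules$yield[spec2$rules$yield_kind == "one_minus_mu"],
               rep(1, 2))

  spec2 <- set_spec_value(spec, "alpha", 0.005)  # scalar goes to the parasite
  expect_equal(spec2$alpha, c(0, 0, 0.005, 0))
  spec2 <- set_spec_value(spec, "alpha[4]", 0.2)
  expect_equal(spec2$alpha[4], 0.2)

  expect_error(set_spec_value(spec, "nonsense", 1), "valid fields")
  expect_error(set_spec_value(spec, "kon[5,1]", 1), "out of range")
  expect_error(set_spec_value(spec, "mu[1]", 1), "scalar")
})
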