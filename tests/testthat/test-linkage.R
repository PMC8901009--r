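test_that("matching weights add per-field agreement/disagreement terms", {
  fields <- list(vp_field("a", agreement_weight = 2),
                 vp_field("b", agreement_weight = 2),
                 vp_field("c", agreement_weight = 2))
  r1 <- list(a = 1, b = "x", c = "y")
  expect_equal(matching_weight(r1, r1, fields), 6)

  fields_d <- list(vp_field("a"), vp_field("b"), vp_field("c"))
  r2 <- list(a = 2, b = "z", c = "w")
  expect_equal(matching_weight(r1, r2, fields_d), -3)

  mixed <- list(vp_field("a", agreement_weight = 2),
                vp_field("b", agreement_weight = 2),
                vp_field("c", agreement_weight = 2))
  r3 <- list(a = 1, b = "x", c = "other")
  expect_equal(matching_weight(r1, r3, mixed), 2 + 2 - 1)

  # missing field contributes zero; numeric comparator uses the tolerance
  expect_equal(matching_weight(list(a = 1), list(a = 1, b = "x"),
                               fields_d), 1)
  numf <- list(vp_field("v", "numeric", tolerance = 0.5))
  expect_equal(matching_weight(list(v = 1.0), list(v = 1.4), numf), 1)
  expect_equal(matching_weight(list(v = 1.0), list(v = 1.6), numf), -1)

  expect_error(vp_field("a", agreement_weight = -1,
                        disagreement_weight = 0), "must exceed")
})

test_that("log2 m/u weight derivation matches the closed form", {
  w <- fs_weights(0.9, 0.1)
  expect_equal(unname(w), c(log2(9), log2(1 / 9)))
})

test_that("extreme thresholds empty or saturate the candidate sets", {
  toy <- toy_linkage(3, 3, 2, seed = 5)
  hi <- build_candidate_sets(toy$A, toy$B, toy$C, default_config(99, 99))
  expect_true(all(lengths(hi$V_AC) == 0))
  expect_true(all(lengths(hi$V_BC) == 0))
  lo <- build_candidate_sets(toy$A, toy$B, toy$C, default_config(-99, -99))
  expect_true(all(lengths(lo$V_AC) == nrow(toy$A)))
  expect_true(all(lengths(lo$V_BC) == nrow(toy$B)))
  # strict inequality: a weight exactly at the threshold is excluded
  wmax <- max(lo$w_AC)
  at <- build_candidate_sets(toy$A, toy$B, toy$C,
                             default_config(wmax, -99))
  expect_false(any(vapply(seq_along(at$V_AC), function(k)
    any(lo$w_AC[at$V_AC[[k]], k] <= wmax), logical(1))))
  expect_error(
    build_candidate_sets(toy$A, toy$B, toy$C,
                         vp_linkage_config(0, 0, list(vp_field("nope")),
                                           list(vp_field("vessel")))),
    "absent")
})

test_that("population size matches brute-force enumeration on toy cases", {
  set.seed(61)
  for (i in 1:12) {
    toy <- toy_linkage(sample(1:5, 1), sample(1:5, 1), sample(1:5, 1),
                       seed = 100 + i)
    cfg <- default_config(sample(c(-3, 0, 1, 2), 1),
                          sample(c(-3, 0, 1, 2), 1))
    pop <- vp_link(toy$A, toy$B, toy$C, cfg)
    expect_equal(nrow(pop$records),
                 brute_population_size(toy$A, toy$B, toy$C, cfg))
    # size invariant |C| + sum_k |V_AC^k||V_BC^k|
    cand <- pop$candidates
    expect_equal(nrow(pop$records),
                 nrow(toy$C) + sum(lengths(cand$V_AC) * lengths(cand$V_BC)))
  }
})

test_that("raising a threshold never grows the population", {
  toy <- toy_linkage(5, 5, 4, seed = 77)
  sizes <- vapply(c(-3, -1, 0, 1, 2, 3), function(th)
    nrow(vp_link(toy$A, toy$B, toy$C, default_config(th, 0))$records),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  sizes_b <- vapply(c(-3, -1, 0, 1, 2, 3), function(th)
    nrow(vp_link(toy$A, toy$B, toy$C, default_config(0, th))$records),
    numeric(1))
  expect_true(all(diff(sizes_b) <= 0))
})

test_that("thresholds above max weight pass C through verbatim", {
  toy <- toy_linkage(4, 4, 3, seed = 9)
  pop <- vp_link(toy$A, toy$B, toy$C, default_config(99, 99))
  expect_equal(nrow(pop$records), nrow(toy$C))
  expect_true(all(pop$records$provenance == "bridge"))
  expect_equal(pop$records$clin_age_band, toy$C$age_band)
  expect_equal(pop$records$geom_vessel, toy$C$vessel)
})

test_that("linked records take fields unchanged from A and B, duplicating
           candidates across bridge rows", {
  A <- data.frame(age_band = c("60s", "60s"), sex = c("M", "M"),
                  extra_clin = c(11, 22))
  B <- data.frame(sten_band = c("50-70", "70-90"),
                  vessel = c("LAD", "RCA"), extra_geom = c(1.5, 2.5))
  C <- data.frame(age_band = c("60s", "60s"), sex = c("M", "M"),
                  sten_band = c("50-70", "50-70"),
                  vessel = c("LAD", "LAD"))
  pop <- vp_link(A, B, C, default_config(1.5, 1.5))
  linked <- pop$records[pop$records$provenance == "linked", ]
  # both A records match both bridge rows; only B1 matches: 2 + 2*2*1
  expect_equal(nrow(pop$records), 2 + 4)
  expect_setequal(linked$clin_extra_clin, c(11, 22))
  expect_true(all(linked$geom_extra_geom == 1.5))
  # an A record in two candidate sets appears in two combined records
  expect_equal(sum(linked$a_index == 1), 2)
  # no field mixing: clinical part comes from A rows untouched
  for (r in seq_len(nrow(linked)))
    expect_equal(unname(unlist(linked[r, c("clin_age_band", "clin_sex",
                                           "clin_extra_clin")])),
                 unname(unlist(A[linked$a_index[r], ])))
})

test_that("linkage configuration JSON round-trips", {
  cfg <- vp_linkage_config(2, 1,
    list(vp_field("age_band", agreement_weight = 2),
         vp_field("stenosis_pct", "numeric", tolerance = 5)),
    list(vp_field("vessel_label")))
  path <- withr::local_tempfile(fileext = ".json")
  out <- list(threshold_AC = cfg$threshold_AC,
              threshold_BC = cfg$threshold_BC,
              fields_AC = lapply(cfg$fields_AC, unclass),
              fields_BC = lapply(cfg$fields_BC, unclass))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_linkage_config(path)
  expect_equal(cfg2, cfg)
})
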