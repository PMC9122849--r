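test_that("diet weights normalize volumes within a period", {
  diet <- data.frame(pollen_type = c("A", "B"), period = "preceding",
                     volume = c(80, 20))
  vr <- compute_vr(diet, "preceding")
  expect_equal(vr$weights, c(A = 0.8, B = 0.2))

  single <- data.frame(pollen_type = "A", period = "preceding", volume = 7)
  expect_equal(compute_vr(single, "preceding")$weights, c(A = 1))

  zero <- data.frame(pollen_type = c("A", "B"), period = "preceding",
                     volume = c(0, 0))
  expect_error(compute_vr(zero, "preceding"), "zero")

  expect_warning(vr2 <- compute_vr(diet, "preceding",
                                   included_types = c("A", "B", "C")),
                 "weight 0.*C")
  expect_equal(unname(vr2$weights["C"]), 0)
})

test_that("pooled diet weights sum volumes across the season first", {
  diet <- data.frame(pollen_type = c("A", "B", "A"),
                     period = c("preceding", "preceding", "synchronous"),
                     volume = c(30, 20, 50))
  vr <- compute_vr(diet, "pooled")
  expect_equal(vr$weights[c("A", "B")], c(A = 0.8, B = 0.2))
})

test_that("cover shares aggregate species within a type and sum to 1", {
  plants <- data.frame(species = c("s1", "s2", "s3"),
                       pollen_type = c("P", "P", "Q"),
                       growth_form = "woody", origin = "wild")
  cover <- data.frame(landscape_id = c("L1", "L1", "L2"),
                      species = c("s1", "s2", "s2"),
                      cover_m2 = c(10, 5, 15))
  cr <- compute_cr(cover, plants, "P", landscape_ids = c("L1", "L2"))
  expect_equal(cr$shares, c(L1 = 0.5, L2 = 0.5))
  expect_equal(sum(cr$shares), 1, tolerance = 1e-15)

  simple <- data.frame(landscape_id = c("L1", "L2"), species = "s1",
                       cover_m2 = c(10, 30))
  cr2 <- compute_cr(simple, plants, "P", landscape_ids = c("L1", "L2"))
  expect_equal(cr2$shares, c(L1 = 0.25, L2 = 0.75))

  crq <- compute_cr(cover, plants, "Q", landscape_ids = c("L1", "L2"))
  expect_true(crq$zero_cover)
  expect_equal(unname(crq$shares), c(0, 0))
})

test_that("the worked 2-landscape index evaluates by hand to {0.8, 1.2}", {
  b <- fixture_tiny()
  ft <- fai_table(b, periods = "preceding")
  expect_equal(ft$fai, c(0.8, 1.2), tolerance = 1e-12)
  expect_equal(mean(ft$fai), 1, tolerance = 1e-12)
})

test_that("identical covers give fai = 1 everywhere; a monopoly landscape gets n", {
  plants <- data.frame(species = c("s1", "s2"), pollen_type = c("P", "Q"),
                       growth_form = "woody", origin = "wild")
  diet <- data.frame(pollen_type = c("P", "Q"), period = "preceding",
                     volume = c(60, 40))
  ids <- paste0("L", 1:4)
  flat <- expand.grid(landscape_id = ids, species = c("s1", "s2"),
                      stringsAsFactors = FALSE)
  flat$cover_m2 <- 5
  pw <- lapply(c("P", "Q"), function(p) compute_cr(flat, plants, p, ids))
  vr <- compute_vr(diet, "preceding")
  expect_equal(unname(compute_fai(pw, vr, 4)), rep(1, 4), tolerance = 1e-12)

  mono <- flat
  mono$cover_m2 <- ifelse(mono$landscape_id == "L3", 9, 0)
  pw2 <- lapply(c("P", "Q"), function(p) compute_cr(mono, plants, p, ids))
  fai <- compute_fai(pw2, vr, 4)
  expect_equal(unname(fai), c(0, 0, 4, 0), tolerance = 1e-12)
  expect_equal(mean(fai), 1, tolerance = 1e-12)
})

test_that("index mean is 1 and cover shares sum to 1 on random bundles", {
  for (seed in c(11, 12, 13)) {
    b <- suppressWarnings(generate(synthetic_config(seed = seed)))
    ft <- suppressMessages(fai_table(b))
    for (t in unique(ft$period)) {
      expect_equal(mean(ft$fai[ft$period == t]), 1, tolerance = 1e-9)
    }
    for (p in unique(b$plants$pollen_type)) {
      cr <- compute_cr(b$cover, b$plants, p, b$landscape_ids)
      if (!cr$zero_cover) expect_equal(sum(cr$shares), 1, tolerance = 1e-12)
    }
  }
})

test_that("index is invariant to common rescaling of covers or volumes", {
  b <- tiny_bundle()
  base <- fai_table(b, "preceding")$fai
  b2 <- b; b2$cover$cover_m2 <- b2$cover$cover_m2 * 137.5
  expect_equal(fai_table(b2, "preceding")$fai, base, tolerance = 1e-12)
  b3 <- b; b3$diet$volume <- b3$diet$volume * 0.004
  expect_equal(fai_table(b3, "preceding")$fai, base, tolerance = 1e-12)
})

test_that("doubling one landscape's covers weakly raises its index, lowers others", {
  b <- suppressWarnings(generate(synthetic_config(n_landscapes = 6, seed = 5)))
  base <- suppressMessages(fai_table(b, "preceding"))
  target <- base$landscape_id[3]
  b2 <- b
  sel <- b2$cover$landscape_id == target
  b2$cover$cover_m2[sel] <- b2$cover$cover_m2[sel] * 2
  after <- suppressMessages(fai_table(b2, "preceding"))
  expect_true(after$fai[3] >= base$fai[3] - 1e-12)
  expect_true(all(after$fai[-3] <= base$fai[-3] + 1e-12))
})

test_that("pollen-type contribution to the aggregate index equals vr", {
  b <- suppressWarnings(generate(synthetic_config(seed = 21)))
  pw <- suppressMessages(floravail:::period_weights(b, "preceding"))
  # brute force: accumulate each type's share of sum_l fai
  n <- length(b$landscape_ids)
  per_type <- vapply(pw$cover_shares, function(cs) {
    w <- pw$vr$weights[cs$pollen_type]
    sum(n * cs$shares * w)
  }, numeric(1))
  agg <- sum(per_type)
  expect_equal(unname(per_type / agg),
               unname(pw$vr$weights[vapply(pw$cover_shares, `[[`, "",
                                           "pollen_type")]),
               tolerance = 1e-12)
  cb <- suppressMessages(contribution_breakdown(b, "preceding", "pollen_type"))
  expect_equal(sum(cb$share), 1, tolerance = 1e-9)
})

test_that("a type set's combined contribution is the sum of its weights", {
  diet <- data.frame(pollen_type = c("a", "b", "c", "d"), period = "preceding",
                     volume = c(0.40, 0.20, 0.15, 0.25))
  plants <- data.frame(species = paste0("s", 1:4),
                       pollen_type = c("a", "b", "c", "d"),
                       growth_form = "woody", origin = "wild")
  cover <- expand.grid(landscape_id = c("L1", "L2"),
                       species = paste0("s", 1:4), stringsAsFactors = FALSE)
  cover$cover_m2 <- seq(2, 16, by = 2)
  landcover <- data.frame(landscape_id = c("L1", "L2"), class = "arable",
                          proportion = 0.5)
  distances <- data.frame(landscape_id = c("L1", "L2"),
                          dist_forest_m = 1, dist_urban_m = 1)
  seedset <- data.frame(landscape_id = c("L1", "L2"), pod_id = "p1",
                        seeds = c(2L, 3L))
  b <- as_bundle(diet, plants, cover, landcover, distances, seedset)
  cb <- contribution_breakdown(b, "preceding", c("a", "b", "c"))
  expect_equal(cb$share, 0.75, tolerance = 1e-12)
  all4 <- contribution_breakdown(b, "preceding", c("a", "b", "c", "d"))
  expect_equal(all4$share, 1, tolerance = 1e-12)
  expect_error(contribution_breakdown(b, "preceding", c("a", "zzz")), "zzz")
})

test_that("group contributions split a type's weight by its cover provenance", {
  diet <- data.frame(pollen_type = "P", period = "preceding", volume = 10)
  plants <- data.frame(species = c("wood_sp", "herb_sp"), pollen_type = "P",
                       growth_form = c("woody", "herbaceous"), origin = "wild")
  cover <- data.frame(landscape_id = rep(c("L1", "L2"), 2),
                      species = rep(c("wood_sp", "herb_sp"), each = 2),
                      cover_m2 = c(3, 2, 1, 4))  # woody 5, herbaceous 5
  landcover <- data.frame(landscape_id = c("L1", "L2"), class = "arable",
                          proportion = 0.5)
  distances <- data.frame(landscape_id = c("L1", "L2"),
                          dist_forest_m = 1, dist_urban_m = 1)
  seedset <- data.frame(landscape_id = c("L1", "L2"), pod_id = "p1",
                        seeds = c(2L, 3L))
  b <- as_bundle(diet, plants, cover, landcover, distances, seedset)
  cb <- contribution_breakdown(b, "preceding", "growth_form")
  expect_equal(cb$share[cb$group == "woody"], 0.5, tolerance = 1e-12)
  expect_equal(cb$share[cb$group == "herbaceous"], 0.5, tolerance = 1e-12)
  expect_equal(sum(cb$share), 1, tolerance = 1e-9)

  wild <- contribution_breakdown(b, "preceding", "origin")
  expect_equal(wild$share[wild$group == "wild"], 1, tolerance = 1e-12)
})

test_that("zero-cover types are dropped with renormalization by default", {
  tabs <- tiny_tables()
  tabs$diet <- rbind(tabs$diet,
                     data.frame(pollen_type = "p3", period = "preceding",
                                volume = 25))
  tabs$plants <- rbind(tabs$plants,
                       data.frame(species = "sp3", pollen_type = "p3",
                                  growth_form = "woody", origin = "wild"))
  b <- do.call(as_bundle, tabs)  # sp3 never appears in the cover table
  expect_message(ft <- fai_table(b, "preceding"), "p3")
  expect_equal(ft$fai, c(0.8, 1.2), tolerance = 1e-12)
  # raw-share mode keeps vr un-renormalized: mean falls below 1
  raw <- fai_table(b, "preceding", vr_include_unmapped = TRUE)
  expect_equal(mean(raw$fai), 100 / 125, tolerance = 1e-12)
})
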