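test_that("the bundled reader-study frequencies score exactly as published", {
  hot <- weighted_scores(reference_frequency_table("hot"))
  tab <- hot$per_category
  cell <- function(t, cat) t$weighted_score[t$category == cat & !is.na(t$weighted_score)]
  expect_equal(cell(tab, "very hypoechoic"), 2.52)
  expect_equal(cell(tab, "hypoechoic"), 0.32)
  expect_equal(cell(tab, "isoechoic"), 0)
  expect_equal(cell(tab, "solid"), 2)
  expect_equal(cell(tab, "macro-calcification"), 0)
  expect_equal(cell(tab, "punctate calcification"), 1.2)
  expect_equal(cell(tab, "none"), 0)
  expect_equal(hot$total, 6.04)

  inact <- weighted_scores(reference_frequency_table("inactivated"))
  tab2 <- inact$per_category
  expect_equal(cell(tab2, "very hypoechoic"), 1.29)
  expect_equal(cell(tab2, "hypoechoic"), 1.04)
  expect_equal(cell(tab2, "isoechoic"), 0.05)
  expect_equal(cell(tab2, "macro-calcification"), 0.16)
  expect_equal(cell(tab2, "punctate calcification"), 0.42)
  expect_equal(inact$total, 4.96)
  # localization rows pass through unscored
  expect_true(all(is.na(tab$weighted_score[tab$attribute == "localization"])))
})

test_that("risk points are consistent with the reference weighted-score ratios", {
  pts <- risk_point_map()
  for (rc in c("hot", "inactivated")) {
    t <- weighted_scores(reference_frequency_table(rc))$per_category
    sc <- t[!is.na(t$weighted_score) & t$probability > 0, ]
    expect_equal(sc$weighted_score / sc$probability,
                 unname(pts[sc$category]), tolerance = 1e-9)
  }
})

test_that("scores are linear in the frequencies and zero for foci-free tables", {
  counts <- data.frame(
    attribute = c("echogenicity", "echogenicity", "echogenicity",
                  "composition", "foci", "foci", "foci"),
    category = c("very hypoechoic", "hypoechoic", "isoechoic", "solid",
                 "macro-calcification", "punctate calcification", "none"),
    count = c(10, 20, 5, 35, 0, 0, 35))
  t1 <- feature_frequency_table(counts, "hot", 100)
  t2 <- feature_frequency_table(transform(counts, count = 2 * count), "hot", 100)
  expect_equal(weighted_scores(t2)$total, 2 * weighted_scores(t1)$total)
  # a table whose only echogenic-foci category is "none" contributes 0 points
  foci_rows <- weighted_scores(t1)$per_category
  expect_equal(sum(foci_rows$weighted_score[foci_rows$attribute == "foci"]), 0)
})

test_that("unknown categories and impossible frequencies are rejected", {
  bad <- data.frame(attribute = "echogenicity", category = "anechoic", count = 1)
  expect_error(feature_frequency_table(bad, "hot", 10), "unknown")
  over <- data.frame(attribute = c("foci", "foci"),
                     category = c("none", "punctate calcification"),
                     count = c(9, 9))
  expect_error(feature_frequency_table(over, "hot", 10), "exceed")
})

test_that("ratings tabulate to exact frequencies and round-trip the reference", {
  two <- data.frame(region_class = "hot",
                    echogenicity = "very hypoechoic",
                    composition = "solid", foci = "none")
  two <- rbind(two, two)
  t <- tabulate_from_ratings(two)[["hot"]]
  expect_equal(t$table$probability[t$table$category == "very hypoechoic"], 1.0)

  # synthesize 100 per-nodule ratings matching the bundled hot-region counts
  ratings <- data.frame(
    region_class = "hot",
    echogenicity = rep(c("very hypoechoic", "hypoechoic"), c(84, 16)),
    composition = "solid",
    foci = rep(c("punctate calcification", "none"), c(40, 60)),
    localization = rep(c("on margin", "not on margin"), c(27, 73)),
    shape = "wider-than-tall")
  expect_message(tabs <- tabulate_from_ratings(ratings), "shape")
  got <- tabs[["hot"]]$table
  ref <- reference_frequency_table("hot")$table
  key <- paste(ref$attribute, ref$category)
  expect_equal(got$probability[match(key, paste(got$attribute, got$category))],
               ref$probability)
  expect_equal(weighted_scores(tabs[["hot"]])$total, 6.04)

  expect_error(tabulate_from_ratings(two[, -2]), "missing required")
  miss <- two; miss$foci[1] <- NA
  expect_error(tabulate_from_ratings(miss), "missing foci")
})

test_that("phantom feature records feed the tabulation directly", {
  cfg <- tiny_phantom()
  ds <- generate_dataset(cfg, 0, 8, seed = 91)
  ratings <- do.call(rbind, lapply(ds, function(s) {
    data.frame(region_class = "hot",
               echogenicity = s$feature_record$echogenicity,
               composition = s$feature_record$composition,
               foci = s$feature_record$foci)
  }))
  t <- tabulate_from_ratings(ratings)[["hot"]]
  expect_equal(sum(t$table$count[t$table$attribute == "echogenicity"]), 8)
  expect_gte(weighted_scores(t)$total, 0)
})
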