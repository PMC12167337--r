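fixture_readings <- function() {
  read_reading_table(system.file("extdata", "reader_angulation.csv",
                                 package = "pocusalign"))
}
fixture_accuracy <- function() {
  read_accuracy_table(system.file("extdata", "reader_accuracy.csv",
                                  package = "pocusalign"))
}

test_that("reference angulations reproduce the tabulated reader means", {
  refs <- reference_angulation(fixture_readings())
  expect_equal(refs[["s03"]], 8.7)
  expect_equal(refs[["s10"]], 10.4)
  expect_equal(refs[["s00"]], 3.9)
  expect_equal(refs[["s09"]], 9.6)
  # all-no-fracture samples keep the marker
  expect_true(all(is.na(refs[c("s01", "s02", "s06", "s08")])))
  # readings of 0 are distinct from the marker only in bookkeeping
  tbl <- reading_table(data.frame(sample = "a", participant = 1:3,
                                  modality = "XRAY", angle_deg = c("0", "0", "0")))
  expect_equal(unname(reference_angulation(tbl)), 0)
})

test_that("per-reader MAEs, discrepancy and pooled correlation match the fixture statistics", {
  tbl <- fixture_readings()
  refs <- reference_angulation(tbl)
  m <- mae(tbl, refs)
  get <- function(p, mod) m$mae[m$participant == p & m$modality == mod]
  expect_equal(get(1, "POCUS"), 4.4)
  expect_equal(get(2, "POCUS"), 3.7)
  expect_equal(get(3, "POCUS"), 5.0)
  expect_equal(get(1, "XRAY"), 2.8)
  expect_equal(get(2, "XRAY"), 1.8)
  expect_equal(get(3, "XRAY"), 2.0)
  expect_equal(mean_discrepancy(m), 2.2)
  expect_equal(round(pooled_pearson(tbl, refs), 2), 0.18)
})

test_that("MAE is zero when readings equal references", {
  df <- expand.grid(sample = c("a", "b"), participant = 1:3,
                    modality = c("POCUS", "XRAY"), stringsAsFactors = FALSE)
  df$angle_deg <- ifelse(df$sample == "a", "4.0", "9.0")
  m <- mae(reading_table(df))
  expect_true(all(m$mae == 0))
  expect_equal(mean_discrepancy(m), 0)
})

test_that("mean discrepancy averages per-participant MAE differences", {
  m <- data.frame(participant = rep(1:3, each = 2),
                  modality = rep(c("POCUS", "XRAY"), 3),
                  mae = c(3, 1, 3, 1, 3, 1))
  expect_equal(mean_discrepancy(m), 2.0)
})

test_that("pooled Pearson is unit-invariant and guards degenerate input", {
  tbl <- fixture_readings()
  refs <- reference_angulation(tbl)
  r1 <- pooled_pearson(tbl, refs)
  tbl2 <- tbl
  tbl2$angle_deg <- tbl2$angle_deg * 2 # rescale the angle unit everywhere
  tbl2 <- reading_table(transform(tbl2, angle_deg = as.character(angle_deg)))
  r2 <- pooled_pearson(tbl2, refs = refs * 2)
  expect_equal(r1, r2, tolerance = 1e-12)

  const <- reading_table(data.frame(sample = rep(c("a", "b"), each = 3),
                                    participant = rep(1:3, 2),
                                    modality = "XRAY",
                                    angle_deg = rep(c("5", "7"), each = 3)))
  expect_error(pooled_pearson(const, modality = "XRAY"), "zero variance")
  # errors exactly proportional to references correlate perfectly
  prop <- data.frame(sample = rep(c("a", "b", "c"), each = 2),
                     participant = rep(1, 6),
                     modality = rep(c("POCUS", "XRAY"), 3),
                     angle_deg = as.character(c(6, 5, 12, 10, 24, 20)))
  expect_equal(pooled_pearson(reading_table(prop)), 1, tolerance = 1e-12)
})

test_that("mean accuracies aggregate the per-reader fixture values", {
  acc <- fixture_accuracy()
  expect_equal(mean_accuracy(acc, "POCUS"), 0.76)
  expect_equal(mean_accuracy(acc, "XRAY"), 0.97)
  all1 <- data.frame(participant = 1:3, modality = "POCUS", accuracy = 1)
  expect_equal(mean_accuracy(all1, "POCUS"), 1)
})

test_that("majority vote requires two agreeing labels", {
  expect_equal(majority_vote(c("B", "B", "N")), "B")
  expect_equal(majority_vote(c("N", "N", "N")), "N")
  expect_error(majority_vote(c("B", "G", "N")), "no majority")
  expect_error(majority_vote(c("B", "B")), "three labels")
})

test_that("the study report is row-order invariant and serializes", {
  tbl <- fixture_readings()
  perm <- tbl[sample(nrow(tbl)), ]
  rep1 <- run_study(tbl, fixture_accuracy())
  rep2 <- run_study(perm, fixture_accuracy())
  expect_equal(rep1$mae_deg, rep2$mae_deg)
  expect_equal(rep1$mean_discrepancy_deg, rep2$mean_discrepancy_deg)
  expect_equal(rep1$pearson_pocus_error_vs_reference, 0.18)
  expect_equal(rep1$mean_accuracy$POCUS, 0.76)
  expect_equal(rep1$mean_accuracy$XRAY, 0.97)

  out <- withr::local_tempfile(fileext = ".json")
  run_study(tbl, fixture_accuracy(), out = out)
  js <- jsonlite::fromJSON(out)
  expect_equal(js$mean_discrepancy_deg, 2.2)
  expect_equal(js$mae_deg[["1_POCUS"]], 4.4)
})

test_that("malformed reading tables are rejected", {
  expect_error(reading_table(data.frame(sample = 1, angle_deg = "3")), "lacks column")
  expect_error(reading_table(data.frame(sample = 1, participant = 1,
                                        modality = "CT", angle_deg = "3")),
               "unknown modality")
})
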