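# header-sheet rows in import-file shape
hdr <- function(name, kind = "numeric", derived = FALSE, from = NA,
                indicator = NA, cutoff = NA, direction = NA,
                replicate = NA) {
  data.frame(Name = name, Kind = kind, Replicate = replicate,
             Time_Point = NA, Readout_Technology = NA, Derived = derived,
             Derived_From = from, Positive_Indicator = indicator,
             Cutoff = cutoff, Direction = direction, Description = NA,
             stringsAsFactors = FALSE)
}

test_that("screen result import types values and counts them", {
  lib <- makeSmLibrary(format = 384, controls = c(A01 = "dmso_control"))
  headers <- rbind(hdr("Rep1", replicate = 1), hdr("Rep2", replicate = 2))
  w <- libraryWells(lib)
  data <- data.frame(Plate = w$plate, Well = w$well,
                     Assay_Well_Type = w$well_type,
                     Rep1 = seq_len(nrow(w)), Rep2 = rev(seq_len(nrow(w))),
                     stringsAsFactors = FALSE)
  sc <- makeScreenWithResult(lib, headers, data)
  sr <- screenResult(sc)
  v <- resultValues(sr)
  expect_identical(nrow(v), 384L)
  # 1 plate x 384 wells x 2 replicate columns = 768 result values
  expect_identical(sum(!is.na(v$Rep1)) + sum(!is.na(v$Rep2)), 768L)
  expect_true(is.numeric(v$Rep1))
  expect_identical(nrow(dataColumns(sr)), 2L)
})

test_that("typed errors cite the cell; unknown wells and cycles rejected", {
  lib <- makeSmLibrary(format = 96)
  headers <- hdr("Score")
  ok <- data.frame(Plate = 1, Well = c("A02", "A03"),
                   Assay_Well_Type = "experimental",
                   Score = c("1.5", "oops"), stringsAsFactors = FALSE)
  expect_error(makeScreenWithResult(lib, headers, ok),
               "sheet 'Data' row 2 column 'Score'.*not numeric")

  bad_well <- data.frame(Plate = 7, Well = "A02",
                         Assay_Well_Type = "experimental", Score = 1,
                         stringsAsFactors = FALSE)
  expect_error(makeScreenWithResult(lib, headers, bad_well),
               "unknown to the screened libraries")

  self_ref <- hdr("Score", derived = TRUE, from = "Score")
  expect_error(makeScreenWithResult(lib, self_ref, ok),
               "earlier columns")
  fwd <- rbind(hdr("A", derived = TRUE, from = "B"), hdr("B"))
  expect_error(makeScreenWithResult(lib, fwd, ok), "earlier columns")
})

test_that("re-import replaces values and keeps the created date", {
  lib <- makeSmLibrary(format = 96)
  headers <- hdr("Score")
  d1 <- data.frame(Plate = 1, Well = "A02",
                   Assay_Well_Type = "experimental", Score = 1.5,
                   stringsAsFactors = FALSE)
  sc <- newScreen("S-9", "small_molecule", libraryNames = "SML")
  sc <- importScreenResult(sc, list(`Data Headers` = headers, Data = d1),
                           list(lib), date = "2026-01-01")
  d2 <- data.frame(Plate = 1, Well = c("A03", "B04"),
                   Assay_Well_Type = "experimental", Score = c(2, 3),
                   stringsAsFactors = FALSE)
  sc <- importScreenResult(sc, list(`Data Headers` = headers, Data = d2),
                           list(lib), date = "2026-03-01")
  sr <- screenResult(sc)
  # no trace of the first import remains
  expect_identical(nrow(resultValues(sr)), 2L)
  expect_false("A02" %in% resultValues(sr)$well)
  expect_identical(sr@dateCreated, as.Date("2026-01-01"))
  expect_identical(sr@dateUpdated, as.Date("2026-03-01"))
})

test_that("positives classify by boolean, partition and both thresholds", {
  lib <- makeSmLibrary(format = 96)
  headers <- rbind(
    hdr("Hit", kind = "boolean", indicator = "boolean"),
    hdr("Band", kind = "partitioned", indicator = "partition"),
    hdr("Up", indicator = "threshold", cutoff = 2, direction = "above"),
    hdr("Down", indicator = "threshold", cutoff = 2, direction = "below"))
  data <- data.frame(
    Plate = 1, Well = c("A02", "A03", "A04", "A01"),
    Assay_Well_Type = c("experimental", "experimental", "experimental",
                        "dmso_control"),
    Hit = c(TRUE, FALSE, TRUE, TRUE),
    Band = c("strong", "none", "weak", "medium"),
    Up = c(2.0, 2.1, 9.9, 9.9),
    Down = c(2.0, 1.9, -1, -9),
    stringsAsFactors = FALSE)
  sc <- makeScreenWithResult(lib, headers, data)

  expect_equal(unname(classifyPositives(sc, "Hit")),
               c(TRUE, FALSE, TRUE))
  expect_equal(unname(classifyPositives(sc, "Band")),
               c(TRUE, FALSE, TRUE))
  # strictly exceed, in the stated direction
  expect_equal(unname(classifyPositives(sc, "Up")),
               c(FALSE, TRUE, TRUE))
  expect_equal(unname(classifyPositives(sc, "Down")),
               c(FALSE, TRUE, TRUE))
  # the control well (value 9.9) is absent from the output
  expect_false("1:A01" %in% names(classifyPositives(sc, "Up")))
  expect_error(classifyPositives(sc, "nope"), "unknown data column")
  expect_error(
    classifyPositives(screenResult(sc), "Up2"), "unknown data column")
})

test_that("positives summaries match brute-force recounts", {
  lib <- makeSmLibrary(format = 384, controls = c())
  withr::with_seed(5, {
    for (trial in 1:5) {
      w <- libraryWells(lib)
      n <- nrow(w)
      headers <- rbind(
        hdr("Up", indicator = "threshold", cutoff = 1.2,
            direction = "above"),
        hdr("Band", kind = "partitioned", indicator = "partition"))
      data <- data.frame(
        Plate = w$plate, Well = w$well, Assay_Well_Type = w$well_type,
        Up = round(rnorm(n), 4),
        Band = sample(c("strong", "medium", "weak", "none"), n,
                      replace = TRUE, prob = c(.02, .03, .05, .9)),
        stringsAsFactors = FALSE)
      sc <- makeScreenWithResult(lib, headers, data)
      # brute force straight off the generated frame
      exp <- data$Assay_Well_Type == "experimental"
      bruteUp <- sum(data$Up[exp] > 1.2)
      bruteBand <- sum(data$Band[exp] != "none")
      su <- positivesSummary(sc, "Up")
      sb <- positivesSummary(sc, "Band")
      expect_identical(su$count, bruteUp)
      expect_identical(sb$count, bruteBand)
      expect_equal(su$percent, 100 * bruteUp / sum(exp))
      expect_equal(sb$percent, 100 * bruteBand / sum(exp))
    }
  })
  # degenerate: no experimental wells with values
  headers <- hdr("Up", indicator = "threshold", cutoff = 0,
                 direction = "above")
  data <- data.frame(Plate = 1, Well = "A01",
                     Assay_Well_Type = "dmso_control", Up = 1,
                     stringsAsFactors = FALSE)
  sc <- makeScreenWithResult(lib, headers, data)
  expect_error(positivesSummary(sc, "Up"), "undefined")
})

test_that("boundary positive percentages come out exact", {
  lib <- makeSmLibrary(format = 384, controls = c())
  w <- libraryWells(lib)
  headers <- hdr("Up", indicator = "threshold", cutoff = 0,
                 direction = "above")
  mk <- function(vals) makeScreenWithResult(
    lib, headers, data.frame(Plate = w$plate, Well = w$well,
                             Assay_Well_Type = w$well_type, Up = vals,
                             stringsAsFactors = FALSE))
  allPos <- positivesSummary(mk(rep(1, 384)), "Up")
  expect_identical(allPos$count, 384L)
  expect_identical(allPos$percent, 100)
  nonePos <- positivesSummary(mk(rep(-1, 384)), "Up")
  expect_identical(nonePos$count, 0L)
  expect_identical(nonePos$percent, 0)
})

test_that("plate heat maps lay values out by row/column", {
  lib <- makeSmLibrary(format = 384, controls = c())
  w <- libraryWells(lib)
  headers <- hdr("Score")
  data <- data.frame(Plate = w$plate, Well = w$well,
                     Assay_Well_Type = w$well_type,
                     Score = seq_len(nrow(w)), stringsAsFactors = FALSE)
  data$Score[data$Well == "B03"] <- 7.5
  sc <- makeScreenWithResult(lib, headers, data)
  m <- plateHeatmap(sc, 1, "Score")
  expect_identical(dim(m), c(16L, 24L))
  expect_identical(m[2, 3], 7.5)  # B03 -> row 2, col 3
  expect_identical(rownames(m)[16], "P")
  expect_error(plateHeatmap(sc, 9, "Score"), "not screened")

  headers2 <- hdr("Label", kind = "text")
  data2 <- data.frame(Plate = 1, Well = "A01",
                      Assay_Well_Type = "experimental", Label = "x",
                      stringsAsFactors = FALSE)
  sc2 <- makeScreenWithResult(lib, headers2, data2)
  expect_error(plateHeatmap(sc2, 1, "Label"), "numeric")
})

test_that("comparison tables outer-join wells across screens and studies", {
  lib <- makeSmLibrary(format = 96)
  headers <- hdr("Score")
  w <- libraryWells(lib)
  ten <- w[w$well_type == "experimental", ][1:10, ]
  mk <- function(rows, vals, id) makeScreenWithResult(
    lib, headers, data.frame(Plate = rows$plate, Well = rows$well,
                             Assay_Well_Type = "experimental",
                             Score = vals, stringsAsFactors = FALSE),
    facilityId = id)
  scA <- mk(ten, 1:10, "A")
  scB <- mk(ten[-5, ], 101:109, "B")  # B lacks the fifth well

  tbl <- mergeComparisonTable(list(A = scA, B = scB), "well")
  expect_identical(nrow(tbl), 10L)  # union of keys
  expect_identical(names(tbl), c("key", "A.Score", "B.Score"))
  missingRow <- tbl[tbl$key == paste0(ten$plate[5], ":", ten$well[5]), ]
  expect_false(is.na(missingRow$A.Score))
  expect_true(is.na(missingRow$B.Score))  # empty, never zero

  # symmetric in source order up to column ordering
  tbl2 <- mergeComparisonTable(list(B = scB, A = scA), "well")
  expect_identical(tbl2[, names(tbl)], tbl)

  # study annotations join by reagent whatever the key mode
  st <- newStudy("100000", "toxicity",
                 data.frame(vendor_id = ten$vendor_id[1:4],
                            Toxic = c(TRUE, FALSE, TRUE, FALSE),
                            stringsAsFactors = FALSE))
  tbl3 <- mergeComparisonTable(list(A = scA, ANN = st), "well")
  expect_identical(sum(!is.na(tbl3$ANN.Toxic)), 4L)
  tbl4 <- mergeComparisonTable(list(A = scA, ANN = st), "reagent")
  expect_identical(nrow(tbl4), 10L)
  expect_identical(sum(!is.na(tbl4$ANN.Toxic)), 4L)
})

test_that("table filtering matches a brute-force double filter", {
  tbl <- data.frame(key = paste0("k", 1:8),
                    x = c(1.9, 2.0, 2.1, NA, 5, -1, 2.05, 3),
                    name = c("kinase A", "phosphatase", "KINASE B", NA,
                             "kin", "ligase", "kinase C", "unknown"),
                    stringsAsFactors = FALSE)
  expect_identical(nrow(filterTable(tbl, list(list(column = "x",
                                                   op = "ge",
                                                   operand = 2)))), 5L)
  got <- filterTable(tbl, list(list(column = "name", op = "contains",
                                    operand = "kinase")))
  expect_setequal(got$key, c("k1", "k3", "k7"))  # case-insensitive

  crit1 <- list(column = "x", op = "between", operand = c(2, 3))
  crit2 <- list(column = "name", op = "contains", operand = "kinase")
  both <- filterTable(tbl, list(crit1, crit2))
  brute <- filterTable(filterTable(tbl, list(crit1)), list(crit2))
  expect_identical(both, brute)
  # NA cells never satisfy any criterion
  expect_false("k4" %in% filterTable(tbl, list(crit1))$key)

  expect_error(filterTable(tbl, list(list(column = "name", op = "ge",
                                          operand = 1))), "numeric")
  expect_error(filterTable(tbl, list(list(column = "x", op = "contains",
                                          operand = "a"))), "text")
})
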