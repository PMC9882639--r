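test_that("item bank round-trips through YAML and validates its invariants", {
  fx <- toyRawData()
  path <- tempfile(fileext = ".yaml")
  writeItemBank(fx$bank, path)
  bank2 <- loadItemBank(path)
  expect_equal(as.data.frame(itemInfo(bank2)), as.data.frame(itemInfo(fx$bank)))
  expect_equal(as.data.frame(sourceCodes(bank2)),
               as.data.frame(sourceCodes(fx$bank)))
  # empty config refuses to build a bank
  empty <- tempfile(fileext = ".yaml")
  writeLines("items: []", empty)
  expect_error(loadItemBank(empty), "no items")
  # duplicate source codes are named in the error
  expect_error(
    ItemBank(data.frame(item_id = c("a", "b"), modality = "Visual",
                        response_pattern = "HYPO"),
             data.frame(instrument = "SP1", code = c("Q1", "Q1"),
                        item_id = c("a", "b"))),
    "duplicate source code.*SP1 Q1")
  # unknown modality rejected
  expect_error(
    ItemBank(data.frame(item_id = "a", modality = "Telepathic",
                        response_pattern = "HYPO"),
             data.frame(instrument = "SP1", code = "Q1", item_id = "a")),
    "unknown modality")
})

test_that("harmonization reverse-scores SP1, merges the crosswalk, and masks by coverage", {
  fx <- toyRawData()
  se <- harmonizeResponses(fx$raw, fx$bank)
  m <- responses(se)
  # SP1 raw 1 -> 5; raw 4 would be 2 but p2 also has SEQ3 (preferred)
  expect_identical(m["aud1", "p1"], 5L)
  # SEQ3 codes pass through unreversed
  expect_identical(m["aud1", "p3"], 2L)
  expect_identical(m["aud3", "p3"], 4L)
  # conflict on p2/aud1: SP1 gives 2 (reversed 4), SEQ3 gives 3; SEQ kept
  expect_identical(m["aud1", "p2"], 3L)
  expect_true(nrow(metadata(se)$conflicts) >= 1)
  # missingness mask equals the instrument-coverage mask:
  # p1 completed only SP1 (no aud3 source), p3 only SEQ3
  expect_true(is.na(m["aud3", "p1"]))
  expect_false(is.na(m["aud3", "p2"]))
  expect_identical(colData(se)$instruments,
                   c(p1 = "SP1", p2 = "SP1,SEQ3", p3 = "SEQ3"))
  # reverse-scoring is an involution
  k <- 1:5
  expect_identical(6L - (6L - k), k)
  # out-of-range code errors with the location
  bad <- fx$raw
  bad$SP1$Q1[1] <- 9L
  expect_error(harmonizeResponses(bad, fx$bank), "person 'p1'")
})

test_that("harmonization never invents observations", {
  fx <- toyRawData()
  se <- harmonizeResponses(fx$raw, fx$bank)
  m <- responses(se)
  sc <- as.data.frame(sourceCodes(fx$bank))
  for (pid in colnames(m)) {
    instr <- strsplit(colData(se)$instruments[pid], ",")[[1]]
    for (it in rownames(m)) {
      src <- sc[sc$item_id == it & sc$instrument %in% instr, ]
      observedRaw <- any(vapply(seq_len(nrow(src)), function(i) {
        d <- fx$raw[[src$instrument[i]]]
        pid %in% d$person_id &&
          !is.na(d[[src$code[i]]][d$person_id == pid])
      }, logical(1)))
      if (!observedRaw) expect_true(is.na(m[it, pid]))
    }
  }
})

test_that("age filtering keeps the closed interval and logs counts", {
  m <- matrix(3L, 2, 4, dimnames = list(c("i1", "i2"), paste0("q", 1:4)))
  se3 <- as(SummarizedExperiment::SummarizedExperiment(
    assays = list(responses = m),
    rowData = S4Vectors::DataFrame(n_categories = rep(5L, 2),
                                   row.names = rownames(m)),
    colData = S4Vectors::DataFrame(study_id = "s1",
                                   age = c(2.9, 3.0, 18.0, 18.1),
                                   row.names = colnames(m))),
    "SensoryExperiment")
  expect_message(out <- filterEligible(se3), "2 persons outside")
  expect_identical(colnames(out), c("q2", "q3"))
  expect_equal(metadata(out)$ageFilter$removed, 2)
  # empty input stays empty
  expect_silent(suppressMessages(e0 <- filterEligible(se3[, FALSE])))
  expect_identical(ncol(e0), 0L)
})

test_that("response matrices round-trip through CSV", {
  fx <- toyRawData()
  se <- harmonizeResponses(fx$raw, fx$bank)
  path <- tempfile(fileext = ".csv")
  writeResponses(se, path)
  se2 <- readResponses(path, fx$bank)
  expect_identical(responses(se2), responses(se))
  expect_identical(colData(se2)$study_id, colData(se)$study_id)
  expect_identical(colData(se2)$instruments, unname(colData(se)$instruments))
})
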