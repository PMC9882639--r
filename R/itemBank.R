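#' Construct an ItemBank
#'
#' @param items data.frame (or DataFrame) of item definitions; required
#'   columns `item_id`, `modality`, `response_pattern`; optional
#'   `n_categories` (default 5), `single_item_indicator`, `most_global`.
#' @param sourceCodes data.frame with columns `instrument`, `code`,
#'   `item_id` mapping instrument-specific question codes to harmonized
#'   items.
#' @param reverseInstruments instruments whose raw codes are reverse-scored
#'   relative to the harmonized direction (default the first Sensory Profile
#'   and its short form).
#' @return a validated [ItemBank-class] object.
#' @export
ItemBank <- function(items, sourceCodes,
                     reverseInstruments = c("SP1", "SSP1")) {
  items <- as.data.frame(items)
  if (is.null(items$n_categories)) items$n_categories <- 5L
  if (is.null(items$single_item_indicator)) items$single_item_indicator <- FALSE
  if (is.null(items$most_global)) items$most_global <- FALSE
  items$n_categories <- as.integer(items$n_categories)
  items <- items[, c("item_id", "modality", "response_pattern",
                     "n_categories", "single_item_indicator", "most_global")]
  sourceCodes <- as.data.frame(sourceCodes)
  for (cl in c("instrument", "code", "item_id"))
    sourceCodes[[cl]] <- as.character(sourceCodes[[cl]])
  sourceCodes <- sourceCodes[order(sourceCodes$item_id,
                                   sourceCodes$instrument,
                                   sourceCodes$code),
                             c("instrument", "code", "item_id")]
  rownames(sourceCodes) <- NULL
  obj <- new("ItemBank",
             items = DataFrame(items),
             sourceCodes = DataFrame(sourceCodes),
             reverseInstruments = as.character(reverseInstruments))
  validObject(obj)
  obj
}

#' Read an item bank from a YAML or JSON config file
#'
#' The config holds one entry per harmonized item with its modality,
#' response pattern, category count, flags, and source-instrument codes,
#' plus an optional top-level `reverse_instruments` list.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [ItemBank-class].
#' @export
loadItemBank <- function(path) {
  if (!file.exists(path)) .stopf("item bank file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg) || !length(cfg$items))
    .stopf("item bank config '%s' defines no items", path)
  rows <- lapply(cfg$items, function(it) {
    for (f in c("item_id", "modality", "response_pattern"))
      if (is.null(it[[f]])) .stopf("item entry missing field '%s'", f)
    data.frame(item_id = it$item_id, modality = it$modality,
               response_pattern = it$response_pattern,
               n_categories = if (is.null(it$n_categories)) 5L else as.integer(it$n_categories),
               single_item_indicator = isTRUE(it$single_item_indicator),
               most_global = isTRUE(it$most_global))
  })
  items <- do.call(rbind, rows)
  src <- do.call(rbind, lapply(cfg$items, function(it) {
    if (!length(it$sources)) .stopf("item '%s' has no source codes", it$item_id)
    do.call(rbind, lapply(it$sources, function(s)
      data.frame(instrument = s$instrument, code = as.character(s$code),
                 item_id = it$item_id)))
  }))
  rev <- if (is.null(cfg$reverse_instruments)) c("SP1", "SSP1")
         else unlist(cfg$reverse_instruments)
  ItemBank(items, src, rev)
}

#' Write an item bank back to YAML
#'
#' Inverse of [loadItemBank()]; the write/read round trip is lossless.
#'
#' @param bank an [ItemBank-class].
#' @param path output path.
#' @export
writeItemBank <- function(bank, path) {
  it <- as.data.frame(itemInfo(bank))
  sc <- as.data.frame(sourceCodes(bank))
  entries <- lapply(seq_len(nrow(it)), function(i) {
    srcs <- sc[sc$item_id == it$item_id[i], , drop = FALSE]
    list(item_id = it$item_id[i], modality = it$modality[i],
         response_pattern = it$response_pattern[i],
         n_categories = it$n_categories[i],
         single_item_indicator = it$single_item_indicator[i],
         most_global = it$most_global[i],
         sources = lapply(seq_len(nrow(srcs)), function(j)
           list(instrument = srcs$instrument[j], code = srcs$code[j])))
  })
  yaml::write_yaml(list(reverse_instruments = as.list(bank@reverseInstruments),
                        items = entries), path)
  invisible(path)
}

#' Harmonize raw per-instrument response tables into one ordinal matrix
#'
#' Merges instrument-specific question columns into harmonized items via the
#' bank's crosswalk, reverse-scores codes from reverse-scored instruments
#' (`k -> n_categories + 1 - k`, so that 5 always means "more frequent"),
#' and records instrument coverage per person. When a person has observed
#' values from more than one instrument for the same harmonized item, the
#' value from the instrument latest in `preference` is kept and the conflict
#' is logged in `metadata(result)$conflicts`.
#'
#' @param raw named list of data.frames, one per instrument; each must have a
#'   `person_id` column, with remaining columns named by source code.
#' @param bank an [ItemBank-class].
#' @param preference character vector of instrument-name prefixes in
#'   increasing priority; defaults to preferring SEQ-family values over
#'   SP-family values for duplicated observations.
#' @param studyId optional named vector mapping person_id to study label; a
#'   single value recycles. Defaults to `"study1"`.
#' @return a [SensoryExperiment-class] (items x persons).
#' @export
harmonizeResponses <- function(raw, bank, preference = c("SP", "SSP", "SEQ"),
                               studyId = "study1") {
  stopifnot(is(bank, "ItemBank"), is.list(raw), length(names(raw)) == length(raw))
  it <- as.data.frame(itemInfo(bank))
  sc <- as.data.frame(sourceCodes(bank))
  persons <- unique(unlist(lapply(raw, function(d) as.character(d$person_id))))
  p <- nrow(it); n <- length(persons)
  m <- matrix(NA_integer_, p, n, dimnames = list(it$item_id, persons))
  prov <- matrix(NA_character_, p, n)  # which instrument supplied each cell
  conflicts <- list()
  prefRank <- function(instr) {
    r <- vapply(preference, function(pref) startsWith(instr, pref), logical(1))
    if (any(r)) max(which(r)) else 0L
  }
  for (instr in names(raw)) {
    d <- raw[[instr]]
    if (is.null(d$person_id)) .stopf("instrument '%s' table lacks person_id", instr)
    pid <- as.character(d$person_id)
    codes <- sc[sc$instrument == instr, , drop = FALSE]
    for (j in seq_len(nrow(codes))) {
      colname <- codes$code[j]
      if (!colname %in% colnames(d)) next
      item <- codes$item_id[j]
      nc <- it$n_categories[match(item, it$item_id)]
      v <- d[[colname]]
      bad <- which(!is.na(v) & (v < 1 | v > nc | v != round(v)))
      if (length(bad))
        .stopf("out-of-range code %s for person '%s', instrument %s item %s",
               v[bad[1]], pid[bad[1]], instr, colname)
      v <- as.integer(v)
      if (instr %in% bank@reverseInstruments) v <- nc + 1L - v
      ci <- match(pid, persons)
      ri <- match(item, it$item_id)
      for (k in seq_along(v)) {
        if (is.na(v[k])) next
        cur <- m[ri, ci[k]]
        if (is.na(cur)) {
          m[ri, ci[k]] <- v[k]
          prov[ri, ci[k]] <- instr
        } else {
          conflicts[[length(conflicts) + 1L]] <-
            data.frame(person_id = pid[k], item_id = item,
                       kept_instrument = NA_character_,
                       old = cur, new = v[k])
          if (prefRank(instr) >= prefRank(prov[ri, ci[k]])) {
            m[ri, ci[k]] <- v[k]
            prov[ri, ci[k]] <- instr
          }
          conflicts[[length(conflicts)]]$kept_instrument <- prov[ri, ci[k]]
        }
      }
    }
  }
  coverage <- vapply(persons, function(pp) {
    paste(names(raw)[vapply(raw, function(d) pp %in% as.character(d$person_id),
                            logical(1))], collapse = ",")
  }, character(1))
  sid <- if (length(studyId) == 1L) rep(studyId, n)
         else unname(studyId[persons])
  se <- SummarizedExperiment(
    assays = list(responses = m),
    rowData = DataFrame(it, row.names = it$item_id),
    colData = DataFrame(study_id = sid, instruments = coverage,
                        row.names = persons))
  se <- as(se, "SensoryExperiment")
  metadata(se)$conflicts <- if (length(conflicts)) do.call(rbind, conflicts)
                            else data.frame()
  validObject(se)
  se
}

#' Filter persons by eligible age range
#'
#' Retains persons whose age lies inside the closed interval
#' `[minAge, maxAge]` (boundaries included). Persons with missing age are
#' retained. Counts of removed persons are stored in
#' `metadata(result)$ageFilter` and reported via `message()`.
#'
#' @param se a [SensoryExperiment-class] whose `colData` has an `age` column,
#'   or `ages` supplied separately.
#' @param minAge,maxAge inclusive bounds in years.
#' @param ages optional numeric vector of ages aligned with columns of `se`.
#' @return the filtered [SensoryExperiment-class].
#' @export
filterEligible <- function(se, minAge = 3, maxAge = 18, ages = NULL) {
  stopifnot(is(se, "SensoryExperiment"))
  if (is.null(ages)) ages <- colData(se)$age
  if (is.null(ages)) {
    message("no ages available; all ", ncol(se), " persons retained")
    return(se)
  }
  keep <- is.na(ages) | (ages >= minAge & ages <= maxAge)
  out <- se[, keep]
  metadata(out)$ageFilter <- list(removed = sum(!keep), retained = sum(keep),
                                  bounds = c(minAge, maxAge))
  message(sum(!keep), " persons outside [", minAge, ", ", maxAge,
          "] years removed; ", sum(keep), " retained")
  out
}

#' Write / read a harmonized response matrix as CSV
#'
#' One person per row: `person_id`, `study_id`, `instruments`, then one
#' column per item. The write/read round trip is lossless for codes, study
#' labels and coverage.
#'
#' @param se a [SensoryExperiment-class].
#' @param path CSV path.
#' @export
writeResponses <- function(se, path) {
  m <- t(responses(se))
  df <- data.frame(person_id = colnames(se),
                   study_id = colData(se)$study_id,
                   instruments = colData(se)$instruments,
                   m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeResponses
#' @param bank optional [ItemBank-class] used to restore item metadata.
#' @export
readResponses <- function(path, bank = NULL) {
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(person_id = "character"))
  meta <- c("person_id", "study_id", "instruments")
  items <- setdiff(colnames(df), meta)
  m <- t(as.matrix(df[, items, drop = FALSE]))
  mode(m) <- "integer"
  colnames(m) <- df$person_id
  rd <- if (!is.null(bank)) {
    it <- as.data.frame(itemInfo(bank))
    DataFrame(it[match(items, it$item_id), , drop = FALSE], row.names = items)
  } else DataFrame(n_categories = rep(max(m, 5L, na.rm = TRUE), length(items)),
                   row.names = items)
  se <- SummarizedExperiment(
    assays = list(responses = m), rowData = rd,
    colData = DataFrame(study_id = df$study_id,
                        instruments = if (is.null(df$instruments)) "" else df$instruments,
                        row.names = df$person_id))
  as(se, "SensoryExperiment")
}
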