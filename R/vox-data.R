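# VOX data model: trial-level records, CSV parsing and validation,
# operant totals, a seeded synthetic generator, and descriptor-table I/O.

vox_trial_columns <- c("speaker_id", "session", "response_form",
                       "condition", "emitted")

#' Speaker metadata record
#'
#' @param speaker_id Label identifying the speaker.
#' @param age Age as a `"YY:MM"` string (months 0-11), e.g. `"3:4"`.
#' @param sex,race_ethnicity,diagnosis Free-text labels.
#' @param home_languages Character vector of home languages.
#' @return A list of class `vox_speaker`.
#' @export
speaker_record <- function(speaker_id, age = NA_character_, sex = NA_character_,
                           race_ethnicity = NA_character_,
                           home_languages = character(),
                           diagnosis = NA_character_) {
  if (!is.na(age)) parse_age(age)  # validates
  structure(list(speaker_id = as.character(speaker_id), age = age, sex = sex,
                 race_ethnicity = race_ethnicity,
                 home_languages = as.character(home_languages),
                 diagnosis = diagnosis),
            class = "vox_speaker")
}

#' Parse a "YY:MM" age into decimal years
#'
#' @param age Character vector like `"4:11"`; months must lie in 0-11.
#' @return Numeric vector of ages in years (months / 12 added).
#' @examples
#' parse_age("4:11")
#' @export
parse_age <- function(age) {
  parts <- strsplit(as.character(age), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2 || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("age must be 'YY:MM', got '", paste(p, collapse = ":"), "'",
           call. = FALSE)
    }
    y <- as.numeric(p[1]); m <- as.numeric(p[2])
    if (m < 0 || m > 11) stop("age months must be 0-11", call. = FALSE)
    y + m / 12
  }, numeric(1))
}

#' Trial-level VOX dataset
#'
#' Wraps a table of probe trials: each row records whether one response
#' form, probed under one operant condition in one session, was emitted.
#' A complete assessment probes every response form under all four
#' conditions in each session, with at least three response forms.
#'
#' @param trials A data frame with columns `speaker_id`, `session`,
#'   `response_form`, `condition` (one of [vox_operants], matched
#'   case-insensitively and stored lower-case), and `emitted` (0/1).
#' @param speaker Optional [speaker_record()].
#' @param strict If `TRUE`, an incomplete probe grid (a response form
#'   missing a condition in its session) or fewer than three response
#'   forms per session is an error; otherwise incomplete grids produce a
#'   warning and missing probes count as not emitted.
#' @return A list of class `vox_dataset` with elements `trials` (tibble)
#'   and `speaker`.
#' @export
vox_dataset <- function(trials, speaker = NULL, strict = FALSE) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(vox_trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  trials <- trials[vox_trial_columns]
  trials$condition <- tolower(as.character(trials$condition))
  bad <- which(!trials$condition %in% vox_operants)
  if (length(bad)) {
    stop("unknown condition '", trials$condition[bad[1]], "' in trial row ",
         bad[1], " (expected one of: ", paste(vox_operants, collapse = ", "),
         ")", call. = FALSE)
  }
  bad <- which(!trials$emitted %in% c(0, 1))
  if (length(bad)) {
    stop("emitted must be 0 or 1; trial row ", bad[1], " has '",
         trials$emitted[bad[1]], "'", call. = FALSE)
  }
  trials$emitted <- as.integer(trials$emitted)
  trials$session <- as.integer(trials$session)
  if (any(trials$session < 0, na.rm = TRUE)) {
    stop("session must be a non-negative integer", call. = FALSE)
  }
  trials$speaker_id <- as.character(trials$speaker_id)
  trials$response_form <- as.character(trials$response_form)
  check_probe_grid(trials, strict = strict)
  structure(list(trials = trials, speaker = speaker), class = "vox_dataset")
}

# Complete-assessment contract: each (response_form, condition) pair once
# per session; >= 3 response forms per session.
check_probe_grid <- function(trials, strict) {
  if (nrow(trials) == 0) return(invisible(TRUE))
  problems <- character()
  for (s in unique(trials$session)) {
    tr <- trials[trials$session == s, ]
    forms <- unique(tr$response_form)
    if (length(forms) < 3) {
      problems <- c(problems, paste0("session ", s, " probes only ",
                                     length(forms), " response form(s)"))
    }
    counts <- table(tr$response_form, factor(tr$condition,
                                             levels = vox_operants))
    if (any(counts > 1)) {
      problems <- c(problems, paste0("session ", s,
                                     " has duplicate (response, condition) probes"))
    } else if (any(counts < 1)) {
      problems <- c(problems, paste0("session ", s,
                                     " has an incomplete probe grid"))
    }
  }
  if (length(problems)) {
    msg <- paste(problems, collapse = "; ")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " (missing probes are treated as not emitted)",
            call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.vox_dataset <- function(x, ...) {
  cat("<VOX dataset>", nrow(x$trials), "trials,",
      length(unique(x$trials$session)), "session(s),",
      length(unique(x$trials$response_form)), "response form(s)\n")
  if (!is.null(x$speaker)) cat("  speaker:", x$speaker$speaker_id, "\n")
  print(x$trials, ...)
  invisible(x)
}

#' Read trial-level VOX records from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row and the
#' canonical columns `speaker_id`, `session`, `response_form`,
#' `condition`, `emitted`. Condition labels are matched
#' case-insensitively; unknown columns are dropped with a warning; row
#' order is preserved.
#'
#' @param file Path or connection.
#' @param speaker Optional [speaker_record()] to attach.
#' @param strict Passed to [vox_dataset()].
#' @return A `vox_dataset`.
#' @export
parse_trials <- function(file, speaker = NULL, strict = FALSE) {
  raw <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  extra <- setdiff(names(raw), vox_trial_columns)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  missing_cols <- setdiff(vox_trial_columns, names(raw))
  if (length(missing_cols)) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw)) {
    em <- suppressWarnings(as.numeric(raw$emitted))
    bad <- which(is.na(em) | !em %in% c(0, 1))
    if (length(bad)) {
      stop("emitted must be 0 or 1; CSV data row ", bad[1], " has '",
           raw$emitted[bad[1]], "'", call. = FALSE)
    }
    raw$emitted <- as.integer(em)
    raw$session <- as.integer(raw$session)
  } else {
    raw$emitted <- integer()
    raw$session <- integer()
  }
  vox_dataset(raw, speaker = speaker, strict = strict)
}

#' Write trial-level VOX records to CSV
#'
#' Emits the canonical column order so that `parse_trials()` /
#' `write_trials()` round-trips are byte-stable.
#'
#' @param dataset A `vox_dataset`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trials <- function(dataset, file) {
  stopifnot(inherits(dataset, "vox_dataset"))
  readr::write_csv(dataset$trials[vox_trial_columns], file, progress = FALSE)
  invisible(file)
}

#' Per-operant totals from a dataset
#'
#' Sums (or averages per session) the emitted responses under each
#' operant condition; these totals are the values plotted on the radar
#' axes. Missing probes contribute nothing, i.e. count as not emitted.
#'
#' @param dataset A `vox_dataset`.
#' @param sessions Optional vector of session numbers to include; default
#'   all.
#' @param aggregate `"sum"` (raw summed frequency, the default) or
#'   `"mean"` (per-session mean frequency, for multi-round assessments
#'   reported on a common scale).
#' @return An [axis_values()] object. An empty selection yields all
#'   zeros.
#' @examples
#' operant_totals(vox_fixture("table2"))  # tact 5, mand 2, echoic 5, sequelic 1
#' @export
operant_totals <- function(dataset, sessions = NULL,
                           aggregate = c("sum", "mean")) {
  stopifnot(inherits(dataset, "vox_dataset"))
  aggregate <- match.arg(aggregate)
  tr <- dataset$trials
  if (!is.null(sessions)) tr <- tr[tr$session %in% sessions, ]
  tot <- vapply(vox_operants,
                function(op) sum(tr$emitted[tr$condition == op]),
                numeric(1))
  if (aggregate == "mean") {
    k <- length(unique(tr$session))
    if (k > 0) tot <- tot / k
  }
  axis_values(tact = tot[["tact"]], mand = tot[["mand"]],
              echoic = tot[["echoic"]], sequelic = tot[["sequelic"]])
}

#' Response-by-condition emission matrix
#'
#' Binary matrix with one row per (session, response form) block and one
#' column per operant condition; the related-samples design behind the
#' functional-independence test. Missing probes are 0.
#'
#' @param dataset A `vox_dataset`.
#' @return Integer matrix with operant column names.
#' @export
vox_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "vox_dataset"))
  tr <- dataset$trials
  if (nrow(tr) == 0) {
    return(matrix(integer(), ncol = 4, dimnames = list(NULL, vox_operants)))
  }
  block <- paste(tr$session, tr$response_form, sep = "\r")
  blocks <- unique(block)
  m <- matrix(0L, nrow = length(blocks), ncol = 4,
              dimnames = list(blocks, vox_operants))
  idx <- cbind(match(block, blocks), match(tr$condition, vox_operants))
  m[idx] <- tr$emitted
  rownames(m) <- sub("^[^\r]*\r", "", blocks)
  m
}

#' Specification for a synthetic VOX dataset
#'
#' Defines the study conditions emulated by [generate_synthetic()]: the
#' number of speaker-selected response forms, the number of assessment
#' rounds, and an independent per-operant Bernoulli emission probability.
#'
#' @param n_responses Positive integer; response forms per session.
#' @param emission_probabilities Numeric vector of 4 probabilities in
#'   `[0, 1]`, named or in the order tact, mand, echoic, sequelic.
#' @param n_sessions Positive integer; default 1.
#' @param seed Integer seed making the draw reproducible.
#' @return A list of class `vox_synthetic_spec`.
#' @export
synthetic_spec <- function(n_responses, emission_probabilities,
                           n_sessions = 1, seed = 1) {
  p <- as.numeric(emission_probabilities)
  if (length(p) != 4 || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("emission_probabilities must be four values in [0, 1]",
         call. = FALSE)
  }
  names(p) <- if (!is.null(names(emission_probabilities)))
    names(emission_probabilities) else vox_operants
  if (!setequal(names(p), vox_operants)) {
    stop("emission_probabilities names must be the four operants",
         call. = FALSE)
  }
  if (n_responses < 1 || n_sessions < 1) {
    stop("n_responses and n_sessions must be positive", call. = FALSE)
  }
  structure(list(n_responses = as.integer(n_responses),
                 n_sessions = as.integer(n_sessions),
                 emission_probabilities = p[vox_operants],
                 seed = as.integer(seed)),
            class = "vox_synthetic_spec")
}

# Run code under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic VOX dataset
#'
#' Draws a complete probe grid (`n_responses` x 4 conditions x
#' `n_sessions`) of independent Bernoulli emissions with the per-operant
#' probabilities of the spec. Identical seeds give identical datasets;
#' the caller's RNG state is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @param speaker_id Label for the generated speaker.
#' @return A `vox_dataset`.
#' @examples
#' generate_synthetic(synthetic_spec(6, c(1, 1, 1, 1), seed = 7))
#' @export
generate_synthetic <- function(spec, speaker_id = "synthetic") {
  stopifnot(inherits(spec, "vox_synthetic_spec"))
  forms <- sprintf("resp_%02d", seq_len(spec$n_responses))
  grid <- expand.grid(condition = vox_operants, response_form = forms,
                      session = seq_len(spec$n_sessions),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- spec$emission_probabilities[grid$condition]
  emitted <- with_seed(spec$seed,
                       as.integer(stats::runif(nrow(grid)) < p))
  vox_dataset(tibble::tibble(speaker_id = speaker_id,
                             session = grid$session,
                             response_form = grid$response_form,
                             condition = grid$condition,
                             emitted = emitted))
}

# ---- descriptor-table I/O ---------------------------------------------

descriptor_numeric_cols <- c("tact", "mand", "echoic", "sequelic",
                             "A", "A_tilde", "x", "y", "R", "Q", "C")
descriptor_cols <- c("speaker_id", "age", descriptor_numeric_cols)

#' Tabulate shape descriptors
#'
#' Flattens descriptor objects or series into the reporting layout (one
#' row per profile: speaker, age, axis values, A, centroid, R, Q, C).
#'
#' @param x A `vox_descriptors`, a `vox_series`, or a list of either.
#' @param speaker_id,age Labels used when `x` carries none.
#' @return A tibble with the columns listed above.
#' @export
descriptor_table <- function(x, speaker_id = NA_character_,
                             age = NA_character_) {
  if (inherits(x, "vox_series")) return(x$table)
  if (inherits(x, "vox_descriptors")) x <- list(x)
  rows <- lapply(x, function(d) {
    if (inherits(d, "vox_series")) return(d$table)
    v <- d$values
    val <- function(op) if (!is.null(v) && op %in% names(v)) v[[op]] else NA_real_
    tibble::tibble(speaker_id = speaker_id, age = age,
                   tact = val("tact"), mand = val("mand"),
                   echoic = val("echoic"), sequelic = val("sequelic"),
                   A = d$A, A_tilde = d$A_tilde,
                   x = d$centroid[["x"]], y = d$centroid[["y"]],
                   R = d$R, Q = d$Q,
                   C = if (is.null(d$C)) NA_real_ else d$C)
  })
  do.call(rbind, rows)
}

#' Write a descriptor table
#'
#' CSV output is the human-readable report: numeric cells rounded to two
#' decimals, mirroring published descriptor tables. JSON output keeps
#' full double precision and round-trips exactly through
#' [read_descriptors()].
#'
#' @param x A descriptor table (tibble), or anything accepted by
#'   [descriptor_table()].
#' @param file Output path; format inferred from the extension unless
#'   given.
#' @param format `"csv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_descriptors <- function(x, file, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", file, ignore.case = TRUE)) "json" else "csv"
  }
  tab <- if (is.data.frame(x)) tibble::as_tibble(x) else descriptor_table(x)
  for (col in setdiff(descriptor_cols, names(tab))) tab[[col]] <- NA_real_
  tab <- tab[descriptor_cols]
  if (format == "json") {
    jsonlite::write_json(tab, file, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    out <- tab
    for (col in descriptor_numeric_cols) {
      out[[col]] <- ifelse(is.na(tab[[col]]), "",
                           sprintf("%.2f", round(tab[[col]], 2)))
    }
    readr::write_csv(out, file, progress = FALSE)
  }
  invisible(file)
}

#' Read a descriptor table written by [write_descriptors()]
#'
#' @param file Path to a `.json` (full precision) or `.csv` (2-decimal
#'   report) descriptor table.
#' @return A tibble in the [descriptor_table()] layout.
#' @export
read_descriptors <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    tab <- tibble::as_tibble(jsonlite::fromJSON(file))
    if (nrow(tab) == 0) {
      tab <- tibble::as_tibble(stats::setNames(
        rep(list(numeric()), length(descriptor_cols)), descriptor_cols))
    }
  } else {
    tab <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  }
  for (col in descriptor_numeric_cols) tab[[col]] <- as.numeric(tab[[col]])
  tab$speaker_id <- as.character(tab$speaker_id)
  tab$age <- as.character(tab$age)
  tab[descriptor_cols]
}
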