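USER_CSV_COLUMNS <- c("age", "sex", "smoker", "diabetes", "height",
                      "weight", "sbp", "on_bp_medication",
                      "total_cholesterol", "family_history")

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  out
}

parse_num <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  attr(out, "bad") <- which(!is.na(x) & x != "" & is.na(out))
  out
}

#' Read user risk-factor records from CSV
#'
#' One row per user; the documented header is `age, sex, smoker,
#' diabetes, height, weight, sbp, on_bp_medication, total_cholesterol,
#' family_history`. An empty `sbp` or `total_cholesterol` cell means
#' the user does not know the value: the record's known flag is set
#' false and imputation supplies a population average downstream. Rows
#' with unparseable cells are dropped and collected, with their line
#' numbers, in the `problems` attribute.
#'
#' @param path CSV file path.
#' @return A data frame of typed user records with `sbp_known` and
#'   `cholesterol_known` columns added; attribute `problems` is a data
#'   frame (`line`, `field`, `message`) of rejected rows.
#' @export
read_user_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(USER_CSV_COLUMNS, names(raw))
  if (length(missing)) {
    stop("input is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  problems <- list()
  note <- function(line, field, message) {
    problems[[length(problems) + 1L]] <<- data.frame(
      line = line, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  # data lines start after the header
  lines <- seq_len(n) + 1L
  num_fields <- c("age", "height", "weight", "sbp", "total_cholesterol")
  bool_fields <- c("smoker", "diabetes", "on_bp_medication",
                   "family_history")
  parsed <- list()
  drop <- rep(FALSE, n)
  for (f in num_fields) {
    v <- parse_num(raw[[f]])
    for (i in attr(v, "bad")) {
      note(lines[i], f, paste0("cannot parse '", raw[[f]][i],
                               "' as a number"))
      drop[i] <- TRUE
    }
    attr(v, "bad") <- NULL
    parsed[[f]] <- v
  }
  for (f in bool_fields) {
    v <- parse_bool(raw[[f]])
    bad <- which(is.na(v))
    for (i in bad) {
      note(lines[i], f, paste0("cannot parse '", raw[[f]][i],
                               "' as true/false"))
      drop[i] <- TRUE
    }
    parsed[[f]] <- v
  }
  sex <- tolower(trimws(raw$sex))
  bad_sex <- which(!sex %in% c("female", "male"))
  for (i in bad_sex) {
    note(lines[i], "sex", paste0("sex must be 'female' or 'male', got '",
                                 raw$sex[i], "'"))
    drop[i] <- TRUE
  }
  for (f in c("age", "height", "weight")) {
    bad <- which(!drop & is.na(parsed[[f]]))
    for (i in bad) {
      note(lines[i], f, "required value is missing")
      drop[i] <- TRUE
    }
  }
  out <- data.frame(
    age = parsed$age, sex = sex, smoker = parsed$smoker,
    diabetes = parsed$diabetes, height = parsed$height,
    weight = parsed$weight, sbp = parsed$sbp,
    on_bp_medication = parsed$on_bp_medication,
    total_cholesterol = parsed$total_cholesterol,
    family_history = parsed$family_history,
    stringsAsFactors = FALSE
  )
  out$sbp_known <- !is.na(out$sbp)
  out$cholesterol_known <- !is.na(out$total_cholesterol)
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- if (length(problems)) {
    do.call(rbind, problems)
  } else {
    data.frame(line = integer(0), field = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Compute heart ages for a data frame of users
#'
#' Runs the full validate / impute / invert pipeline of
#' [calculate_heart_age()] over each row and collects the results.
#'
#' @param users A data frame as returned by [read_user_csv()] or
#'   [generate_users()].
#' @inheritParams calculate_heart_age
#' @return A data frame, one row per user, with columns `user_id` (when
#'   present in the input), `age`, `sex`, `heart_age_display`,
#'   `heart_age_raw`, `category`, `risk`, `sbp_imputed`,
#'   `cholesterol_imputed`, `blocked`, `advisories` (messages collapsed
#'   with `" | "`).
#' @export
calculate_heart_ages <- function(users,
                                 coeffs = default_coefficients(),
                                 table = read_imputation_table(),
                                 rules = default_validation_rules(),
                                 bounds = heart_age_bounds()) {
  stopifnot(is.data.frame(users))
  rows <- lapply(seq_len(nrow(users)), function(i) {
    u <- users[i, ]
    p <- risk_profile(
      age = u$age, sex = u$sex, smoker = u$smoker,
      diabetes = u$diabetes, height = u$height, weight = u$weight,
      sbp = u$sbp, on_bp_medication = u$on_bp_medication,
      total_cholesterol = u$total_cholesterol,
      family_history = u$family_history,
      sbp_known = if ("sbp_known" %in% names(u)) u$sbp_known else
        !is.na(u$sbp),
      cholesterol_known = if ("cholesterol_known" %in% names(u))
        u$cholesterol_known else !is.na(u$total_cholesterol)
    )
    res <- calculate_heart_age(p, coeffs, table, rules, bounds)
    data.frame(
      user_id = if ("user_id" %in% names(u)) u$user_id else i,
      age = u$age, sex = u$sex,
      heart_age_display = res$heart_age_display,
      heart_age_raw = res$heart_age_raw,
      category = res$category,
      risk = if (is.null(res$risk)) NA_real_ else res$risk$risk,
      sbp_imputed = res$sbp_imputed,
      cholesterol_imputed = res$cholesterol_imputed,
      blocked = any(res$advisories$severity == "range_error"),
      advisories = paste(res$advisories$message, collapse = " | "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

RESULT_CSV_COLUMNS <- c("user_id", "age", "sex", "heart_age_display",
                        "heart_age_raw", "category", "risk",
                        "sbp_imputed", "cholesterol_imputed", "blocked",
                        "advisories")

#' Write heart-age results to CSV
#'
#' UTF-8, comma-delimited, RFC 4180 quoting, stable column order;
#' logical columns serialize as `true`/`false` and censored heart ages
#' as their display strings (`"<35"`, `">=85"`). [read_results_csv()]
#' round-trips the file losslessly.
#'
#' @param results Output of [calculate_heart_ages()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  stopifnot(is.data.frame(results))
  missing <- setdiff(RESULT_CSV_COLUMNS, names(results))
  if (length(missing)) {
    stop("results are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- results[, RESULT_CSV_COLUMNS, drop = FALSE]
  for (f in c("sbp_imputed", "cholesterol_imputed", "blocked")) {
    out[[f]] <- ifelse(out[[f]], "true", "false")
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a results CSV written by [write_results_csv()]
#'
#' @param path File path.
#' @return A typed data frame with the documented result columns.
#' @export
read_results_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(RESULT_CSV_COLUMNS, names(raw))
  if (length(missing)) {
    stop("results file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data.frame(
    user_id = as.integer(raw$user_id),
    age = as.numeric(raw$age), sex = raw$sex,
    heart_age_display = ifelse(raw$heart_age_display == "",
                               NA_character_, raw$heart_age_display),
    heart_age_raw = suppressWarnings(as.numeric(raw$heart_age_raw)),
    category = ifelse(raw$category == "", NA_character_, raw$category),
    risk = suppressWarnings(as.numeric(raw$risk)),
    sbp_imputed = parse_bool(raw$sbp_imputed),
    cholesterol_imputed = parse_bool(raw$cholesterol_imputed),
    blocked = parse_bool(raw$blocked),
    advisories = raw$advisories,
    stringsAsFactors = FALSE
  )
}

#' Write a JSON run manifest
#'
#' Every command-line run emits one manifest tying its outputs to the
#' exact configuration (MD5 hash), seed, inputs and package version.
#'
#' @param command Subcommand name.
#' @param config_path Configuration file used, or `NA`.
#' @param seed Integer seed, or `NA`.
#' @param inputs,outputs Character vectors of file paths.
#' @param path Where to write the manifest; default is the first
#'   output path with a `.manifest.json` suffix.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(command, config_path = NA, seed = NA,
                           inputs = character(0),
                           outputs = character(0),
                           path = NULL) {
  if (is.null(path)) {
    stopifnot(length(outputs) >= 1)
    path <- paste0(outputs[1], ".manifest.json")
  }
  manifest <- list(
    command = command,
    config = if (is.na(config_path)) NULL else config_path,
    config_md5 = if (!is.na(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else NULL,
    seed = if (is.na(seed)) NULL else as.integer(seed),
    inputs = as.list(inputs), outputs = as.list(outputs),
    package_version =
      as.character(utils::packageVersion("heartage")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
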