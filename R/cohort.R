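# Reserved (non-parameter) columns of the cohort table. External clock score
# columns use the "score_" prefix; everything else is a clinical parameter.
.cohort_reserved <- c(
  "id", "sex", "chron_age", "follow_up_time", "event", "cause_of_death",
  "age_top_coded", "dsst_score", "walk_time", "work_able", "true_death_time"
)

.is_score_col <- function(nm) startsWith(nm, "score_")
.is_adl_col <- function(nm) startsWith(nm, "adl_")

#' Clinical parameter columns of a cohort table
#'
#' A cohort table is a plain `data.frame` with one row per subject and a
#' fixed core schema (`id`, `sex`, `chron_age`, `follow_up_time`, `event`,
#' `cause_of_death`, `age_top_coded`, healthspan fields, optional
#' `score_<Clock>` columns). Every remaining column is treated as a named
#' clinical parameter in its native laboratory units.
#'
#' @param cohort A cohort `data.frame`.
#' @return Character vector of parameter column names.
#' @export
cohort_params <- function(cohort) {
  nm <- names(cohort)
  nm[!(nm %in% .cohort_reserved | .is_score_col(nm) | .is_adl_col(nm))]
}

#' Validate a cohort table
#'
#' Checks the core schema invariants: unique ids, sexes in
#' \{"male","female"\}, non-negative follow-up, events in
#' \{"died","censored"\} with a cause of death recorded for every death.
#'
#' @param cohort A cohort `data.frame`.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending column (and row where applicable).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("id", "sex", "chron_age", "follow_up_time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L) {
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) {
    stop("cohort column 'id': subject ids must be unique")
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    bad <- which(!cohort$sex %in% c("male", "female"))[1L]
    stop("cohort column 'sex', row ", bad, ": must be 'male' or 'female'")
  }
  if (any(!is.finite(cohort$chron_age)) || any(cohort$chron_age < 0)) {
    stop("cohort column 'chron_age': ages must be finite and non-negative")
  }
  bad <- which(!is.finite(cohort$follow_up_time) | cohort$follow_up_time < 0)
  if (length(bad) > 0L) {
    stop("cohort column 'follow_up_time', row ", bad[1L],
         ": must be finite and >= 0")
  }
  if (!all(cohort$event %in% c("died", "censored"))) {
    bad <- which(!cohort$event %in% c("died", "censored"))[1L]
    stop("cohort column 'event', row ", bad, ": must be 'died' or 'censored'")
  }
  if ("cause_of_death" %in% names(cohort)) {
    bad <- which(cohort$event == "died" &
                   (is.na(cohort$cause_of_death) | cohort$cause_of_death == ""))
    if (length(bad) > 0L) {
      stop("cohort column 'cause_of_death', row ", bad[1L],
           ": every death must have a cause recorded")
    }
  }
  invisible(cohort)
}

#' Read / write cohort tables
#'
#' Cohort tables are stored as comma-separated UTF-8 text with a header row,
#' dot decimals, and empty fields for missing values (never a numeric
#' sentinel). The writer formats numerics with 17 significant digits so a
#' write/read round trip is lossless for doubles. Unknown extra columns are
#' read and preserved untouched (they are treated as clinical parameters
#' unless prefixed `score_` or `adl_`).
#'
#' @param path File path.
#' @param cohort A cohort `data.frame`.
#' @return `read_cohort` returns a validated cohort `data.frame`;
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = "", check.names = FALSE)
  chr_cols <- c("id", "sex", "event", "cause_of_death", "work_able")
  for (cc in intersect(chr_cols, names(cohort))) {
    cohort[[cc]] <- as.character(cohort[[cc]])
  }
  for (cc in names(cohort)[.is_adl_col(names(cohort))]) {
    cohort[[cc]] <- as.character(cohort[[cc]])
  }
  if ("age_top_coded" %in% names(cohort)) {
    cohort$age_top_coded <- as.logical(cohort$age_top_coded)
  }
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}
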