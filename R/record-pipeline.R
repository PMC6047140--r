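#' Read and write episode-level records
#'
#' The episode CSV dialect has a header row and columns `infant_id`,
#' `unit_id`, `year`, `admission_date`, `discharge_date` (ISO 8601 dates),
#' `gestational_weeks` (completed weeks at birth) and `codes`
#' (semicolon-separated catalog tokens). A row that cannot be parsed is a
#' hard error reporting the row number: surveillance must not silently skip
#' malformed input.
#'
#' @param path File path.
#' @return `read_episodes()` returns the episode tibble; `write_episodes()`
#'   returns `path` invisibly.
#' @export
read_episodes <- function(path) {
  # readr warns about parse problems; we escalate them to hard errors below
  out <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      infant_id = readr::col_character(),
      unit_id = readr::col_character(),
      year = readr::col_integer(),
      admission_date = readr::col_date(),
      discharge_date = readr::col_date(),
      gestational_weeks = readr::col_integer(),
      codes = readr::col_character()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("unparseable episode rows: %s",
                  paste(unique(probs$row), collapse = ", ")),
          class = "neosurv_parse_error")
  }
  missing <- setdiff(episode_cols, names(out))
  if (length(missing)) {
    abort(sprintf("episode CSV missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "neosurv_parse_error")
  }
  out$codes[is.na(out$codes)] <- ""
  out[episode_cols]
}

#' @rdname read_episodes
#' @param episodes Episode tibble.
#' @export
write_episodes <- function(episodes, path) {
  readr::write_csv(episodes[episode_cols], path, progress = FALSE)
  invisible(path)
}

#' Clean episode records
#'
#' Mirrors the registry's preparation steps: exact duplicates (identical on
#' all fields) are collapsed to a single copy, and episodes with impossible
#' values are rejected with a machine-readable reason. Every input row is
#' classified exactly once; a row with several defects gets the first reason
#' in the order duplicate, gestation out of range, date inversion.
#'
#' Cleaning rules:
#' * `duplicate`: an identical earlier row was kept;
#' * `gestation_out_of_range`: gestational age missing or outside 22-44
#'   completed weeks;
#' * `date_inversion`: discharge date before admission date.
#'
#' @param episodes Episode tibble.
#' @return A list with `retained` (clean episodes) and `rejects` (rejected
#'   episodes with a `reason` column).
#' @export
#' @examples
#' ep <- tibble::tibble(
#'   infant_id = "a", unit_id = "U1", year = 2015L,
#'   admission_date = as.Date("2015-02-01"),
#'   discharge_date = as.Date("2015-02-05"),
#'   gestational_weeks = 99L, codes = ""
#' )
#' clean_episodes(ep)$rejects$reason
clean_episodes <- function(episodes) {
  episodes <- as_tibble(episodes)
  dup <- duplicated(episodes)
  ga_bad <- !dup & (is.na(episodes$gestational_weeks) |
                      episodes$gestational_weeks < 22 |
                      episodes$gestational_weeks > 44)
  date_bad <- !dup & !ga_bad &
    (is.na(episodes$admission_date) | is.na(episodes$discharge_date) |
       episodes$discharge_date < episodes$admission_date)

  reason <- rep(NA_character_, nrow(episodes))
  reason[dup] <- "duplicate"
  reason[ga_bad] <- "gestation_out_of_range"
  reason[date_bad] <- "date_inversion"

  keep <- is.na(reason)
  list(
    retained = episodes[keep, , drop = FALSE],
    rejects = mutate(episodes[!keep, , drop = FALSE],
                     reason = reason[!keep])
  )
}

#' Merge episodes into one record per infant
#'
#' Collapses the retained episodes of each infant into a single infant
#' record, the unit of case ascertainment: diagnosis codes are unioned across
#' episodes, the cohort year and gestational age are taken from the earliest
#' admission (the episode closest to birth), and the episode count is kept.
#' The operation is idempotent: merging an already-merged cohort changes
#' nothing.
#'
#' Gestational ages recorded more than one completed week apart across an
#' infant's episodes are flagged as internal inconsistencies; the
#' earliest-episode value is used and the conflict is reported in the
#' `ga_conflicts` attribute (a tibble of infant ids with their recorded
#' ranges).
#'
#' @param retained Cleaned episode tibble (see [clean_episodes()]).
#' @return A tibble with one row per `infant_id`: `year`,
#'   `gestational_weeks`, `codes` (sorted union, semicolon-separated) and
#'   `n_episodes`, with attribute `ga_conflicts`.
#' @export
merge_to_infants <- function(retained) {
  retained <- as_tibble(retained)
  if (nrow(retained) == 0) {
    out <- tibble(infant_id = character(), year = integer(),
                  gestational_weeks = integer(), codes = character(),
                  n_episodes = integer())
    attr(out, "ga_conflicts") <- tibble(infant_id = character(),
                                        ga_min = integer(), ga_max = integer(),
                                        reason = character())
    return(out)
  }
  ord <- order(retained$infant_id, retained$admission_date)
  x <- retained[ord, , drop = FALSE]
  grp <- x$infant_id
  first <- !duplicated(grp)

  code_list <- split_codes(x$codes)
  merged_codes <- tapply(code_list, grp,
                         function(l) paste(sort(unique(unlist(l))), collapse = ";"))
  ga_min <- tapply(x$gestational_weeks, grp, min)
  ga_max <- tapply(x$gestational_weeks, grp, max)
  n_ep <- tapply(grp, grp, length)

  ids <- x$infant_id[first]
  out <- tibble(
    infant_id = ids,
    year = x$year[first],
    gestational_weeks = x$gestational_weeks[first],
    codes = as.character(merged_codes[ids]),
    n_episodes = as.integer(n_ep[ids])
  )
  conflict <- (ga_max - ga_min) > 1
  attr(out, "ga_conflicts") <- tibble(
    infant_id = ids[conflict[ids]],
    ga_min = as.integer(ga_min[ids[conflict[ids]]]),
    ga_max = as.integer(ga_max[ids[conflict[ids]]]),
    reason = rep("gestation_inconsistent", sum(conflict[ids]))
  )
  out
}
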